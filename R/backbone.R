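# Collinearity-rule product prediction: monomer chains for NRPS lines and
# chemistry summaries for PKS lines.

.module_has <- function(m, kind) any(m$tokens$kind == kind)
.module_c_subtype <- function(m) {
  q <- m$tokens$qualifier[m$tokens$kind == "C"]
  if (length(q) == 0) NA_character_ else q[1]
}

# default per-A-module substrate calls from the parsed qualifiers
.default_calls <- function(line) {
  a_modules <- Filter(function(m) .module_has(m, "A"), line$modules)
  lapply(a_modules, function(m) {
    arow <- m$tokens[m$tokens$kind == "A", ][1, ]
    if (is.na(arow$qualifier))
      structure(list(monomer = "x", confidence = "unknown",
                     evidence = character(), code_best_match = NA_character_),
                class = "substrate_call")
    else
      structure(list(monomer = arow$qualifier,
                     confidence = if (arow$tentative) "tentative"
                                  else "confirmed",
                     evidence = character(), code_best_match = NA_character_),
                class = "substrate_call")
  })
}

.as_call <- function(x) {
  if (inherits(x, "substrate_call")) return(x)
  if (is.na(x)) return(NULL)
  structure(list(monomer = x, confidence = "confirmed",
                 evidence = character(), code_best_match = NA_character_),
            class = "substrate_call")
}

.monomer_display <- function(label) {
  if (label %in% names(.MONOMER_DISPLAY)) unname(.MONOMER_DISPLAY[label])
  else label
}

#' Predict the nonribosomal peptide backbone of an assembly line
#'
#' Walks the modules in collinear order and emits one product position per
#' chain-building module: `s` for a loading module without an A domain (the
#' starter molecule), the substrate label for an A-domain module (`x` when
#' the substrate is unknown), `y` for a condensation module that carries a
#' thiolation domain but no A domain, and `pk` for an interleaved PKS
#' module. A methyltransferase in the module adds an `m` prefix; an
#' epimerization domain adds a `d` prefix unless the module is the terminal
#' one (a terminal epimerization has no downstream acceptor C domain to
#' read it out). A module led by a modifying C subtype (`C_M`) loading
#' serine emits dehydroalanine (`Dha`); a heterocyclization-led module
#' loading cysteine emits a thiazoline (`Thz(Cys)`). A CoA-ligase loading
#' module with a known starter substrate emits that label.
#'
#' @param line an `assembly_line` with at least one NRPS module.
#' @param calls optional per-A-module substrate calls overriding the calls
#'   derived from the parsed qualifiers: a list or vector with one entry
#'   per A-containing module in line order, each a `substrate_call`, a
#'   monomer label, or `NA` to keep the default.
#' @return an object of class `monomer_chain`: list with `tokens`
#'   (character vector of positions), `terminated` (TE/TD reached),
#'   `te_ambiguous` (more than one chain-release domain) and
#'   `iterative_hint`.
#' @export
predict_peptide <- function(line, calls = NULL) {
  stopifnot(inherits(line, "assembly_line"))
  is_nrps <- vapply(line$modules, function(m)
    m$kind %in% c("nrps_loading", "nrps_extension") ||
      .module_has(m, "A"), logical(1))
  if (!any(is_nrps))
    stop("assembly line has no NRPS modules; see predict_polyketide()")

  defaults <- .default_calls(line)
  if (!is.null(calls)) {
    if (length(calls) != length(defaults))
      stop("calls must have one entry per A-containing module (",
           length(defaults), ")")
    for (i in seq_along(calls)) {
      ov <- .as_call(calls[[i]])
      if (!is.null(ov)) defaults[[i]] <- ov
    }
  }

  emits <- function(m) {
    if (.module_has(m, "KS")) return(TRUE)                      # pk
    if (.module_has(m, "A")) return(TRUE)                       # residue
    if (m$kind %in% c("nrps_loading", "pks_loading")) return(TRUE)  # s
    if (m$kind == "nrps_extension" && m$carrier_present) return(TRUE)  # y
    FALSE
  }
  emitting <- which(vapply(line$modules, emits, logical(1)))
  last_emit <- if (length(emitting)) max(emitting) else 0L

  tokens <- character()
  a_idx <- 0L
  for (i in seq_along(line$modules)) {
    m <- line$modules[[i]]
    if (.module_has(m, "A")) a_idx <- a_idx + 1L
    if (!(i %in% emitting)) next
    if (.module_has(m, "KS")) { tokens <- c(tokens, "pk"); next }
    if (!.module_has(m, "A")) {
      if (m$kind %in% c("nrps_loading", "pks_loading")) {
        col <- m$tokens[m$tokens$kind == "CoL", ]
        lab <- if (nrow(col) && !is.na(col$qualifier[1]))
          .monomer_display(col$qualifier[1]) else "s"
        tokens <- c(tokens, lab)
      } else tokens <- c(tokens, "y")
      next
    }
    call <- defaults[[a_idx]]
    mono <- call$monomer
    subtype <- .module_c_subtype(m)
    if (!is.na(subtype) && subtype == "M" && identical(mono, "ser")) {
      tokens <- c(tokens, "Dha"); next
    }
    if (!is.na(subtype) && subtype == "Cy" && identical(mono, "cys")) {
      tokens <- c(tokens, "Thz(Cys)"); next
    }
    lab <- if (identical(mono, "x")) "x" else .monomer_display(mono)
    if (.module_has(m, "MT")) lab <- paste0("m", lab)
    if (.module_has(m, "E") && i != last_emit) lab <- paste0("d", lab)
    tokens <- c(tokens, lab)
  }

  terminated <- any(vapply(line$modules, function(m)
    any(m$tokens$kind %in% c("TE", "TD")), logical(1)))
  structure(list(tokens = tokens, terminated = terminated,
                 te_ambiguous = line$n_te >= 2L,
                 iterative_hint = line$n_te >= 2L),
            class = "monomer_chain")
}

#' @export
format.monomer_chain <- function(x, ...) paste(x$tokens, collapse = "-")

#' @export
print.monomer_chain <- function(x, ...) {
  cat(format(x),
      if (x$terminated) " [terminated]" else "",
      if (x$te_ambiguous) " [multiple release domains]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Chain length of a predicted product
#'
#' Printed peptide-size words mix two conventions: a "heptapeptide" may
#' count the starter position while a "nonapeptide" counts amino-acid
#' positions after the starter. Both are available: `tokens` counts every
#' position (starter and polyketide positions included), `residues` counts
#' amino-acid positions only (`x` and `y` included, `s` and `pk` excluded).
#'
#' @param chain a `monomer_chain`.
#' @param count `"tokens"` (default) or `"residues"`.
#' @return integer.
#' @export
chain_length <- function(chain, count = c("tokens", "residues")) {
  stopifnot(inherits(chain, "monomer_chain"))
  count <- match.arg(count)
  if (count == "tokens") return(length(chain$tokens))
  sum(!chain$tokens %in% c("s", "pk"))
}

#' Monomer composition of a predicted product
#'
#' @param chain a `monomer_chain`.
#' @return named integer vector of counts per position label (`x`, `y`,
#'   `s`, `pk` reported under their own names).
#' @export
composition <- function(chain) {
  stopifnot(inherits(chain, "monomer_chain"))
  if (length(chain$tokens) == 0) return(integer(0))
  tab <- table(chain$tokens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Polyketide chemistry summary of an assembly line
#'
#' Derives the product-level PKS features from the module count and the
#' reduction-state census: each extension module adds two backbone carbons;
#' a DH-KR pair yields a C=C double bond, a lone KR a hydroxyl, DH-ER-KR a
#' fully reduced methylene. A product with at least `polyene_threshold`
#' double bonds is called a polyene.
#'
#' @param line an `assembly_line` with at least one PKS module.
#' @param polyene_threshold minimum number of C=C double bonds for a
#'   polyene call; default 3.
#' @return an object of class `polyketide_features` with fields
#'   `module_count`, `chain_carbons`, `double_bonds`, `hydroxyls`,
#'   `fully_reduced`, `polyene`, `enediyne_flag`, `type3_starter`.
#' @export
predict_polyketide <- function(line, polyene_threshold = 3) {
  stopifnot(inherits(line, "assembly_line"))
  n <- count_pks_modules(line)
  if (n == 0) stop("assembly line has no PKS modules")
  census <- reduction_census(line)
  structure(list(module_count = n,
                 chain_carbons = 2L * n,
                 double_bonds = unname(census["dh_kr"]),
                 hydroxyls = unname(census["kr_only"]),
                 fully_reduced = unname(census["dh_er_kr"]),
                 polyene = unname(census["dh_kr"]) >= polyene_threshold,
                 enediyne_flag = is_enediyne_pks(line),
                 type3_starter = line$has_type3_ks),
            class = "polyketide_features")
}

#' @export
print.polyketide_features <- function(x, ...) {
  cat(sprintf(paste0("<polyketide_features> %d modules (C%d chain), ",
                     "%d C=C, %d OH, %d reduced%s%s%s\n"),
              x$module_count, x$chain_carbons, x$double_bonds, x$hydroxyls,
              x$fully_reduced,
              if (x$polyene) ", polyene" else "",
              if (x$enediyne_flag) ", enediyne signature" else "",
              if (x$type3_starter) ", type-III starter" else ""))
  invisible(x)
}
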