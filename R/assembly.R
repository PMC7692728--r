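# Assembly-line reconstruction: merge ordered ORF architectures into one
# module sequence under the collinearity rule, tolerant of modules split
# across ORF boundaries, and compute module/domain-state counts.

.PKS_PART <- c("AT", "KR", "DH", "ER", "ACP")   # extend, never start
.MODULE_STARTER <- c("KS", "C", "CoL", "FkbH")

.is_pks_module <- function(tokens)
  any(tokens$kind %in% c("KS", "CoL", "FkbH"))
.is_nrps_module <- function(tokens)
  any(tokens$kind %in% c("C", "A")) && !any(tokens$kind == "KS")

#' Merge a gene cluster's ORFs into a single assembly line
#'
#' Applies the collinearity rule to the concatenated domain tokens of a
#' cluster's ORFs (table order; strand marks are annotation only). A new PKS
#' module opens at every KS token and a new NRPS module at every C token (or
#' at the first A/T before any C); CoL and FkbH open loading-type modules.
#' Tokens between module starts join the open module across ORF boundaries,
#' so a KR printed on the next protein still pairs with its module's DH. PKS
#' part domains (AT, KR, DH, ER, ACP) extend the open PKS module only if
#' that domain kind is not already present; a duplicate kind rejects the
#' rest of the ORF's unstarted run to the standalone list, which is how
#' free-standing trans-acting ER and ACP proteins are recognised; an ORF
#' made of two or more AT domains (a trans-AT didomain protein) is placed
#' standalone as a whole.
#' Free-standing A proteins in a PKS context (an ORF of only A/TE/TD
#' domains) are standalone; in an NRPS context an A extends an A-less
#' module or opens a new one. Type-III KS tokens are always standalone and
#' set `has_type3_ks`.
#'
#' @param cluster a `gene_cluster`.
#' @return an object of class `assembly_line`: list with `cluster_id`,
#'   `strain`, `modules` (each a list with `kind`, `tokens`,
#'   `carrier_present`, `reduction_state`, `modifications`), `standalone`
#'   (token data frame), `has_type3_ks` and `n_te`.
#' @export
assemble_line <- function(cluster) {
  stopifnot(inherits(cluster, "gene_cluster"))
  modules <- list()       # list of token data frames
  standalone <- .empty_tokens()
  has_ks3 <- FALSE
  cur <- 0L               # index of the open module, 0 = none
  orf_rejected <- FALSE   # current ORF's extension run was rejected

  push_module <- function(tok) {
    modules[[length(modules) + 1L]] <<- tok
    cur <<- length(modules)
    orf_rejected <<- FALSE
  }
  extend <- function(tok) {
    modules[[cur]] <<- rbind(modules[[cur]], tok)
  }
  drop_standalone <- function(tok) {
    standalone <<- rbind(standalone, tok)
  }

  for (orf in cluster$orfs) {
    tk <- orf$tokens
    orf_rejected <- FALSE
    pks_context <- cur > 0L && .is_pks_module(modules[[cur]])
    # free-standing A protein in PKS context
    all_a <- all(tk$kind %in% c("A", "TE", "TD")) && any(tk$kind == "A")
    # free-standing multi-AT protein: the canonical trans-AT signature
    all_at <- nrow(tk) >= 2L && all(tk$kind == "AT")
    if ((all_a && pks_context) || all_at) {
      for (i in seq_len(nrow(tk))) drop_standalone(tk[i, ])
      next
    }
    for (i in seq_len(nrow(tk))) {
      tok <- tk[i, ]
      kind <- tok$kind
      if (kind == "KS3") {
        has_ks3 <- TRUE
        drop_standalone(tok)
      } else if (kind %in% c("KS", "C", "CoL", "FkbH")) {
        push_module(tok)
      } else if (kind == "A") {
        if (cur == 0L) {
          push_module(tok)
        } else if (.is_nrps_module(modules[[cur]]) ||
                   !any(modules[[cur]]$kind %in% c("KS", "CoL", "FkbH"))) {
          if (any(modules[[cur]]$kind == "A")) push_module(tok)
          else extend(tok)
        } else {
          push_module(tok)   # ORF carries more than a lone A: open a module
        }
      } else if (kind %in% c("T", "E")) {
        if (cur > 0L && (.is_nrps_module(modules[[cur]]) ||
                         all(modules[[cur]]$kind %in%
                             c("T", "CoL", "FkbH", "MT", "E", "TE", "TD"))))
          extend(tok)
        else if (cur == 0L && kind == "T")
          push_module(tok)               # carrier-only loading module
        else
          drop_standalone(tok)
      } else if (kind == "MT") {
        if (cur > 0L && !orf_rejected) extend(tok) else drop_standalone(tok)
      } else if (kind %in% c("TE", "TD")) {
        if (cur > 0L) extend(tok) else drop_standalone(tok)
      } else if (kind %in% .PKS_PART) {
        if (cur > 0L && !orf_rejected &&
            (.is_pks_module(modules[[cur]]) ||
             nrow(modules[[cur]]) == 0L) &&
            !any(modules[[cur]]$kind == kind)) {
          extend(tok)
        } else {
          drop_standalone(tok)
          if (cur > 0L && .is_pks_module(modules[[cur]])) orf_rejected <- TRUE
        }
      } else {
        drop_standalone(tok)
      }
    }
  }

  ann <- lapply(seq_along(modules), function(i)
    .annotate_module(modules[[i]], first = i == 1L))
  structure(list(cluster_id = cluster$cluster_id, strain = cluster$strain,
                 modules = ann, standalone = standalone,
                 has_type3_ks = has_ks3,
                 n_te = sum(vapply(modules, function(m)
                   sum(m$kind %in% c("TE", "TD")), integer(1))) +
                   sum(standalone$kind %in% c("TE", "TD"))),
            class = "assembly_line")
}

.annotate_module <- function(tokens, first = FALSE) {
  kinds <- tokens$kind
  has_ks <- any(kinds == "KS")
  has_carrier <- any(kinds %in% c("T", "ACP"))
  is_loading <- first &&
    (!any(kinds %in% c("KS", "C")) ||
       any(kinds %in% c("CoL", "FkbH")) ||
       any(kinds == "KS" & !is.na(tokens$qualifier) &
             tokens$qualifier == "first") ||
       any(kinds == "C" & !is.na(tokens$qualifier) &
             tokens$qualifier == "S"))
  pks <- has_ks || any(kinds %in% c("CoL", "FkbH"))
  nrps <- !has_ks && any(kinds %in% c("C", "A"))
  kind <- if (is_loading && pks) "pks_loading"
  else if (is_loading) "nrps_loading"
  else if (has_ks) "pks_extension"
  else if (nrps) "nrps_extension"
  else if (all(kinds %in% c("TE", "TD"))) "termination_only"
  else "trans_acting"
  reduction <- NA_character_
  if (has_ks) {
    reduction <- if (all(c("DH", "ER", "KR") %in% kinds)) "dh_er_kr"
    else if (all(c("DH", "KR") %in% kinds)) "dh_kr"
    else if ("KR" %in% kinds) "kr_only"
    else "none"
  }
  mods <- character()
  if (nrps || kind == "nrps_loading") {
    csub <- tokens$qualifier[kinds == "C"]
    if ("MT" %in% kinds) mods <- c(mods, "methylated")
    if ("E" %in% kinds) mods <- c(mods, "epimerized")
    if (length(csub) && !is.na(csub[1]) && csub[1] == "M")
      mods <- c(mods, "dehydrated")
    if (length(csub) && !is.na(csub[1]) && csub[1] == "Cy")
      mods <- c(mods, "heterocyclized")
  }
  list(kind = kind, tokens = tokens, carrier_present = has_carrier,
       reduction_state = reduction, modifications = mods)
}

#' @export
print.assembly_line <- function(x, ...) {
  cat(sprintf("<assembly_line> %s (%s): %d module(s), %d standalone domain(s)%s\n",
              x$cluster_id, x$strain, length(x$modules), nrow(x$standalone),
              if (x$has_type3_ks) ", type-III KS present" else ""))
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    arch <- structure(list(locus_tag = NA, strand = "forward",
                           length_aa = NA, tokens = m$tokens,
                           boundaries = integer()),
                      class = "orf_architecture")
    cat(sprintf("  [%d] %-14s %s%s\n", i, m$kind,
                serialize_architecture(arch),
                if (!is.na(m$reduction_state) && m$reduction_state != "none")
                  paste0("  (", m$reduction_state, ")") else ""))
  }
  if (nrow(x$standalone))
    cat("  standalone:", paste(x$standalone$kind, collapse = ", "), "\n")
  invisible(x)
}

#' Count PKS extension/loading modules
#'
#' The module count of a PKS assembly line equals the number of KS domains
#' placed in modules (the loading-module KS included, free-standing
#' type-III KS excluded) — the convention that reproduces printed counts
#' such as the twelve modules of t1pks-7.
#'
#' @param line an `assembly_line`.
#' @return integer count.
#' @export
count_pks_modules <- function(line) {
  stopifnot(inherits(line, "assembly_line"))
  sum(vapply(line$modules, function(m) sum(m$tokens$kind == "KS"),
             integer(1)))
}

#' Count NRPS modules
#'
#' The NRPS module count equals the number of A domains placed in modules
#' (standalone A proteins excluded).
#'
#' @param line an `assembly_line`.
#' @return integer count.
#' @export
count_nrps_modules <- function(line) {
  stopifnot(inherits(line, "assembly_line"))
  sum(vapply(line$modules, function(m) sum(m$tokens$kind == "A"),
             integer(1)))
}

#' Reduction-state census of the PKS modules
#'
#' Assigns every KS-containing module to exactly one reduction state:
#' `kr_only` (KR, no DH: hydroxyl), `dh_kr` (DH and KR, no ER: C=C double
#' bond), `dh_er_kr` (DH, ER and KR: fully reduced methylene) or `none`.
#'
#' @param line an `assembly_line`.
#' @return named integer vector with elements `kr_only`, `dh_kr`,
#'   `dh_er_kr`, `none`.
#' @export
reduction_census <- function(line) {
  stopifnot(inherits(line, "assembly_line"))
  states <- vapply(line$modules, function(m) m$reduction_state, character(1))
  states <- states[!is.na(states)]
  c(kr_only = sum(states == "kr_only"),
    dh_kr = sum(states == "dh_kr"),
    dh_er_kr = sum(states == "dh_er_kr"),
    none = sum(states == "none"))
}

# total tokens in a line (modules + standalone); used by conservation tests
.line_token_count <- function(line) {
  sum(vapply(line$modules, function(m) nrow(m$tokens), integer(1))) +
    nrow(line$standalone)
}
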