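# A-domain substrate consensus and C-domain subtype semantics.

#' Fractional identity of two specificity-conferring codes
#'
#' The ~10 active-site residues of an adenylation domain (its
#' specificity-conferring code) predict the amino acid it loads; two codes
#' are compared position-by-position.
#'
#' @param a,b character scalars of equal length (typically 10, uppercase).
#' @return fraction of matching positions in `[0, 1]`.
#' @examples
#' code_identity("DAWEVGLVDK", "DAWEGGLVDK")  # 0.9
#' @export
code_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb))
    stop("specificity codes have different lengths (", length(ca), " vs ",
         length(cb), ")")
  if (length(ca) == 0) stop("empty specificity code")
  mean(ca == cb)
}

#' Consensus substrate call for an A domain
#'
#' Implements the two-predictor consensus rule: a substrate is `confirmed`
#' when two independent predictors agree, or when the domain's
#' specificity-conferring code is at least `threshold` identical to the
#' reference code of the predicted substrate. A primary-only prediction is
#' retained as `tentative`; no prediction at all yields the unknown monomer
#' `"x"`.
#'
#' @param pred_primary substrate label from the primary predictor, or `NA`.
#' @param pred_secondary substrate label from a second predictor, or `NA`.
#' @param code the domain's specificity-conferring code, or `NA`.
#' @param reference_codes named character vector mapping substrate labels to
#'   reference codes (see [reference_codes()]).
#' @param threshold identity fraction required for a code match; default
#'   0.9, applied inclusively so that a 9/10 match confirms.
#' @return an object of class `substrate_call`: list with `monomer`
#'   (label or `"x"`), `confidence` (`confirmed`/`tentative`/`unknown`) and
#'   `evidence` (subset of `predictor_agreement`, `code_match`; a
#'   `code_match` records the best-matching reference monomer as
#'   `code_best_match` attribute-style field).
#' @export
consensus_substrate <- function(pred_primary = NA, pred_secondary = NA,
                                code = NA,
                                reference_codes = character(),
                                threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  pp <- if (is.null(pred_primary)) NA else pred_primary
  ps <- if (is.null(pred_secondary)) NA else pred_secondary
  evidence <- character()
  best_match <- NA_character_
  if (is.na(pp)) {
    call <- list(monomer = "x", confidence = "unknown", evidence = evidence,
                 code_best_match = best_match)
    return(structure(call, class = "substrate_call"))
  }
  if (!is.na(ps) && identical(pp, ps)) evidence <- c(evidence, "predictor_agreement")
  if (!is.na(code) && length(reference_codes)) {
    ids <- vapply(reference_codes, code_identity, numeric(1), a = code)
    best_match <- names(reference_codes)[which.max(ids)]
    if (pp %in% names(reference_codes) &&
        ids[[pp]] >= threshold)
      evidence <- c(evidence, "code_match")
  }
  confidence <- if (length(evidence)) "confirmed" else "tentative"
  structure(list(monomer = pp, confidence = confidence, evidence = evidence,
                 code_best_match = best_match),
            class = "substrate_call")
}

#' @export
print.substrate_call <- function(x, ...) {
  cat(sprintf("<substrate_call> %s (%s)%s\n", x$monomer, x$confidence,
              if (length(x$evidence))
                paste0(" [", paste(x$evidence, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Bundled reference specificity codes
#'
#' Reads the packaged table of reference specificity-conferring codes (only
#' codes appearing in the analysed clusters are bundled; the table is an
#' editable TSV with columns `monomer` and `code`).
#'
#' @param path optional path to an alternative code table.
#' @return named character vector, labels to codes.
#' @export
reference_codes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "specificity_codes.tsv",
                        package = "bgcline", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stats::setNames(df$code, df$monomer)
}

.C_EFFECTS <- c(LCL = "link_L", DCL = "link_after_D",
                Du = "epimerize_and_link", M = "modify",
                S = "acylate_start", Cy = "heterocyclize")

#' Functional effect of a condensation-domain subtype
#'
#' Maps a C-domain subtype to its effect on the growing peptide: `LCL`
#' links two L-residues; `DCL` links an L-residue to a chain ending in a
#' D-residue; the dual E/C domain epimerizes and links; `M` modifies the
#' incorporated residue (e.g. dehydrates serine to dehydroalanine); the
#' starter domain acylates the first residue with a beta-hydroxy acid; `Cy`
#' forms the peptide bond and cyclizes Cys/Ser/Thr to a (thia/oxa)zoline.
#'
#' @param subtype one of `LCL`, `DCL`, `Du`, `M`, `S`, `Cy`.
#' @return effect tag (character scalar).
#' @export
c_subtype_effect <- function(subtype) {
  if (!subtype %in% names(.C_EFFECTS))
    stop("unknown C-domain subtype: ", subtype)
  unname(.C_EFFECTS[subtype])
}
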