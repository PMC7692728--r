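# Cluster-category derivation and architecture-signature flags.

#' Derive the category of an assembled cluster
#'
#' `t1pks` for modular-KS-only lines, `t3pks` for lines whose only
#' ketosynthase is a free-standing type-III KS, `t1pks_t3pks` for both
#' without NRPS modules, `nrps` for pure C/A/T lines, `pks_nrps` when NRPS
#' modules (or free-standing A/C domains) co-occur with any PKS (modular or
#' type-III).
#'
#' @param line an `assembly_line`.
#' @return one of `"t1pks"`, `"t3pks"`, `"t1pks_t3pks"`, `"nrps"`,
#'   `"pks_nrps"`.
#' @export
derive_category <- function(line) {
  stopifnot(inherits(line, "assembly_line"))
  if (length(line$modules) == 0 && nrow(line$standalone) == 0)
    stop("empty assembly line")
  has_mod_ks <- any(vapply(line$modules, function(m)
    any(m$tokens$kind == "KS"), logical(1)))
  has_nrps <- any(vapply(line$modules, function(m)
    any(m$tokens$kind %in% c("A", "C")), logical(1))) ||
    any(line$standalone$kind %in% c("A", "C"))
  has_ks3 <- line$has_type3_ks
  if (has_nrps && (has_mod_ks || has_ks3)) return("pks_nrps")
  if (has_mod_ks && has_ks3) return("t1pks_t3pks")
  if (has_mod_ks) return("t1pks")
  if (has_ks3) return("t3pks")
  if (has_nrps) return("nrps")
  stop("assembly line contains neither PKS nor NRPS modules")
}

#' Detect the iterative enediyne PKS signature
#'
#' The enediyne-warhead iterative PKS is recognised by its atypical
#' single-module architecture: KS, AT, KR and DH on one protein with KR
#' preceding DH (the canonical modular order is DH before KR) and no ACP in
#' the annotation.
#'
#' @param line an `assembly_line`.
#' @return logical.
#' @export
is_enediyne_pks <- function(line) {
  stopifnot(inherits(line, "assembly_line"))
  for (m in line$modules) {
    k <- m$tokens$kind
    if (!any(k == "KS")) next
    if (!all(c("AT", "KR", "DH") %in% k)) next
    if (any(k == "ACP")) next
    if (match("KR", k) < match("DH", k)) return(TRUE)
  }
  FALSE
}

#' Detect a trans-AT (AT-less) PKS assembly line
#'
#' True when at least one KS-containing extension module lacks an embedded
#' AT domain and the cluster supplies a free-standing (standalone) AT
#' protein to act in trans.
#'
#' @param line an `assembly_line`.
#' @return logical.
#' @export
is_at_less <- function(line) {
  stopifnot(inherits(line, "assembly_line"))
  trans_at <- any(line$standalone$kind == "AT")
  if (!trans_at) return(FALSE)
  any(vapply(line$modules, function(m) {
    k <- m$tokens$kind
    any(k == "KS") && !any(k == "AT") && m$kind == "pks_extension"
  }, logical(1)))
}
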