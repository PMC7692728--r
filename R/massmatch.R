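# Exact-mass dereplication of LC-MS ion peaks against candidate compounds.

.PROTON_MASS <- 1.00728  # Da

#' Protonated-ion m/z of a neutral compound
#'
#' @param exact_mass neutral monoisotopic mass in Da (vectorised).
#' @return the `[M+H]+` m/z, `exact_mass + 1.00728`.
#' @export
mh_plus <- function(exact_mass) {
  if (any(!is.finite(exact_mass)) || any(exact_mass <= 0))
    stop("exact_mass must be positive")
  exact_mass + .PROTON_MASS
}

#' Match observed ion peaks to candidate compounds by exact mass
#'
#' A peak matches a candidate when its m/z is within `tolerance_ppm` of the
#' candidate's `[M+H]+` value; candidates without any matching peak are
#' reported as absent explicitly.
#'
#' @param peaks data frame with at least an `mz` column (optionally
#'   `rt_min`, `strain`, `media`), as returned by [lcms_peaks()].
#' @param candidates data frame with columns `name` and `exact_mass`, as
#'   returned by [known_compounds()].
#' @param tolerance_ppm relative mass tolerance in parts per million;
#'   default 10 (a high-resolution Orbitrap-class instrument).
#' @return data frame with one row per candidate: `name`, `exact_mass`,
#'   `mh`, `n_matches`, `matched_mz` (comma-separated observed m/z values,
#'   `""` when absent), `absent` (logical).
#' @export
match_peaks <- function(peaks, candidates, tolerance_ppm = 10) {
  stopifnot(is.data.frame(peaks), is.data.frame(candidates),
            tolerance_ppm > 0)
  if (nrow(peaks) && any(peaks$mz <= 0)) stop("peak m/z must be positive")
  out <- candidates[, c("name", "exact_mass")]
  out$mh <- mh_plus(candidates$exact_mass)
  hits <- lapply(out$mh, function(mh) {
    if (!nrow(peaks)) return(numeric(0))
    peaks$mz[abs(peaks$mz - mh) / mh <= tolerance_ppm * 1e-6]
  })
  out$n_matches <- vapply(hits, length, integer(1))
  out$matched_mz <- vapply(hits, function(h)
    paste(format(h, trim = TRUE), collapse = ","), character(1))
  out$matched_mz[out$n_matches == 0] <- ""
  out$absent <- out$n_matches == 0
  rownames(out) <- NULL
  out
}

#' Strain-by-peak incidence matrix
#'
#' @param peaks data frame with columns `mz`, `rt_min`, `strain` (one row
#'   per strain in which a peak was observed).
#' @param strains optional strain order for the rows; defaults to order of
#'   appearance.
#' @return logical matrix, strains in rows, peaks (labelled
#'   `rt_min/mz`) in columns.
#' @export
presence_table <- function(peaks, strains = NULL) {
  stopifnot(is.data.frame(peaks))
  if (!nrow(peaks)) {
    return(matrix(logical(0), nrow = length(strains), ncol = 0,
                  dimnames = list(strains, character(0))))
  }
  key <- paste0(peaks$rt_min, "min/", peaks$mz)
  cols <- unique(key)
  if (is.null(strains)) strains <- unique(peaks$strain)
  m <- matrix(FALSE, length(strains), length(cols),
              dimnames = list(strains, cols))
  for (i in seq_len(nrow(peaks)))
    m[peaks$strain[i], key[i]] <- TRUE
  m
}

#' Packaged LC-MS peak list
#'
#' Representative ion peaks observed in the culture extracts of the four
#' Phytohabitans type strains (positive mode, `[M+H]+` assumed), one row
#' per strain in which a peak was seen, with retention time (min) and
#' culture media (TSA2 = double-diluted tryptic soy agar, ISP2_2 =
#' double-diluted ISP-2; semicolon-separated when both).
#'
#' @return data frame with columns `peak`, `rt_min`, `mz`, `strain`,
#'   `media`.
#' @export
lcms_peaks <- function() {
  path <- system.file("extdata", "lcms_peaks.csv", package = "bgcline",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged candidate-compound masses
#'
#' Known products attributable to the analysed gene clusters, with neutral
#' monoisotopic exact masses (Da), used to confirm the absence of their
#' `[M+H]+` ions from the culture extracts.
#'
#' @return data frame with columns `name`, `exact_mass`.
#' @export
known_compounds <- function() {
  path <- system.file("extdata", "known_compounds.csv", package = "bgcline",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
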