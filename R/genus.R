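# Genus-level sharing statistics over a multi-strain cluster inventory.

#' Summarise cluster sharing and per-strain category counts
#'
#' Computes, from an inventory with ortholog-group labels, the per-strain
#' category counts (categories re-derived from the assembled lines, not
#' read from the declared column), the total number of clusters, the number
#' of distinct cluster types (ortholog groups, each strain-specific cluster
#' counting as its own group), the number of groups shared by at least two
#' strains, and the strain-specific cluster counts.
#'
#' @param inv a `cluster_inventory`.
#' @return an object of class `genus_summary`: list with `per_strain`
#'   (data frame of category counts and totals, one row per strain),
#'   `total_clusters`, `distinct_types`, `shared_groups`,
#'   `unshared_clusters`, `specific_per_strain` (named integer vector).
#' @export
genus_summary <- function(inv) {
  stopifnot(inherits(inv, "cluster_inventory"))
  cl <- inv$clusters
  strains <- inv$strains
  cats <- vapply(cl, function(x) derive_category(assemble_line(x)),
                 character(1))
  cl_strain <- vapply(cl, `[[`, character(1), "strain")
  grp <- vapply(cl, `[[`, character(1), "ortholog_group")

  per <- do.call(rbind, lapply(strains, function(s) {
    cs <- cats[cl_strain == s]
    data.frame(strain = s,
               t1pks = sum(cs == "t1pks"),
               t3pks = sum(cs == "t3pks"),
               t1pks_t3pks = sum(cs == "t1pks_t3pks"),
               nrps = sum(cs == "nrps"),
               pks_nrps = sum(cs == "pks_nrps"),
               total = length(cs),
               stringsAsFactors = FALSE)
  }))

  members <- table(grp)
  shared <- names(members)[members >= 2]
  singleton <- names(members)[members == 1]
  specific <- vapply(strains, function(s)
    sum(grp %in% singleton & cl_strain == s), integer(1))

  structure(list(per_strain = per,
                 total_clusters = length(cl),
                 distinct_types = length(members),
                 shared_groups = length(shared),
                 unshared_clusters = sum(members[singleton]),
                 specific_per_strain = specific),
            class = "genus_summary")
}

#' @export
print.genus_summary <- function(x, ...) {
  cat(sprintf(paste0("<genus_summary> %d clusters, %d distinct types ",
                     "(%d shared groups, %d strain-specific)\n"),
              x$total_clusters, x$distinct_types, x$shared_groups,
              x$unshared_clusters))
  print(x$per_strain, row.names = FALSE)
  invisible(x)
}

#' Strain-by-strain ortholog-group co-occurrence matrix
#'
#' Off-diagonal cells count ortholog groups with members in both strains;
#' the diagonal holds per-strain cluster totals.
#'
#' @param inv a `cluster_inventory`.
#' @return symmetric integer matrix with strain dimnames.
#' @export
sharing_matrix <- function(inv) {
  stopifnot(inherits(inv, "cluster_inventory"))
  strains <- inv$strains
  grp <- vapply(inv$clusters, `[[`, character(1), "ortholog_group")
  cl_strain <- vapply(inv$clusters, `[[`, character(1), "strain")
  m <- matrix(0L, length(strains), length(strains),
              dimnames = list(strains, strains))
  for (g in unique(grp)) {
    ss <- unique(cl_strain[grp == g])
    for (a in ss) for (b in ss) if (a != b) m[a, b] <- m[a, b] + 1L
  }
  diag(m) <- as.integer(table(factor(cl_strain, levels = strains)))
  m
}

# module-level serialization of a cluster: one string per module
.module_strings <- function(cluster) {
  line <- assemble_line(cluster)
  vapply(line$modules, function(m) {
    arch <- structure(list(locus_tag = NA, strand = "forward",
                           length_aa = NA, tokens = m$tokens,
                           boundaries = integer()),
                      class = "orf_architecture")
    serialize_architecture(arch)
  }, character(1))
}

#' Architecture similarity of two clusters
#'
#' Label-free fallback for proposing ortholog groups: a normalized global
#' alignment of the two clusters' module-level strings. With the default
#' costs (match 1, mismatch 0, gap 0) the alignment score is the length of
#' the longest common subsequence of module strings, normalized by the
#' longer module count, so identical architectures score 1.
#'
#' @param a,b `gene_cluster` objects.
#' @param match,mismatch,gap alignment scores.
#' @return similarity in `[0, 1]`.
#' @export
architecture_similarity <- function(a, b, match = 1, mismatch = 0, gap = 0) {
  stopifnot(inherits(a, "gene_cluster"), inherits(b, "gene_cluster"))
  sa <- .module_strings(a)
  sb <- .module_strings(b)
  if (length(sa) == 0 && length(sb) == 0) return(1)
  if (length(sa) == 0 || length(sb) == 0) return(0)
  n <- length(sa); m <- length(sb)
  # Needleman-Wunsch on module strings
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- if (sa[i] == sb[j]) match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + sc, D[i, j + 1] + gap,
                           D[i + 1, j] + gap)
  }
  best <- D[n + 1, m + 1]
  denom <- match * max(n, m)
  if (denom <= 0) return(0)
  max(0, min(1, best / denom))
}
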