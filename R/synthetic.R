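# Seeded generators: assembly lines with known ground-truth products, random
# ORF re-splits, and multi-strain inventories with controlled sharing.

# run expr with a local RNG state seeded deterministically
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.display_to_label <- function() {
  x <- names(.MONOMER_DISPLAY)
  names(x) <- unname(.MONOMER_DISPLAY)
  x
}

# token strings for one product position; returns character vector of
# serialized domain words forming one module
.module_for_position <- function(token, first, last) {
  if (token == "s") {
    if (!first) stop("starter token 's' is only supported at position 1")
    return("T")
  }
  if (token == "pk") return(c("KS", "AT_m", "ACP"))
  if (token == "y") {
    if (first) stop("'y' (A-less position) is not supported at position 1")
    return(c("LCL", "T"))
  }
  if (token == "Dha") return(c("C_M", "A_ser", "T"))
  if (token == "Thz(Cys)") return(c("C_Cy", "A_cys", "T"))
  d2l <- .display_to_label()
  rest <- token
  d <- grepl("^d", rest) && !rest %in% names(d2l)
  if (d) rest <- sub("^d", "", rest)
  m <- grepl("^m", rest) && !rest %in% names(d2l)
  if (m) rest <- sub("^m", "", rest)
  if (d && last)
    stop("unsupported token '", token,
         "': a terminal epimerization is never read out")
  a <- if (rest == "x") "A"
  else if (rest %in% names(d2l))
    paste0("A_", d2l[[rest]])
  else stop("unsupported product token '", token, "'")
  words <- c(if (!first) "LCL", a, if (m) "MT", "T", if (d) "E")
  words
}

#' Generate a gene cluster with a known ground-truth product
#'
#' Inverts the collinearity rules: given a target peptide chain (product
#' tokens such as `s`, `x`, `Asn`, `dVal`, `mOrn`, `Dha`, `Thz(Cys)`, `pk`,
#' `y`) or a target polyketide reduction profile, emits a gene cluster
#' whose assembled line predicts exactly that product. The module sequence
#' is split across a seeded random number of ORFs (module boundaries need
#' not coincide with ORF boundaries, as in real genomes), with random
#' cosmetic strand marks.
#'
#' @param peptide character vector of product-chain tokens, or `NULL`.
#' @param polyketide list with `module_count` and optionally `double_bonds`
#'   (DH-KR modules), `hydroxyls` (KR-only), `fully_reduced` (DH-ER-KR), or
#'   `NULL`. Exactly one of `peptide`/`polyketide` must be given.
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @param n_orfs optional fixed number of ORFs; default seeded random.
#' @param cluster_id,strain labels for the emitted cluster.
#' @return a `gene_cluster`.
#' @export
generate_line <- function(peptide = NULL, polyketide = NULL, seed,
                          n_orfs = NULL, cluster_id = "synthetic-1",
                          strain = "synthetic") {
  if (is.null(peptide) == is.null(polyketide))
    stop("give exactly one of 'peptide' or 'polyketide'")
  if (!is.null(peptide)) {
    stopifnot(is.character(peptide), length(peptide) >= 1)
    words <- character()
    bounds <- integer()
    for (i in seq_along(peptide)) {
      mod <- .module_for_position(peptide[i], first = i == 1L,
                                  last = i == length(peptide))
      words <- c(words, mod)
      if (i < length(peptide)) bounds <- c(bounds, length(words))
    }
    words <- c(words, "TE")
    category <- if (any(peptide == "pk")) "pks_nrps" else "nrps"
  } else {
    mc <- polyketide$module_count
    db <- polyketide$double_bonds %||% 0L
    oh <- polyketide$hydroxyls %||% 0L
    fr <- polyketide$fully_reduced %||% 0L
    if (is.null(mc)) mc <- db + oh + fr
    if (mc < 1 || db + oh + fr > mc)
      stop("inconsistent polyketide spec: reduction states exceed modules")
    mods <- c(rep(list(c("KS", "AT_m", "DH", "KR", "ACP")), db),
              rep(list(c("KS", "AT_m", "KR", "ACP")), oh),
              rep(list(c("KS", "AT_m", "DH", "ER", "KR", "ACP")), fr),
              rep(list(c("KS", "AT_m", "ACP")), mc - db - oh - fr))
    words <- unlist(mods)
    words <- c(words, "TE")
    category <- "t1pks"
  }
  .with_seed(seed, {
    n <- length(words)
    k <- if (is.null(n_orfs)) sample(seq_len(min(n, max(1L, n %/% 2L))), 1L)
    else n_orfs
    if (k < 1 || k > n) stop("n_orfs must be in 1..", n)
    cuts <- if (k > 1) sort(sample(seq_len(n - 1L), k - 1L)) else integer()
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    orfs <- lapply(seq_len(k), function(i) {
      parse_architecture(paste(words[starts[i]:ends[i]], collapse = "/"),
                         locus_tag = sprintf("SYN_%04d0", i),
                         strand = sample(c("forward", "complement"), 1L,
                                         prob = c(0.8, 0.2)))
    })
    gene_cluster(cluster_id, strain, category, cluster_id, orfs)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-split a cluster's domain tokens across a different ORF partition
#'
#' Keeps the concatenated domain-token sequence (the assembly line) intact
#' while re-partitioning it into `n_orfs` contiguous ORFs with seeded
#' random cut points and cosmetic strand marks. All assembly counts and
#' product predictions are invariant under re-splitting.
#'
#' @param cluster a `gene_cluster`.
#' @param n_orfs number of ORFs in the new partition (1 to token count).
#' @param seed integer seed.
#' @return a `gene_cluster` with the same cluster metadata.
#' @export
resplit <- function(cluster, n_orfs, seed) {
  stopifnot(inherits(cluster, "gene_cluster"))
  tokens <- do.call(rbind, lapply(cluster$orfs, `[[`, "tokens"))
  n <- nrow(tokens)
  if (n_orfs < 1 || n_orfs > n)
    stop("n_orfs must be between 1 and the token count (", n, ")")
  .with_seed(seed, {
    cuts <- if (n_orfs > 1) sort(sample(seq_len(n - 1L), n_orfs - 1L))
    else integer()
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    orfs <- lapply(seq_len(n_orfs), function(i) {
      structure(list(locus_tag = sprintf("RSP_%04d0", i),
                     strand = sample(c("forward", "complement"), 1L,
                                     prob = c(0.8, 0.2)),
                     length_aa = NA_integer_,
                     tokens = tokens[starts[i]:ends[i], , drop = FALSE],
                     boundaries = integer()),
                class = "orf_architecture")
    })
    gene_cluster(cluster$cluster_id, cluster$strain,
                 cluster$declared_category, cluster$ortholog_group, orfs,
                 cluster$deduced_product)
  })
}

.SYN_MONOMERS <- c("asn", "ser", "gly", "orn", "val", "thr", "tyr", "asp",
                   "phe", "leu", "cys", "pro", "gln", "ala", "aad")

# random peptide product spec (no terminal d, starter optional)
.random_peptide_spec <- function() {
  len <- sample(2:6, 1)
  labs <- c(unname(.MONOMER_DISPLAY[.SYN_MONOMERS]), "x")
  toks <- sample(labs, len, replace = TRUE)
  if (stats::runif(1) < 0.4) toks <- c("s", toks)
  toks
}

#' Generate a multi-strain inventory with controlled sharing structure
#'
#' Builds `n_shared_groups` ortholog groups, each replicated into a seeded
#' random subset of strains (or subsets of the sizes given in
#' `shared_sizes`), plus the requested number of strain-specific clusters,
#' every cluster carrying a known ground-truth product.
#'
#' @param n_strains number of strains.
#' @param n_shared_groups number of ortholog groups spanning >= 2 strains.
#' @param n_specific_per_strain integer vector (recycled to `n_strains`)
#'   of strain-specific cluster counts.
#' @param seed integer seed.
#' @param shared_sizes optional integer vector of member counts (2 to
#'   `n_strains`) per shared group; default seeded random.
#' @return a `cluster_inventory`.
#' @export
generate_inventory <- function(n_strains, n_shared_groups,
                               n_specific_per_strain, seed,
                               shared_sizes = NULL) {
  stopifnot(n_strains >= 1, n_shared_groups >= 0)
  if (n_shared_groups > 0 && n_strains < 2)
    stop("shared groups need at least two strains")
  spec_counts <- rep_len(as.integer(n_specific_per_strain), n_strains)
  strains <- sprintf("strain%d", seq_len(n_strains))
  .with_seed(seed, {
    if (is.null(shared_sizes) && n_shared_groups > 0)
      shared_sizes <- sample(2:n_strains, n_shared_groups, replace = TRUE)
    if (n_shared_groups > 0)
      stopifnot(length(shared_sizes) == n_shared_groups,
                all(shared_sizes >= 2), all(shared_sizes <= n_strains))
    sub_seeds <- sample.int(2^20, n_shared_groups + sum(spec_counts) +
                              n_shared_groups * n_strains, replace = FALSE)
    clusters <- list()
    si <- 0L
    for (g in seq_len(n_shared_groups)) {
      members <- sort(sample(seq_len(n_strains), shared_sizes[g]))
      spec <- .random_peptide_spec()
      gid <- sprintf("shared-%d", g)
      for (s in members) {
        si <- si + 1L
        cl <- generate_line(peptide = spec, seed = sub_seeds[si],
                            cluster_id = gid, strain = strains[s])
        cl$ortholog_group <- gid
        clusters[[length(clusters) + 1L]] <- cl
      }
    }
    for (s in seq_len(n_strains)) {
      for (j in seq_len(spec_counts[s])) {
        si <- si + 1L
        cid <- sprintf("specific-%s-%d", strains[s], j)
        cl <- generate_line(peptide = .random_peptide_spec(),
                            seed = sub_seeds[si], cluster_id = cid,
                            strain = strains[s])
        cl$ortholog_group <- cid
        clusters[[length(clusters) + 1L]] <- cl
      }
    }
    cluster_inventory(clusters, strains = strains)
  })
}
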