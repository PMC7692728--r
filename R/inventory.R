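# Cluster inventory: gene clusters as ordered ORF architectures, multi-strain
# inventories, and the packaged Phytohabitans transcription.

.CATEGORIES <- c("t1pks", "t3pks", "t1pks_t3pks", "nrps", "pks_nrps")

#' Construct a gene cluster
#'
#' @param cluster_id cluster label, e.g. `"nrps-3"`; unique within a strain.
#' @param strain strain label.
#' @param declared_category one of `t1pks`, `t3pks`, `t1pks_t3pks`, `nrps`,
#'   `pks_nrps`.
#' @param ortholog_group label shared by orthologous clusters across strains;
#'   strain-specific clusters sit in singleton groups.
#' @param orfs list of `orf_architecture` objects in biosynthetic (table)
#'   order.
#' @param deduced_product optional free-text product annotation.
#' @return an object of class `gene_cluster`.
#' @export
gene_cluster <- function(cluster_id, strain, declared_category,
                         ortholog_group = cluster_id, orfs,
                         deduced_product = NA_character_) {
  stopifnot(is.character(cluster_id), nzchar(cluster_id))
  if (!declared_category %in% .CATEGORIES)
    stop("unknown category: ", declared_category)
  if (!is.list(orfs) || length(orfs) == 0)
    stop("cluster '", cluster_id, "' must contain at least one ORF")
  ok <- vapply(orfs, inherits, logical(1), "orf_architecture")
  if (!all(ok)) stop("orfs must be orf_architecture objects")
  structure(list(cluster_id = cluster_id, strain = strain,
                 declared_category = declared_category,
                 ortholog_group = ortholog_group, orfs = orfs,
                 deduced_product = deduced_product),
            class = "gene_cluster")
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster> %s [%s, %s] %d ORF(s)\n", x$cluster_id,
              x$strain, x$declared_category, length(x$orfs)))
  for (o in x$orfs) print(o)
  invisible(x)
}

#' Construct a multi-strain cluster inventory
#'
#' @param clusters list of `gene_cluster` objects.
#' @param strains ordered strain labels; defaults to order of first
#'   appearance.
#' @return an object of class `cluster_inventory`.
#' @export
cluster_inventory <- function(clusters, strains = NULL) {
  stopifnot(is.list(clusters))
  cl_strains <- vapply(clusters, function(x) x$strain, character(1))
  if (is.null(strains)) strains <- unique(cl_strains)
  if (!all(cl_strains %in% strains))
    stop("cluster strain not listed in strains: ",
         paste(setdiff(cl_strains, strains), collapse = ", "))
  ids <- paste(cl_strains, vapply(clusters, `[[`, character(1), "cluster_id"))
  if (anyDuplicated(ids))
    stop("duplicated cluster_id within a strain: ", ids[duplicated(ids)][1])
  # ortholog groups with >= 2 members must span distinct strains
  grp <- vapply(clusters, `[[`, character(1), "ortholog_group")
  for (g in unique(grp[duplicated(grp)])) {
    s <- cl_strains[grp == g]
    if (anyDuplicated(s))
      stop("ortholog group '", g, "' has two members in strain ",
           s[duplicated(s)][1])
  }
  structure(list(strains = strains, clusters = clusters),
            class = "cluster_inventory")
}

#' @export
print.cluster_inventory <- function(x, ...) {
  cat(sprintf("<cluster_inventory> %d clusters across %d strain(s): %s\n",
              length(x$clusters), length(x$strains),
              paste(x$strains, collapse = ", ")))
  invisible(x)
}

#' Extract one cluster from an inventory
#'
#' @param inv a `cluster_inventory`.
#' @param cluster_id cluster label.
#' @param strain strain label; may be omitted when the id is unambiguous.
#' @return a `gene_cluster`.
#' @export
get_cluster <- function(inv, cluster_id, strain = NULL) {
  stopifnot(inherits(inv, "cluster_inventory"))
  hit <- Filter(function(x) x$cluster_id == cluster_id &&
                  (is.null(strain) || x$strain == strain), inv$clusters)
  if (length(hit) == 0) stop("no such cluster: ", cluster_id)
  if (length(hit) > 1)
    stop("cluster id '", cluster_id, "' is present in several strains; ",
         "give a strain")
  hit[[1]]
}

#' Restrict an inventory to selected strains
#'
#' @param inv a `cluster_inventory`.
#' @param strains strain labels to keep.
#' @return a `cluster_inventory`.
#' @export
subset_inventory <- function(inv, strains) {
  stopifnot(inherits(inv, "cluster_inventory"))
  keep <- Filter(function(x) x$strain %in% strains, inv$clusters)
  cluster_inventory(keep, strains = intersect(inv$strains, strains))
}

.INVENTORY_COLUMNS <- c("strain", "cluster_id", "ortholog_group",
                        "declared_category", "locus_tag", "strand",
                        "length_aa", "domain_string", "deduced_product")

#' Load a cluster inventory from TSV
#'
#' One row per ORF; header columns `strain`, `cluster_id`, `ortholog_group`,
#' `declared_category`, `locus_tag`, `strand` (`+`/`-`), `length_aa` (may be
#' `NA`), `domain_string`, and optional `deduced_product` (carried on the
#' first row of a cluster). Row order within a cluster is the biosynthetic
#' order of the ORFs; clusters appear in file order.
#'
#' @param path path to a TSV file.
#' @return a `cluster_inventory`.
#' @export
load_inventory <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  need <- setdiff(.INVENTORY_COLUMNS[1:8], names(df))
  if (length(need))
    stop("inventory file is missing column(s): ", paste(need, collapse = ", "))
  if (!"deduced_product" %in% names(df)) df$deduced_product <- ""
  clusters <- list()
  key <- paste(df$strain, df$cluster_id)
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    orfs <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (!r$strand %in% c("+", "-"))
        stop("row ", rownames(rows)[i], " (", r$locus_tag,
             "): strand must be '+' or '-'")
      len <- suppressWarnings(as.integer(r$length_aa))
      if (!is.na(len) && len <= 0)
        stop("row ", rownames(rows)[i], " (", r$locus_tag,
             "): length_aa must be positive")
      orfs[[i]] <- tryCatch(
        parse_architecture(r$domain_string, locus_tag = r$locus_tag,
                           strand = if (r$strand == "-") "complement"
                                    else "forward",
                           length_aa = len),
        error = function(e) stop("row ", rownames(rows)[i], " (",
                                 r$locus_tag, "): ", conditionMessage(e)))
    }
    prod <- rows$deduced_product[nzchar(rows$deduced_product)]
    clusters[[length(clusters) + 1L]] <-
      gene_cluster(rows$cluster_id[1], rows$strain[1],
                   rows$declared_category[1], rows$ortholog_group[1],
                   orfs, if (length(prod)) prod[1] else NA_character_)
  }
  cluster_inventory(clusters, strains = unique(df$strain))
}

#' Write a cluster inventory to TSV
#'
#' @param inv a `cluster_inventory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inv, path) {
  stopifnot(inherits(inv, "cluster_inventory"))
  rows <- do.call(rbind, lapply(inv$clusters, function(cl) {
    data.frame(
      strain = cl$strain, cluster_id = cl$cluster_id,
      ortholog_group = cl$ortholog_group,
      declared_category = cl$declared_category,
      locus_tag = vapply(cl$orfs, `[[`, character(1), "locus_tag"),
      strand = vapply(cl$orfs, function(o)
        if (o$strand == "complement") "-" else "+", character(1)),
      length_aa = vapply(cl$orfs, function(o)
        as.character(o$length_aa), character(1)),
      domain_string = vapply(cl$orfs, serialize_architecture, character(1)),
      deduced_product = c(if (is.na(cl$deduced_product)) ""
                          else cl$deduced_product,
                          rep("", length(cl$orfs) - 1L)),
      stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged Phytohabitans cluster inventory
#'
#' The full machine-readable transcription of the PKS/NRPS cluster tables of
#' the four Phytohabitans type strains (P. flavus NBRC 107702, P. rumicis
#' NBRC 108638, P. houttuyneae NBRC 108639, P. suffuscus NBRC 105367):
#' 56 gene clusters with per-ORF locus tags, strand marks, protein sizes and
#' domain-organization strings. The strain-specific type-III PKS cluster of
#' P. houttuyneae that shares the printed name "t3pks-4" with an orthologous
#' two-strain cluster is stored as `t3pks-4b` so that identity-based
#' statistics are well defined.
#'
#' @return a `cluster_inventory` with 4 strains and 56 clusters.
#' @export
phytohabitans_inventory <- function() {
  path <- system.file("extdata", "phytohabitans_clusters.tsv",
                      package = "bgcline", mustWork = TRUE)
  load_inventory(path)
}
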