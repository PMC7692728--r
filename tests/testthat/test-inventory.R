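test_that("domain-organization strings parse into the right tokens", {
  a <- parse_architecture("KS/AT_m_/KR/DH")
  expect_equal(a$tokens$kind, c("KS", "AT", "KR", "DH"))
  expect_equal(a$tokens$qualifier[2], "m")
  expect_length(a$boundaries, 0)

  # typographic dialect: en dash, superscript C-subtype prefix, italics
  b <- parse_architecture("A_haorn_/MT/T–^D^C_L/A/T")
  expect_equal(nrow(b$tokens), 6)
  expect_equal(b$boundaries, 3L)
  expect_equal(b$tokens$qualifier[1], "haorn")
  expect_equal(b$tokens$kind[4], "C")
  expect_equal(b$tokens$qualifier[4], "DCL")

  it <- parse_architecture("C_M/A*_orn_*/T")
  expect_true(it$tokens$tentative[2])
  expect_equal(it$tokens$qualifier[2], "orn")

  # space as domain separator, as printed in some rows
  sp <- parse_architecture("KS AT_p/KR/ACP")
  expect_equal(sp$tokens$kind, c("KS", "AT", "KR", "ACP"))

  # stray separators normalized, not fatal
  st <- parse_architecture("T/-TE")
  expect_equal(st$tokens$kind, c("T", "TE"))
})

test_that("unknown tokens are rejected with their position", {
  expect_error(parse_architecture("KS/??/ACP"), "position 2")
  expect_error(parse_architecture("KS/AT_q/ACP"), "AT_q")
  expect_error(parse_architecture("   "), "empty")
})

test_that("token qualifiers are namespace-checked", {
  expect_error(domain_token("KR", "m"), "not legal")
  expect_error(domain_token("AT", "ser"), "not legal")
  expect_error(domain_token("A", "ser", tentative = TRUE), NA)
  expect_error(domain_token("AT", "m", tentative = TRUE), "tentative")
})

test_that("serialization is canonical and round-trips", {
  expect_equal(serialize_architecture(parse_architecture("AT_m_")), "AT_m")
  expect_equal(serialize_architecture(parse_architecture("A*_ser_*")),
               "A_ser?")
  withr::with_seed(101, {
    for (i in 1:200) {
      txt <- random_architecture()
      a <- parse_architecture(txt)
      b <- parse_architecture(serialize_architecture(a))
      expect_true(bgcline:::.arch_equal(a, b), info = txt)
    }
  })
})

test_that("every fixture domain string parses and round-trips", {
  inv <- phy_inv()
  for (cl in inv$clusters) for (o in cl$orfs) {
    r <- parse_architecture(serialize_architecture(o))
    expect_true(bgcline:::.arch_equal(o, r),
                info = paste(cl$strain, cl$cluster_id, o$locus_tag))
  }
})

test_that("the packaged inventory matches the published cluster tables", {
  inv <- phy_inv()
  expect_length(inv$strains, 4)
  expect_length(inv$clusters, 56)
  strains <- vapply(inv$clusters, `[[`, character(1), "strain")
  expect_equal(as.vector(table(strains)[inv$strains]),
               c(10L, 14L, 18L, 14L))

  fl <- subset_inventory(inv, "flavus")
  expect_length(fl$clusters, 10)

  t1pks7 <- get_cluster(inv, "t1pks-7", "suffuscus")
  expect_length(t1pks7$orfs, 17)

  grp <- vapply(inv$clusters, `[[`, character(1), "ortholog_group")
  expect_equal(sum(table(grp) >= 2), 9)

  nrps14 <- get_cluster(inv, "nrps-14", "suffuscus")
  expect_length(nrps14$orfs, 1)
  expect_equal(serialize_architecture(nrps14$orfs[[1]]),
               "A_aad/T-DCL/A_cys/T-LCL/A_val/T/E-TE")

  # complement-strand marks survive the ingestion
  nrps13 <- get_cluster(inv, "nrps-13", "suffuscus")
  expect_equal(nrps13$orfs[[1]]$strand, "complement")
})

test_that("inventory IO validates its schema", {
  expect_error(gene_cluster("c1", "s1", "nrps", orfs = list()),
               "at least one ORF")
  expect_error(gene_cluster("c1", "s1", "bogus",
                            orfs = list(parse_architecture("A/T"))),
               "category")
  # duplicate cluster id within a strain
  cl <- gene_cluster("c1", "s1", "nrps", orfs = list(parse_architecture("A/T")))
  expect_error(cluster_inventory(list(cl, cl)), "duplicated")

  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("strain\tcluster_id\tortholog_group\tdeclared_category\tlocus_tag\tstrand\tlength_aa\tdomain_string",
               "s1\tc1\tc1\tnrps\tL1\t?\t100\tA/T"), tmp)
  expect_error(load_inventory(tmp), "strand")

  tmp2 <- tempfile(fileext = ".tsv")
  writeLines("strain\tcluster_id\tlocus_tag", tmp2)
  expect_error(load_inventory(tmp2), "missing column")
})

test_that("write_inventory/load_inventory round-trips an inventory", {
  inv <- subset_inventory(phy_inv(), c("flavus", "rumicis"))
  tmp <- tempfile(fileext = ".tsv")
  write_inventory(inv, tmp)
  back <- load_inventory(tmp)
  expect_equal(length(back$clusters), length(inv$clusters))
  expect_equal(vapply(back$clusters, `[[`, character(1), "cluster_id"),
               vapply(inv$clusters, `[[`, character(1), "cluster_id"))
  for (i in seq_along(inv$clusters))
    expect_equal(vapply(back$clusters[[i]]$orfs, serialize_architecture,
                        character(1)),
                 vapply(inv$clusters[[i]]$orfs, serialize_architecture,
                        character(1)))
})
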