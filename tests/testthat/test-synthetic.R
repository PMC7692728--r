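test_that("generators are pure functions of (spec, seed)", {
  a <- generate_line(peptide = c("s", "x", "Asn"), seed = 42)
  b <- generate_line(peptide = c("s", "x", "Asn"), seed = 42)
  expect_equal(vapply(a$orfs, serialize_architecture, character(1)),
               vapply(b$orfs, serialize_architecture, character(1)))
  expect_equal(vapply(a$orfs, `[[`, character(1), "strand"),
               vapply(b$orfs, `[[`, character(1), "strand"))

  r1 <- resplit(a, 3, seed = 9)
  r2 <- resplit(a, 3, seed = 9)
  expect_equal(vapply(r1$orfs, serialize_architecture, character(1)),
               vapply(r2$orfs, serialize_architecture, character(1)))

  i1 <- generate_inventory(2, 1, c(1, 1), seed = 5)
  i2 <- generate_inventory(2, 1, c(1, 1), seed = 5)
  expect_equal(write_read <- vapply(i1$clusters, `[[`, character(1),
                                    "cluster_id"),
               vapply(i2$clusters, `[[`, character(1), "cluster_id"))
})

test_that("generated lines recover their ground-truth products", {
  specs <- list(c("s", "x", "Asn"),
                c("x", "dVal", "Val"),
                c("s", "y", "Asp"),
                c("Aad", "Cys", "dVal", "x"),
                c("mOrn", "x", "pk", "Ser"),
                c("x", "Dha", "Thz(Cys)", "Gly"),
                c("s", "x", "mx", "dx", "Leu"))
  for (k in seq_along(specs)) {
    cl <- generate_line(peptide = specs[[k]], seed = 100 + k)
    chain <- predict_peptide(assemble_line(cl))
    expect_equal(chain$tokens, specs[[k]], info = paste(specs[[k]],
                                                        collapse = "-"))
    expect_true(chain$terminated)
  }
})

test_that("a dVal spec emits an epimerization read out by the line", {
  cl <- generate_line(peptide = c("x", "dVal", "Val"), seed = 3)
  toks <- do.call(rbind, lapply(cl$orfs, `[[`, "tokens"))
  expect_true(any(toks$kind == "E"))
})

test_that("polyketide specs reproduce their reduction census", {
  cl <- generate_line(polyketide = list(module_count = 9, double_bonds = 6,
                                        hydroxyls = 2), seed = 8)
  line <- assemble_line(cl)
  census <- reduction_census(line)
  expect_equal(unname(census["dh_kr"]), 6)
  expect_equal(unname(census["kr_only"]), 2)
  expect_equal(count_pks_modules(line), 9)
  feats <- predict_polyketide(line)
  expect_true(feats$polyene)
})

test_that("unsupported product tokens are rejected", {
  expect_error(generate_line(peptide = c("x", "Qux"), seed = 1),
               "unsupported")
  expect_error(generate_line(peptide = c("x", "dVal"), seed = 1),
               "terminal")
  expect_error(generate_line(peptide = c("x", "s"), seed = 1), "position 1")
  expect_error(generate_line(seed = 1), "exactly one")
  expect_error(generate_line(peptide = "x",
                             polyketide = list(module_count = 1), seed = 1),
               "exactly one")
})

test_that("resplit preserves the token sequence and rejects bad sizes", {
  cl <- get_cluster(phy_inv(), "nrps-2", "flavus")
  n_tok <- sum(vapply(cl$orfs, function(o) nrow(o$tokens), integer(1)))
  one <- resplit(cl, 1, seed = 2)
  expect_length(one$orfs, 1)
  expect_equal(format(predict_peptide(assemble_line(one))),
               format(predict_peptide(assemble_line(cl))))
  many <- resplit(cl, n_tok, seed = 2)
  expect_length(many$orfs, n_tok)
  expect_error(resplit(cl, 0, seed = 1), "between")
  expect_error(resplit(cl, n_tok + 1, seed = 1), "between")
})

test_that("generated inventories have the requested sharing structure", {
  inv <- generate_inventory(4, 9, c(5, 8, 10, 8), seed = 20,
                            shared_sizes = c(4, 4, 4, 3, 2, 2, 2, 2, 2))
  g <- genus_summary(inv)
  expect_equal(g$total_clusters, 56)
  expect_equal(g$distinct_types, 40)
  expect_equal(g$shared_groups, 9)
  expect_equal(g$unshared_clusters, 31)
  expect_equal(unname(g$specific_per_strain), c(5L, 8L, 10L, 8L))

  single <- generate_inventory(1, 0, 7, seed = 4)
  gs <- genus_summary(single)
  expect_equal(gs$shared_groups, 0)
  expect_equal(gs$distinct_types, gs$total_clusters)
  expect_equal(gs$total_clusters, 7)
})
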