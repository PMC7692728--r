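Package: bgcline
Title: Assembly-Line Analysis of PKS and NRPS Gene Clusters
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for turning polyketide synthase (PKS) and nonribosomal
    peptide synthetase (NRPS) domain-organization annotations into predicted
    product backbones and genus-level secondary-metabolite statistics. Parses
    the compact domain-organization notation used in cluster tables (slash
    between domains, hyphen between modules), merges ORF-split proteins into a
    single assembly line under the collinearity rule, infers polyketide
    reduction states and nonribosomal peptide monomer chains, classifies
    cluster architectures (trans-AT, iterative enediyne, type-III
    involvement), computes cluster-sharing statistics across strains, and
    dereplicates LC-MS ion peaks against known compounds by exact [M+H]+
    mass. Ships a machine-readable inventory of the PKS/NRPS clusters of the
    four Phytohabitans type strains together with seeded generators of
    synthetic assembly lines with known ground-truth products.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
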