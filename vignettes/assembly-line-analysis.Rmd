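---
title: "From domain organizations to product backbones: the bgcline model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From domain organizations to product backbones: the bgcline model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcline)
```

## The problem

Modular polyketide synthases (type-I PKS) and nonribosomal peptide
synthetases (NRPS) are assembly lines: each module performs one cycle of
chain elongation, and the order of modules along the line mirrors the order
of monomers in the product (the collinearity rule). A minimal PKS module is
KS + AT + ACP; a minimal NRPS module is C + A + T. Optional domains modify
the growing chain — KR reduces the β-keto group to a hydroxyl, KR + DH
eliminate it to a C=C double bond, KR + DH + ER reduce it fully; MT
methylates, E epimerizes, TE/TD release the chain.

`bgcline` turns compact per-ORF domain-organization annotations (the kind
produced by manual curation of cluster-detection output) into:

1. a parsed, validated cluster inventory,
2. a single merged assembly line per cluster,
3. module and reduction-state counts,
4. a predicted product backbone (a monomer chain for NRPS lines, a
   chemistry summary for PKS lines),
5. genus-level sharing statistics over a multi-strain inventory, and
6. exact-mass dereplication of LC-MS ion peaks against candidate
   compounds.

The package ships a complete machine-readable inventory of the 56 PKS/NRPS
gene clusters of the four *Phytohabitans* type strains (*P. flavus* NBRC
107702, *P. rumicis* NBRC 108638, *P. houttuyneae* NBRC 108639,
*P. suffuscus* NBRC 105367), transcribed ORF by ORF with locus tags,
strand marks, protein sizes and domain strings.

## The domain-organization grammar

Architectures are written with `/` (or whitespace) between domains and `-`
between modules, e.g. `KS/AT_m/DH/KR/ACP-KS/AT_p/KR/ACP`. Substrate tags
follow the domain (`AT_m` = malonyl-CoA, `AT_p` = methylmalonyl-CoA,
`A_ser` = serine); C-domain subtypes are `LCL`, `DCL`, `C_Du` (dual E/C),
`C_M` (modifying), `C_S` (starter), `C_Cy` (heterocyclizing). A trailing
`?` (or the typographic italics markup `A*_ser_*`) marks a substrate
supported by a single predictor only. `KS1` is a loading-module KS, `KS3`
a free-standing type-III (chalcone-synthase-like) KS. The parser also
accepts the typographic variants found in printed tables — en dashes,
superscript subtype prefixes (`^L^C_L`, `^D^C_L`), trailing underscores
and stray separators — and rejects anything else with the offending token
and position. Serialization emits a canonical ASCII form and
`parse(serialize(x))` is the identity; this round-trip is property-tested
over the whole bundled inventory and over random architectures.

```{r}
parse_architecture("A_haorn_/MT/T–^D^C_L/A/T")
```

## Merging ORFs into one assembly line

In these genomes modules are frequently split across several proteins (a
KS/AT/DH on one ORF, its KR/ACP on the next). `assemble_line()` therefore
segments the concatenated token stream, not the individual proteins:

* a new PKS module opens at every `KS`; `CoL` and `FkbH` open
  loading-type modules; `KS3` never enters a module (it is recorded as a
  standalone domain and sets `has_type3_ks`),
* a new NRPS module opens at every `C`; an `A` extends an A-less NRPS
  module and otherwise opens a new one; `T`, `E`, `MT`, `TE`, `TD` extend
  the open module,
* PKS part domains (`AT`, `KR`, `DH`, `ER`, `ACP`) extend the open PKS
  module only if that domain kind is not already present; a duplicate
  rejects the remainder of that ORF's run to the standalone list. This is
  what recognises free-standing trans-acting ATs, ERs and ACPs. An ORF
  consisting of two or more AT domains (the canonical trans-AT didomain
  protein) or of a lone A protein in a PKS context is standalone as a
  whole.

Counts are then defined so that they are invariant to how the line happens
to be distributed over ORFs: the PKS module count is the number of modular
KS tokens (loading KS included, type-III KS excluded) and the NRPS module
count the number of in-module A tokens. The reduction census assigns every
KS-containing module to exactly one of `kr_only`, `dh_kr`, `dh_er_kr` or
`none`. These conventions reproduce, from the bundled domain strings
alone, all the architecture numbers carried in the inventory's annotation
column (e.g. 12 modules with six DH-KR pairs for *t1pks-7*, 10 KR-only and
11 DH-KR modules for *pks/nrps-3*, 13 PKS modules with a 4/4 census for
*pks/nrps-12*, six NRPS modules for *pks/nrps-9*), and every count is
property-tested to be stable under random re-splits of the token stream
(`resplit()`).

Printed module separators are retained only for serialization round-trips;
segmentation never relies on them, because an ORF boundary can fall inside
a module and a separator can be absent at an ORF junction.

## Substrate calls

A-domain substrates follow a two-predictor consensus: a call is
*confirmed* when two independent predictors agree, or when the domain's
10-residue specificity-conferring code is at least 90% identical to the
reference code of the predicted monomer; a primary-only prediction is kept
as *tentative*; otherwise the position is the unknown monomer `x`. The
threshold is a parameter applied inclusively (`>= 0.9`), because the
flagship hydroxy-ornithine call rests on a 9/10 code match
(`DAWEVGLVDK` vs `DAWEGGLVDK`); a strict `>` would reject the package's
own reference case. Only the codes attested in the bundled clusters ship
with the package (an editable two-column TSV); when the best-matching
reference monomer differs from the predicted one, the call keeps the
prediction and records the best match as evidence — ties between
predictors and codes are not silently re-resolved.

## Product backbones

`predict_peptide()` emits one position per chain-building module, walking
the line in collinear order: `s` for a loading module without an A domain,
the substrate label for an A module (`x` if unknown), `y` for a C module
that carries a T but no A, `pk` for an interleaved PKS module. `MT` in a
module adds an `m` prefix. A `C_M`-led module loading serine emits
dehydroalanine (`Dha`) — the rule deliberately requires the modifying C to
*lead* the module, so a trailing `C_M` (as in *pks/nrps-5*) does not
dehydrate its own serine. A `C_Cy`-led cysteine module emits `Thz(Cys)`.

Epimerization: a module's `E` domain adds a `d` prefix **unless the module
is terminal**. The alternative conventions (mark every E-containing
module, or mark modules followed by a `DCL`/dual condensation) were
rejected because they are inconsistent with the curated product
annotations shipped in the inventory: the siderophore line *nrps-3* ends
in an E-containing module yet its product is annotated `hOrn`, not
`d`-marked, and the dual-C modules of *pks/nrps-7* carry no stereo marks
either. Chemically, an epimerized residue is read out by the downstream
acceptor C domain; a terminal E has no downstream acceptor. One curated
chain (*nrps-9*) cannot be reproduced under any uniform convention — its
printed strings contain ten A-domain modules but a nine-position product,
and two structurally identical modules carry different stereo marks — so
the package reports its own derivation for that cluster and the
discrepancy is visible in the test suite rather than patched over.

Peptide-size words in the literature mix two conventions ("heptapeptide"
counting the starter position, "nonapeptide" counting residues after it),
so `chain_length()` exposes both `tokens` and `residues`. Lines with two
release domains (*nrps-15*) are flagged `te_ambiguous`/`iterative_hint`
rather than resolved; iterative use (enterobactin-like trimerization) is
never expanded into a multimer.

`predict_polyketide()` summarises PKS chemistry: chain carbons = 2 ×
module count, double bonds = `dh_kr` modules, hydroxyls = `kr_only`,
fully reduced = `dh_er_kr`. The polyene flag fires at
`polyene_threshold = 3` double bonds: the smallest line annotated as a
polyene in the bundled inventory has four DH-KR modules and the larger
ones six and eleven, so three separates polyenes from ordinary partially
reduced chains while remaining a visible, overridable parameter.

## Architecture signatures and categories

`derive_category()` re-derives the cluster class from the assembled line
(modular KS → `t1pks`, type-III KS only → `t3pks`, both without NRPS →
`t1pks_t3pks`, C/A/T only → `nrps`, NRPS plus any PKS → `pks_nrps`);
free-standing A or C proteins count as NRPS evidence, which is what makes
the large polyene line with its orphan A protein a hybrid. The iterative
enediyne PKS is recognised by its atypical single-module architecture
(KS/AT with KR *before* DH and no ACP); the 9- versus 10-membered warhead
distinction requires phylogeny and is out of scope, so the flag reads
"enediyne, ring size undetermined". Trans-AT status requires both an
AT-less KS module and a free-standing AT to serve it. Type-II PKS systems
are represented only by their absence: no detection model is built.

## Genus-level statistics

Ortholog groups are inventory-declared (assigning them is a
sequence-similarity step outside this package's scope); each
strain-specific cluster counts as its own group, so distinct types =
shared groups + unshared clusters. One naming collision in the source
tables — two unrelated type-III clusters printed under the same name in
one strain — is resolved in the fixture by renaming the strain-specific
one `t3pks-4b`; without the rename, identity-based statistics would
conflate two different cluster types. `architecture_similarity()` is a
label-free fallback: a normalized global alignment of module-level strings
whose default costs (match 1, mismatch 0, gap 0) make the score an LCS
ratio, cross-checked in the tests against a brute-force oracle. It is not
used for any headline statistic.

## Dereplication

Candidates are matched as `[M+H]+` ions (proton mass 1.00728 Da) within a
relative tolerance, default 10 ppm — chosen for a 70,000-resolution
Orbitrap-class instrument and exposed as a parameter since the source
peak lists state none. Other adducts (Na+, 2H+) are deliberately out of
scope. Absences are first-class results: the headline finding the bundled
peak list supports is that none of the fifteen candidate compounds'
ions occur in any extract, while the 656.31 ion co-occurs exactly with
the strains whose siderophore line carries its fifth module.

## The synthetic-data generator

`generate_line()` inverts the backbone rules: given a product chain (or a
polyketide reduction profile) it emits a cluster whose assembled line
predicts that product exactly, with the module stream split across a
seeded random ORF partition and cosmetic strand marks.
`generate_inventory()` builds multi-strain inventories with a requested
sharing structure. The generators emulate the features the pipeline is
sensitive to — ORF splitting at arbitrary token boundaries, unknown
substrates, epimerized/methylated positions, interleaved PKS modules,
controlled ortholog sharing — and deliberately do not emulate nucleotide
or protein sequences, annotation noise (mis-called domains), or
disagreement between predictors. Passing ground-truth recovery on
generated data therefore validates the internal consistency of the
parse → assemble → predict chain, not the upstream annotation quality of
real genomes. Monomer alphabets are restricted to labels attested in the
bundled inventory. All generators are pure functions of (spec, seed); a
terminal `d`-position is rejected as unsupported because a terminal
epimerization is never read out (see above). Group spans in
`generate_inventory()` default to seeded draws of 2..n strains and can be
pinned with `shared_sizes` when an exact total is wanted.

Test problem sizes were chosen to keep the default suite quick while
exercising every rule: 200 + 100 random architectures for round-trip
properties, 1,000 random product specs for ground-truth recovery, re-splits
at 1/3/10/30 ORFs for invariance, and a handful of random inventories for
the conservation laws.

## Degenerate inputs and numerical choices

Empty domain strings, unknown tokens, illegal qualifier namespaces,
non-positive masses, zero-length specificity codes, clusters without ORFs
and out-of-range `n_orfs` are errors, never silent fixes. Stray or doubled
separators in printed tables are normalized away. Modules that contain
only a C domain (a structural remnant at a line end) emit no product
position; an A-less C module emits `y` only when it carries a T. All
tolerances (`threshold`, `polyene_threshold`, `tolerance_ppm`) are
parameters with the defaults documented above.

## Known limitations

* Products are backbones only: tailoring reactions, stereochemistry beyond
  the `d` prefix, and final structures (SMILES) are out of scope.
* Ortholog groups are taken from the inventory, not inferred; the
  similarity score is a heuristic aid.
* The assembler trusts the annotation: it cannot recover domains the
  upstream annotation missed, and module boundaries are inferred from
  domain content, never from protein sequence.
* A lone trailing A protein's role (as in the large polyene line) is
  reported as standalone; whether it participates in synthesis is an open
  biological question.
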