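Package: sparsecell
Title: Supercell Deconvolution for Crystals with Sparse-Layer Lattice Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining crystal structures with partial lattice
    (sparse-layer / lattice-translocation) disorder by the supercell
    deconvolution procedure: a small-cell model is expanded into an n-fold
    supercell whose translated copies separate overlapping molecules,
    reflection data are reindexed into the supercell (completeness 1/n),
    edits are propagated between copies by exact non-crystallographic
    symmetry, and the model is collapsed back to the small cell with
    fractional occupancies 1/n.  Includes direct-summation structure
    factors, R factors and map coefficients with the Fcalc substitution
    rule for unmeasured reflections, Matthews/solvent-content arithmetic,
    Kabsch superposition, a synthetic layered-disorder crystal simulator,
    and twinning diagnostics (L-test, H-test, r.m.s.d. to a symmetrized
    structure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
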