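# sparsecell

Tools for solving and refining crystal structures with **sparse-layer
lattice disorder** — crystals in which well-ordered molecular layers
alternate with a layer whose molecules occupy one of *n* translational
slots in random order, so that every small-cell model overlaps its own
lattice-translated images.

The package implements the **supercell ("triple-cell") deconvolution
procedure**: expand the small-cell model into an *n*-fold supercell whose
translated copies separate the overlapping molecules, reindex the data as
(h, k, l) → (n·h, k, l) (completeness ≈ 1/n in the expanded cell),
rebuild with exact NCS copying between the ordered copies, and collapse
back to the small cell with occupancies 1 and 1/n. The procedure works
because of the exact identity

    F_expanded(n·h, k, l) = n · F_collapsed(h, k, l)

so the n copies contribute identically to every reflection that carries an
observation. Alongside the core method the package provides:

* direct-summation structure factors, least-squares scaling and R factors;
* 2Fo−Fc / Fo−Fc map coefficients with the Fcalc-substitution rule for
  unmeasured reflections (missing data contribute model density to
  2Fo−Fc maps and exactly nothing to difference maps);
* free-R flag generation over *all* reflections, measured or not;
* Matthews coefficient / solvent content arithmetic;
* Kabsch rigid-body superposition and rotation angle/axis decomposition;
* a synthetic layered-disorder crystal simulator (analytic and empirical
  Bragg amplitudes, voids, orientations, twinning);
* twinning and pseudo-symmetry diagnostics: L-test, H-test with twin
  fraction estimate, and r.m.s.d. to a symmetrized structure.

Reflection data are tibbles (pipe-friendly, dplyr-ready), models are
light S3 objects, results come with broom-style `tidy()` / `glance()`
methods and ggplot2 `autoplot()`s, and plain-text PDB/HKL/config formats
round-trip through `read_pdb()` / `write_pdb()` / `read_hkl()` /
`write_hkl()` / `read_config()`. A command-line interface
(`inst/cli/sparsecell`, or `sc_cli()` from R) exposes the pipeline as
subcommands (`simulate`, `expand`, `reindex`, `collapse`, `fcalc`,
`rfactor`, `maps`, `ltest`, `htest`, `matthews`, `superpose`, `occscan`,
`demo`).

## Worked example

Simulate a period-3 sparse-layer crystal, look at the data in the triple
cell, and recover the sparse-chain occupancy from the amplitudes:

```r
library(sparsecell)

spec <- disorder_spec(seed = 1)                    # period 3, 2% noise
data_small <- simulate_bragg(spec, d_min = 2.2, mode = "analytic")
data_small
#> <reflection_set> P1, 2961 reflections (2961 observed), d_min 2.200 A

map <- make_mapping(spec$base_cell, "a", 3)        # 20 A -> 60 A
tri <- reindex_supercell(data_small, map)
completeness(tri)
#> [1] 0.3338957

truth <- average_model(spec)                       # ordered + 1/3-occupied sparse
scan <- estimate_sparse_occupancy(truth, "B", data_small)
scan
#> <occupancy_scan> chain B: best occupancy 0.340 (R = 0.0172) over 51 grid points, 2961 reflections
```

The reindexed data are one third complete — only reflections with
h ≡ 0 (mod 3) exist in the supercell — and the R-factor scan recovers the
sparse layer's 1/3 occupancy (0.34 is the grid point nearest 1/3; R at
the optimum reflects the 2% simulated noise). `autoplot(scan)` draws the
R-factor profile. The whole cycle — expand, propagate an edit, collapse,
rescore — is wired together in the demo:

```sh
Rscript inst/cli/sparsecell demo --seed 7
#> === supercell deconvolution demo ===
#> small cell a = 20.00 A -> triple cell a' = 60.00 A
#> completeness after reindexing (triple cell): 0.3301
#> free reflections flagged (measured or not): 568 of 11787
#> collapsed occupancies: A=1.00, B=0.33
#> molecules per ASU: 1.33
#> R factor, collapsed model vs data: 0.0160
#> recovered sparse occupancy: 0.34 (true 0.333)
```

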