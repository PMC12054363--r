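---
title: "Supercell deconvolution of sparse-layer lattice disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supercell deconvolution of sparse-layer lattice disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsecell)
```

## The problem

Some protein crystals are built from well-ordered molecular layers
interleaved with a *sparse* layer: a layer whose molecules occupy one of
$n$ translationally related positions (or sometimes a void, or one of two
symmetry-related orientations) in random order from column to column.
Such lattice-translocation disorder leaves the diffraction pattern
indexable in the small cell, but every model placed in that cell overlaps
its own lattice-translated images, and conventional rebuilding against
overlapping density is painful.

The supercell ("triple-cell") device makes the overlap explicit instead
of fighting it. One cell axis is multiplied by an integer $n$ (the
disorder period). In the expanded cell the ordered molecule appears as
$n$ translated copies — chains A, B, C for $n = 3$ — and the alternative
conformation of the sparse layer becomes one more chain (D) that no
longer clashes with anything. The reflection data are reindexed as
$(h, k, l) \rightarrow (n h, k, l)$, giving a data set of completeness
$\approx 1/n$ in the expanded cell. After rebuilding, the model is
collapsed back into the small cell: one ordered chain at occupancy 1 and
the sparse chain at occupancy $1/n$, i.e. $1 + 1/n$ occupancy-weighted
molecules per asymmetric unit ($1.33$ for $n = 3$).

## Why the supercell refines correctly

The package's central identity ties the two descriptions together. Let
$F_{\mathrm{exp}}$ be structure factors of the expanded model in the
$n$-fold cell and $F_{\mathrm{coll}}$ those of the collapsed model in the
small cell. For every index,

$$F_{\mathrm{exp}}(n h, k, l) = n\, F_{\mathrm{coll}}(h, k, l)$$

as complex numbers: a copy translated by $k/n$ of the expanded axis picks
up a phase $e^{2\pi i (n h)(k/n)} = 1$ on the surviving sublattice, so
the $n$ copies contribute *identically* to every reflection with an
observation, and an atom can be modelled in any of its $n$
symmetry-independent positions without changing the fit to the data.
That is what lets edits made in one copy be propagated to the others by
exact NCS copying (`propagate_ncs()`) and the whole model be collapsed at
the end (`collapse_model()`) without changing any calculated amplitude.
`test-supercell.R` and the acceptance suite verify the identity to
better than $10^{-8}$ (relative to the r.m.s. amplitude — pointwise
relative error is meaningless on systematically absent reflections,
where $F$ is exactly 0).

One caveat governs C-centred cells: for even $n$ a small-cell reflection
with $h$ and $k$ both odd maps to a centring-extinct supercell index, so
the identity is only testable on the surviving sublattice. The
identity-sweep tests therefore randomize over P1 and P2~1~ models with
$n \in \{2, 3, 4\}$; the C222~1~ case with the odd period $n = 3$ — the
configuration the method was built for — is exercised separately.

## What completeness 1/3 means exactly

Reindexing a complete small-cell set by $n = 3$ gives completeness
$\approx 1/3$, not exactly $1/3$: completeness is a ratio of *unique*
reflection counts, and symmetry orbits on the zone planes make the
unique count of the tripled cell slightly less than three times that of
the small cell at any finite resolution. On the 41.84 / 185.32 /
128.39 Å orthorhombic cell at 1.64 Å the computed value is 0.340,
approaching $1/3$ from above as the resolution limit tightens. The
package computes completeness against lattice-allowed unique reflections
only (centring-extinct indices are excluded from the denominator),
matching standard practice.

## Free flags and map coefficients for unmeasured data

Free-R flags are generated *for all reflections, measured or not*
(`assign_free_flags(include_unmeasured = TRUE)`); the flag is a
deterministic hash of `(seed, h, k, l)` against the free fraction, so a
subset of indices always keeps its flags. The free fraction defaults to
0.05, a conventional choice.

Flagging the unmeasured reflections matters because of the map mode it
enables. In first approximation, maps computed from incomplete data
substitute $F_{\mathrm{calc}}$ for the missing observations:

* $2F_o - F_c$-type coefficients: $(2|F_o| - k|F_c|)e^{i\varphi_c}$ when
  measured, $k|F_c| e^{i\varphi_c}$ when not;
* $F_o - F_c$-type coefficients: $(|F_o| - k|F_c|)e^{i\varphi_c}$ when
  measured, exactly 0 when not.

So with $2/3$ of the observations missing the $2F_o - F_c$ map follows
the model closely wherever the model is right, while missing data
contribute *nothing* to the difference map — wrong regions still show
up. `map_coefficients()` implements exactly this rule; the
likelihood-weighted refinement-engine variant is intentionally out of
scope. The map $\sigma$ level is the r.m.s. density over a uniform
grid (64³ by default, computed by FFT).

## The scattering model

Structure factors are computed by direct summation over atoms and
symmetry operations,

$$F(\mathbf h) = \sum_{\mathrm{ops}} \sum_{\mathrm{atoms}}
  \mathrm{occ} \cdot f_{\mathrm{elem}} \cdot e^{-B s^2 / 4}
  \cdot e^{2\pi i\, \mathbf h \cdot (R\mathbf x + \mathbf t)},
  \qquad s = 1/d,$$

with *point-atom* form factors $f_{\mathrm{elem}} = Z$ (the atomic
number, resolution-independent). Every identity used by the method is
form-factor independent, and point atoms keep the test oracles exact;
Gaussian form-factor tables are an extension point, not a need. There is
no bulk-solvent model. The observed/calculated scale is the
least-squares $k = \sum|F_o||F_c| / \sum|F_c|^2$ and
$R = \sum\bigl||F_o| - k|F_c|\bigr| / \sum|F_o|$. Note that the classic
"$R \approx 0.586$ between unrelated acentric structures" reference
value presumes amplitudes on a common scale; with the least-squares
scale the expectation is slightly lower (~0.55). The test suite checks
0.586 under the assumption of its derivation.

Space-group operation tables are hard-coded for P1, P2~1~, C222~1~ and
P6~3~ — the settings the method and its diagnostics need — with closure
and determinant +1 verified by tests; further groups are an extension
point. Unique reflections are reduced to the lexicographically largest
index equivalent under the point group plus Friedel inversion. Special
positions are not merged; toy models are placed at general positions.

## The synthetic-data generator

`disorder_spec()` parameterizes the crystal the package is built to
handle: a base cell with an ordered layer (one molecule per cell,
occupancy 1) and a sparse layer in which each period of $n$ cells along
the disorder axis carries at most one molecule — slot drawn from
`slot_probabilities`, void with `void_probability`, orientation from an
allowed set. Defaults are the uniform threefold case: period 3, uniform
slots, no voids, identity orientation, 2% multiplicative amplitude
noise, 500 realizations for empirical averages, a 20 × 30 × 25 Å P1
base cell and a 20-atom random compact "molecule". These defaults are
the package's study conditions; occupancy-recovery robustness is
assessed at 5% noise.

Two Bragg modes are tied together by construction:

* **analytic** — the coherent Bragg component of a substitutionally
  disordered crystal is $|\langle F\rangle|$ of the *average* structure:
  ordered sites at occupancy 1, the sparse site at occupancy
  $(1 - p_{\mathrm{void}})/n$. This average model is exactly what
  `collapse_model()` produces from a correct supercell model, so the
  simulator's truth *is* the collapse output.
* **empirical** — complex structure factors of seeded one-period
  realizations are averaged in the $n$-fold supercell and mapped to
  small-cell indices ($F = \langle F_{\mathrm{super}}(nh)\rangle / n$).
  On the sublattice the slot translations are invisible (the
  deconvolution identity again), so with no voids the empirical mean
  equals the analytic value exactly; voids introduce genuine
  Monte-Carlo fluctuation of order $1/\sqrt{M}$. Off the sublattice the
  mean amplitude decays toward zero with the number of realizations —
  those indices carry only diffuse (non-Bragg) intensity, which is why
  the observed data index in the small cell. Diffuse intensity itself
  is out of scope.

Noise is multiplicative Gaussian on amplitudes, truncated at zero, with
`sig_f = noise × amplitude`. What the generator does *not* emulate:
atomic-level conformational differences between layers, correlated
(non-independent) disorder between columns, experimental error models
beyond the single noise fraction, and solvent. Passing tests therefore
demonstrate the arithmetic of the method — expansion, reindexing,
propagation, collapse, occupancy recovery — not robustness to every
pathology of real data.

## Twinning and pseudo-symmetry diagnostics

Crystals with pseudo-symmetry invite twinning diagnoses, genuine or
spurious, so the package carries the standard intensity checks:

* `l_test()` pairs each reflection with an unrelated local neighbour
  (index offsets within $|\Delta| \le 2$, nearest first, excluding
  symmetry and Friedel mates) and reports the moments of
  $L = (I_1 - I_2)/(I_1 + I_2)$: untwinned acentric data give
  $\langle|L|\rangle = 1/2$, $\langle L^2\rangle = 1/3$; a perfect twin
  gives $3/8$ and $1/5$.
* `h_test()` compares twin-law-related mates,
  $H = |I - I_{\mathrm{op}}| / (I + I_{\mathrm{op}})$, and estimates the
  twin fraction as $\hat\alpha = 1/2 - \langle H\rangle$, clipped to
  $[0, 0.5]$ with a warning when sampling noise pushes
  $\langle H\rangle$ above $1/2$. The operator must be an involution on
  the set; for a threefold twin, apply the test to each pairing
  operator separately.
* `symmetrized_rmsd()` quantifies pseudo-symmetry as the r.m.s.d. of a
  model from the average of its superposed, operation-permuted copies —
  zero exactly when the model is invariant under the candidate
  operations.

Toy diagnostic data are generated in P1/P2~1~, where no centric zones
contaminate the acentric statistics; centric corrections are out of
scope.

## Numerical choices and degenerate inputs

* Orthogonalization follows the PDB convention (a along x, b in the
  x–y plane); coordinates in files are orthogonal Å, internal
  coordinates fractional.
* Resolution cutoffs are closed: $d \ge d_{\min}$ is included.
* Collapse keeps copy 0 of each ordered group (tie-break rule) and
  requires the copies to agree to $10^{-6}$ of the axis length after
  translation removal — strict, because propagation in this package is
  exact copying, not restrained refinement.
* Occupancy scans use the decomposition
  $F(q) = F_{\mathrm{rest}} + q\,F_{\mathrm{sparse}}$, so a grid scan
  costs two direct summations; ties break toward the smaller occupancy.
  The default grid step is 0.02.
* Superposition enforces a proper rotation (det $+1$); mirrored inputs
  fit with non-zero r.m.s.d. rather than an inversion. Fewer than three
  points, or collinear points, are refused.
* Matthews computations use the conventional protein constant
  1.230 Å³/Da (configurable) and, when only residue counts are known, a
  mean residue mass of 110 Da. A solvent fraction outside $[0, 1]$ is
  returned with a warning — it flags implausible input, not a failure.
* Degenerate cells (non-positive metric volume) and occupancies outside
  $[0, 1]$ are rejected at construction.

## Problem sizes used by the tests

The test and acceptance computations run at desk scale by design: toy
molecules of 4–20 atoms, cells of 10–40 Å, resolution limits of
1.5–4 Å (10³–10⁴ unique reflections), 500 realizations for empirical
averages, 20 seeds for occupancy recovery, and the one full-size
computation — the published 41.84 × 185.32 × 128.39 Å cell at 1.64 Å
(62k unique reflections, 182k in the tripled cell) — for the
completeness bookkeeping. Final refinement R factors against measured
diffraction data require a production likelihood refinement engine and
are deliberately outside this package's claims.

## Known limitations

Point-atom scattering and no bulk solvent mean absolute amplitudes are
not comparable to refinement-engine output; only ratios, R factors and
identities are. The supercell machinery assumes exactly one disorder
axis and integer period. Expanded models carry one sparse conformation
per chain (alternative orientations enter through the `alt_model`
mechanism and the simulator's orientation set, not as altLocs). The
CLI's `collapse` subcommand reconstructs copy assignments from mean
axis positions, which assumes the copies have not been moved far from
their lattice slots.
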