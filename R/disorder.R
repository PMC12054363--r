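# Synthetic layered-disorder crystals: well-ordered molecular layers
# interleaved with a sparse layer whose molecules occupy one of n
# translational slots (or a void, optionally in one of several
# orientations) in random order. Only the average structure diffracts
# coherently (Bragg component |<F>|); the diffuse component shows up as
# the vanishing of non-sublattice supercell reflections.

#' Build a compact random toy molecule
#'
#' A seeded pseudo-random cluster of atoms within `radius` of its
#' centroid, in orthogonal Å coordinates relative to the centroid.
#' Deterministic per seed.
#'
#' @param n_atoms Number of atoms, `>= 1`.
#' @param radius Cluster radius (Å).
#' @param seed Integer seed.
#' @param element Element symbol (default carbon).
#' @param b B factor for every atom (Å²).
#' @return Tibble with columns `atom`, `element`, `dx`, `dy`, `dz`
#'   (Å offsets from the centroid), `b`.
#' @export
make_toy_molecule <- function(n_atoms, radius = 3, seed = 1, element = "C",
                              b = 15) {
  stopifnot(n_atoms >= 1)
  withr::with_seed(as.integer(seed), {
    # uniform directions, radii biased outward for a compact shell-ish cluster
    u <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- radius * stats::runif(n_atoms)^(1 / 3)
    xyz <- u * r
  })
  xyz <- sweep(xyz, 2, colMeans(xyz))
  # recentring can push atoms slightly out; rescale to the stated radius
  rmax <- max(sqrt(rowSums(xyz^2)))
  if (rmax > radius) xyz <- xyz * (radius / rmax)
  tibble::tibble(atom = paste0("C", seq_len(n_atoms)), element = element,
                 dx = xyz[, 1], dy = xyz[, 2], dz = xyz[, 3], b = b)
}

#' Parameterize a synthetic layered-disorder crystal
#'
#' Describes a crystal built from an ordered layer (one molecule per
#' cell) and a sparse layer in which each period of `n` cells along
#' `axis` carries at most one molecule, placed in slot `0..n-1` with
#' probabilities `slot_probabilities` (void with `void_probability`), in
#' one of the allowed `orientations`. Defaults model the uniform-random
#' threefold case: `period = 3`, uniform slots, no voids, identity
#' orientation only, 2% multiplicative amplitude noise.
#'
#' @param base_cell Small [unit_cell()] (default 20 x 30 x 25 Å, P1).
#' @param spacegroup A [spacegroup()] or symbol (default `"P1"`).
#' @param period Integer `n >= 1` (default 3).
#' @param axis Disorder axis, `"a"`, `"b"` or `"c"`.
#' @param molecule Toy molecule tibble ([make_toy_molecule()]).
#' @param ordered_placement,sparse_placement Fractional centroid of the
#'   ordered- and sparse-layer molecule in the base cell.
#' @param slot_probabilities Length-`period` probabilities summing to 1.
#' @param orientations List of proper rotation matrices allowed for the
#'   sparse molecule (default identity only).
#' @param orientation_probabilities Probabilities over `orientations`.
#' @param void_probability Probability in `[0, 1)` that a period is empty.
#' @param amplitude_noise Multiplicative Gaussian amplitude noise
#'   fraction, `>= 0` (default 0.02).
#' @param n_realizations Realizations for the empirical Bragg average.
#' @param seed Integer seed.
#' @return An object of class `disorder_spec`.
#' @export
disorder_spec <- function(base_cell = unit_cell(20, 30, 25),
                          spacegroup = "P1",
                          period = 3,
                          axis = "a",
                          molecule = make_toy_molecule(20, 3, seed = 1),
                          ordered_placement = c(0.20, 0.25, 0.50),
                          sparse_placement = c(0.55, 0.75, 0.40),
                          slot_probabilities = NULL,
                          orientations = list(diag(3)),
                          orientation_probabilities = NULL,
                          void_probability = 0,
                          amplitude_noise = 0.02,
                          n_realizations = 500,
                          seed = 1) {
  stopifnot(is_unit_cell(base_cell), period >= 1, period == round(period))
  period <- as.integer(period)
  sg <- spacegroup(spacegroup)
  slot_probabilities <- slot_probabilities %||% rep(1 / period, period)
  if (length(slot_probabilities) != period ||
      abs(sum(slot_probabilities) - 1) > 1e-12) {
    stop("slot_probabilities must have length `period` and sum to 1",
         call. = FALSE)
  }
  orientation_probabilities <- orientation_probabilities %||%
    rep(1 / length(orientations), length(orientations))
  if (length(orientation_probabilities) != length(orientations) ||
      abs(sum(orientation_probabilities) - 1) > 1e-12) {
    stop("orientation_probabilities must match orientations and sum to 1",
         call. = FALSE)
  }
  if (void_probability < 0 || void_probability >= 1) {
    stop("void_probability must lie in [0, 1)", call. = FALSE)
  }
  if (amplitude_noise < 0) stop("amplitude_noise must be >= 0", call. = FALSE)
  structure(list(
    base_cell = base_cell, spacegroup = sg, period = period, axis = axis,
    molecule = molecule,
    ordered_placement = ordered_placement,
    sparse_placement = sparse_placement,
    slot_probabilities = slot_probabilities,
    orientations = orientations,
    orientation_probabilities = orientation_probabilities,
    void_probability = void_probability,
    amplitude_noise = amplitude_noise,
    n_realizations = as.integer(n_realizations),
    seed = as.integer(seed)
  ), class = "disorder_spec")
}

#' @export
print.disorder_spec <- function(x, ...) {
  cat(sprintf("<disorder_spec> %s, period %d along %s, void p=%.2f, noise %.1f%%, %d atoms/molecule\n",
              x$spacegroup$symbol, x$period, x$axis, x$void_probability,
              100 * x$amplitude_noise, nrow(x$molecule)))
  invisible(x)
}

# Atom tibble for one molecule placed at fractional centroid `place` in
# `cell`, optionally rotated (orthogonal-space rotation about the
# centroid), as chain `chain`.
place_molecule <- function(molecule, cell, place, chain, occ = 1,
                           rotation = NULL) {
  off <- as.matrix(molecule[, c("dx", "dy", "dz")])
  if (!is.null(rotation)) off <- off %*% t(rotation)
  fr <- sweep(orth_to_frac(cell, off), 2, place, "+")
  atom_sites(chain = chain, resno = seq_len(nrow(molecule)),
             atom = molecule$atom, element = molecule$element,
             x = fr[, 1], y = fr[, 2], z = fr[, 3],
             occ = occ, b = molecule$b)
}

#' Average (collapsed-occupancy) model of a disorder spec
#'
#' The coherently diffracting structure: the ordered molecule at
#' occupancy 1 (chain A) and the sparse molecule at occupancy
#' `(1 - void_probability) / period` per orientation weight (chains B,
#' C, ...). This is exactly the model that [collapse_model()] recovers
#' from a correct supercell model of the same crystal.
#'
#' @param spec A [disorder_spec()].
#' @return A [structure_model()] in the base cell.
#' @export
average_model <- function(spec) {
  stopifnot(inherits(spec, "disorder_spec"))
  occ_sparse <- (1 - spec$void_probability) / spec$period
  pieces <- list(place_molecule(spec$molecule, spec$base_cell,
                                spec$ordered_placement, "A"))
  ids <- next_chain_ids(length(spec$orientations), used = "A")
  for (i in seq_along(spec$orientations)) {
    pieces[[i + 1]] <- place_molecule(
      spec$molecule, spec$base_cell, spec$sparse_placement, ids[i],
      occ = occ_sparse * spec$orientation_probabilities[i],
      rotation = spec$orientations[[i]]
    )
  }
  structure_model(spec$base_cell, spec$spacegroup, dplyr::bind_rows(pieces))
}

#' Sample a disordered-crystal realization
#'
#' Draws, for each of `n_periods` periods, the slot index (or void) and
#' orientation of the sparse-layer molecule, and builds the full atom
#' list in the corresponding large supercell (`period * n_periods` base
#' cells along the disorder axis; the ordered layer is fully occupied).
#'
#' @param spec A [disorder_spec()].
#' @param n_periods Number of periods, `>= 1`.
#' @param seed Integer seed (defaults to the spec's).
#' @param build_atoms Build the full atom list (default `TRUE`); with
#'   `FALSE` only the slot/orientation choices are drawn, for large
#'   frequency studies.
#' @return An object of class `crystal_realization`: `choices` (tibble
#'   with `period`, `slot` — `NA` for a void — and `orientation`),
#'   `model` (a [structure_model()] in the large supercell, space group
#'   P1, or `NULL` when `build_atoms = FALSE`), and `cell`.
#' @export
sample_realization <- function(spec, n_periods, seed = NULL,
                               build_atoms = TRUE) {
  stopifnot(inherits(spec, "disorder_spec"), n_periods >= 1)
  n_periods <- as.integer(n_periods)
  seed <- as.integer(seed %||% spec$seed)
  n <- spec$period
  draws <- withr::with_seed(seed, {
    void <- stats::runif(n_periods) < spec$void_probability
    slot <- sample.int(n, n_periods, replace = TRUE,
                       prob = spec$slot_probabilities) - 1L
    ori <- sample.int(length(spec$orientations), n_periods, replace = TRUE,
                      prob = spec$orientation_probabilities)
    list(void = void, slot = slot, ori = ori)
  })
  slot <- ifelse(draws$void, NA_integer_, draws$slot)
  choices <- tibble::tibble(period = seq_len(n_periods),
                            slot = slot, orientation = draws$ori)
  total <- n * n_periods
  big <- make_mapping(spec$base_cell, spec$axis, total)$expanded_cell
  ai <- match(spec$axis, c("a", "b", "c"))
  if (!build_atoms) {
    return(structure(list(choices = choices, model = NULL, cell = big),
                     class = "crystal_realization"))
  }
  pieces <- vector("list", 0)
  for (cellk in seq_len(total) - 1L) {
    place <- spec$ordered_placement
    place[ai] <- (place[ai] + cellk) / total
    pieces[[length(pieces) + 1L]] <-
      place_molecule(spec$molecule, big, place, chain = "A")
  }
  for (p in seq_len(n_periods)) {
    if (is.na(choices$slot[p])) next
    cellk <- (p - 1L) * n + choices$slot[p]
    place <- spec$sparse_placement
    place[ai] <- (place[ai] + cellk) / total
    pieces[[length(pieces) + 1L]] <- place_molecule(
      spec$molecule, big, place, chain = "D",
      rotation = spec$orientations[[choices$orientation[p]]]
    )
  }
  atoms <- dplyr::bind_rows(pieces)
  structure(list(choices = choices,
                 model = structure_model(big, "P1", atoms),
                 cell = big),
            class = "crystal_realization")
}

#' @export
print.crystal_realization <- function(x, ...) {
  nv <- sum(is.na(x$choices$slot))
  na <- if (is.null(x$model)) 0L else nrow(x$model$atoms)
  cat(sprintf("<crystal_realization> %d periods (%d voids), %d atoms\n",
              nrow(x$choices), nv, na))
  invisible(x)
}

# Complex F of the ordered copies and of the sparse molecule in each
# (slot, orientation) placement, over one period in the n-fold supercell.
supercell_components <- function(spec, hkl) {
  n <- spec$period
  map <- make_mapping(spec$base_cell, spec$axis, n)
  ai <- map$axis_index
  ord_pieces <- lapply(seq_len(n) - 1L, function(kk) {
    place <- spec$ordered_placement
    place[ai] <- (place[ai] + kk) / n
    place_molecule(spec$molecule, map$expanded_cell, place, "A")
  })
  ord_model <- structure_model(map$expanded_cell, spec$spacegroup,
                               dplyr::bind_rows(ord_pieces))
  f_ord <- fcalc_complex(ord_model, hkl)
  f_sp <- vector("list", n)
  for (s in seq_len(n) - 1L) {
    f_sp[[s + 1]] <- lapply(seq_along(spec$orientations), function(o) {
      place <- spec$sparse_placement
      place[ai] <- (place[ai] + s) / n
      m <- structure_model(map$expanded_cell, spec$spacegroup,
                           place_molecule(spec$molecule, map$expanded_cell,
                                          place, "D",
                                          rotation = spec$orientations[[o]]))
      fcalc_complex(m, hkl)
    })
  }
  list(mapping = map, f_ord = f_ord, f_sp = f_sp)
}

apply_amplitude_noise <- function(amp, fraction, seed) {
  if (fraction <= 0) {
    return(list(f_obs = amp, sig_f = rep(0, length(amp))))
  }
  noisy <- withr::with_seed(as.integer(seed), {
    pmax(amp * (1 + fraction * stats::rnorm(length(amp))), 0)
  })
  list(f_obs = noisy, sig_f = fraction * amp)
}

#' Simulate Bragg amplitudes of a layered-disorder crystal
#'
#' In `analytic` mode the Bragg amplitudes are `|F|` of the average
#' structure ([average_model()]): ordered sites at occupancy 1, the
#' sparse site at occupancy `(1 - void) / n` — the coherent average
#' `|<F>|` of the substitutionally disordered crystal. In `empirical`
#' mode the complex structure factors of `n_realizations` seeded
#' one-period realizations are averaged in the n-fold supercell and
#' mapped to small-cell indices (`F_small(h) = <F_super(n h)> / n`);
#' supercell reflections off the sublattice (index not divisible by n on
#' the disorder axis) average toward zero with the number of
#' realizations — they carry only diffuse, non-Bragg intensity.
#' Optional multiplicative Gaussian amplitude noise (truncated at zero)
#' fills `sig_f` with `noise * amplitude`.
#'
#' @param spec A [disorder_spec()].
#' @param d_min Resolution limit (Å).
#' @param mode `"analytic"` or `"empirical"`.
#' @param sublattice_only In empirical mode, return the small-cell set
#'   (default). With `FALSE`, return the full supercell set (indices not
#'   reduced to the sublattice), for inspecting the diffuse components.
#' @param n_realizations,seed Override the spec's values.
#' @return A [reflection_set()] with `f_obs` (and `sig_f`) filled, in the
#'   base cell (or the n-fold supercell when `sublattice_only = FALSE`).
#' @export
simulate_bragg <- function(spec, d_min,
                           mode = c("analytic", "empirical"),
                           sublattice_only = TRUE,
                           n_realizations = NULL, seed = NULL) {
  stopifnot(inherits(spec, "disorder_spec"))
  mode <- match.arg(mode)
  seed <- as.integer(seed %||% spec$seed)
  if (mode == "analytic") {
    refls <- generate_unique_hkl(spec$base_cell, spec$spacegroup, d_min)
    avg <- average_model(spec)
    refls <- fcalc(avg, refls)
    nz <- apply_amplitude_noise(refls$f_calc, spec$amplitude_noise, seed)
    refls$f_obs <- nz$f_obs
    refls$sig_f <- nz$sig_f
    refls$observed <- TRUE
    refls$f_calc <- NA_real_
    refls$phi_calc <- NA_real_
    return(refls)
  }
  m <- n_realizations %||% spec$n_realizations
  if (m < 2) stop("insufficient sampling: empirical mode needs n_realizations >= 2",
                  call. = FALSE)
  n <- spec$period
  map <- make_mapping(spec$base_cell, spec$axis, n)
  super <- generate_unique_hkl(map$expanded_cell, spec$spacegroup, d_min)
  hkl <- as.matrix(super[, c("h", "k", "l")])
  comp <- supercell_components(spec, hkl)
  draws <- withr::with_seed(seed, {
    void <- stats::runif(m) < spec$void_probability
    slot <- sample.int(n, m, replace = TRUE, prob = spec$slot_probabilities)
    ori <- sample.int(length(spec$orientations), m, replace = TRUE,
                      prob = spec$orientation_probabilities)
    list(void = void, slot = slot, ori = ori)
  })
  f_mean <- comp$f_ord  # ordered part identical in every realization
  for (s in seq_len(n)) {
    for (o in seq_along(spec$orientations)) {
      cnt <- sum(!draws$void & draws$slot == s & draws$ori == o)
      if (cnt > 0) f_mean <- f_mean + (cnt / m) * comp$f_sp[[s]][[o]]
    }
  }
  ai <- map$axis_index
  on_sub <- hkl[, ai] %% n == 0
  if (!sublattice_only) {
    nz <- apply_amplitude_noise(Mod(f_mean), spec$amplitude_noise, seed + 1L)
    super$f_obs <- nz$f_obs
    super$sig_f <- nz$sig_f
    super$observed <- TRUE
    return(super)
  }
  idx <- hkl[on_sub, , drop = FALSE]
  idx[, ai] <- idx[, ai] %/% n
  amp <- Mod(f_mean[on_sub]) / n
  nz <- apply_amplitude_noise(amp, spec$amplitude_noise, seed + 1L)
  reflection_set(
    tibble::tibble(h = idx[, 1], k = idx[, 2], l = idx[, 3],
                   f_obs = nz$f_obs, sig_f = nz$sig_f, observed = TRUE),
    spec$base_cell, spec$spacegroup, d_min = d_min
  )
}

#' Simulate merohedral twinning
#'
#' Sums twin-domain intensities: `I_twin(h) = sum_i fraction_i *
#' I(op_i h)`. Intensities are taken from the `intensity` column, or
#' `f_obs^2` when absent; amplitudes are updated to `sqrt(I_twin)`.
#'
#' @param refls A [reflection_set()] with intensities (or amplitudes).
#' @param twin_ops List of 3 x 3 integer index permutation matrices
#'   (include the identity for the reference domain).
#' @param fractions Twin fractions, `>= 0`, summing to 1.
#' @return The reflection set with twinned `intensity` and `f_obs`.
#' @export
simulate_twin <- function(refls, twin_ops, fractions) {
  stopifnot(inherits(refls, "reflection_set"))
  if (length(twin_ops) != length(fractions) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be >= 0, one per twin operator, and sum to 1",
         call. = FALSE)
  }
  intens <- refls$intensity
  if (all(is.na(intens))) intens <- refls$f_obs^2
  if (anyNA(intens)) stop("intensities (or f_obs) required for all reflections",
                          call. = FALSE)
  keys <- hkl_key(refls$h, refls$k, refls$l)
  hkl <- as.matrix(refls[, c("h", "k", "l")])
  out <- rep(0, nrow(refls))
  for (i in seq_along(twin_ops)) {
    mapped <- round(hkl %*% as.matrix(twin_ops[[i]]))
    # map back to the set's unique representatives (mates share intensity)
    mapped <- reduce_hkl(mapped, rs_spacegroup(refls))
    j <- match(hkl_key(mapped[, 1], mapped[, 2], mapped[, 3]), keys)
    if (anyNA(j)) {
      stop("incomplete coverage: twin operator maps outside the reflection set",
           call. = FALSE)
    }
    out <- out + fractions[i] * intens[j]
  }
  refls$intensity <- out
  refls$f_obs <- sqrt(out)
  refls
}

#' Simulate untwinned acentric (Wilson) intensities
#'
#' Fills the `intensity` column with independent exponential draws (the
#' acentric Wilson distribution with unit mean) and `f_obs` with their
#' square roots. A convenience generator for the twinning diagnostics.
#'
#' @param refls A [reflection_set()].
#' @param seed Integer seed.
#' @return The reflection set with `intensity` and `f_obs` filled,
#'   observed.
#' @export
simulate_wilson <- function(refls, seed = 1) {
  stopifnot(inherits(refls, "reflection_set"))
  refls$intensity <- withr::with_seed(as.integer(seed),
                                      stats::rexp(nrow(refls)))
  refls$f_obs <- sqrt(refls$intensity)
  refls$observed <- TRUE
  refls
}
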