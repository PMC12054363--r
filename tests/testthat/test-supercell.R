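small_cell <- unit_cell(15, 22, 18)

# one ordered chain (A) plus a sparse-layer chain (B) in another place
two_chain_model <- function(cell = small_cell, sg = "P21") {
  toy_cluster_model(cell, sg,
                    list(A = c(0.20, 0.30, 0.40), B = c(0.60, 0.75, 0.10)))
}

split_chains <- function(model, chains) {
  out <- model
  out$atoms <- model$atoms[model$atoms$chain %in% chains, ]
  out
}

build_triple <- function(n = 3, sg = "P21", cell = small_cell) {
  both <- two_chain_model(cell, sg)
  ordered <- split_chains(both, "A")
  map <- make_mapping(cell, "a", n)
  expand_model(ordered, map, alt_model = both, anchor_chain = "A",
               sparse_chains = "B")
}

test_that("mapping arithmetic: tripling a = 41.84 A gives a' = 125.52 A", {
  cl <- unit_cell(41.84, 185.32, 128.39)
  map <- make_mapping(cl, "a", 3)
  expect_identical(map$expanded_cell$a, 3 * 41.84)
  expect_equal(map$expanded_cell$a, 125.52, tolerance = 1e-12)
  expect_equal(map$expanded_cell$b, cl$b)
  expect_equal(length(map$copy_translations), 3)
  # n = 1 is the identity; n = 2 on b gives {0, 1/2} along b
  expect_equal(make_mapping(cl, "a", 1)$expanded_cell$a, cl$a)
  m2 <- make_mapping(unit_cell(50, 100, 60), "b", 2)
  expect_equal(m2$expanded_cell$b, 200)
  expect_equal(m2$copy_translations, list(c(0, 0, 0), c(0, 0.5, 0)))
  expect_error(make_mapping(cl, "a", 0), "invalid factor")
})

test_that("expansion makes n ordered copies plus the sparse chain", {
  tri <- build_triple(3)
  expect_equal(model_chains(tri), c("A", "B", "C", "D"))
  roles <- chain_roles(tri)
  expect_equal(roles$role, c("ordered", "ordered", "ordered", "sparse"))
  # copy k differs from copy 0 by exactly k/n on the mapping axis
  a <- tri$atoms[tri$atoms$chain == "A", ]
  for (kk in 1:2) {
    cp <- tri$atoms[tri$atoms$chain == c("B", "C")[kk], ]
    expect_equal(cp$x - a$x, rep(kk / 3, nrow(a)), tolerance = 1e-12)
    expect_equal(cp$y, a$y)
    expect_equal(cp$z, a$z)
  }
})

test_that("a grossly misaligned anchor is rejected", {
  both <- two_chain_model()
  ordered <- split_chains(both, "A")
  shifted <- both
  # non-rigid distortion of the anchor: a rigid fit cannot absorb it
  set.seed(99)
  na <- nrow(shifted$atoms)
  shifted$atoms$y <- shifted$atoms$y + runif(na, -0.5, 0.5)
  shifted$atoms$z <- shifted$atoms$z + runif(na, -0.5, 0.5)
  map <- make_mapping(small_cell, "a", 3)
  expect_error(
    expand_model(ordered, map, alt_model = shifted, anchor_chain = "A",
                 sparse_chains = "B", max_anchor_rmsd = 5),
    "misalignment")
})

test_that("NCS propagation copies edits to translated copies and is idempotent", {
  tri <- build_triple(3)
  # edit one atom of chain A
  i <- which(tri$atoms$chain == "A")[1]
  tri$atoms$y[i] <- tri$atoms$y[i] + 0.07
  tri$atoms$b[i] <- 55
  d_before <- tri$atoms[tri$atoms$chain == "D", ]
  p1 <- propagate_ncs(tri, "A", c("B", "C"))
  a <- p1$atoms[p1$atoms$chain == "A", ]
  b <- p1$atoms[p1$atoms$chain == "B", ]
  expect_equal(b$y, a$y)
  expect_equal(b$b, a$b)
  expect_equal(b$x - a$x, rep(1 / 3, nrow(a)), tolerance = 1e-12)
  # idempotent
  p2 <- propagate_ncs(p1, "A", c("B", "C"))
  expect_equal(p2$atoms, p1$atoms)
  # the sparse chain is untouched
  expect_equal(p1$atoms[p1$atoms$chain == "D", ], d_before)
})

test_that("collapse assigns occupancies (1, 1/n) and counts molecules per ASU", {
  tri <- build_triple(3)
  coll <- collapse_model(tri)
  occ <- vapply(split(coll$atoms$occ, coll$atoms$chain), unique, numeric(1))
  expect_equal(unname(occ), c(1, 1 / 3))
  expect_equal(molecules_per_asu(coll), 1 + 1 / 3)
  expect_equal(round(molecules_per_asu(coll), 2), 1.33)
  # n = 2 reproduces the half-occupancy overlap case
  dup <- build_triple(2)
  coll2 <- collapse_model(dup)
  expect_equal(min(coll2$atoms$occ), 0.5)
  expect_equal(molecules_per_asu(coll2), 1.5)
  # n = 1 collapse is the identity on coordinates and occupancies
  one <- build_triple(1)
  coll1 <- collapse_model(one)
  both <- two_chain_model()
  expect_equal(coll1$atoms$x, both$atoms$x %% 1, tolerance = 1e-12)
  expect_equal(unique(coll1$atoms$occ), 1)
})

test_that("expand -> collapse round trip restores the small-cell model", {
  both <- two_chain_model()
  coll <- collapse_model(build_triple(3))
  orth0 <- frac_to_orth(small_cell, both$atoms)
  orth1 <- frac_to_orth(small_cell, coll$atoms)
  # same coordinates modulo lattice translations
  dfr <- sparsecell:::wrap_frac(as.matrix(coll$atoms[, c("x", "y", "z")]) -
                                  as.matrix(both$atoms[, c("x", "y", "z")]))
  dev <- frac_to_orth(small_cell, dfr)
  expect_lt(max(abs(dev)), 1e-8)
})

test_that("inconsistent ordered copies are refused at collapse", {
  tri <- build_triple(3)
  i <- which(tri$atoms$chain == "B")[2]
  tri$atoms$z[i] <- tri$atoms$z[i] + 0.01
  expect_error(collapse_model(tri), "inconsistency")
})

test_that("deconvolution identity: F_expanded(n h, k, l) = n F_collapsed(h, k, l)", {
  set.seed(55)
  for (trial in 1:50) {
    n <- sample(2:4, 1)
    sg <- sample(c("P1", "P21"), 1)
    cl <- unit_cell(runif(1, 10, 18), runif(1, 12, 24), runif(1, 10, 20))
    both <- toy_cluster_model(cl, sg,
                              list(A = runif(3, 0.05, 0.45),
                                   B = runif(3, 0.5, 0.95)),
                              n_atoms = 4, mol_seed = trial)
    ordered <- both
    ordered$atoms <- both$atoms[both$atoms$chain == "A", ]
    map <- make_mapping(cl, "a", n)
    expd <- expand_model(ordered, map, alt_model = both, anchor_chain = "A",
                         sparse_chains = "B")
    coll <- collapse_model(expd)
    hkl <- as.matrix(generate_unique_hkl(cl, sg, 4)[, c("h", "k", "l")])
    hkl_exp <- hkl
    hkl_exp[, 1] <- n * hkl[, 1]
    f_exp <- sparsecell:::fcalc_complex(expd, hkl_exp)
    f_coll <- sparsecell:::fcalc_complex(coll, hkl)
    scale <- sqrt(mean(Mod(n * f_coll)^2))
    expect_lt(max(Mod(f_exp - n * f_coll)), 1e-8 * scale)
  }
})

test_that("the n ordered copies contribute equally to sublattice reflections", {
  tri <- build_triple(3)
  hkl <- as.matrix(generate_unique_hkl(small_cell, "P21", 4)[, c("h", "k", "l")])
  hkl[, 1] <- 3 * hkl[, 1]
  fs <- lapply(c("A", "B", "C"), function(ch) {
    m <- split_chains(tri, ch)
    sparsecell:::fcalc_complex(m, hkl)
  })
  scale <- sqrt(mean(Mod(fs[[1]])^2))
  expect_lt(max(Mod(fs[[2]] - fs[[1]])), 1e-10 * scale)
  expect_lt(max(Mod(fs[[3]] - fs[[1]])), 1e-10 * scale)
})

test_that("occupancy scans recover the simulated truth", {
  spec <- disorder_spec(amplitude_noise = 0)
  data <- simulate_bragg(spec, 2.8, mode = "analytic")
  truth <- average_model(spec)
  scan <- estimate_sparse_occupancy(truth, "B", data)
  expect_lte(abs(scan$best_occupancy - 1 / 3), 0.011)  # a grid point adjacent to 1/3
  expect_equal(glance(scan)$best_occupancy, scan$best_occupancy)
  # noise-free profile decreases toward the optimum from both sides
  prof <- tidy(scan)
  i0 <- which.min(prof$r_factor)
  expect_true(all(diff(prof$r_factor[1:i0]) < 0))
  expect_true(all(diff(prof$r_factor[i0:nrow(prof)]) > 0))
  # data simulated without the sparse chain: scan returns zero
  spec0 <- disorder_spec(void_probability = 1 - 1e-9, amplitude_noise = 0)
  data0 <- simulate_bragg(spec0, 2.8, mode = "analytic")
  scan0 <- estimate_sparse_occupancy(truth, "B", data0)
  expect_equal(scan0$best_occupancy, 0)
  expect_error(estimate_sparse_occupancy(truth, "B",
                                         generate_unique_hkl(spec$base_cell, "P1", 3)),
               "no data")
})

test_that("occupancy recovery holds under 5% amplitude noise across seeds", {
  hits <- vapply(1:20, function(s) {
    spec <- disorder_spec(amplitude_noise = 0.05, seed = s)
    data <- simulate_bragg(spec, 2.8, mode = "analytic", seed = s)
    scan <- estimate_sparse_occupancy(average_model(spec), "B", data)
    scan$best_occupancy
  }, numeric(1))
  expect_true(all(abs(hits - 1 / 3) <= 0.05))
})
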