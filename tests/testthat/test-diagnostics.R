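wilson_set <- function(d_min = 2.2, seed = 5, a = 30) {
  rs <- generate_unique_hkl(unit_cell(a, a, a), "P1", d_min)
  simulate_wilson(rs, seed = seed)
}

twofold_op <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3)

test_that("L-test moments match the acentric closed forms", {
  rs <- wilson_set()
  lt <- l_test(rs)
  expect_true(all(abs(lt$values) <= 1))
  expect_lt(abs(lt$mean_abs_L - 0.500), 0.01)
  expect_lt(abs(lt$mean_L2 - 1 / 3), 0.01)
  tw <- simulate_twin(rs, list(diag(3), twofold_op), c(0.5, 0.5))
  lt2 <- l_test(tw)
  expect_lt(abs(lt2$mean_abs_L - 0.375), 0.01)
  expect_lt(abs(lt2$mean_L2 - 0.200), 0.01)
  tiny <- simulate_wilson(generate_unique_hkl(unit_cell(8, 8, 8), "P1", 4),
                          seed = 1)
  expect_error(l_test(tiny), "insufficient pairs")
})

test_that("L- and H-test moments track the closed forms across seeds", {
  # 10 seeds; compare to the theory values within 3 Monte-Carlo s.e.
  for (s in 1:10) {
    rs <- wilson_set(d_min = 2.8, seed = s, a = 25)
    lt <- l_test(rs)
    se_abs <- stats::sd(abs(lt$values)) / sqrt(lt$n_pairs)
    se_sq <- stats::sd(lt$values^2) / sqrt(lt$n_pairs)
    expect_lt(abs(lt$mean_abs_L - 0.5), 3 * se_abs + 1e-6)
    expect_lt(abs(lt$mean_L2 - 1 / 3), 3 * se_sq + 1e-6)
    suppressWarnings(ht <- h_test(rs, twofold_op))
    se_h <- stats::sd(ht$values) / sqrt(ht$n_pairs)
    expect_lt(abs((0.5 - ht$alpha_hat) - 0.5), 3 * se_h + 1e-2)
  }
})

test_that("H-test estimates the twin fraction", {
  rs <- wilson_set(d_min = 1.9, seed = 6)
  # untwinned: alpha ~ 0
  suppressWarnings(h0 <- h_test(rs, twofold_op))
  expect_lt(h0$alpha_hat, 0.02)
  # perfect twin: H identically 0, alpha = 0.5
  tw <- simulate_twin(rs, list(diag(3), twofold_op), c(0.5, 0.5))
  h5 <- h_test(tw, twofold_op)
  expect_lt(max(h5$values), 1e-12)
  expect_equal(h5$alpha_hat, 0.5)
  # alpha = 0.2 recovered within 0.02
  t2 <- simulate_twin(rs, list(diag(3), twofold_op), c(0.8, 0.2))
  h2 <- h_test(t2, twofold_op)
  expect_equal(h2$alpha_hat, 0.2, tolerance = 0.02 / 0.2)
  expect_lt(abs(h2$alpha_hat - 0.2), 0.02)
  # non-involution operator is rejected
  op3 <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3)  # order 3
  expect_error(h_test(rs, op3), "involution")
})

test_that("alpha_hat is monotone in the simulated twin fraction", {
  rs <- wilson_set(d_min = 2.0, seed = 8)
  fr <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  alpha <- vapply(fr, function(a) {
    tw <- simulate_twin(rs, list(diag(3), twofold_op), c(1 - a, a))
    suppressWarnings(h_test(tw, twofold_op)$alpha_hat)
  }, numeric(1))
  expect_true(all(diff(alpha) > -1e-6))
  expect_equal(alpha, fr, tolerance = 0.1)
})

# an exactly threefold-symmetric trimer about z, one cluster per chain
toy_trimer <- function(cell = unit_cell(40, 40, 40), displace = NULL,
                       n_atoms = 6) {
  mol <- make_toy_molecule(n_atoms, 2, seed = 9)
  centre <- c(20, 20, 20)
  arm <- c(8, 0, 0)
  atoms <- dplyr::bind_rows(lapply(0:2, function(i) {
    r <- rotation_about_axis(c(0, 0, 1), 120 * i)
    xyz <- sweep(as.matrix(mol[, c("dx", "dy", "dz")]) %*% t(r), 2,
                 centre + as.numeric(r %*% arm), "+")
    fr <- orth_to_frac(cell, xyz)
    atom_sites(LETTERS[i + 1], seq_len(nrow(mol)), mol$atom,
               x = fr[, 1], y = fr[, 2], z = fr[, 3], b = mol$b)
  }))
  m <- structure_model(cell, "P1", atoms)
  if (!is.null(displace)) {
    # displace atom 1 of chain A by `displace` (A, orthogonal)
    i <- which(m$atoms$chain == "A")[1]
    fr <- orth_to_frac(cell, matrix(displace, 1, 3))
    m$atoms$x[i] <- m$atoms$x[i] + fr[1]
    m$atoms$y[i] <- m$atoms$y[i] + fr[2]
    m$atoms$z[i] <- m$atoms$z[i] + fr[3]
  }
  m
}

cyclic_perms <- list(c(A = "B", B = "C", C = "A"),
                     c(A = "C", B = "A", C = "B"))

test_that("an exactly symmetric trimer has zero symmetrized r.m.s.d.", {
  m <- toy_trimer()
  expect_lt(symmetrized_rmsd(m, cyclic_perms), 1e-9)
})

test_that("a displaced atom gives the closed-form symmetrized r.m.s.d.", {
  # averaging the three cyclic copies spreads a displacement v over the
  # three image atoms: deviations 2v/3, v/3, v/3 among the 3N atoms.
  # Large chains make the rigid-fit correction (O(1/N)) negligible.
  v <- c(0.02, -0.01, 0.015)
  n <- 200
  m <- toy_trimer(displace = v, n_atoms = n)
  expected <- sqrt(sum(v^2) * (4 / 9 + 1 / 9 + 1 / 9) / (3 * n))
  got <- symmetrized_rmsd(m, cyclic_perms)
  expect_equal(got, expected, tolerance = 0.01)
  expect_gt(got, 0)
})

test_that("symmetrized r.m.s.d. validates its inputs", {
  m <- toy_trimer()
  m$atoms <- m$atoms[-1, ]  # unequal chain lengths
  expect_error(symmetrized_rmsd(m, cyclic_perms), "atom count")
  expect_error(symmetrized_rmsd(toy_trimer(), list(c(A = "B", B = "B", C = "A"))),
               "bijection")
  expect_error(symmetrized_rmsd(toy_trimer(), cyclic_perms, atom_filter = "XX"),
               "no atoms")
})
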