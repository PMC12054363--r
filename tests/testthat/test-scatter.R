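ortho_cell <- unit_cell(12, 14, 16)

test_that("a single atom at the origin scatters its atomic number everywhere", {
  m <- structure_model(ortho_cell, "P1",
                       atom_sites("A", 1, "C1", x = 0, y = 0, z = 0, b = 0))
  rs <- fcalc(m, generate_unique_hkl(ortho_cell, "P1", 3))
  expect_equal(rs$f_calc, rep(6, nrow(rs)), tolerance = 1e-12)
  expect_equal(rs$phi_calc %% 360, rep(0, nrow(rs)), tolerance = 1e-8)
})

test_that("the shift theorem holds: translation changes phases, not amplitudes", {
  m <- toy_cluster_model(ortho_cell, "P1", list(A = c(0.2, 0.3, 0.4)))
  v <- c(0.17, -0.26, 0.08)
  m2 <- m
  m2$atoms$x <- m$atoms$x + v[1]
  m2$atoms$y <- m$atoms$y + v[2]
  m2$atoms$z <- m$atoms$z + v[3]
  rs <- generate_unique_hkl(ortho_cell, "P1", 2.5)
  hkl <- as.matrix(rs[, c("h", "k", "l")])
  f1 <- sparsecell:::fcalc_complex(m, hkl)
  f2 <- sparsecell:::fcalc_complex(m2, hkl)
  expect_equal(Mod(f1), Mod(f2), tolerance = 1e-10)
  shift <- exp(2i * pi * as.numeric(hkl %*% v))
  expect_lt(max(Mod(f2 - f1 * shift)), 1e-8 * max(Mod(f1)))
})

test_that("half-cell-related atom pairs extinguish odd reflections", {
  atoms <- dplyr::bind_rows(
    atom_sites("A", 1, "C1", x = 0.13, y = 0.22, z = 0.31, b = 7),
    atom_sites("A", 2, "C2", x = 0.63, y = 0.22, z = 0.31, b = 7)
  )
  m <- structure_model(ortho_cell, "P1", atoms)
  rs <- fcalc(m, generate_unique_hkl(ortho_cell, "P1", 2.5))
  odd <- rs$h %% 2 == 1
  expect_lt(max(rs$f_calc[odd]), 1e-9)
  expect_gt(min(rs$f_calc[!odd]), 0)
})

test_that("Friedel symmetry |F(h)| = |F(-h)| holds exactly", {
  m <- toy_cluster_model(ortho_cell, "P1", list(A = c(0.2, 0.3, 0.4)))
  set.seed(21)
  hkl <- matrix(sample(-6:6, 150, replace = TRUE), ncol = 3)
  fp <- sparsecell:::fcalc_complex(m, hkl)
  fm <- sparsecell:::fcalc_complex(m, -hkl)
  expect_equal(Mod(fp), Mod(fm), tolerance = 1e-12)
  expect_lt(max(Mod(fm - Conj(fp))), 1e-8 * max(Mod(fp)))
})

test_that("fcalc with symmetry equals a brute-force P1 sum over expanded sites", {
  cl_ortho <- unit_cell(18, 22, 26)
  cl_hex <- unit_cell(18, 18, 14, 90, 90, 120)
  cases <- list(list(cell = cl_ortho, sg = "P21"),
                list(cell = cl_ortho, sg = "C2221"),
                list(cell = cl_hex, sg = "P63"))
  for (cs in cases) {
    m <- toy_cluster_model(cs$cell, cs$sg, list(A = c(0.11, 0.23, 0.37)),
                           n_atoms = 5)
    rs <- generate_unique_hkl(cs$cell, cs$sg, 3)
    hkl <- as.matrix(rs[, c("h", "k", "l")])
    f_sym <- sparsecell:::fcalc_complex(m, hkl)
    expanded <- apply_symmetry(m)
    p1 <- structure_model(cs$cell, "P1", expanded[, names(m$atoms)])
    f_p1 <- sparsecell:::fcalc_complex(p1, hkl)
    expect_lt(max(Mod(f_sym - f_p1)), 1e-8 * max(Mod(f_sym)))
  }
})

test_that("scaling recovers exact multiples and R is scale-invariant", {
  m <- toy_cluster_model(ortho_cell, "P1", list(A = c(0.2, 0.3, 0.4)))
  rs <- fcalc(m, generate_unique_hkl(ortho_cell, "P1", 2.5))
  rs$f_obs <- 2 * rs$f_calc
  rs$observed <- TRUE
  res <- scale_and_rfactor(rs)
  expect_equal(res$scale, 2, tolerance = 1e-12)
  expect_equal(res$r_factor, 0, tolerance = 1e-12)
  # multiplying Fo by a constant leaves R unchanged
  rs$f_obs <- rs$f_calc * runif(nrow(rs), 0.5, 1.5)
  r1 <- scale_and_rfactor(rs)$r_factor
  rs2 <- rs
  rs2$f_obs <- rs$f_obs * 7.3
  expect_equal(scale_and_rfactor(rs2)$r_factor, r1, tolerance = 1e-12)
})

test_that("independent Wilson amplitude sets give R near the acentric limit", {
  # two independent exponential intensity sets on a common scale:
  # R converges to 2 - sqrt(2) ~ 0.586
  set.seed(31)
  n <- 1e5
  fo <- sqrt(rexp(n))
  fc <- sqrt(rexp(n))
  r <- sum(abs(fo - fc)) / sum(fo)
  expect_lt(abs(r - 0.586), 0.01)
  # and a model against itself gives R = 0 through the package path
  m <- toy_cluster_model(ortho_cell, "P1", list(A = c(0.2, 0.3, 0.4)))
  rs <- fcalc(m, generate_unique_hkl(ortho_cell, "P1", 2.5))
  rs$f_obs <- rs$f_calc
  rs$observed <- TRUE
  expect_equal(scale_and_rfactor(rs)$r_factor, 0, tolerance = 1e-12)
})

test_that("map coefficients implement the substitution rule", {
  m <- toy_cluster_model(ortho_cell, "P1", list(A = c(0.2, 0.3, 0.4)))
  rs <- fcalc(m, generate_unique_hkl(ortho_cell, "P1", 2.5))
  # fully observed at Fo = k Fc: difference map vanishes, 2Fo-Fc = Fc map
  rs$f_obs <- 1.7 * rs$f_calc
  rs$observed <- TRUE
  co <- map_coefficients(rs)
  expect_lt(max(Mod(co$coef_fofc)), 1e-9)
  fcmap <- 1.7 * rs$f_calc * exp(1i * rs$phi_calc * pi / 180)
  expect_lt(max(Mod(co$coef_2fofc - fcmap)), 1e-8 * max(Mod(fcmap)))
  # zero observations: 2Fo-Fc coefficients are exactly the Fcalc coefficients
  rs0 <- rs
  rs0$f_obs <- NA_real_
  rs0$observed <- FALSE
  co0 <- map_coefficients(rs0)
  fcmap0 <- rs$f_calc * exp(1i * rs$phi_calc * pi / 180)
  expect_lt(max(Mod(co0$coef_2fofc - fcmap0)), 1e-10 * max(Mod(fcmap0)))
  expect_true(all(Mod(co0$coef_fofc) == 0))
  expect_error(map_coefficients(generate_unique_hkl(ortho_cell, "P1", 3)),
               "missing phases")
})

test_that("density synthesis matches the one-term closed form and is linear", {
  cl <- unit_cell(10, 10, 10)
  df <- tibble::tibble(h = 1, k = 0, l = 0, f_obs = 5, observed = TRUE)
  rs <- reflection_set(df, cl, "P1", d_min = 5)
  rs$f_calc <- 5
  rs$phi_calc <- 0
  co <- map_coefficients(rs, scale = 1)
  x <- seq(0, 0.9, by = 0.1)
  pts <- cbind(x, 0.2, 0.7)
  rho <- density_at_points(co, pts)
  expect_equal(rho, 2 * 5 / cell_volume(cl) * cos(2 * pi * x),
               tolerance = 1e-8)
  # linearity: doubling the coefficients doubles the density
  co2 <- co
  co2$coef_2fofc <- 2 * co$coef_2fofc
  expect_equal(density_at_points(co2, pts), 2 * rho, tolerance = 1e-10)
})

test_that("model density peaks at atom centres", {
  m <- toy_cluster_model(ortho_cell, "P1", list(A = c(0.2, 0.3, 0.4)),
                         n_atoms = 6)
  rs <- fcalc(m, generate_unique_hkl(ortho_cell, "P1", 1.5))
  rs$f_obs <- rs$f_calc
  rs$observed <- TRUE
  co <- map_coefficients(rs, scale = 1)
  at_atoms <- density_at_points(co, as.matrix(m$atoms[, c("x", "y", "z")]))
  set.seed(41)
  random_pts <- matrix(runif(300), ncol = 3)
  at_random <- density_at_points(co, random_pts)
  # every atom centre should beat the 95th percentile of random points
  expect_gt(min(at_atoms), quantile(at_random, 0.95))
  # sigma level via the FFT grid is positive and finite
  expect_gt(map_sigma(co, "2fofc", grid = 32), 0)
})
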