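# Direct-summation structure factors, scaling/R factors, map coefficients
# with the Fcalc substitution rule, and point-wise Fourier synthesis.
#
# Point-atom form factors (f = atomic number, resolution-independent) keep
# every identity in this package exact; Gaussian form-factor tables are an
# extension point.

# Complex structure factors for the given index matrix.
fcalc_complex <- function(model, hkl, chunk = 20000L) {
  stopifnot(is_structure_model(model))
  atoms <- model$atoms
  if (nrow(atoms) == 0) return(rep(complex(real = 0), nrow(hkl)))
  sg <- model$spacegroup
  hkl <- as_xyz_matrix(hkl)
  z <- element_z(atoms$element)
  x <- as.matrix(atoms[, c("x", "y", "z")])
  inv_d2 <- rowSums((hkl %*% rs_metric(model$cell)) * hkl)
  f <- complex(real = rep(0, nrow(hkl)))
  idx <- seq_len(nrow(hkl))
  for (part in split(idx, ceiling(idx / chunk))) {
    hp <- hkl[part, , drop = FALSE]
    # reflection-dependent Debye-Waller factor times occupancy and f_elem
    w <- exp(-outer(inv_d2[part] / 4, atoms$b)) *
      rep(atoms$occ * z, each = length(part))
    acc <- complex(real = rep(0, length(part)))
    for (op in sg$ops) {
      xs <- sweep(x %*% t(op$R), 2, op$t, "+")
      ph <- 2 * pi * (hp %*% t(xs))
      acc <- acc + rowSums(w * exp(1i * ph))
    }
    cen <- complex(real = rep(0, length(part)))
    for (tc in sg$centring) {
      cen <- cen + exp(2i * pi * as.numeric(hp %*% tc))
    }
    f[part] <- acc * cen
  }
  f
}

rs_metric <- function(cell) cell$recip_metric

#' Calculated structure factors by direct summation
#'
#' Computes `F(h) = sum_ops sum_atoms occ * f_elem * exp(-B s^2 / 4) *
#' exp(2 pi i h . (R x + t))` with `s = 1/d` and point-atom form factors
#' `f_elem` equal to the atomic number, and stores amplitude and phase in
#' the `f_calc` and `phi_calc` columns.
#'
#' @param model A [structure_model()]; its space group must be supported
#'   and all B factors non-negative.
#' @param refls A [reflection_set()] giving the indices.
#' @return `refls` with `f_calc` (amplitude) and `phi_calc` (degrees)
#'   filled.
#' @export
fcalc <- function(model, refls) {
  stopifnot(inherits(refls, "reflection_set"))
  f <- fcalc_complex(model, as.matrix(refls[, c("h", "k", "l")]))
  refls$f_calc <- Mod(f)
  refls$phi_calc <- Arg(f) * 180 / pi
  refls
}

rs_complex_fcalc <- function(refls) {
  refls$f_calc * exp(1i * refls$phi_calc * pi / 180)
}

#' Least-squares scale and R factor between observed and calculated
#' amplitudes
#'
#' The scale is `k = sum(|Fo| |Fc|) / sum(|Fc|^2)` and the R factor is
#' `R = sum(| |Fo| - k |Fc| |) / sum(|Fo|)`, both over the common observed
#' reflections. R is invariant to rescaling all observed amplitudes.
#'
#' @param obs A [reflection_set()] carrying `f_obs`. If it also carries
#'   `f_calc`, `calc` may be omitted.
#' @param calc Optional [reflection_set()] carrying `f_calc` for the same
#'   indices.
#' @return A one-row tibble with `scale`, `r_factor` and `n` (reflections
#'   compared).
#' @export
scale_and_rfactor <- function(obs, calc = NULL) {
  stopifnot(inherits(obs, "reflection_set"))
  fo <- obs$f_obs
  if (is.null(calc)) {
    fc <- obs$f_calc
  } else {
    i <- match(hkl_key(obs$h, obs$k, obs$l), hkl_key(calc$h, calc$k, calc$l))
    fc <- calc$f_calc[i]
  }
  use <- obs$observed & !is.na(fo) & !is.na(fc)
  if (!any(use)) stop("no overlap between observed and calculated sets",
                      call. = FALSE)
  fo <- fo[use]; fc <- fc[use]
  k <- sum(fo * fc) / sum(fc^2)
  tibble::tibble(scale = k,
                 r_factor = sum(abs(fo - k * fc)) / sum(fo),
                 n = sum(use))
}

#' Map coefficients with the Fcalc substitution rule for unmeasured data
#'
#' For observed reflections the 2Fo-Fc coefficient is
#' `(2 |Fo| - k |Fc|) exp(i phi_calc)` and the difference (Fo-Fc)
#' coefficient `(|Fo| - k |Fc|) exp(i phi_calc)`. For unmeasured
#' reflections `Fcalc` is substituted: the 2Fo-Fc coefficient is
#' `k |Fc| exp(i phi_calc)` and the difference coefficient is exactly
#' zero, so missing observations contribute model density to 2Fo-Fc maps
#' and nothing to difference maps.
#'
#' @param refls A [reflection_set()] with `f_calc` and `phi_calc` present
#'   for every reflection (see [fcalc()], [fill_unique()]).
#' @param scale Observed-to-calculated scale `k`; by default the
#'   least-squares scale over the observed reflections (1 if none).
#' @return A `map_coefficients` tibble with complex columns `coef_2fofc`
#'   and `coef_fofc` and logical `substituted`, carrying the cell as an
#'   attribute.
#' @export
map_coefficients <- function(refls, scale = NULL) {
  stopifnot(inherits(refls, "reflection_set"))
  if (anyNA(refls$f_calc) || anyNA(refls$phi_calc)) {
    stop("missing phases: f_calc/phi_calc must be present for all reflections",
         call. = FALSE)
  }
  if (is.null(scale)) {
    scale <- if (any(refls$observed)) scale_and_rfactor(refls)$scale else 1
  }
  ph <- exp(1i * refls$phi_calc * pi / 180)
  kfc <- scale * refls$f_calc
  obs <- refls$observed & !is.na(refls$f_obs)
  c2 <- ifelse(obs, 2 * refls$f_obs - kfc, kfc) * ph
  cd <- ifelse(obs, refls$f_obs - kfc, 0) * ph
  cd[is.na(cd)] <- 0
  out <- tibble::tibble(h = refls$h, k = refls$k, l = refls$l, d = refls$d,
                        coef_2fofc = c2, coef_fofc = cd,
                        substituted = !obs)
  structure(out, class = c("map_coefficients", class(tibble::tibble())),
            cell = rs_cell(refls), scale = scale)
}

#' Sigma level (r.m.s. density) of a map
#'
#' Synthesizes the map on a uniform grid by FFT and returns the r.m.s.
#' density, the unit in which map contour levels are quoted.
#'
#' @param coeffs A [map_coefficients()] tibble.
#' @param type `"2fofc"` or `"fofc"`.
#' @param grid Grid points per cell edge (default 64).
#' @return r.m.s. density (e/Å³ in the point-atom convention).
#' @export
map_sigma <- function(coeffs, type = c("2fofc", "fofc"), grid = 64L) {
  type <- match.arg(type)
  cf <- if (type == "2fofc") coeffs$coef_2fofc else coeffs$coef_fofc
  cell <- attr(coeffs, "cell", exact = TRUE)
  n <- as.integer(grid)
  arr <- array(complex(real = 0), dim = c(n, n, n))
  put <- function(h, k, l, v) {
    i <- (h %% n) + 1L; j <- (k %% n) + 1L; m <- (l %% n) + 1L
    idx <- cbind(i, j, m)
    arr[idx] <<- arr[idx] + v
  }
  put(coeffs$h, coeffs$k, coeffs$l, cf)
  put(-coeffs$h, -coeffs$k, -coeffs$l, Conj(cf))
  rho <- Re(stats::fft(arr)) / cell$volume
  sqrt(mean(rho^2))
}

#' Electron density at arbitrary fractional points
#'
#' Fourier synthesis `rho(x) = (1/V) sum_h coef(h) exp(-2 pi i h . x)`
#' over the stored reflections and their Friedel mates.
#'
#' @param coeffs A [map_coefficients()] tibble.
#' @param points Fractional coordinates (n x 3 matrix or data frame).
#' @param type `"2fofc"` or `"fofc"`.
#' @return Numeric density values, one per point.
#' @export
density_at_points <- function(coeffs, points, type = c("2fofc", "fofc")) {
  type <- match.arg(type)
  cf <- if (type == "2fofc") coeffs$coef_2fofc else coeffs$coef_fofc
  cell <- attr(coeffs, "cell", exact = TRUE)
  pts <- as_xyz_matrix(points)
  hkl <- cbind(coeffs$h, coeffs$k, coeffs$l)
  ph <- exp(-2i * pi * (hkl %*% t(pts)))
  # stored half-set plus Friedel mates: 2 Re(...)
  as.numeric(2 * Re(colSums(cf * ph))) / cell$volume
}
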