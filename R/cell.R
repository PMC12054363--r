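# Unit-cell arithmetic. Orthogonalization follows the PDB convention:
# a along x, b in the x-y plane.

#' Create a unit cell
#'
#' Cell lengths are in ångström, angles in degrees. The object carries the
#' fractional-to-orthogonal matrix (`orth`, PDB convention: a along x, b in
#' the x--y plane), its inverse (`frac`), the cell volume and the reciprocal
#' metric tensor used for d-spacings.
#'
#' @param a,b,c Cell edge lengths (Å), all `> 0`.
#' @param alpha,beta,gamma Cell angles (degrees), each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' cl <- unit_cell(41.84, 185.32, 128.39)
#' cell_volume(cl)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("cell lengths must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) {
    stop("degenerate angle combination: metric volume is non-positive",
         call. = FALSE)
  }
  v <- sqrt(v2)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * v / sg
  ), nrow = 3, byrow = TRUE)
  structure(
    list(
      a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
      orth = orth,
      frac = solve(orth),
      volume = a * b * c * v,
      recip_metric = solve(crossprod(orth))
    ),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

#' Cell volume
#'
#' @param cell A [unit_cell()].
#' @return Volume in Å³ (closed-form metric expression).
#' @export
cell_volume <- function(cell) {
  stopifnot(is_unit_cell(cell))
  cell$volume
}

as_xyz_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = FALSE)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3)
  x
}

#' Convert fractional coordinates to orthogonal ångström coordinates
#'
#' @param cell A [unit_cell()].
#' @param x Numeric matrix (n x 3), data frame with `x`,`y`,`z`, or length-3
#'   vector of fractional coordinates.
#' @return An n x 3 matrix of orthogonal coordinates (Å).
#' @export
frac_to_orth <- function(cell, x) {
  stopifnot(is_unit_cell(cell))
  as_xyz_matrix(x) %*% t(cell$orth)
}

#' Convert orthogonal ångström coordinates to fractional coordinates
#'
#' @inheritParams frac_to_orth
#' @param x Coordinates in Å (n x 3 matrix, data frame, or length-3 vector).
#' @return An n x 3 matrix of fractional coordinates.
#' @export
orth_to_frac <- function(cell, x) {
  stopifnot(is_unit_cell(cell))
  as_xyz_matrix(x) %*% t(cell$frac)
}

#' Resolution of reflections in a cell
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @return d-spacings in Å.
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(is_unit_cell(cell))
  hkl <- as_xyz_matrix(hkl)
  inv_d2 <- rowSums((hkl %*% cell$recip_metric) * hkl)
  1 / sqrt(inv_d2)
}

#' Matthews coefficient and solvent content
#'
#' Computes the Matthews volume `Vm = V_cell / (Z * chains_per_asu *
#' chain_mass)` and the solvent fraction `Vs = 1 - vm_constant / Vm`, where
#' `Z` is the number of symmetry operations (including centring) of the
#' space group and `vm_constant` is the conventional protein
#' partial-specific-volume constant 1.230 Å³/Da.
#'
#' `chains_per_asu` may be fractional (occupancy-weighted), as for crystals
#' in which a partially occupied chain contributes e.g. 1/3 of a molecule.
#' When only a residue count is known, a mean residue mass of 110 Da is the
#' conventional assumption for `chain_mass = n_residues * 110`.
#'
#' A solvent fraction outside [0, 1] signals physically implausible input;
#' it is returned with a warning.
#'
#' @param cell A [unit_cell()].
#' @param sg A [spacegroup()].
#' @param chains_per_asu Number of chains per asymmetric unit (may be
#'   fractional, occupancy-weighted); `> 0`.
#' @param chain_mass Mass of one chain in Da; `> 0`.
#' @param vm_constant Protein packing constant in Å³/Da, default 1.230.
#' @return A one-row tibble with `matthews_volume` (Å³/Da) and
#'   `solvent_fraction`.
#' @examples
#' cl <- unit_cell(195.19, 84.50, 195.48, 90, 119.91, 90)
#' matthews_solvent(cl, spacegroup("P21"), chains_per_asu = 6,
#'                  chain_mass = 297 * 110)
#' @export
matthews_solvent <- function(cell, sg, chains_per_asu, chain_mass,
                             vm_constant = 1.230) {
  stopifnot(is_unit_cell(cell), is_spacegroup(sg))
  if (chains_per_asu <= 0) stop("chains_per_asu must be > 0", call. = FALSE)
  if (chain_mass <= 0) stop("chain_mass must be > 0", call. = FALSE)
  vm <- cell$volume / (sg_multiplicity(sg) * chains_per_asu * chain_mass)
  vs <- 1 - vm_constant / vm
  if (vs < 0 || vs > 1) {
    warning(sprintf("solvent fraction %.3f outside [0, 1]: physically implausible input", vs),
            call. = FALSE)
  }
  tibble::tibble(matthews_volume = vm, solvent_fraction = vs)
}
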