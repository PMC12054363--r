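# Rigid-body least-squares superposition (Kabsch) and rotation decomposition.

#' Least-squares rigid-body superposition
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimizing
#' the r.m.s. deviation of `R %*% moving + t` from `fixed` over the given
#' correspondence (Kabsch algorithm via SVD). Chirality is preserved:
#' improper rotations are never returned, so a mirrored set fits with a
#' non-zero r.m.s.d.
#'
#' @param moving,fixed Coordinate matrices (n x 3, Å) or data frames with
#'   `x`,`y`,`z`.
#' @param correspondence Optional two-column integer matrix of index pairs
#'   (moving index, fixed index); by default row i corresponds to row i.
#' @return An object of class `superposition` with elements `rotation`,
#'   `translation`, `rmsd`, `angle` (degrees), `axis` (unit vector) and `n`.
#'   [generics::tidy()] returns the per-element fields as a one-row tibble.
#' @examples
#' set.seed(1)
#' p <- matrix(rnorm(60), ncol = 3)
#' r <- rotation_about_axis(c(0, 0, 1), 11.5)
#' fit <- superpose(p %*% t(r), p)
#' fit$angle
#' @export
superpose <- function(moving, fixed, correspondence = NULL) {
  p <- as_xyz_matrix(moving)
  q <- as_xyz_matrix(fixed)
  if (!is.null(correspondence)) {
    correspondence <- as.matrix(correspondence)
    p <- p[correspondence[, 1], , drop = FALSE]
    q <- q[correspondence[, 2], , drop = FALSE]
  }
  if (nrow(p) != nrow(q)) {
    stop("moving and fixed must have the same number of corresponding points",
         call. = FALSE)
  }
  n <- nrow(p)
  if (n < 3) stop("degenerate fit: need at least 3 points", call. = FALSE)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  if (svd(pc)$d[2] < 1e-8 * max(1, svd(pc)$d[1])) {
    stop("degenerate fit: points are collinear", call. = FALSE)
  }
  h <- crossprod(pc, qc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- pc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - qc)^2)))
  aa <- rotation_angle_axis(rot)
  structure(
    list(rotation = rot, translation = as.numeric(cq - rot %*% cp),
         rmsd = rmsd, angle = aa$angle, axis = aa$axis, n = n),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> n=%d  rmsd=%.4f A  angle=%.2f deg  axis=(%.3f, %.3f, %.3f)\n",
              x$n, x$rmsd, x$angle, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' @export
#' @rdname superpose
#' @param x A `superposition` object.
#' @param ... Unused.
tidy.superposition <- function(x, ...) {
  tibble::tibble(
    rmsd = x$rmsd, angle = x$angle,
    axis_x = x$axis[1], axis_y = x$axis[2], axis_z = x$axis[3],
    n = x$n
  )
}

#' Apply a superposition to coordinates
#'
#' @param fit A `superposition` object.
#' @param x Coordinates (n x 3 matrix or data frame with `x`,`y`,`z`).
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(fit, x) {
  stopifnot(inherits(fit, "superposition"))
  sweep(as_xyz_matrix(x) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Rotation matrix about an axis
#'
#' @param axis Length-3 axis vector (normalized internally).
#' @param angle Rotation angle in degrees.
#' @return A 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Rotation angle and axis of a proper rotation matrix
#'
#' The angle is `acos((trace - 1) / 2)` in `[0, 180]` degrees; the axis is
#' the rotation's fixed direction (for a 180° rotation the sign of the axis
#' is arbitrary).
#'
#' @param rotation A 3 x 3 orthonormal matrix with determinant +1.
#' @return A list with `angle` (degrees) and `axis` (unit vector).
#' @export
rotation_angle_axis <- function(rotation) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("invalid rotation: matrix is not orthonormal with determinant +1",
         call. = FALSE)
  }
  ct <- (sum(diag(rotation)) - 1) / 2
  angle <- acos(min(1, max(-1, ct))) * 180 / pi
  skew <- c(rotation[3, 2] - rotation[2, 3],
            rotation[1, 3] - rotation[3, 1],
            rotation[2, 1] - rotation[1, 2])
  if (sqrt(sum(skew^2)) > 1e-8) {
    axis <- skew / sqrt(sum(skew^2))
  } else if (angle < 90) {
    axis <- c(0, 0, 1)  # identity: any axis; pick z
  } else {
    # 180 degrees: fixed eigenvector of (R + I)
    m <- rotation + diag(3)
    axis <- m[, which.max(colSums(m^2))]
    axis <- axis / sqrt(sum(axis^2))
  }
  list(angle = angle, axis = as.numeric(axis))
}
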