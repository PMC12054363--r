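# Hard-coded operation tables for the supported space groups.
# Rotation parts are integer matrices acting on fractional column vectors
# (x' = R x + t); translations are in fractions of the cell edges.
# Adding a group means adding an entry to .sg_tables.

sg_op <- function(r, t) list(R = matrix(as.numeric(r), 3, 3, byrow = TRUE),
                             t = as.numeric(t))

.sg_tables <- list(
  P1 = list(
    symbol = "P1", pdb_symbol = "P 1",
    ops = list(sg_op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0))),
    centring = list(c(0, 0, 0))
  ),
  # unique axis b: twofold screw along b
  P21 = list(
    symbol = "P21", pdb_symbol = "P 1 21 1",
    ops = list(
      sg_op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0)),
      sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 1 / 2, 0))
    ),
    centring = list(c(0, 0, 0))
  ),
  C2221 = list(
    symbol = "C2221", pdb_symbol = "C 2 2 21",
    ops = list(
      sg_op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0)),
      sg_op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 1 / 2)),
      sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 0, 1 / 2)),
      sg_op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(0, 0, 0))
    ),
    centring = list(c(0, 0, 0), c(1 / 2, 1 / 2, 0))
  ),
  P63 = list(
    symbol = "P63", pdb_symbol = "P 63",
    ops = list(
      sg_op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0)),
      sg_op(c(0, -1, 0, 1, -1, 0, 0, 0, 1), c(0, 0, 0)),
      sg_op(c(-1, 1, 0, -1, 0, 0, 0, 0, 1), c(0, 0, 0)),
      sg_op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 1 / 2)),
      sg_op(c(0, 1, 0, -1, 1, 0, 0, 0, 1), c(0, 0, 1 / 2)),
      sg_op(c(1, -1, 0, 1, 0, 0, 0, 0, 1), c(0, 0, 1 / 2))
    ),
    centring = list(c(0, 0, 0))
  )
)

normalize_sg_symbol <- function(symbol) {
  s <- toupper(gsub("[ _()]", "", symbol))
  s <- sub("^P1211$", "P21", s)
  s <- sub("^P121$", "P2", s)
  s
}

#' Space-group operations
#'
#' Supported symbols: `P1`, `P21` (unique axis b), `C2221`, `P63`.
#' Spaces and underscores in symbols are ignored, so `"P 1 21 1"`,
#' `"C 2 2 21"` and `"P 63"` are accepted. Operation tables are hard-coded;
#' rotation parts are integer matrices on fractional coordinates and all
#' have determinant +1.
#'
#' @param symbol Space-group symbol (character).
#' @return An object of class `spacegroup` with elements `symbol`,
#'   `pdb_symbol`, `ops` (list of `R`, `t` pairs) and `centring` (list of
#'   fractional centring translations).
#' @examples
#' sg <- spacegroup("C2221")
#' sg_multiplicity(sg)
#' @export
spacegroup <- function(symbol) {
  if (is_spacegroup(symbol)) return(symbol)
  key <- normalize_sg_symbol(symbol)
  tab <- .sg_tables[[key]]
  if (is.null(tab)) {
    stop(sprintf("unsupported space group '%s' (supported: %s)", symbol,
                 paste(names(.sg_tables), collapse = ", ")), call. = FALSE)
  }
  structure(tab, class = "spacegroup")
}

is_spacegroup <- function(x) inherits(x, "spacegroup")

#' @export
print.spacegroup <- function(x, ...) {
  cat(sprintf("<spacegroup> %s: %d ops x %d centring (multiplicity %d)\n",
              x$symbol, length(x$ops), length(x$centring), sg_multiplicity(x)))
  invisible(x)
}

#' Number of symmetry operations of a space group
#'
#' Multiplicity of a general position: rotational operations times centring
#' translations (the `Z` of the Matthews computation).
#'
#' @param sg A [spacegroup()].
#' @return Integer count.
#' @export
sg_multiplicity <- function(sg) {
  sg <- spacegroup(sg)
  length(sg$ops) * length(sg$centring)
}

# Unique rotation parts (the point group).
point_rotations <- function(sg) {
  sg <- spacegroup(sg)
  rs <- lapply(sg$ops, `[[`, "R")
  rs[!duplicated(vapply(rs, function(r) paste(r, collapse = ","), ""))]
}

# Point group plus Friedel inversion: the rotations under which reflection
# indices are equivalent.
laue_rotations <- function(sg) {
  rs <- point_rotations(sg)
  all <- c(rs, lapply(rs, function(r) -r))
  all[!duplicated(vapply(all, function(r) paste(r, collapse = ","), ""))]
}

#' Expand a model over its space-group operations
#'
#' Applies every rotational operation and centring translation of the
#' model's space group to every atom site, reducing fractional coordinates
#' to `[0, 1)`. Special positions are not merged: a site on a special
#' position yields coincident copies.
#'
#' @param model A [structure_model()].
#' @return A tibble of symmetry-expanded atom sites with columns as in
#'   `model$atoms` plus `sym_op` and `sym_centring` indices. The row count
#'   is `nrow(model$atoms) * n_ops * n_centrings`.
#' @export
apply_symmetry <- function(model) {
  stopifnot(is_structure_model(model))
  sg <- model$spacegroup
  x <- as.matrix(model$atoms[, c("x", "y", "z")])
  out <- list()
  i <- 0L
  for (io in seq_along(sg$ops)) {
    op <- sg$ops[[io]]
    xo <- x %*% t(op$R)
    xo <- sweep(xo, 2, op$t, "+")
    for (ic in seq_along(sg$centring)) {
      xc <- sweep(xo, 2, sg$centring[[ic]], "+") %% 1
      i <- i + 1L
      img <- model$atoms
      img$x <- xc[, 1]; img$y <- xc[, 2]; img$z <- xc[, 3]
      img$sym_op <- io
      img$sym_centring <- ic
      out[[i]] <- img
    }
  }
  dplyr::bind_rows(out)
}
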