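# Reflection sets: tibbles of Miller indices and amplitudes carrying the
# cell, space group and resolution limit as attributes.

RS_COLS <- c("h", "k", "l", "d", "f_obs", "sig_f", "intensity",
             "f_calc", "phi_calc", "free", "observed")

#' Create a reflection set
#'
#' A reflection set is a tibble with columns `h`, `k`, `l`, `d` (Å),
#' `f_obs`, `sig_f`, `intensity`, `f_calc`, `phi_calc` (degrees), `free`
#' and `observed`, carrying the [unit_cell()], [spacegroup()] and `d_min`
#' as attributes. Missing quantities are `NA`; `observed` defaults to
#' `!is.na(f_obs)`.
#'
#' @param data Data frame with at least `h`, `k`, `l`.
#' @param cell A [unit_cell()].
#' @param spacegroup A [spacegroup()] or symbol.
#' @param d_min Resolution limit in Å (closed: reflections with
#'   `d >= d_min` belong to the set).
#' @return A `reflection_set` tibble.
#' @export
reflection_set <- function(data, cell, spacegroup, d_min = NULL) {
  sg <- spacegroup(spacegroup)
  stopifnot(is_unit_cell(cell))
  df <- tibble::as_tibble(data)
  stopifnot(all(c("h", "k", "l") %in% names(df)))
  df$h <- as.integer(round(df$h)); df$k <- as.integer(round(df$k))
  df$l <- as.integer(round(df$l))
  for (col in setdiff(RS_COLS, c("h", "k", "l", "d", "free", "observed"))) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  if (is.null(df[["free"]])) df$free <- NA
  df$free <- as.logical(df$free)
  df$d <- d_spacing(cell, cbind(df$h, df$k, df$l))
  if (is.null(df[["observed"]])) df$observed <- !is.na(df$f_obs)
  df$observed <- as.logical(df$observed)
  if (any(df$f_obs < 0, na.rm = TRUE)) stop("f_obs must be >= 0", call. = FALSE)
  if (any(df$sig_f < 0, na.rm = TRUE)) stop("sig_f must be >= 0", call. = FALSE)
  if (is.null(d_min)) d_min <- min(df$d)
  df <- df[, RS_COLS]
  new_reflection_set(df, cell, sg, d_min)
}

new_reflection_set <- function(df, cell, sg, d_min) {
  structure(df,
            class = c("reflection_set", class(tibble::tibble())),
            cell = cell, spacegroup = sg, d_min = d_min)
}

# Rebuild a reflection_set around a plain tibble, keeping metadata from a
# template (dplyr verbs strip custom attributes).
restore_rs <- function(df, template, cell = NULL, d_min = NULL) {
  new_reflection_set(tibble::as_tibble(as.data.frame(df))[, RS_COLS],
                     cell %||% rs_cell(template),
                     rs_spacegroup(template),
                     d_min %||% rs_dmin(template))
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %s, %d reflections (%d observed), d_min %.3f A\n",
              rs_spacegroup(x)$symbol, nrow(x), sum(x$observed), rs_dmin(x)))
  NextMethod()
}

#' Metadata of a reflection set
#'
#' @param refls A [reflection_set()].
#' @return The unit cell, space group, or resolution limit stored on the
#'   set.
#' @export
rs_cell <- function(refls) attr(refls, "cell", exact = TRUE)

#' @rdname rs_cell
#' @export
rs_spacegroup <- function(refls) attr(refls, "spacegroup", exact = TRUE)

#' @rdname rs_cell
#' @export
rs_dmin <- function(refls) attr(refls, "d_min", exact = TRUE)

# Collapsed integer key for index triples; exact for |index| < 1024.
hkl_key <- function(h, k, l) {
  ((h + 1024) * 2048 + (k + 1024)) * 2048 + (l + 1024)
}

#' Reduce Miller indices to unique representatives
#'
#' Each index triple is replaced by the lexicographically largest
#' equivalent under the point-group rotations and Friedel inversion of the
#' space group. This is the reduction rule used throughout the package for
#' uniqueness and completeness bookkeeping.
#'
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @param sg A [spacegroup()] or symbol.
#' @return An n x 3 integer matrix of representative indices.
#' @export
reduce_hkl <- function(hkl, sg) {
  sg <- spacegroup(sg)
  hkl <- as_xyz_matrix(hkl)
  rots <- laue_rotations(sg)
  best <- matrix(-Inf, nrow(hkl), 3)
  best_key <- rep(-Inf, nrow(hkl))
  for (r in rots) {
    # reflection indices transform as row vectors: h' = h R
    cand <- round(hkl %*% r)
    key <- hkl_key(cand[, 1], cand[, 2], cand[, 3])
    take <- key > best_key
    if (any(take)) {
      best[take, ] <- cand[take, , drop = FALSE]
      best_key[take] <- key[take]
    }
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  best
}

# TRUE for indices extinct by a centring translation.
centring_forbidden <- function(hkl, sg) {
  sg <- spacegroup(sg)
  hkl <- as_xyz_matrix(hkl)
  bad <- rep(FALSE, nrow(hkl))
  for (tc in sg$centring) {
    if (all(tc == 0)) next
    phase <- hkl %*% tc
    bad <- bad | (abs(phase - round(phase)) > 1e-9)
  }
  bad
}

#' Generate all unique reflections to a resolution limit
#'
#' Enumerates every lattice-allowed unique reflection with `d >= d_min`
#' exactly once, by the reduction rule of [reduce_hkl()]. Centring-extinct
#' reflections are excluded; (0,0,0) is excluded.
#'
#' @param cell A [unit_cell()].
#' @param sg A [spacegroup()] or symbol.
#' @param d_min Resolution limit in Å, `> 0` (closed cutoff).
#' @return A [reflection_set()] with all reflections unobserved.
#' @export
generate_unique_hkl <- function(cell, sg, d_min) {
  sg <- spacegroup(sg)
  stopifnot(is_unit_cell(cell))
  if (!is.numeric(d_min) || d_min <= 0) {
    stop("invalid resolution: d_min must be > 0", call. = FALSE)
  }
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  hs <- seq.int(-hmax, hmax)
  ks <- seq.int(-kmax, kmax)
  ls <- seq.int(-lmax, lmax)
  nh <- length(hs); nk <- length(ks); nl <- length(ls)
  h <- rep(hs, each = nk * nl)
  k <- rep(rep(ks, each = nl), times = nh)
  l <- rep(ls, times = nh * nk)
  hkl <- cbind(h, k, l)
  inv_d2 <- rowSums((hkl %*% cell$recip_metric) * hkl)
  keep <- inv_d2 <= 1 / d_min^2 + 1e-12 & inv_d2 > 0
  hkl <- hkl[keep, , drop = FALSE]
  hkl <- hkl[!centring_forbidden(hkl, sg), , drop = FALSE]
  # keep only self-representative triples: exactly one row per orbit
  red <- reduce_hkl(hkl, sg)
  own <- hkl_key(hkl[, 1], hkl[, 2], hkl[, 3]) ==
    hkl_key(red[, 1], red[, 2], red[, 3])
  hkl <- hkl[own, , drop = FALSE]
  reflection_set(tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                                observed = FALSE),
                 cell, sg, d_min = d_min)
}

#' Reindex a reflection set into an n-fold supercell
#'
#' Maps every index to the expanded cell of `mapping`: for an expansion
#' along `a` by factor `n`, `(h, k, l)` becomes `(n h, k, l)` (cyclically
#' for the other axes) and the cell edge on that axis is multiplied by
#' `n`. d-spacings and all data columns, including observed and free
#' flags, are preserved.
#'
#' @param refls A [reflection_set()].
#' @param mapping A [make_mapping()] built from the set's cell.
#' @return A [reflection_set()] in the expanded cell.
#' @export
reindex_supercell <- function(refls, mapping) {
  stopifnot(inherits(refls, "reflection_set"), inherits(mapping, "supercell_mapping"))
  ai <- mapping$axis_index
  df <- tibble::as_tibble(as.data.frame(refls))
  idx <- as.matrix(df[, c("h", "k", "l")])
  idx[, ai] <- idx[, ai] * mapping$factor
  df$h <- idx[, 1]; df$k <- idx[, 2]; df$l <- idx[, 3]
  out <- restore_rs(df, refls, cell = mapping$expanded_cell)
  out$d <- d_spacing(mapping$expanded_cell, idx)
  out
}

#' Completeness of a reflection set
#'
#' Fraction of lattice-allowed unique reflections with `d >= d_min` that
#' carry observations. The denominator excludes centring-extinct
#' reflections, matching standard practice.
#'
#' @param refls A [reflection_set()].
#' @param d_min Resolution limit (Å); defaults to the set's `d_min`.
#' @return Completeness in `[0, 1]`.
#' @export
completeness <- function(refls, d_min = NULL) {
  stopifnot(inherits(refls, "reflection_set"))
  d_min <- d_min %||% rs_dmin(refls)
  ref <- generate_unique_hkl(rs_cell(refls), rs_spacegroup(refls), d_min)
  if (nrow(ref) == 0) {
    stop("undefined completeness: no lattice-allowed reflections at this resolution",
         call. = FALSE)
  }
  obs <- refls[refls$observed & refls$d >= d_min - 1e-9, c("h", "k", "l")]
  red <- reduce_hkl(as.matrix(obs), rs_spacegroup(refls))
  nobs <- length(intersect(unique(hkl_key(red[, 1], red[, 2], red[, 3])),
                           hkl_key(ref$h, ref$k, ref$l)))
  nobs / nrow(ref)
}

#' Add missing unique reflections to a set as unmeasured rows
#'
#' Unions the set with every lattice-allowed unique reflection at the
#' set's resolution limit; added rows are unobserved with `NA` data. Used
#' before free-flag assignment over "all reflections, measured or not" and
#' before map-coefficient calculation on incomplete data.
#'
#' @param refls A [reflection_set()].
#' @param d_min Resolution limit (Å); defaults to the set's `d_min`.
#' @return A [reflection_set()] containing the full unique set.
#' @export
fill_unique <- function(refls, d_min = NULL) {
  stopifnot(inherits(refls, "reflection_set"))
  d_min <- d_min %||% rs_dmin(refls)
  ref <- generate_unique_hkl(rs_cell(refls), rs_spacegroup(refls), d_min)
  red <- reduce_hkl(as.matrix(refls[, c("h", "k", "l")]), rs_spacegroup(refls))
  have <- hkl_key(red[, 1], red[, 2], red[, 3])
  add <- ref[!(hkl_key(ref$h, ref$k, ref$l) %in% have), ]
  if (nrow(add)) {
    out <- dplyr::bind_rows(tibble::as_tibble(as.data.frame(refls)),
                            tibble::as_tibble(as.data.frame(add)))
  } else {
    out <- refls
  }
  restore_rs(out, refls, d_min = d_min)
}

# Deterministic per-index uniform variate in [0, 1): exact 32-bit
# arithmetic in doubles (a*b mod 2^32 via 16-bit split).
mulmod32 <- function(a, b) {
  alo <- a %% 65536
  ahi <- a %/% 65536
  (alo * b + ((ahi * b) %% 65536) * 65536) %% 4294967296
}

hash01 <- function(h, k, l, seed) {
  slo <- seed %% 65536
  shi <- (seed %/% 65536) %% 65536
  v <- ((h + 2048) * 73856093 + (k + 2048) * 19349663 +
          (l + 2048) * 83492791 + slo * 2971215073 + shi * 433494437) %% 4294967296
  v <- mulmod32(v, 2654435761)
  v <- (v + v %/% 65536 + 2246822519) %% 4294967296
  v <- mulmod32(v, 2246822519)
  v <- (v + v %/% 65536) %% 4294967296
  v / 4294967296
}

#' Assign cross-validation (free-R) flags
#'
#' Flags are a deterministic function of `(seed, h, k, l)`: each
#' reflection's hash is compared against `fraction`, so the same seed
#' always reproduces the same flags and any subset of indices keeps its
#' flags. With `include_unmeasured = TRUE` (default) the set is first
#' completed with [fill_unique()] so that flags cover the full unique set,
#' measured or not; work and free reflections partition the set.
#'
#' @param refls A [reflection_set()].
#' @param fraction Free-set fraction in (0, 1); default 0.05.
#' @param seed Integer seed for the hash.
#' @param include_unmeasured Flag unmeasured reflections too (default
#'   `TRUE`).
#' @return A [reflection_set()] with the `free` column filled.
#' @export
assign_free_flags <- function(refls, fraction = 0.05, seed = 1,
                              include_unmeasured = TRUE) {
  stopifnot(inherits(refls, "reflection_set"))
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (include_unmeasured) refls <- fill_unique(refls)
  u <- hash01(refls$h, refls$k, refls$l, as.numeric(seed))
  free <- u < fraction
  if (!include_unmeasured) free[!refls$observed] <- NA
  refls$free <- free
  refls
}

`%||%` <- function(a, b) if (is.null(a)) b else a
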