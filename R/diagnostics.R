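# Twinning and pseudo-symmetry diagnostics: local-pair L-test, twin-law
# H-test, and r.m.s.d. of a model from its symmetrized version.

twin_stats_obj <- function(l_values = NULL, h_values = NULL, alpha_hat = NA_real_,
                           test = c("L", "H"), n_pairs) {
  test <- match.arg(test)
  v <- if (test == "L") l_values else h_values
  structure(
    list(test = test,
         values = v,
         mean_abs_L = mean(abs(v)),
         mean_L2 = mean(v^2),
         alpha_hat = alpha_hat,
         n_pairs = n_pairs),
    class = "twin_stats"
  )
}

#' @export
print.twin_stats <- function(x, ...) {
  if (x$test == "L") {
    cat(sprintf("<twin_stats> L-test, %d pairs: <|L|> = %.4f (untwinned 0.500, perfect twin 0.375), <L^2> = %.4f (0.333 / 0.200)\n",
                x$n_pairs, x$mean_abs_L, x$mean_L2))
  } else {
    cat(sprintf("<twin_stats> H-test, %d pairs: <H> = %.4f, twin fraction alpha = %.3f\n",
                x$n_pairs, x$mean_abs_L, x$alpha_hat))
  }
  invisible(x)
}

#' @export
#' @rdname l_test
#' @param x A `twin_stats` object.
#' @param ... Unused.
glance.twin_stats <- function(x, ...) {
  tibble::tibble(test = x$test, mean_abs = x$mean_abs_L,
                 mean_sq = x$mean_L2, alpha_hat = x$alpha_hat,
                 n_pairs = x$n_pairs)
}

#' @export
#' @rdname l_test
tidy.twin_stats <- function(x, ...) {
  tibble::tibble(value = x$values)
}

rs_intensities <- function(refls) {
  intens <- refls$intensity
  if (all(is.na(intens))) intens <- refls$f_obs^2
  intens
}

# Fixed stencil of local index offsets (|dh|,|dk|,|dl| <= 2), nearest
# first; the conventional local-pair scheme.
local_stencil <- function(max_offset = 2L) {
  g <- expand.grid(dh = -max_offset:max_offset, dk = -max_offset:max_offset,
                   dl = -max_offset:max_offset)
  g <- g[!(g$dh == 0 & g$dk == 0 & g$dl == 0), ]
  g <- g[order(g$dh^2 + g$dk^2 + g$dl^2, g$dh, g$dk, g$dl), ]
  as.matrix(g)
}

#' Local-intensity L-test for twinning
#'
#' Pairs each reflection with an unrelated neighbour (index offsets
#' within `|dh|, |dk|, |dl| <= max_offset`, excluding symmetry and
#' Friedel mates) and computes `L = (I1 - I2) / (I1 + I2)`. For
#' untwinned acentric data `L` is uniform on (-1, 1): `<|L|> = 1/2`,
#' `<L^2> = 1/3`; a perfect twin gives `3/8` and `1/5`.
#'
#' @param refls A [reflection_set()] with intensities (or amplitudes,
#'   squared internally).
#' @param max_offset Local stencil half-width (default 2).
#' @param min_pairs Minimum number of valid pairs (default 100).
#' @return A `twin_stats` object with `mean_abs_L`, `mean_L2`,
#'   `n_pairs`; [generics::tidy()] returns the L values,
#'   [ggplot2::autoplot()] the cumulative |L| curve against the
#'   untwinned and perfect-twin references.
#' @export
l_test <- function(refls, max_offset = 2L, min_pairs = 100L) {
  stopifnot(inherits(refls, "reflection_set"))
  intens <- rs_intensities(refls)
  ok <- !is.na(intens)
  hkl <- as.matrix(refls[, c("h", "k", "l")])[ok, , drop = FALSE]
  intens <- intens[ok]
  keys <- hkl_key(hkl[, 1], hkl[, 2], hkl[, 3])
  sg <- rs_spacegroup(refls)
  rep_keys <- {
    r <- reduce_hkl(hkl, sg)
    hkl_key(r[, 1], r[, 2], r[, 3])
  }
  n <- nrow(hkl)
  partner <- rep(NA_integer_, n)
  used <- rep(FALSE, n)
  stencil <- local_stencil(max_offset)
  for (s in seq_len(nrow(stencil))) {
    if (all(used)) break
    d <- stencil[s, ]
    cand <- match(hkl_key(hkl[, 1] + d[1], hkl[, 2] + d[2], hkl[, 3] + d[3]),
                  keys)
    free_i <- which(!used & !is.na(cand))
    if (!length(free_i)) next
    j <- cand[free_i]
    good <- !used[j] & free_i != j & rep_keys[free_i] != rep_keys[j]
    free_i <- free_i[good]; j <- j[good]
    # greedy within-pass pairing: each reflection enters at most one pair
    for (t in seq_along(free_i)) {
      a <- free_i[t]; bb <- j[t]
      if (!used[a] && !used[bb]) {
        partner[a] <- bb
        used[a] <- TRUE
        used[bb] <- TRUE
      }
    }
  }
  i <- which(!is.na(partner))
  i1 <- intens[i]; i2 <- intens[partner[i]]
  keep <- (i1 + i2) > 0
  lval <- (i1[keep] - i2[keep]) / (i1[keep] + i2[keep])
  if (length(lval) < min_pairs) {
    stop(sprintf("insufficient pairs: %d valid local pairs (< %d)",
                 length(lval), min_pairs), call. = FALSE)
  }
  twin_stats_obj(l_values = lval, test = "L", n_pairs = length(lval))
}

#' Twin-law H-test and twin-fraction estimate
#'
#' For reflections related by the twin operator, `H = |I(h) - I(op h)| /
#' (I(h) + I(op h))`; for acentric data `<H> = (1 - 2 alpha) / 2`, so the
#' twin fraction is estimated as `alpha_hat = 1/2 - <H>`, clipped to
#' `[0, 0.5]` (with a warning when sampling noise puts `<H>` above 1/2).
#' The operator must be an involution on the set; for higher-order twin
#' laws, test each pairing operator separately.
#'
#' @param refls A [reflection_set()] with intensities (or amplitudes).
#' @param twin_op A 3 x 3 integer index permutation matrix.
#' @param min_pairs Minimum number of twin-related pairs (default 100).
#' @return A `twin_stats` object with `alpha_hat` filled.
#' @export
h_test <- function(refls, twin_op, min_pairs = 100L) {
  stopifnot(inherits(refls, "reflection_set"))
  twin_op <- as.matrix(twin_op)
  if (max(abs(twin_op %*% twin_op - diag(3))) > 1e-9) {
    stop("invalid operator: twin_op must be an involution (op %*% op == identity)",
         call. = FALSE)
  }
  intens <- rs_intensities(refls)
  ok <- !is.na(intens)
  hkl <- as.matrix(refls[, c("h", "k", "l")])[ok, , drop = FALSE]
  intens <- intens[ok]
  keys <- hkl_key(hkl[, 1], hkl[, 2], hkl[, 3])
  mapped <- round(hkl %*% twin_op)
  mapped <- reduce_hkl(mapped, rs_spacegroup(refls))
  j <- match(hkl_key(mapped[, 1], mapped[, 2], mapped[, 3]), keys)
  i <- which(!is.na(j) & j != seq_along(j))
  i <- i[i < j[i]]  # each unordered pair once
  if (length(i) < min_pairs) {
    stop(sprintf("insufficient pairs: %d twin-related pairs (< %d)",
                 length(i), min_pairs), call. = FALSE)
  }
  i1 <- intens[i]; i2 <- intens[j[i]]
  keep <- (i1 + i2) > 0
  hval <- abs(i1[keep] - i2[keep]) / (i1[keep] + i2[keep])
  alpha <- 0.5 - mean(hval)
  if (alpha < 0) {
    warning("mean H exceeds 1/2 (sampling noise); twin fraction clipped to 0",
            call. = FALSE)
  }
  alpha <- min(0.5, max(0, alpha))
  twin_stats_obj(h_values = hval, alpha_hat = alpha, test = "H",
                 n_pairs = length(hval))
}

#' r.m.s.d. of a model from its symmetrized version
#'
#' Builds the symmetrized structure as the average over
#' op-transformed, superposed copies of the model: for every chain
#' permutation in `perms` (e.g. the cyclic permutations of the subunits
#' of a pseudo-symmetric trimer) the permuted copy is rigidly superposed
#' onto the original and the fitted coordinates are averaged (the
#' identity is always included). Returns the r.m.s.d. of the selected
#' atoms between the original and the symmetrized structure: zero iff
#' the model is exactly invariant under the candidate operations.
#'
#' @param model A [structure_model()].
#' @param perms List of named character vectors; `perm[c] = c2` means
#'   chain `c` of the permuted copy takes its coordinates from chain
#'   `c2`. All involved chains must have equal atom counts, in
#'   corresponding order.
#' @param atom_filter Optional atom-name filter (e.g. `"CA"`); default
#'   all atoms of the involved chains.
#' @return r.m.s.d. in Å.
#' @export
symmetrized_rmsd <- function(model, perms, atom_filter = NULL) {
  stopifnot(is_structure_model(model))
  chains <- unique(unlist(lapply(perms, function(p) c(names(p), p))))
  atoms <- model$atoms[model$atoms$chain %in% chains, ]
  counts <- table(atoms$chain)
  if (length(unique(as.integer(counts))) != 1) {
    stop("input error: involved chains differ in atom count", call. = FALSE)
  }
  orth <- frac_to_orth(model$cell, atoms)
  rows_of <- function(ch) which(atoms$chain == ch)
  copies <- list(orth)
  for (p in perms) {
    if (!setequal(names(p), as.character(p)) || anyDuplicated(p)) {
      stop("input error: each permutation must be a bijection of its chains",
           call. = FALSE)
    }
    xg <- orth
    for (ch in names(p)) xg[rows_of(ch), ] <- orth[rows_of(p[[ch]]), ]
    fit <- superpose(xg, orth)
    copies[[length(copies) + 1L]] <- apply_superposition(fit, xg)
  }
  sym <- Reduce(`+`, copies) / length(copies)
  sel <- if (is.null(atom_filter)) rep(TRUE, nrow(atoms)) else
    atoms$atom %in% atom_filter
  if (!any(sel)) stop("atom_filter selects no atoms", call. = FALSE)
  sqrt(mean(rowSums((orth[sel, , drop = FALSE] -
                       sym[sel, , drop = FALSE])^2)))
}
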