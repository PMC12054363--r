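# The core method: expansion of a small-cell model into an n-fold
# supercell, exact NCS propagation between the translated copies, collapse
# back to the small cell with occupancies 1/n, and occupancy estimation.

#' Supercell mapping
#'
#' Links a small cell to the cell expanded by an integer factor `n` along
#' one axis. Carries the n copy translations `0, 1/n, ..., (n-1)/n`
#' (expanded-cell fractions along the axis) and the reindexing rule
#' `(h, k, l) -> (n h, k, l)` (cyclic for the other axes).
#'
#' @param cell The small [unit_cell()].
#' @param axis `"a"`, `"b"` or `"c"`.
#' @param n Integer expansion factor `>= 1`.
#' @return An object of class `supercell_mapping`.
#' @examples
#' make_mapping(unit_cell(41.84, 185.32, 128.39), "a", 3)$expanded_cell$a
#' @export
make_mapping <- function(cell, axis = c("a", "b", "c"), n) {
  stopifnot(is_unit_cell(cell))
  axis <- match.arg(axis)
  if (!is.numeric(n) || n < 1 || n != round(n)) {
    stop("invalid factor: n must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  ai <- match(axis, c("a", "b", "c"))
  len <- c(cell$a, cell$b, cell$c)
  len[ai] <- len[ai] * n
  expanded <- unit_cell(len[1], len[2], len[3],
                        cell$alpha, cell$beta, cell$gamma)
  translations <- lapply(seq_len(n) - 1L, function(k) {
    v <- c(0, 0, 0); v[ai] <- k / n; v
  })
  structure(list(axis = axis, axis_index = ai, factor = n,
                 small_cell = cell, expanded_cell = expanded,
                 copy_translations = translations),
            class = "supercell_mapping")
}

#' @export
print.supercell_mapping <- function(x, ...) {
  cat(sprintf("<supercell_mapping> axis %s x %d: %.2f A -> %.2f A\n",
              x$axis, x$factor,
              c(x$small_cell$a, x$small_cell$b, x$small_cell$c)[x$axis_index],
              c(x$expanded_cell$a, x$expanded_cell$b,
                x$expanded_cell$c)[x$axis_index]))
  invisible(x)
}

next_chain_ids <- function(n, used = character()) {
  pool <- c(LETTERS, letters, as.character(0:9))
  pool <- setdiff(pool, used)
  if (n > length(pool)) stop("too many chains to name", call. = FALSE)
  pool[seq_len(n)]
}

#' Expand a small-cell model into an n-fold supercell
#'
#' Every chain of `ordered_model` appears `n` times in the expanded cell,
#' copy `k` translated by `k/n` along the mapping axis. When an
#' `alt_model` is given (a model of the same crystal in another setting
#' containing the alternative, sparse-layer conformation), it is first
#' superposed onto `ordered_model` via the shared `anchor_chain` and its
#' `sparse_chains` are transferred into the expanded cell unchanged.
#' Chain ids are reassigned alphabetically: the ordered copies take
#' successive letters from the anchor (A -> A, B, C for n = 3), sparse
#' chains continue (D, ...).
#'
#' @param ordered_model A [structure_model()] in the small cell whose
#'   chains form the well-ordered layers.
#' @param mapping A [make_mapping()] built from the small cell.
#' @param alt_model Optional [structure_model()] carrying the sparse-layer
#'   chains; must share `anchor_chain` with `ordered_model`.
#' @param anchor_chain Chain id present in both models, used for the
#'   superposition.
#' @param sparse_chains Chain ids of `alt_model` to transfer as sparse
#'   layers.
#' @param max_anchor_rmsd Misalignment threshold (Å) for the anchor
#'   superposition; default 5.
#' @return A [structure_model()] in the expanded cell with a `roles`
#'   attribute (tibble: chain, role, source_chain, copy) and the mapping
#'   attached.
#' @export
expand_model <- function(ordered_model, mapping, alt_model = NULL,
                         anchor_chain = NULL, sparse_chains = NULL,
                         max_anchor_rmsd = 5) {
  stopifnot(is_structure_model(ordered_model),
            inherits(mapping, "supercell_mapping"))
  n <- mapping$factor
  ai <- mapping$axis_index
  axis_col <- c("x", "y", "z")[ai]
  pieces <- list()
  roles <- list()
  for (ch in model_chains(ordered_model)) {
    src <- ordered_model$atoms[ordered_model$atoms$chain == ch, ]
    for (kk in seq_len(n) - 1L) {
      cp <- src
      cp[[axis_col]] <- cp[[axis_col]] / n + kk / n
      pieces[[length(pieces) + 1L]] <- cp
      roles[[length(roles) + 1L]] <-
        tibble::tibble(role = "ordered", source_chain = ch, copy = kk)
    }
  }
  if (!is.null(alt_model)) {
    stopifnot(is_structure_model(alt_model))
    if (is.null(anchor_chain) ||
        !(anchor_chain %in% model_chains(ordered_model)) ||
        !(anchor_chain %in% model_chains(alt_model))) {
      stop("anchor_chain must be present in both models", call. = FALSE)
    }
    mov <- model_orth(alt_model, anchor_chain)
    fix <- model_orth(ordered_model, anchor_chain)
    if (nrow(mov) != nrow(fix)) {
      stop("anchor chains differ in atom count", call. = FALSE)
    }
    fit <- superpose(mov, fix)
    if (fit$rmsd > max_anchor_rmsd) {
      stop(sprintf("misalignment: anchor superposition rmsd %.2f A exceeds %.2f A",
                   fit$rmsd, max_anchor_rmsd), call. = FALSE)
    }
    for (ch in sparse_chains) {
      src <- alt_model$atoms[alt_model$atoms$chain == ch, ]
      if (nrow(src) == 0) stop(sprintf("sparse chain '%s' not in alt_model", ch),
                               call. = FALSE)
      orth <- apply_superposition(fit, frac_to_orth(alt_model$cell, src))
      fr <- orth_to_frac(mapping$expanded_cell, orth)
      src$x <- fr[, 1]; src$y <- fr[, 2]; src$z <- fr[, 3]
      pieces[[length(pieces) + 1L]] <- src
      roles[[length(roles) + 1L]] <-
        tibble::tibble(role = "sparse", source_chain = ch, copy = NA_integer_)
    }
  }
  ids <- next_chain_ids(length(pieces))
  atoms <- dplyr::bind_rows(purrr::map2(pieces, ids, function(p, id) {
    p$chain <- id
    p
  }))
  roles <- dplyr::bind_rows(roles)
  roles$chain <- ids
  roles <- roles[, c("chain", "role", "source_chain", "copy")]
  out <- structure_model(mapping$expanded_cell, ordered_model$spacegroup, atoms)
  attr(out, "mapping") <- mapping
  attr(out, "roles") <- roles
  out
}

#' Chain roles of an expanded model
#'
#' @param model A model produced by [expand_model()].
#' @return Tibble with columns `chain`, `role`, `source_chain`, `copy`.
#' @export
chain_roles <- function(model) attr(model, "roles", exact = TRUE)

# wrap fractional differences into [-0.5, 0.5)
wrap_frac <- function(x) x - round(x)

#' Propagate edits between supercell copies (exact NCS copying)
#'
#' Overwrites each target chain with the source chain, shifted by the
#' lattice translation separating the copies along the mapping axis. After
#' propagation every target is identical to the source up to that
#' translation; propagation is idempotent and chains outside the target
#' set are untouched.
#'
#' @param expanded A [structure_model()] produced by [expand_model()].
#' @param source_chain Chain id to copy from.
#' @param target_chains Chain ids to copy to (translated copies of the
#'   source).
#' @param mapping A [make_mapping()]; defaults to the one attached to
#'   `expanded`.
#' @return The model with targets replaced.
#' @export
propagate_ncs <- function(expanded, source_chain, target_chains,
                          mapping = NULL) {
  stopifnot(is_structure_model(expanded))
  mapping <- mapping %||% attr(expanded, "mapping", exact = TRUE)
  stopifnot(inherits(mapping, "supercell_mapping"))
  n <- mapping$factor
  axis_col <- c("x", "y", "z")[mapping$axis_index]
  atoms <- expanded$atoms
  src <- atoms[atoms$chain == source_chain, ]
  if (nrow(src) == 0) stop("source chain not found", call. = FALSE)
  for (tg in target_chains) {
    old <- atoms[atoms$chain == tg, ]
    if (nrow(old) != nrow(src)) {
      stop(sprintf("propagation error: chain '%s' length differs from source", tg),
           call. = FALSE)
    }
    shift <- round(n * (mean(old[[axis_col]]) - mean(src[[axis_col]]))) / n
    new <- src
    new$chain <- tg
    new[[axis_col]] <- src[[axis_col]] + shift
    atoms[atoms$chain == tg, ] <- new
  }
  expanded$atoms <- atoms
  expanded
}

#' Collapse a supercell model back into the small cell
#'
#' The `n` translated copies of each ordered chain are checked for
#' consistency (after removing the copy translations the coordinates must
#' agree to `tol`) and replaced by copy 0, refolded into the small cell at
#' occupancy 1. Each sparse chain is refolded at occupancy `occ / n`: in
#' the small cell it overlaps its own lattice-translated images, and the
#' fractional occupancy encodes that only one image in n is present in the
#' real crystal. Chains are renamed alphabetically (ordered prototypes
#' first). The occupancy-weighted molecule count per asymmetric unit,
#' `n_ordered + n_sparse / n`, is attached as attribute
#' `molecules_per_asu`.
#'
#' @param expanded A [structure_model()] produced by [expand_model()] (or
#'   equivalent).
#' @param mapping A [make_mapping()]; defaults to the attached one.
#' @param roles Tibble as from [chain_roles()]; defaults to the attached
#'   one.
#' @param tol Consistency tolerance for ordered copies, as a fraction of
#'   the axis length (default 1e-6).
#' @return A [structure_model()] in the small cell.
#' @export
collapse_model <- function(expanded, mapping = NULL, roles = NULL,
                           tol = 1e-6) {
  stopifnot(is_structure_model(expanded))
  mapping <- mapping %||% attr(expanded, "mapping", exact = TRUE)
  roles <- roles %||% chain_roles(expanded)
  stopifnot(inherits(mapping, "supercell_mapping"), is.data.frame(roles))
  n <- mapping$factor
  ai <- mapping$axis_index
  axis_col <- c("x", "y", "z")[ai]
  atoms <- expanded$atoms
  ordered <- roles[roles$role == "ordered", ]
  sparse <- roles[roles$role == "sparse", ]
  pieces <- list()
  for (src in unique(ordered$source_chain)) {
    grp <- ordered[ordered$source_chain == src, ]
    grp <- grp[order(grp$copy), ]
    if (nrow(grp) != n) {
      stop(sprintf("inconsistency: expected %d ordered copies of '%s', found %d",
                   n, src, nrow(grp)), call. = FALSE)
    }
    ref <- atoms[atoms$chain == grp$chain[1], ]
    for (i in seq_len(nrow(grp))[-1]) {
      cp <- atoms[atoms$chain == grp$chain[i], ]
      if (nrow(cp) != nrow(ref)) {
        stop("inconsistency: ordered copies differ in atom count", call. = FALSE)
      }
      dev <- cbind(wrap_frac(cp$x - ref$x), wrap_frac(cp$y - ref$y),
                   wrap_frac(cp$z - ref$z))
      dev[, ai] <- wrap_frac(dev[, ai] - grp$copy[i] / n + grp$copy[1] / n)
      if (max(abs(dev)) > tol) {
        stop(sprintf("inconsistency: ordered copies of '%s' deviate by %.2g (frac) after translation removal",
                     src, max(abs(dev))), call. = FALSE)
      }
    }
    out <- ref
    out[[axis_col]] <- (out[[axis_col]] * n) %% 1
    pieces[[length(pieces) + 1L]] <- out
  }
  for (i in seq_len(nrow(sparse))) {
    sp <- atoms[atoms$chain == sparse$chain[i], ]
    sp[[axis_col]] <- (sp[[axis_col]] * n) %% 1
    sp$occ <- sp$occ / n
    pieces[[length(pieces) + 1L]] <- sp
  }
  ids <- next_chain_ids(length(pieces))
  out_atoms <- dplyr::bind_rows(purrr::map2(pieces, ids, function(p, id) {
    p$chain <- id
    p
  }))
  out <- structure_model(mapping$small_cell, expanded$spacegroup, out_atoms)
  attr(out, "molecules_per_asu") <-
    length(unique(ordered$source_chain)) + nrow(sparse) / n
  out
}

#' Occupancy-weighted molecules per asymmetric unit
#'
#' @param model A model produced by [collapse_model()].
#' @return Numeric count (e.g. 1.33 for one ordered plus one 1/3-occupied
#'   sparse chain).
#' @export
molecules_per_asu <- function(model) attr(model, "molecules_per_asu", exact = TRUE)

#' Estimate the occupancy of a sparse chain by an R-factor scan
#'
#' Recomputes calculated structure factors with the sparse chain set to
#' each occupancy on `grid` (the rest of the model fixed) and returns the
#' R factor profile against the observed amplitudes and its minimizer.
#' The structure-factor decomposition `F(q) = F_rest + q F_sparse` makes
#' the scan a single pair of direct summations. Ties break toward the
#' smaller occupancy.
#'
#' @param model A [structure_model()] in the small cell.
#' @param sparse_chain Chain id whose occupancy is scanned.
#' @param refls A [reflection_set()] carrying observed amplitudes.
#' @param grid Occupancy grid in `[0, 1]`; default `seq(0, 1, 0.02)`.
#' @return An object of class `occupancy_scan`; [generics::tidy()] gives
#'   the full profile, [generics::glance()] the optimum,
#'   [ggplot2::autoplot()] the R-factor curve.
#' @export
estimate_sparse_occupancy <- function(model, sparse_chain, refls,
                                      grid = seq(0, 1, by = 0.02)) {
  stopifnot(is_structure_model(model), inherits(refls, "reflection_set"))
  if (!any(refls$observed & !is.na(refls$f_obs))) {
    stop("no data: reflection set carries no observed amplitudes", call. = FALSE)
  }
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]", call. = FALSE)
  grid <- sort(grid)
  use <- refls$observed & !is.na(refls$f_obs)
  hkl <- as.matrix(refls[use, c("h", "k", "l")])
  fo <- refls$f_obs[use]
  rest <- model
  rest$atoms <- model$atoms[model$atoms$chain != sparse_chain, ]
  sp <- model
  sp$atoms <- model$atoms[model$atoms$chain == sparse_chain, ]
  if (nrow(sp$atoms) == 0) stop("sparse chain not found in model", call. = FALSE)
  sp$atoms$occ <- 1
  f_rest <- fcalc_complex(rest, hkl)
  f_sp <- fcalc_complex(sp, hkl)
  r_of_q <- vapply(grid, function(q) {
    fc <- Mod(f_rest + q * f_sp)
    kk <- sum(fo * fc) / sum(fc^2)
    sum(abs(fo - kk * fc)) / sum(fo)
  }, numeric(1))
  best <- which.min(r_of_q)  # first minimum = smallest occupancy on ties
  structure(
    list(profile = tibble::tibble(occupancy = grid, r_factor = r_of_q),
         best_occupancy = grid[best], r_min = r_of_q[best],
         sparse_chain = sparse_chain, n_obs = sum(use)),
    class = "occupancy_scan"
  )
}

#' @export
print.occupancy_scan <- function(x, ...) {
  cat(sprintf("<occupancy_scan> chain %s: best occupancy %.3f (R = %.4f) over %d grid points, %d reflections\n",
              x$sparse_chain, x$best_occupancy, x$r_min,
              nrow(x$profile), x$n_obs))
  invisible(x)
}

#' @export
#' @rdname estimate_sparse_occupancy
#' @param x An `occupancy_scan` object.
#' @param ... Unused.
tidy.occupancy_scan <- function(x, ...) x$profile

#' @export
#' @rdname estimate_sparse_occupancy
glance.occupancy_scan <- function(x, ...) {
  tibble::tibble(best_occupancy = x$best_occupancy, r_min = x$r_min,
                 n_obs = x$n_obs)
}
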