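# Programmatic fixtures: toy cluster models and an independent
# brute-force unique-reflection oracle.

# A model with one compact random cluster per chain, centroids at the
# given fractional placements.
toy_cluster_model <- function(cell, sg, placements, n_atoms = 8,
                              radius = 2.5, mol_seed = 3, b = 12) {
  mol <- make_toy_molecule(n_atoms, radius, seed = mol_seed, b = b)
  off <- orth_to_frac(cell, as.matrix(mol[, c("dx", "dy", "dz")]))
  atoms <- dplyr::bind_rows(lapply(names(placements), function(ch) {
    p <- placements[[ch]]
    atom_sites(ch, seq_len(n_atoms), mol$atom,
               x = p[1] + off[, 1], y = p[2] + off[, 2], z = p[3] + off[, 3],
               b = mol$b)
  }))
  structure_model(cell, sg, atoms)
}

# Independent enumeration oracle for unique reflections: brute-force box,
# resolution filter, centring filter, then orbit reduction by exhaustive
# comparison. Only for small cells.
brute_force_unique <- function(cell, sg, d_min) {
  sg <- spacegroup(sg)
  hmax <- floor(cell$a / d_min) + 1
  kmax <- floor(cell$b / d_min) + 1
  lmax <- floor(cell$c / d_min) + 1
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  d <- d_spacing(cell, as.matrix(g))
  g <- g[d >= d_min - 1e-9, ]
  # drop centring-extinct rows
  keep <- rep(TRUE, nrow(g))
  for (tc in sg$centring) {
    if (all(tc == 0)) next
    ph <- as.matrix(g) %*% tc
    keep <- keep & abs(ph - round(ph)) < 1e-9
  }
  g <- g[keep, ]
  # orbit reduction: exhaustively collect each orbit, keep one per orbit
  rots <- sparsecell:::laue_rotations(sg)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  seen <- character(0)
  out <- list()
  gk <- key(as.matrix(g))
  for (i in seq_len(nrow(g))) {
    if (gk[i] %in% seen) next
    out[[length(out) + 1L]] <- as.numeric(g[i, ])
    orbit <- do.call(rbind, lapply(rots, function(r) {
      round(as.matrix(g[i, , drop = FALSE]) %*% r)
    }))
    seen <- c(seen, key(orbit))
  }
  do.call(rbind, out)
}

expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
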