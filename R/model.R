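# Atomic models: a unit cell, a space group and a tibble of atom sites in
# fractional coordinates.

# Point-atom scattering factors: f = atomic number (resolution-independent).
.element_z <- c(
  H = 1, C = 6, N = 7, O = 8, NA. = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA. = 20, MN = 25, FE = 26, CO = 27, NI = 28,
  CU = 29, ZN = 30, SE = 34, BR = 35, I = 53
)

element_z <- function(element) {
  key <- toupper(trimws(element))
  key[key %in% c("NA", "CA")] <- paste0(key[key %in% c("NA", "CA")], ".")
  z <- .element_z[key]
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    stop(sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  unname(z)
}

#' Build an atom-site tibble
#'
#' Coordinates are fractional. Occupancies must lie in `[0, 1]` and B
#' factors must be non-negative.
#'
#' @param chain,resno,resname,atom,element Identifier vectors (recycled).
#' @param x,y,z Fractional coordinates.
#' @param occ Occupancies in `[0, 1]`.
#' @param b Isotropic B factors (Å²), `>= 0`.
#' @return A tibble of atom sites.
#' @export
atom_sites <- function(chain, resno, atom, x, y, z, occ = 1, b = 20,
                       element = "C", resname = "ALA") {
  out <- tibble::tibble(
    chain = as.character(chain), resno = as.integer(resno),
    resname = as.character(resname), atom = as.character(atom),
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    occ = as.numeric(occ), b = as.numeric(b)
  )
  validate_atoms(out)
  out
}

validate_atoms <- function(atoms) {
  need <- c("chain", "resno", "resname", "atom", "element",
            "x", "y", "z", "occ", "b")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  if (any(atoms$b < 0, na.rm = TRUE)) {
    stop("B factors must be >= 0", call. = FALSE)
  }
  invisible(atoms)
}

#' Create a structure model
#'
#' @param cell A [unit_cell()].
#' @param spacegroup A [spacegroup()] or symbol.
#' @param atoms A tibble as produced by [atom_sites()], fractional
#'   coordinates.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(cell, spacegroup, atoms) {
  stopifnot(is_unit_cell(cell))
  sg <- spacegroup(spacegroup)
  validate_atoms(atoms)
  structure(list(cell = cell, spacegroup = sg, atoms = tibble::as_tibble(atoms)),
            class = "structure_model")
}

is_structure_model <- function(x) inherits(x, "structure_model")

#' @export
print.structure_model <- function(x, ...) {
  ch <- model_chains(x)
  cat(sprintf("<structure_model> %s, %d atoms in %d chain(s) [%s]\n",
              x$spacegroup$symbol, nrow(x$atoms), length(ch),
              paste(ch, collapse = ", ")))
  print(x$cell)
  invisible(x)
}

#' Chain identifiers of a model
#'
#' @param model A [structure_model()].
#' @return Character vector of chain ids in order of first appearance.
#' @export
model_chains <- function(model) {
  stopifnot(is_structure_model(model))
  unique(model$atoms$chain)
}

# Orthogonal coordinates (Å) of a model's atoms (optionally one chain).
model_orth <- function(model, chain = NULL) {
  atoms <- model$atoms
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, ]
  frac_to_orth(model$cell, atoms)
}
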