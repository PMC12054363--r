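# File formats: fixed-column PDB (CRYST1 + ATOM/TER/END), the plain-text
# HKL dialect, and key = value run configuration.

pdb_sg_symbols <- c(P1 = "P 1", P21 = "P 1 21 1", C2221 = "C 2 2 21",
                    P63 = "P 63")

#' Read a structure model from a PDB file
#'
#' The file must carry a CRYST1 record with a supported space-group
#' symbol; ATOM/HETATM records are parsed with `bio3d::read.pdb` and
#' coordinates converted from orthogonal Å to fractional.
#'
#' @param path File path.
#' @return A [structure_model()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("format error: no CRYST1 record in ", path, call. = FALSE)
  cr <- cr[1]
  num <- function(from, to) as.numeric(substr(cr, from, to))
  cell <- unit_cell(num(7, 15), num(16, 24), num(25, 33),
                    num(34, 40), num(41, 47), num(48, 54))
  sg <- spacegroup(trimws(substr(cr, 56, 66)))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  fr <- orth_to_frac(cell, cbind(at$x, at$y, at$z))
  element <- ifelse(is.na(at$elesy) | at$elesy == "",
                    substr(trimws(at$elety), 1, 1), trimws(at$elesy))
  atoms <- atom_sites(chain = at$chain, resno = at$resno,
                      resname = at$resid, atom = trimws(at$elety),
                      element = element,
                      x = fr[, 1], y = fr[, 2], z = fr[, 3],
                      occ = at$o, b = at$b)
  structure_model(cell, sg, atoms)
}

#' Write a structure model to a PDB file
#'
#' Fixed-column PDB dialect: CRYST1 (cell + space-group symbol), ATOM
#' records with orthogonal Å coordinates (3 decimals), occupancy and B
#' factor (2 decimals), TER between chains, END. Occupancies such as 1/3
#' round-trip as 0.33.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(is_structure_model(model))
  cell <- model$cell
  sgsym <- pdb_sg_symbols[[model$spacegroup$symbol]]
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                   sgsym, sg_multiplicity(model$spacegroup))
  at <- model$atoms
  orth <- frac_to_orth(cell, at)
  serial <- seq_len(nrow(at))
  name4 <- ifelse(nchar(at$atom) >= 4, substr(at$atom, 1, 4),
                  sprintf(" %-3s", at$atom))
  rec <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 serial %% 100000, name4, substr(at$resname, 1, 3),
                 substr(at$chain, 1, 1), at$resno %% 10000,
                 orth[, 1], orth[, 2], orth[, 3], at$occ, at$b,
                 toupper(at$element))
  # TER after the last atom of each chain
  last <- cumsum(rle(at$chain)$lengths)
  out <- character(0)
  prev <- 0L
  for (e in last) {
    out <- c(out, rec[(prev + 1):e], "TER")
    prev <- e
  }
  writeLines(c(lines, out, "END"), path)
  invisible(path)
}

HKL_FILE_COLS <- c("h", "k", "l", "f_obs", "sig_f", "intensity",
                   "f_calc", "phi_calc", "free", "observed")

#' Read a reflection set from a plain-text HKL table
#'
#' The dialect is whitespace-separated columns with `#` comment headers
#' identifying the columns, cell, space group and resolution limit (as
#' written by [write_hkl()]); unmeasured amplitudes use the sentinel
#' `NA`.
#'
#' @param path File path.
#' @return A [reflection_set()].
#' @export
read_hkl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(tag) {
    ln <- grep(paste0("^# ", tag, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("parse error: missing '# ", tag, ":' header in ",
                          path, call. = FALSE)
    trimws(sub(paste0("^# ", tag, ":"), "", ln[1]))
  }
  cellv <- as.numeric(strsplit(get("cell"), "[ ]+")[[1]])
  cell <- unit_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6])
  sg <- spacegroup(get("spacegroup"))
  d_min <- as.numeric(get("d_min"))
  cols <- strsplit(get("columns"), "[ ]+")[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = body, col.names = cols,
                          na.strings = "NA", colClasses = "numeric")
  df <- tibble::as_tibble(df)
  if (!is.null(df$free)) df$free <- as.logical(df$free)
  if (!is.null(df$observed)) df$observed <- as.logical(df$observed)
  reflection_set(df, cell, sg, d_min = d_min)
}

#' Write a reflection set to a plain-text HKL table
#'
#' @param refls A [reflection_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hkl <- function(refls, path) {
  stopifnot(inherits(refls, "reflection_set"))
  cell <- rs_cell(refls)
  hdr <- c(
    "# sparsecell reflection table",
    sprintf("# cell: %.6g %.6g %.6g %.6g %.6g %.6g",
            cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
    sprintf("# spacegroup: %s", rs_spacegroup(refls)$symbol),
    sprintf("# d_min: %.6g", rs_dmin(refls)),
    paste("# columns:", paste(HKL_FILE_COLS, collapse = " "))
  )
  fmt <- function(x, digits = 6) {
    out <- formatC(x, digits = digits, format = "g")
    out[is.na(x)] <- "NA"
    out
  }
  body <- paste(refls$h, refls$k, refls$l,
                fmt(refls$f_obs), fmt(refls$sig_f), fmt(refls$intensity),
                fmt(refls$f_calc), fmt(refls$phi_calc),
                ifelse(is.na(refls$free), "NA", as.integer(refls$free)),
                as.integer(refls$observed))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a plain-text key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; comma-separated values
#' become vectors; numeric-looking values are converted.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("parse error in config line: ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}
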