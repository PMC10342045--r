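#' Read a multi-model PDB file into a structure ensemble
#'
#' Parses all MODEL blocks of a PDB file (fixed-column format, via
#' bio3d) into a frames x atoms x 3 coordinate array with a shared atom
#' table. Every model must contain the same atoms in the same order;
#' an inconsistent model is reported by its MODEL number before any
#' coordinates are used.
#'
#' @param path PDB file with one or more MODEL blocks (a single
#'   coordinate block counts as one model).
#' @param dt Frame spacing in ns attached to the ensemble.
#'
#' @return An object of class `structure_ensemble`: list with `coords`
#'   (frames x atoms x 3, Angstrom), `atoms` (data frame with columns
#'   `elety`, `resid`, `resno`, `chain`), and `dt`.
#' @export
read_multi_model_pdb <- function(path, dt = 0.1) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path)
  atom_sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atom_sel)) stop("no ATOM/HETATM records in ", path)
  # Fixed-column coordinate fields must parse on every ATOM line.
  coord_txt <- substr(lines[atom_sel], 31, 54)
  bad <- which(is.na(suppressWarnings(as.numeric(substr(coord_txt, 1, 8)))) |
               is.na(suppressWarnings(as.numeric(substr(coord_txt, 9, 16)))) |
               is.na(suppressWarnings(as.numeric(substr(coord_txt, 17, 24)))))
  if (length(bad) > 0) {
    stop(sprintf("malformed ATOM record at line %d of %s",
                 which(atom_sel)[bad[1]], path))
  }
  # Per-model atom counts, validated before handing off to the parser.
  model_idx <- cumsum(grepl("^MODEL", lines))
  if (max(model_idx) > 0) {
    counts <- table(model_idx[atom_sel])
    if (any(names(counts) == "0")) {
      stop("ATOM records found outside MODEL blocks in ", path)
    }
    if (length(unique(as.integer(counts))) != 1L) {
      ref <- as.integer(counts[1])
      off <- which(as.integer(counts) != ref)[1]
      stop(sprintf("MODEL %s has %d atoms but MODEL %s has %d: models must match",
                   names(counts)[off], as.integer(counts)[off],
                   names(counts)[1], ref))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(n_frames, n_atoms, 3L))
  coords[, , 1L] <- xyz[, seq(1L, by = 3L, length.out = n_atoms), drop = FALSE]
  coords[, , 2L] <- xyz[, seq(2L, by = 3L, length.out = n_atoms), drop = FALSE]
  coords[, , 3L] <- xyz[, seq(3L, by = 3L, length.out = n_atoms), drop = FALSE]
  atoms <- data.frame(elety = pdb$atom$elety, resid = pdb$atom$resid,
                      resno = pdb$atom$resno,
                      chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
                      stringsAsFactors = FALSE)
  structure_ensemble(coords, atoms, dt = dt)
}

#' Construct a structure ensemble from coordinates and an atom table
#'
#' @param coords frames x atoms x 3 numeric array (Angstrom), or a
#'   single atoms x 3 matrix for a one-frame ensemble.
#' @param atoms Data frame with columns `elety` (atom name), `resid`
#'   (residue name), `resno` (residue number), `chain`.
#' @param dt Frame spacing in ns.
#' @export
structure_ensemble <- function(coords, atoms, dt = 0.1) {
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (any(!is.finite(coords))) stop("ensemble coordinates must be finite")
  if (nrow(atoms) != dim(coords)[2]) {
    stop("atom table rows must equal the atom dimension of 'coords'")
  }
  if (dt <= 0) stop("'dt' must be positive")
  structure(list(coords = coords, atoms = atoms, dt = dt),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d frames x %d atoms, dt = %g ns\n",
              dim(x$coords)[1], dim(x$coords)[2], x$dt))
  invisible(x)
}

#' Write a structure ensemble as a multi-model PDB
#'
#' @param ens A [structure_ensemble()].
#' @param path Output path.
#' @param b Optional per-atom values for the temperature-factor column
#'   (e.g. computed B-factors), recycled across frames.
#' @export
write_multi_model_pdb <- function(ens, path, b = NULL) {
  stopifnot(inherits(ens, "structure_ensemble"))
  n_frames <- dim(ens$coords)[1]
  n_atoms <- dim(ens$coords)[2]
  b <- rep_len(b %||% 0, n_atoms)
  at <- ens$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    # pad short atom names per PDB convention (column 13 blank for
    # 1-3 character names)
    nm <- ifelse(nchar(at$elety) < 4L, paste0(" ", at$elety), at$elety)
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(n_atoms), nm, "", substr(at$resid, 1, 3), at$chain,
      at$resno, "", ens$coords[f, , 1], ens$coords[f, , 2],
      ens$coords[f, , 3], 1, b), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
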