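#' Molecular system: atoms plus one coordinate set
#'
#' A `MolecularSystem` holds an ordered atom table and one Cartesian
#' coordinate set in Angstrom. Atom order is stable across all operations in
#' the package; residue identity is the key `(chain, resid, icode)` and is
#' never renumbered from the source file.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `icode`, `heavy` (logical).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `MolecularSystem`.
#' @export
molecular_system <- function(atoms, xyz) {
  required <- c("serial", "name", "element", "resname", "resid", "chain",
                "icode", "heavy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L) {
    stop("xyz must be an n_atoms x 3 matrix matching the atom table")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "MolecularSystem")
}

#' @export
print.MolecularSystem <- function(x, ...) {
  res <- unique(x$atoms[, c("chain", "resid", "icode")])
  cat(sprintf("<MolecularSystem> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), nrow(res),
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a system or trajectory topology
#' @param x a `MolecularSystem` or `Trajectory`
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

# Element guessed from a PDB/GRO atom name: strip leading digits, take the
# first alphabetic character. Good enough for C/N/O/S/P/H in biomolecules.
guess_element <- function(name) {
  core <- sub("^[0-9']*", "", trimws(name))
  toupper(substr(core, 1L, 1L))
}

is_heavy_element <- function(element) {
  toupper(trimws(element)) != "H" & trimws(element) != ""
}

validate_system <- function(system) {
  stopifnot(inherits(system, "MolecularSystem"))
  at <- system$atoms
  key <- paste(at$chain, at$resid, at$icode, at$resname, at$name, sep = "|")
  if (anyDuplicated(key)) {
    warning("duplicate (chain, resid, icode, resname, name) atom keys present")
  }
  invisible(system)
}
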