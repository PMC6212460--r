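#' Read a structure file (PDB or GRO)
#'
#' Parses ATOM/HETATM records of a PDB file or a single-frame GRO file into a
#' [molecular_system()]. PDB alternate locations are resolved by keeping the
#' highest-occupancy altloc (ties broken in favour of altloc "A"); insertion
#' codes are kept as part of the residue key. GRO coordinates (nm) are
#' converted to Angstrom.
#'
#' @param path file path.
#' @param format "pdb" or "gro"; default guessed from the file extension.
#' @return a `MolecularSystem`.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- resolve_structure_format(path, format)
  switch(format,
         pdb = read_pdb_system(readLines(path, warn = FALSE), path),
         gro = read_gro_system(readLines(path, warn = FALSE), path),
         stop("unknown structure format: ", format))
}

resolve_structure_format <- function(path, format) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else ext
  }
  format <- tolower(format)
  if (!format %in% c("pdb", "gro")) {
    stop("unsupported structure format '", format, "' (use \"pdb\" or \"gro\")")
  }
  format
}

pdb_field <- function(lines, from, to) substr(lines, from, to)

parse_pdb_atoms <- function(lines, path = "<connection>") {
  rec <- pdb_field(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path)
  n <- length(lines)
  num_or_fail <- function(txt, what, cols) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(out))
    if (length(bad) > 0L) {
      stop(sprintf("malformed PDB %s field at line %d of %s (columns %s): '%s'",
                   what, which(keep)[bad[1]], path, cols, txt[bad[1]]))
    }
    out
  }
  serial <- num_or_fail(pdb_field(lines, 7, 11), "serial", "7-11")
  name <- trimws(pdb_field(lines, 13, 16))
  altloc <- pdb_field(lines, 17, 17)
  resname <- trimws(pdb_field(lines, 18, 21))
  chain <- pdb_field(lines, 22, 22)
  resid <- num_or_fail(pdb_field(lines, 23, 26), "residue number", "23-26")
  icode <- trimws(pdb_field(lines, 27, 27))
  x <- num_or_fail(pdb_field(lines, 31, 38), "x", "31-38")
  y <- num_or_fail(pdb_field(lines, 39, 46), "y", "39-46")
  z <- num_or_fail(pdb_field(lines, 47, 54), "z", "47-54")
  occ <- suppressWarnings(as.numeric(pdb_field(lines, 55, 60)))
  occ[!is.finite(occ)] <- 1.0
  element <- trimws(pdb_field(lines, 77, 78))
  no_el <- element == ""
  element[no_el] <- guess_element(name[no_el])

  atoms <- data.frame(serial = as.integer(serial), name = name,
                      element = element, resname = resname,
                      resid = as.integer(resid), chain = chain,
                      icode = icode, altloc = altloc, occ = occ,
                      stringsAsFactors = FALSE)
  atoms$heavy <- is_heavy_element(atoms$element)
  xyz <- cbind(x, y, z)
  # altloc resolution: within each (chain,resid,icode,name) group keep the
  # highest occupancy; tie -> blank altloc first, then 'A'
  if (any(atoms$altloc != " ")) {
    key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name, sep = "|")
    rank <- order(key, -atoms$occ, atoms$altloc != " ", atoms$altloc)
    keep_idx <- rank[!duplicated(key[rank])]
    keep_idx <- sort(keep_idx)
    atoms <- atoms[keep_idx, , drop = FALSE]
    xyz <- xyz[keep_idx, , drop = FALSE]
  }
  atoms$altloc <- NULL
  atoms$occ <- NULL
  molecular_system(atoms, xyz)
}

read_pdb_system <- function(lines, path) {
  # single-structure read: if MODEL records are present use the first model
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) == 0L) ends <- length(lines)
    lines <- lines[seq(model_starts[1], ends[1])]
  }
  parse_pdb_atoms(lines, path)
}

read_gro_system <- function(lines, path) {
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (!is.finite(n) || n < 1L) stop("malformed GRO atom count at line 2 of ", path)
  if (length(lines) < 2L + n) stop("GRO file shorter than declared atom count: ", path)
  body <- lines[3:(2 + n)]
  resid <- suppressWarnings(as.integer(substr(body, 1, 5)))
  resname <- trimws(substr(body, 6, 10))
  name <- trimws(substr(body, 11, 15))
  serial <- suppressWarnings(as.integer(substr(body, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(body, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(body, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(body, 37, 44)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | !is.finite(resid))
  if (length(bad) > 0L) {
    stop(sprintf("malformed GRO record at line %d of %s", 2L + bad[1], path))
  }
  element <- guess_element(name)
  atoms <- data.frame(serial = serial, name = name, element = element,
                      resname = resname, resid = resid, chain = "A",
                      icode = "", heavy = is_heavy_element(element),
                      stringsAsFactors = FALSE)
  molecular_system(atoms, cbind(x, y, z) * 10.0)  # nm -> Angstrom
}

format_pdb_atom_lines <- function(atoms, xyz, hetero = NULL) {
  n <- nrow(atoms)
  if (is.null(hetero)) {
    std_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
                "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                "TYR", "VAL")
    hetero <- !(atoms$resname %in% std_aa)
  }
  rec <- ifelse(hetero, "HETATM", "ATOM  ")
  # atom-name column convention: 1-2 char element names start in column 14
  nm <- atoms$name
  nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  sprintf("%s%5d %-4s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, atoms$serial %% 100000L, nm4, substr(atoms$resname, 1, 4),
          substr(paste0(atoms$chain, " "), 1, 1), atoms$resid %% 10000L,
          substr(paste0(atoms$icode, " "), 1, 1),
          xyz[, 1], xyz[, 2], xyz[, 3], 1.0, 0.0,
          toupper(substr(atoms$element, 1, 2)))
}

#' Write a structure file (PDB or GRO)
#'
#' Fields preserved by the format round-trip through [read_structure()]
#' unchanged; PDB coordinates are written at the format's 0.001 A precision,
#' GRO at 0.001 nm (0.01 A).
#'
#' @param system a `MolecularSystem`.
#' @param path output path.
#' @param format "pdb" or "gro"; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, format = NULL) {
  stopifnot(inherits(system, "MolecularSystem"))
  format <- resolve_structure_format(path, format)
  if (format == "pdb") {
    lines <- c(format_pdb_atom_lines(system$atoms, system$xyz), "END")
  } else {
    at <- system$atoms
    nm <- system$xyz / 10.0
    lines <- c("written by cavitybind", sprintf("%5d", nrow(at)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$resid %% 100000L, substr(at$resname, 1, 5),
                       substr(at$name, 1, 5), at$serial %% 100000L,
                       nm[, 1], nm[, 2], nm[, 3]),
               sprintf("%10.5f%10.5f%10.5f", 10, 10, 10))
  }
  writeLines(lines, path)
  invisible(path)
}
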