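#' Trajectory: topology plus per-frame coordinates
#'
#' Frames are stored as a 3-D array `n_atoms x 3 x n_frames` in Angstrom,
#' with strictly increasing times in nanoseconds. Frame indices are 0-based
#' everywhere in this package (the convention of mainstream trajectory
#' tools), so `times = t0 + frame * dt`.
#'
#' @param topology a `MolecularSystem`.
#' @param coords array `n_atoms x 3 x n_frames`, or a list of coordinate
#'   matrices.
#' @param times numeric vector of frame times (ns); default `(0:(n-1)) * dt`.
#' @param dt frame interval in ns (required if `times` is missing).
#' @return an object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, dt = NULL) {
  stopifnot(inherits(topology, "MolecularSystem"))
  if (is.list(coords)) {
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3L, length(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != n_atoms(topology)) {
    stop(sprintf("frame atom count (%d) does not match topology (%d)",
                 dim(coords)[1], n_atoms(topology)))
  }
  nf <- dim(coords)[3]
  if (is.null(times)) {
    if (is.null(dt)) stop("provide either times or dt")
    times <- (seq_len(nf) - 1) * dt
  }
  if (length(times) != nf) stop("times length must equal number of frames")
  if (times[1] < 0) stop("times[0] must be >= 0")
  if (nf > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("times must be strictly increasing")
    if (is.null(dt)) dt <- dts[1]
    if (any(abs(dts - dt) > 1e-9)) {
      stop("frame times are not consistent with a constant dt (tolerance 1e-9 ns)")
    }
  } else if (is.null(dt)) dt <- 1.0
  if (dt <= 0) stop("dt must be positive")
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), dt = dt),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d atoms, %d frames, dt = %g ns, t = [%g, %g] ns\n",
              n_atoms(x), n_frames(x), x$dt, x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' @rdname trajectory
#' @param x a `Trajectory`
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' Extract one frame's coordinates
#' @param traj a `Trajectory`
#' @param frame 0-based frame index
#' @return n_atoms x 3 coordinate matrix (Angstrom)
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 0 || frame >= n_frames(traj)) {
    stop("frame index out of range: ", frame)
  }
  traj$coords[, , frame + 1L]
}

#' Read a trajectory (multi-model PDB or DCD)
#'
#' @param topology_path structure file defining the atoms (PDB or GRO).
#' @param traj_path trajectory file.
#' @param format "multipdb", "dcd" or "xtc"; guessed from the extension
#'   (".pdb" means multi-model PDB here). XTC is not supported: its
#'   compression codec has no R implementation available; convert to DCD.
#' @param dt frame interval (ns), used when the file carries no times.
#' @param stride keep every `stride`-th frame (default 1).
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(topology_path, traj_path, format = NULL,
                            dt = NULL, stride = 1L) {
  topo <- if (inherits(topology_path, "MolecularSystem")) topology_path
          else read_structure(topology_path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(traj_path)),
                     pdb = "multipdb", dcd = "dcd", xtc = "xtc",
                     tolower(tools::file_ext(traj_path)))
  }
  format <- tolower(format)
  traj <- switch(format,
    multipdb = read_multipdb(topo, traj_path, dt),
    dcd = read_dcd(topo, traj_path),
    xtc = stop("XTC is not supported (no xdr3dfcoord codec available); ",
               "convert the trajectory to DCD or multi-model PDB"),
    stop("unknown trajectory format: ", format))
  stride <- as.integer(stride)
  if (stride > 1L) {
    keep <- seq(1L, n_frames(traj), by = stride)
    traj <- trajectory(traj$topology, traj$coords[, , keep, drop = FALSE],
                       times = traj$times[keep])
  }
  check_frame_jumps(traj)
  traj
}

# Inputs are assumed whole/imaged (no PBC handling); flag suspicious jumps.
check_frame_jumps <- function(traj, max_jump = 20) {
  nf <- n_frames(traj)
  if (nf < 2L) return(invisible(traj))
  for (k in seq_len(nf - 1L)) {
    d2 <- rowSums((traj$coords[, , k + 1L] - traj$coords[, , k])^2)
    if (any(d2 > max_jump^2)) {
      warning(sprintf(paste0("atom displacement > %g A between frames %d and ",
                             "%d; coordinates may not be PBC-whole"),
                      max_jump, k - 1L, k))
      break
    }
  }
  invisible(traj)
}

read_multipdb <- function(topo, path, dt = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) starts <- 1L
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  na <- n_atoms(topo)
  frames <- vector("list", length(starts))
  times <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    tline <- grep("^REMARK +TIME_NS=", chunk, value = TRUE)
    if (length(tline) > 0L) {
      times[k] <- as.numeric(sub("^REMARK +TIME_NS= *", "", tline[1]))
    }
    sys <- parse_pdb_atoms(chunk, path)
    if (n_atoms(sys) != na) {
      stop(sprintf("frame %d of %s has %d atoms, topology has %d",
                   k - 1L, path, n_atoms(sys), na))
    }
    frames[[k]] <- sys$xyz
  }
  if (anyNA(times)) {
    if (is.null(dt)) dt <- 1.0
    times <- (seq_along(starts) - 1) * dt
  }
  trajectory(topo, frames, times = times)
}

#' Write a trajectory (multi-model PDB or DCD)
#'
#' Multi-model PDB frames carry `REMARK TIME_NS=` lines so times round-trip;
#' DCD stores dt in the header time-step field (interpreted as ns here).
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @param format "multipdb" or "dcd"; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "multipdb", dcd = "dcd",
                     tolower(tools::file_ext(path)))
  }
  format <- tolower(format)
  if (format == "multipdb") {
    at <- traj$topology$atoms
    out <- character(0)
    for (k in seq_len(n_frames(traj))) {
      out <- c(out,
               sprintf("MODEL     %4d", k),
               sprintf("REMARK TIME_NS= %.9f", traj$times[k]),
               format_pdb_atom_lines(at, traj$coords[, , k]),
               "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else if (format == "dcd") {
    write_dcd(traj, path)
  } else stop("unknown trajectory format: ", format)
  invisible(path)
}

# --- DCD binary format (CHARMM-style, no unit cell, little-endian) ---------
# Fortran unformatted records: each block is <int32 len><payload><int32 len>.

write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wblock <- function(writer) writer
  nf <- n_frames(traj)
  # header block: 'CORD' + 20 int32 control words (delta stored as float32
  # in word 10; interpreted as ns by this package's reader)
  writeBin(84L, con, size = 4, endian = "little")
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf
  icntrl[2] <- 1L     # first step
  icntrl[3] <- 1L     # step interval
  icntrl[4] <- nf
  icntrl[20] <- 24L   # CHARMM version flag
  writeBin(icntrl[1:9], con, size = 4, endian = "little")
  writeBin(as.numeric(traj$dt), con, size = 4, endian = "little")
  writeBin(icntrl[11:20], con, size = 4, endian = "little")
  writeBin(84L, con, size = 4, endian = "little")
  # title block
  title <- sprintf("%-80s", "cavitybind trajectory")
  writeBin(84L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 4, endian = "little")
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(84L, con, size = 4, endian = "little")
  # natoms block
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(n_atoms(traj), con, size = 4, endian = "little")
  writeBin(4L, con, size = 4, endian = "little")
  na <- n_atoms(traj)
  blen <- 4L * na
  for (k in seq_len(nf)) {
    for (ax in 1:3) {
      writeBin(blen, con, size = 4, endian = "little")
      writeBin(as.numeric(traj$coords[, ax, k]), con, size = 4,
               endian = "little")
      writeBin(blen, con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

read_dcd <- function(topo, path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1L) readBin(con, "integer", n = n, size = 4,
                                   endian = "little")
  len <- rint()
  if (length(len) == 0L || len != 84L) stop("not a DCD file: ", path)
  magic <- readChar(con, 4)
  if (!identical(magic, "CORD")) stop("not a DCD file (no CORD magic): ", path)
  icntrl_a <- rint(9)
  delta <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  rint(10)  # remaining control words
  rint()    # trailing 84
  tlen <- rint()
  ntitle <- rint()
  readChar(con, 80L * ntitle, useBytes = TRUE)
  rint()
  rint()
  na <- rint()
  rint()
  if (na != n_atoms(topo)) {
    stop(sprintf("DCD atom count (%d) does not match topology (%d)",
                 na, n_atoms(topo)))
  }
  nf_declared <- icntrl_a[1]
  frames <- list()
  k <- 0L
  repeat {
    blen <- rint()
    if (length(blen) == 0L) break
    xyz <- matrix(0.0, na, 3L)
    for (ax in 1:3) {
      if (ax > 1L) blen <- rint()
      vals <- readBin(con, "numeric", n = na, size = 4, endian = "little")
      if (length(vals) < na) {
        stop(sprintf("truncated DCD file %s at frame %d", path, k))
      }
      xyz[, ax] <- vals
      rint()
    }
    k <- k + 1L
    frames[[k]] <- xyz
  }
  if (nf_declared > 0L && k != nf_declared) {
    stop(sprintf("truncated DCD file %s: header declares %d frames, read %d",
                 path, nf_declared, k))
  }
  dt <- if (is.finite(delta) && delta > 0) delta else 1.0
  trajectory(topo, frames, dt = dt)
}
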