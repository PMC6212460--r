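#' Specification of a toy receptor-ligand complex
#'
#' The toy complex abstracts a buried binding cavity: scaffold pseudo-atoms
#' on a spherical shell around an internal cavity, two entrance channels cut
#' into the shell as cones (labelled A and B), gate pseudo-residues on each
#' channel rim, and a rigid 5-atom ligand (hydroxyl oxygen O1, bridging
#' carbon C1, two phosphorus P1/P2, ring-centre dummy R1) at the cavity
#' centre with its O1->C1 axis along +z.
#'
#' @param n_scaffold_atoms number of shell pseudo-atoms before cone removal.
#' @param cavity_radius shell radius in Angstrom.
#' @param channel_axis_A,channel_axis_B unit vectors of the channel axes
#'   (normalized internally); must subtend more than 20 degrees.
#' @param half_angle_A,half_angle_B channel opening half-angles (degrees).
#' @param n_gate_atoms gate pseudo-atoms per channel, placed on the cone rim.
#' @return an object of class `ToyComplexSpec`.
#' @export
toy_complex_spec <- function(n_scaffold_atoms = 400L,
                             cavity_radius = 12,
                             channel_axis_A = c(1, 0, 0),
                             channel_axis_B = c(0, 0.6, 0.8),
                             half_angle_A = 25,
                             half_angle_B = 25,
                             n_gate_atoms = 6L) {
  axis_a <- channel_axis_A / sqrt(sum(channel_axis_A^2))
  axis_b <- channel_axis_B / sqrt(sum(channel_axis_B^2))
  sep <- acos(max(-1, min(1, sum(axis_a * axis_b)))) * 180 / pi
  if (sep <= 20) {
    stop(sprintf("channel axes subtend %.1f degrees; must be > 20", sep))
  }
  if (sep < 0.5 * (half_angle_A + half_angle_B)) {
    stop("channel cones overlap by more than half their width")
  }
  stopifnot(n_scaffold_atoms >= 10L, cavity_radius > 0,
            half_angle_A >= 0, half_angle_B >= 0)
  structure(list(n_scaffold_atoms = as.integer(n_scaffold_atoms),
                 cavity_radius = cavity_radius,
                 axis_A = axis_a, axis_B = axis_b,
                 half_angle_A = half_angle_A, half_angle_B = half_angle_B,
                 n_gate_atoms = as.integer(n_gate_atoms)),
            class = "ToyComplexSpec")
}

# Rigid 5-heavy-atom ligand template (Angstrom), O1 at the origin and the
# O1->C1 axis along +z. Geometry loosely inspired by a bisphosphonate ester
# core; only rigidity matters downstream.
ligand_template <- function() {
  m <- rbind(O1 = c(0.0, 0.0, 0.0),
             C1 = c(0.0, 0.0, 1.54),
             P1 = c(1.55, 0.0, 2.45),
             P2 = c(-1.55, 0.0, 2.45),
             R1 = c(0.0, 1.40, -0.95))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Build a toy complex structure
#'
#' Scaffold atoms are placed deterministically on a Fibonacci lattice over
#' the shell, then atoms falling inside either channel cone are removed.
#' Gate pseudo-residues (resnames `GTA`, `GTB`) sit on each cone rim. All
#' pseudo-atoms are named `CA` so a `name CA` fit selection works; the
#' ligand has resname `LIG`, chain `L`.
#'
#' @param spec a [toy_complex_spec()].
#' @param seed integer seed (the lattice itself is deterministic; the seed
#'   fixes the lattice phase offset so distinct seeds give distinct shells).
#' @return a `MolecularSystem`.
#' @export
make_toy_complex <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ToyComplexSpec"))
  n <- spec$n_scaffold_atoms
  golden <- pi * (3 - sqrt(5))
  phase <- (as.integer(seed) %% 997L) / 997
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ang <- golden * i + 2 * pi * phase
  dirs <- cbind(r * cos(ang), r * sin(ang), z)
  in_cone <- function(d, axis, half_deg) {
    acos(pmax(-1, pmin(1, d %*% axis))) * 180 / pi < half_deg
  }
  drop <- in_cone(dirs, spec$axis_A, spec$half_angle_A) |
    in_cone(dirs, spec$axis_B, spec$half_angle_B)
  shell <- dirs[!drop, , drop = FALSE] * spec$cavity_radius

  rim_atoms <- function(axis, half_deg, n_gate) {
    rot <- rotation_between(c(0, 0, 1), axis)
    th <- (half_deg + 2) * pi / 180   # just outside the cone edge
    az <- 2 * pi * (seq_len(n_gate) - 1) / n_gate
    local <- cbind(sin(th) * cos(az), sin(th) * sin(az), cos(th))
    local %*% rot * spec$cavity_radius
  }
  gate_a <- rim_atoms(spec$axis_A, spec$half_angle_A, spec$n_gate_atoms)
  gate_b <- rim_atoms(spec$axis_B, spec$half_angle_B, spec$n_gate_atoms)
  lig <- ligand_template()

  ns <- nrow(shell); ng <- spec$n_gate_atoms
  atoms <- data.frame(
    serial = seq_len(ns + 2L * ng + nrow(lig)),
    name = c(rep("CA", ns + 2L * ng), rownames(lig)),
    element = c(rep("C", ns + 2L * ng), c("O", "C", "P", "P", "C")),
    resname = c(rep("SCF", ns), rep("GTA", ng), rep("GTB", ng),
                rep("LIG", nrow(lig))),
    resid = c(seq_len(ns), ns + seq_len(ng), ns + ng + seq_len(ng),
              rep(ns + 2L * ng + 1L, nrow(lig))),
    chain = c(rep("A", ns), rep("G", 2L * ng), rep("L", nrow(lig))),
    icode = "", heavy = TRUE, stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, rbind(shell, gate_a, gate_b, unname(lig)))
  attr(sys, "toy_spec") <- spec
  sys
}

#' Mixture of concentrated directional distributions on the sphere
#'
#' Each component is a von Mises-Fisher distribution given by its mean
#' direction in polar coordinates (degrees), concentration kappa and weight.
#'
#' @param theta,phi component mean directions (degrees; theta in [0, 180],
#'   phi in (-180, 180]).
#' @param kappa concentrations (> 0, or 0 for uniform).
#' @param weight mixing weights (normalized to sum to one; must be positive).
#' @return an object of class `OrientationMixtureSpec`.
#' @export
orientation_mixture <- function(theta, phi, kappa, weight = NULL) {
  k <- length(theta)
  stopifnot(length(phi) == k, length(kappa) == k)
  if (is.null(weight)) weight <- rep(1 / k, k)
  stopifnot(length(weight) == k, all(weight > 0))
  if (any(kappa < 0)) stop("kappa must be >= 0")
  weight <- weight / sum(weight)
  structure(list(theta = theta, phi = phi, kappa = kappa, weight = weight),
            class = "OrientationMixtureSpec")
}

sph_to_unit <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

unit_to_sph <- function(u) {
  u <- u / sqrt(rowSums(u^2))
  theta <- acos(pmax(-1, pmin(1, u[, 3]))) * 180 / pi
  phi <- atan2(u[, 2], u[, 1]) * 180 / pi
  pole <- abs(u[, 3]) > 1 - 1e-12
  phi[pole] <- 0
  phi[phi <= -180] <- phi[phi <= -180] + 360
  cbind(theta = theta, phi = phi)
}

#' Sample unit vectors from a von Mises-Fisher distribution
#'
#' Uses the standard inversion method for the polar cosine:
#' `w = 1 + log(u + (1 - u) exp(-2 kappa)) / kappa` for `u ~ U(0,1)`, an
#' azimuth uniform in `[0, 2 pi)`, then rotation of the +z pole onto the mean
#' direction. `kappa = 0` gives the uniform distribution on the sphere
#' (`w ~ U(-1, 1)`).
#'
#' @param n number of draws.
#' @param mu mean direction (length-3, normalized internally).
#' @param kappa concentration (>= 0).
#' @return n x 3 matrix of unit vectors.
#' @export
rvmf <- function(n, mu = c(0, 0, 1), kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  u <- stats::runif(n)
  if (kappa == 0) {
    w <- 2 * u - 1
  } else {
    # written to stay finite for large kappa: log(u + (1-u) e^{-2k})
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  v <- 2 * pi * stats::runif(n)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(v), s * sin(v), w)
  rot <- rotation_between(c(0, 0, 1), mu)
  local %*% rot
}

#' Simulate a ligand-orientation trajectory in the toy cavity
#'
#' Per frame a mixture component is drawn by weight and a direction from its
#' von Mises-Fisher distribution; the rigid ligand is rotated so its O1->C1
#' axis matches the draw (minimal rotation, fixed roll), keeping O1 at the
#' cavity centre. If `escape_frame` is set, the ligand is additionally
#' translated 15 Angstrom outward along channel B from that frame on, which
#' guarantees a ligand RMSD from frame 0 permanently above 4 Angstrom. The
#' scaffold never moves.
#'
#' @param complex a toy complex from [make_toy_complex()].
#' @param mixture an [orientation_mixture()].
#' @param n_frames number of frames.
#' @param dt frame interval (ns).
#' @param escape_frame optional 0-based frame of the scheduled escape.
#' @param seed integer seed.
#' @return list with `trajectory` (a `Trajectory`) and `truth`
#'   (data.frame: frame, component, theta, phi) plus `escape_frame`.
#' @export
simulate_binding_trajectory <- function(complex, mixture, n_frames, dt = 0.1,
                                        escape_frame = NULL, seed = 1L) {
  stopifnot(inherits(mixture, "OrientationMixtureSpec"))
  spec <- attr(complex, "toy_spec")
  if (is.null(spec)) stop("complex must come from make_toy_complex()")
  if (!is.null(escape_frame) && escape_frame >= n_frames) {
    stop("escape_frame must be smaller than n_frames")
  }
  lig_idx <- which(complex$atoms$resname == "LIG")
  tmpl <- ligand_template()
  center <- c(0, 0, 0)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  comp <- sample.int(length(mixture$weight), n_frames, replace = TRUE,
                     prob = mixture$weight)
  mus <- sph_to_unit(mixture$theta, mixture$phi)
  dirs <- matrix(0, n_frames, 3)
  for (c_id in unique(comp)) {
    rows <- which(comp == c_id)
    dirs[rows, ] <- rvmf(length(rows), mus[c_id, ], mixture$kappa[c_id])
  }
  coords <- array(rep(complex$xyz, n_frames),
                  dim = c(nrow(complex$xyz), 3L, n_frames))
  shift <- spec$axis_B * (spec$cavity_radius + 3)
  for (k in seq_len(n_frames)) {
    rot <- rotation_between(c(0, 0, 1), dirs[k, ])
    lig <- tmpl %*% rot
    lig <- sweep(lig, 2, -center)
    if (!is.null(escape_frame) && (k - 1L) >= escape_frame) {
      lig <- sweep(lig, 2, -shift)
    }
    coords[lig_idx, , k] <- lig
  }
  sph <- unit_to_sph(dirs)
  list(trajectory = trajectory(complex, coords, dt = dt),
       truth = data.frame(frame = seq_len(n_frames) - 1L, component = comp,
                          theta = sph[, "theta"], phi = sph[, "phi"]),
       escape_frame = if (is.null(escape_frame)) NA_integer_
                      else as.integer(escape_frame))
}

#' Simulate tracer waters exchanging through the cavity channels
#'
#' Waters are non-interacting tracers. Each scheduled event moves a water
#' along its channel axis between a bulk position (outside the shell) and a
#' cavity position near the centre at the scheduled frame. With probability
#' `flicker_prob` an event is followed by a short boundary re-crossing of
#' length at most `flicker_max_len` frames, emulating thermal flicker at the
#' cavity boundary; flicker never changes the scheduled event count.
#'
#' @param complex toy complex from [make_toy_complex()].
#' @param n_waters number of tracer waters (ids `1..n_waters`).
#' @param schedule data.frame with columns `water`, `frame` (0-based),
#'   `direction` ("entry"/"exit"), `channel` ("A"/"B").
#' @param n_frames total frames.
#' @param dt frame interval (ns).
#' @param flicker_prob probability a crossing is followed by a flicker blip.
#' @param flicker_max_len maximum blip length in frames.
#' @param seed integer seed.
#' @param r_inside,r_outside radial positions (Angstrom) of the settled
#'   inside/outside states; defaults 2 and `cavity_radius + 6`.
#' @return list with `trajectory` (topology = complex + waters, resname
#'   `HOH`, chain `W`, atom name `OW`) and `truth` (the schedule, ordered).
#' @export
simulate_water_trajectory <- function(complex, n_waters, schedule,
                                      n_frames, dt = 0.01,
                                      flicker_prob = 0, flicker_max_len = 2L,
                                      seed = 1L, r_inside = 2,
                                      r_outside = NULL) {
  spec <- attr(complex, "toy_spec")
  if (is.null(spec)) stop("complex must come from make_toy_complex()")
  if (is.null(r_outside)) r_outside <- spec$cavity_radius + 6
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("water", "frame", "direction", "channel") %in% names(schedule)))
  if (any(schedule$frame < 1L | schedule$frame >= n_frames)) {
    stop("scheduled frames must lie in [1, n_frames)")
  }
  if (!all(schedule$direction %in% c("entry", "exit"))) {
    stop("direction must be 'entry' or 'exit'")
  }
  if (!all(schedule$channel %in% c("A", "B"))) stop("channel must be 'A' or 'B'")
  schedule <- schedule[order(schedule$water, schedule$frame), , drop = FALSE]
  rownames(schedule) <- NULL
  by_w <- split(schedule, schedule$water)
  for (sw in by_w) {
    if (nrow(sw) > 1L && any(diff(sw$frame) < 2L * flicker_max_len)) {
      stop("two events for one water closer than 2*flicker_max_len frames")
    }
    if (any(sw$direction[-1] == sw$direction[-nrow(sw)])) {
      stop("per-water events must alternate entry/exit")
    }
  }
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))

  axes <- list(A = spec$axis_A, B = spec$axis_B)
  nw <- as.integer(n_waters)
  na0 <- nrow(complex$atoms)
  watoms <- data.frame(serial = na0 + seq_len(nw), name = "OW",
                       element = "O", resname = "HOH",
                       resid = seq_len(nw), chain = "W", icode = "",
                       heavy = TRUE, stringsAsFactors = FALSE)
  atoms <- rbind(complex$atoms, watoms)

  # per-water piecewise-constant radial position along its channel axis
  wpos <- array(0, dim = c(nw, 3L, n_frames))
  for (w in seq_len(nw)) {
    sw <- by_w[[as.character(w)]]
    first_dir <- if (is.null(sw) || nrow(sw) == 0L) NA_character_
                 else sw$direction[1]
    ax <- if (is.null(sw) || nrow(sw) == 0L) axes$A else axes[[sw$channel[1]]]
    start_inside <- identical(first_dir, "exit")
    r_now <- if (is.na(first_dir)) r_outside + 10 + w %% 7
             else if (start_inside) r_inside else r_outside
    radius <- rep(r_now, n_frames)
    axis_per_frame <- matrix(rep(ax, each = n_frames), n_frames, 3)
    if (!is.null(sw)) for (e in seq_len(nrow(sw))) {
      f <- sw$frame[e] + 1L  # 1-based
      ax_e <- axes[[sw$channel[e]]]
      axis_per_frame[f:n_frames, ] <- matrix(rep(ax_e, each = n_frames - f + 1L),
                                             ncol = 3)
      target <- if (sw$direction[e] == "entry") r_inside else r_outside
      radius[f:n_frames] <- target
      if (flicker_prob > 0 && stats::runif(1) < flicker_prob) {
        len <- sample.int(flicker_max_len, 1L)
        blip <- (f + 1L):min(f + len, n_frames)
        radius[blip] <- if (sw$direction[e] == "entry") r_outside else r_inside
      }
    }
    jitter <- matrix(stats::runif(3L * n_frames, -0.2, 0.2), n_frames, 3)
    wpos[w, , ] <- t(axis_per_frame * radius + jitter)
  }
  coords <- array(0, dim = c(na0 + nw, 3L, n_frames))
  coords[seq_len(na0), , ] <- rep(complex$xyz, n_frames)
  coords[na0 + seq_len(nw), , ] <- wpos
  topo <- molecular_system(atoms, coords[, , 1])
  attr(topo, "toy_spec") <- spec
  list(trajectory = trajectory(topo, coords, dt = dt), truth = schedule)
}

# Seed hygiene: generators must be deterministic given seed without
# clobbering the caller's RNG stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
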