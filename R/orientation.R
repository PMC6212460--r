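#' Polar orientation collective variables of a ligand axis
#'
#' For each frame the system is superposed onto the reference on
#' `fit_selection` (protein C-alpha atoms by convention), then the unit
#' vector `u` from the hydroxyl oxygen to the bridging carbon is expressed
#' in the reference's lab frame and converted to polar coordinates:
#' `theta = acos(u_z)` in `[0, 180]` degrees and `phi = atan2(u_y, u_x)` in
#' `(-180, 180]` degrees. At the poles (`theta` 0 or 180) `phi` is set to 0
#' by convention. Because only the direction of the internal O->C vector
#' enters, the CVs capture ligand rotation while ignoring translation.
#'
#' @param traj a `Trajectory`.
#' @param oxygen_atom,carbon_atom selections resolving to exactly one atom
#'   each (e.g. `"resname LIG and name O1"`).
#' @param fit_selection fit atoms; default `"name CA"`.
#' @param reference a `MolecularSystem`, an n x 3 matrix, or a 0-based frame
#'   index into `traj` (default frame 0).
#' @return data.frame with columns `frame` (0-based), `theta`, `phi` (deg).
#' @export
orientation_angles <- function(traj, oxygen_atom, carbon_atom,
                               fit_selection = "name CA", reference = 0L) {
  topo <- traj$topology
  oi <- selection_indices(topo, oxygen_atom)
  ci <- selection_indices(topo, carbon_atom)
  if (length(oi) != 1L || length(ci) != 1L) {
    stop("oxygen_atom and carbon_atom must each resolve to exactly one atom")
  }
  if (oi == ci) stop("oxygen and carbon atoms must be distinct")
  fi <- selection_indices(topo, fit_selection)
  ref <- if (inherits(reference, "MolecularSystem")) reference$xyz
         else if (is.matrix(reference)) reference
         else frame_coords(traj, reference)
  nf <- n_frames(traj)
  u <- matrix(0, nf, 3)
  for (k in seq_len(nf)) {
    fitted <- superpose(traj$coords[, , k], ref, fi)$coords
    v <- fitted[ci, ] - fitted[oi, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6) stop("degenerate O->C vector at frame ", k - 1L)
    u[k, ] <- v / nv
  }
  sph <- unit_to_sph(u)
  data.frame(frame = seq_len(nf) - 1L, theta = sph[, "theta"],
             phi = sph[, "phi"])
}

#' Build a solid-angle-reweighted orientation probability map
#'
#' Bins the `(theta, phi)` series on a regular grid and normalizes each bin
#' count by the number of samples and the bin's solid angle
#' `Omega = d_phi_rad * (cos theta_lo - cos theta_hi)`, so the density is
#' per steradian and integrates to one: `sum(density * Omega) = 1`. The
#' cosine-difference form handles polar bins without any division by
#' `sin(theta)`.
#'
#' @param angles data.frame with `theta`, `phi` columns (degrees), as from
#'   [orientation_angles()].
#' @param d_theta,d_phi bin widths in degrees (defaults 10); must divide 180
#'   and 360.
#' @return an `OrientationMap`: list with `theta_edges`, `phi_edges`
#'   (degrees), `counts`, `omega` (sr), `density` (1/sr) matrices
#'   (theta x phi), and `n`.
#' @export
build_orientation_map <- function(angles, d_theta = 10, d_phi = 10) {
  if (d_theta <= 0 || d_phi <= 0) stop("bin widths must be positive")
  if (abs(180 / d_theta - round(180 / d_theta)) > 1e-9 ||
      abs(360 / d_phi - round(360 / d_phi)) > 1e-9) {
    stop("d_theta must divide 180 and d_phi must divide 360")
  }
  th <- angles$theta
  ph <- angles$phi
  if (any(th < 0 | th > 180)) stop("theta out of [0, 180]")
  if (any(ph <= -180 - 1e-9 | ph > 180 + 1e-9)) stop("phi out of (-180, 180]")
  t_edges <- seq(0, 180, by = d_theta)
  p_edges <- seq(-180, 180, by = d_phi)
  nt <- length(t_edges) - 1L
  np <- length(p_edges) - 1L
  # theta bins [lo, hi); the last bin closes at 180. phi bins (lo, hi].
  ti <- pmin(nt, floor(th / d_theta) + 1L)
  pi_ <- pmax(1L, ceiling((ph + 180) / d_phi))
  pi_ <- pmin(np, pi_)
  counts <- matrix(0L, nt, np)
  tab <- table(factor(ti, levels = seq_len(nt)),
               factor(pi_, levels = seq_len(np)))
  counts[] <- as.integer(tab)
  omega <- outer(cos(t_edges[-length(t_edges)] * pi / 180) -
                   cos(t_edges[-1] * pi / 180),
                 rep(d_phi * pi / 180, np))
  n <- nrow(angles)
  density <- counts / (n * omega)
  structure(list(theta_edges = t_edges, phi_edges = p_edges, counts = counts,
                 omega = omega, density = density, n = n,
                 d_theta = d_theta, d_phi = d_phi),
            class = "OrientationMap")
}

#' @export
print.OrientationMap <- function(x, ...) {
  cat(sprintf("<OrientationMap> %dx%d bins (%g x %g deg), %d samples, sum(density*omega) = %.9f\n",
              nrow(x$counts), ncol(x$counts), x$d_theta, x$d_phi, x$n,
              sum(x$density * x$omega)))
  invisible(x)
}

#' Bin centres of the top-density map modes
#' @param map an `OrientationMap`.
#' @param k number of modes.
#' @return data.frame `theta`, `phi` (bin centres, deg), `density`, ranked.
#' @export
map_modes <- function(map, k = 1L) {
  ord <- order(map$density, decreasing = TRUE)[seq_len(k)]
  ti <- (ord - 1L) %% nrow(map$density) + 1L
  pi_ <- (ord - 1L) %/% nrow(map$density) + 1L
  data.frame(
    theta = (map$theta_edges[ti] + map$theta_edges[ti + 1L]) / 2,
    phi = (map$phi_edges[pi_] + map$phi_edges[pi_ + 1L]) / 2,
    density = map$density[ord])
}

#' Project reference poses onto the orientation-CV plane
#'
#' Each reference structure is superposed onto the common reference by the
#' matched C-alpha atoms (keyed by chain/residue/atom name), then its O->C
#' vector is converted to `(theta, phi)` with the same convention as
#' [orientation_angles()] — the way crystal poses are overlaid on a map.
#'
#' @param structures named list of `MolecularSystem`s.
#' @param oxygen_atom,carbon_atom single-atom selections evaluated on each
#'   structure.
#' @param common_reference the `MolecularSystem` defining the lab frame.
#' @param fit_selection correspondence atoms; default `"name CA"`.
#' @return data.frame with `structure`, `theta`, `phi` (degrees).
#' @export
project_reference_poses <- function(structures, oxygen_atom, carbon_atom,
                                    common_reference,
                                    fit_selection = "name CA") {
  stopifnot(length(structures) > 0L)
  out <- lapply(names(structures), function(nm) {
    s <- structures[[nm]]
    ca_s <- selection_indices(s, fit_selection)
    mm <- match_atoms(s, common_reference, ca_s)
    if (length(mm$a) < 3L) {
      stop("fewer than 3 matched fit atoms for structure ", nm)
    }
    sub <- superpose(s$xyz[mm$a, , drop = FALSE],
                     common_reference$xyz[mm$b, , drop = FALSE])
    fit <- list(coords = sweep(s$xyz %*% sub$rotation, 2, -sub$translation))
    oi <- selection_indices(s, oxygen_atom)
    ci <- selection_indices(s, carbon_atom)
    if (length(oi) != 1L || length(ci) != 1L) {
      stop("oxygen/carbon selection not unique in structure ", nm)
    }
    v <- fit$coords[ci, ] - fit$coords[oi, ]
    sph <- unit_to_sph(matrix(v, 1, 3))
    data.frame(structure = nm, theta = sph[1, "theta"], phi = sph[1, "phi"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render an orientation map as a heat map
#' @param map an `OrientationMap`.
#' @param poses optional data.frame from [project_reference_poses()].
#' @param file optional png path.
#' @return invisibly, `map`.
#' @export
plot_orientation_map <- function(map, poses = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  tc <- (map$theta_edges[-1] + map$theta_edges[-length(map$theta_edges)]) / 2
  pc <- (map$phi_edges[-1] + map$phi_edges[-length(map$phi_edges)]) / 2
  graphics::image(tc, pc, map$density, xlab = "theta (deg)",
                  ylab = "phi (deg)", main = "orientation probability (1/sr)",
                  col = grDevices::hcl.colors(64, "viridis"))
  if (!is.null(poses)) {
    graphics::points(poses$theta, poses$phi, pch = 21, bg = "white", cex = 1.4)
    graphics::text(poses$theta, poses$phi, poses$structure, pos = 3,
                   col = "white")
  }
  invisible(map)
}
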