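#' Define a binding site from a reference complex
#'
#' The binding site is the set of protein heavy atoms lying within `cutoff`
#' of any ligand heavy atom in the reference coordinates (inclusive <=).
#' Membership is computed once on the reference and frozen, so that dRMSD
#' values computed against different models remain comparable.
#'
#' @param reference a `MolecularSystem` containing protein and ligand.
#' @param ligand_selection selection (expression, `Selection`, or indices)
#'   of the ligand atoms; restricted to heavy atoms internally.
#' @param cutoff distance cutoff in Angstrom (default 6.0).
#' @param heavy_only_site if TRUE (default) only protein heavy atoms enter
#'   the site.
#' @return an object of class `BindingSiteDefinition` with the frozen ligand
#'   and site index vectors, the cutoff and the pair count
#'   `N = |ligand| * |site|`.
#' @export
define_binding_site <- function(reference, ligand_selection, cutoff = 6.0,
                                heavy_only_site = TRUE) {
  stopifnot(inherits(reference, "MolecularSystem"), cutoff >= 0)
  lig <- selection_indices(reference, ligand_selection)
  lig <- lig[reference$atoms$heavy[lig]]
  if (length(lig) == 0L) stop("ligand selection has no heavy atoms")
  cand <- setdiff(seq_len(n_atoms(reference)), lig)
  if (heavy_only_site) cand <- cand[reference$atoms$heavy[cand]]
  if (length(cand) == 0L) stop("reference has no protein atoms")
  d <- pair_min_dist_to_set(reference$xyz[cand, , drop = FALSE],
                            reference$xyz[lig, , drop = FALSE])
  site <- cand[d <= cutoff]
  if (length(site) == 0L) {
    stop(sprintf("no site atoms within %.2f A of the ligand; increase cutoff",
                 cutoff))
  }
  structure(list(reference = reference, ligand = lig, site = site,
                 cutoff = cutoff, n_pairs = length(lig) * length(site),
                 ref_dist = cross_dist(reference$xyz[lig, , drop = FALSE],
                                       reference$xyz[site, , drop = FALSE])),
            class = "BindingSiteDefinition")
}

#' @export
print.BindingSiteDefinition <- function(x, ...) {
  cat(sprintf("<BindingSiteDefinition> %d ligand x %d site atoms (N = %d), cutoff %.2f A\n",
              length(x$ligand), length(x$site), x$n_pairs, x$cutoff))
  invisible(x)
}

# |A| x |B| Euclidean distance matrix
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# per-row minimum distance from points `a` to the set `b`
pair_min_dist_to_set <- function(a, b) {
  apply(cross_dist(a, b), 1, min)
}

# atom subset of one frame as a plain matrix (guards 1-atom selections)
frame_slice <- function(traj, idx, k) {
  m <- traj$coords[idx, , k, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Distance RMSD between a model pose and the reference pose
#'
#' Superposition-free pose metric: the root-mean-square difference between
#' the ligand-to-site distance matrices of the reference (`x`) and the model
#' (`m`), `sqrt(sum_ij (d_ij^x - d_ij^m)^2 / N)` with
#' `N = |ligand| * |site|`. Because only internal distances enter, the value
#' is invariant under any rigid transform of either structure and symmetric
#' in the two structures.
#'
#' @param model_coords n_atoms x 3 coordinates with the same atom ordering
#'   as the site definition's reference system.
#' @param site_def a [define_binding_site()] result.
#' @param reference_coords optional override of the reference coordinates
#'   (defaults to the definition's frozen reference).
#' @return dRMSD in Angstrom.
#' @export
drmsd <- function(model_coords, site_def, reference_coords = NULL) {
  stopifnot(inherits(site_def, "BindingSiteDefinition"))
  model_coords <- as.matrix(model_coords)
  if (nrow(model_coords) != n_atoms(site_def$reference)) {
    stop(sprintf("model has %d atoms; site definition expects %d",
                 nrow(model_coords), n_atoms(site_def$reference)))
  }
  dref <- if (is.null(reference_coords)) site_def$ref_dist else
    cross_dist(reference_coords[site_def$ligand, , drop = FALSE],
               reference_coords[site_def$site, , drop = FALSE])
  dmod <- cross_dist(model_coords[site_def$ligand, , drop = FALSE],
                     model_coords[site_def$site, , drop = FALSE])
  sqrt(sum((dref - dmod)^2) / site_def$n_pairs)
}

#' dRMSD for every frame of a trajectory
#' @param traj a `Trajectory` sharing atom ordering with the site reference.
#' @param site_def a `BindingSiteDefinition`.
#' @return numeric vector, one dRMSD (Angstrom) per frame.
#' @export
drmsd_series <- function(traj, site_def) {
  vapply(seq_len(n_frames(traj)),
         function(k) drmsd(traj$coords[, , k], site_def), numeric(1))
}

# residue-keyed atom correspondence between two systems:
# match by (chain, resid, icode, atom name); returns index pairs
match_atoms <- function(a, b, indices_a = NULL) {
  key <- function(s, idx) paste(s$atoms$chain[idx], s$atoms$resid[idx],
                                s$atoms$icode[idx], s$atoms$name[idx],
                                sep = "|")
  ia <- if (is.null(indices_a)) seq_len(n_atoms(a)) else indices_a
  ka <- key(a, ia)
  kb <- key(b, seq_len(n_atoms(b)))
  hit <- match(ka, kb)
  dropped <- sum(is.na(hit))
  if (dropped > 0L) {
    message(sprintf("dropped %d atoms with no counterpart in the second structure",
                    dropped))
  }
  keep <- !is.na(hit)
  list(a = ia[keep], b = hit[keep], n_dropped = dropped)
}

#' Pairwise RMSD between two structures on a shared site selection
#'
#' Atoms are matched across structures by `(chain, residue number, insertion
#' code, atom name)`; unmatched atoms are dropped (count reported via
#' `message`). With `fit = TRUE` (default) the second structure is first
#' superposed onto the first on the matched atoms (Kabsch), matching the
#' usual "pairwise RMSD on binding-site heavy atoms" convention.
#'
#' @param struct_a,struct_b `MolecularSystem`s.
#' @param site_selection selection (evaluated on `struct_a`) of the atoms to
#'   compare; default all heavy atoms.
#' @param fit superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
pairwise_site_rmsd <- function(struct_a, struct_b,
                               site_selection = "heavy", fit = TRUE) {
  ia <- selection_indices(struct_a, site_selection)
  mm <- match_atoms(struct_a, struct_b, ia)
  if (length(mm$a) < 3L) {
    stop("fewer than 3 matched atoms between the two structures")
  }
  ca <- struct_a$xyz[mm$a, , drop = FALSE]
  cb <- struct_b$xyz[mm$b, , drop = FALSE]
  if (fit) superpose(cb, ca)$rmsd else coord_rmsd(cb, ca)
}

#' Minimum ligand-residue distance per frame
#'
#' The minimum over all (ligand heavy atom, residue heavy atom) pairs,
#' evaluated per frame — the quantity used both for switch-off-residue
#' progress monitoring and for frame filtering.
#'
#' @param traj a `Trajectory`.
#' @param ligand_selection,residue_selection selections on the topology;
#'   restricted to heavy atoms.
#' @return numeric vector (Angstrom), one value per frame.
#' @export
min_residue_distance <- function(traj, ligand_selection, residue_selection) {
  topo <- traj$topology
  li <- selection_indices(topo, ligand_selection)
  li <- li[topo$atoms$heavy[li]]
  ri <- selection_indices(topo, residue_selection)
  ri <- ri[topo$atoms$heavy[ri]]
  if (length(li) == 0L || length(ri) == 0L) {
    stop("ligand and residue selections must contain heavy atoms")
  }
  vapply(seq_len(n_frames(traj)), function(k) {
    min(cross_dist(frame_slice(traj, li, k), frame_slice(traj, ri, k)))
  }, numeric(1))
}

#' Frames below a distance threshold (strict <)
#' @param series per-frame values.
#' @param threshold strict upper bound.
#' @return 0-based frame indices with `series < threshold`.
#' @export
filter_frames <- function(series, threshold) {
  which(series < threshold) - 1L
}

#' Salt-bridge distance monitor
#'
#' Minimum distance per frame between the acidic side-chain oxygens and the
#' basic side-chain nitrogens, with a broken flag where the distance exceeds
#' `broken_cutoff` and the length of the longest broken stretch.
#'
#' @param traj a `Trajectory`.
#' @param acidic_selection,basic_selection selections of the two charged
#'   groups' atoms.
#' @param broken_cutoff distance (Angstrom) above which the bridge counts as
#'   broken; default 4.5.
#' @return list with `distance` (per frame, Angstrom), `broken` (logical per
#'   frame), `longest_broken_stretch` (frames).
#' @export
salt_bridge_series <- function(traj, acidic_selection, basic_selection,
                               broken_cutoff = 4.5) {
  topo <- traj$topology
  ai <- selection_indices(topo, acidic_selection)
  bi <- selection_indices(topo, basic_selection)
  if (length(ai) == 0L || length(bi) == 0L) {
    stop("salt-bridge selections must be nonempty")
  }
  d <- vapply(seq_len(n_frames(traj)), function(k) {
    min(cross_dist(frame_slice(traj, ai, k), frame_slice(traj, bi, k)))
  }, numeric(1))
  broken <- d > broken_cutoff
  longest <- if (any(broken)) {
    r <- rle(broken); max(r$lengths[r$values])
  } else 0L
  list(distance = d, broken = broken,
       longest_broken_stretch = as.integer(longest))
}

#' Region RMSD series after a global fit
#'
#' Every frame is superposed onto the reference on `fit_selection` (default:
#' all `CA` atoms), then the RMSD is measured on `region_selection` without
#' refitting — the convention used for monitoring local displacements such
#' as a helix shift.
#'
#' @param traj a `Trajectory`.
#' @param region_selection atoms whose displacement is measured.
#' @param reference a `MolecularSystem` (or n x 3 matrix) with the same atom
#'   ordering as the trajectory topology.
#' @param fit_selection fit atoms; default `"name CA"`.
#' @return numeric vector (Angstrom per frame) with attributes `min`/`max`.
#' @export
region_rmsd_series <- function(traj, region_selection, reference,
                               fit_selection = "name CA") {
  topo <- traj$topology
  ri <- selection_indices(topo, region_selection)
  if (length(ri) == 0L) stop("region selection is empty")
  fi <- selection_indices(topo, fit_selection)
  ref <- if (inherits(reference, "MolecularSystem")) reference$xyz
         else as.matrix(reference)
  out <- vapply(seq_len(n_frames(traj)), function(k) {
    fitted <- superpose(traj$coords[, , k], ref, fi)$coords
    coord_rmsd(fitted[ri, , drop = FALSE], ref[ri, , drop = FALSE])
  }, numeric(1))
  attr(out, "min") <- min(out)
  attr(out, "max") <- max(out)
  out
}
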