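#' GROMOS (Daura) RMSD-based clustering of ligand conformations
#'
#' Every frame is first superposed onto the reference with one global fit on
#' `fit_selection` (no per-pair refitting — refitting on the ligand would
#' erase exactly the orientational differences the clustering is meant to
#' resolve). The all-pairs RMSD over the ligand heavy atoms is then
#' thresholded at `cutoff` (inclusive `<=`) and the greedy algorithm
#' repeats: take the frame with the most neighbours (ties: lowest frame
#' index), emit it as a cluster centroid together with its neighbours,
#' remove them, until no frames remain.
#'
#' @param traj a `Trajectory`.
#' @param ligand_selection ligand atoms (restricted to heavy).
#' @param fit_selection global fit atoms; default `"name CA"`.
#' @param reference reference for the global fit: `MolecularSystem`, matrix
#'   or 0-based frame index (default 0).
#' @param cutoff neighbour cutoff in Angstrom (default 2.0).
#' @param stride cluster every `stride`-th frame (default 1; logged via
#'   message when > 1).
#' @return a `ClusterResult`: list with `members` (list of 0-based frame
#'   vectors, size-descending), `centroids` (0-based), `sizes`, `cutoff`,
#'   `n_frames`.
#' @export
daura_cluster <- function(traj, ligand_selection, fit_selection = "name CA",
                          reference = 0L, cutoff = 2.0, stride = 1L) {
  topo <- traj$topology
  li <- selection_indices(topo, ligand_selection)
  li <- li[topo$atoms$heavy[li]]
  if (length(li) == 0L) stop("ligand selection has no heavy atoms")
  fi <- selection_indices(topo, fit_selection)
  ref <- if (inherits(reference, "MolecularSystem")) reference$xyz
         else if (is.matrix(reference)) reference
         else frame_coords(traj, reference)
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  if (stride > 1L) {
    message(sprintf("clustering strided frames: every %d of %d", stride,
                    n_frames(traj)))
  }
  lig <- lapply(frames, function(k) {
    superpose(traj$coords[, , k], ref, fi)$coords[li, , drop = FALSE]
  })
  dm <- ligand_rmsd_matrix(lig)
  res <- daura_from_matrix(dm, cutoff)
  # translate matrix rows back to 0-based original frame indices
  res$members <- lapply(res$members, function(m) frames[m] - 1L)
  res$centroids <- frames[res$centroids] - 1L
  res$n_frames <- length(frames)
  res
}

ligand_rmsd_matrix <- function(lig_coords_list) {
  n <- length(lig_coords_list)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a <- lig_coords_list[[i]]
    for (j in seq_len(i - 1L)) {
      dm[i, j] <- dm[j, i] <- coord_rmsd(a, lig_coords_list[[j]])
    }
  }
  dm
}

# Greedy neighbour clustering on a precomputed RMSD matrix. 1-based rows.
daura_from_matrix <- function(dm, cutoff) {
  dimnames(dm) <- NULL
  n <- nrow(dm)
  adj <- dm <= cutoff
  alive <- rep(TRUE, n)
  members <- list()
  centroids <- integer(0)
  while (any(alive)) {
    counts <- colSums(adj & alive)  # neighbours among alive frames (incl self)
    counts[!alive] <- -1L
    c_idx <- which.max(counts)      # which.max takes the first (lowest) index
    grp <- which(alive & adj[, c_idx])
    members[[length(members) + 1L]] <- grp
    centroids <- c(centroids, c_idx)
    alive[grp] <- FALSE
  }
  sizes <- lengths(members)
  ord <- order(-sizes, centroids)
  structure(list(members = members[ord], centroids = centroids[ord],
                 sizes = sizes[ord], cutoff = cutoff, n_frames = n),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("<ClusterResult> %d clusters over %d frames (cutoff %.2f A); sizes: %s%s\n",
              length(x$sizes), x$n_frames, x$cutoff,
              paste(utils::head(x$sizes, 10), collapse = " "),
              if (length(x$sizes) > 10) " ..." else ""))
  invisible(x)
}

#' Rank clusters and project their centroids onto the orientation map
#'
#' @param clusters a `ClusterResult`.
#' @param angles data.frame from [orientation_angles()] covering the
#'   clustered frames.
#' @param k number of top clusters (default 7); truncated with a warning
#'   when fewer clusters exist.
#' @return data.frame: `rank`, `centroid_frame` (0-based), `population`,
#'   `theta`, `phi`.
#' @export
rank_and_project <- function(clusters, angles, k = 7L) {
  stopifnot(inherits(clusters, "ClusterResult"))
  if (k > length(clusters$sizes)) {
    warning(sprintf("requested top %d clusters but only %d exist; truncating",
                    k, length(clusters$sizes)))
    k <- length(clusters$sizes)
  }
  idx <- match(clusters$centroids[seq_len(k)], angles$frame)
  if (anyNA(idx)) stop("centroid frames missing from the angle series")
  data.frame(rank = seq_len(k),
             centroid_frame = clusters$centroids[seq_len(k)],
             population = clusters$sizes[seq_len(k)],
             theta = angles$theta[idx], phi = angles$phi[idx])
}

#' Write cluster centroid structures as PDB files
#' @param clusters a `ClusterResult`.
#' @param traj the clustered `Trajectory`.
#' @param dir output directory.
#' @param k how many top centroids to write (default all).
#' @return invisibly, the written paths.
#' @export
write_centroids <- function(clusters, traj, dir, k = NULL) {
  if (is.null(k)) k <- length(clusters$centroids)
  k <- min(k, length(clusters$centroids))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(k)
  for (i in seq_len(k)) {
    f <- clusters$centroids[i]
    sys <- molecular_system(traj$topology$atoms, frame_coords(traj, f))
    paths[i] <- file.path(dir, sprintf("centroid_%02d_frame%05d.pdb", i, f))
    write_structure(sys, paths[i])
  }
  invisible(paths)
}
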