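#' Ligand RMSD series relative to a reference frame
#'
#' For each frame the whole system is superposed onto the reference frame on
#' `fit_selection` (by default the scaffold C-alpha atoms), then the RMSD is
#' computed on the ligand heavy atoms without refitting. By construction
#' `series[reference_frame] == 0`.
#'
#' @param traj a `Trajectory`.
#' @param ligand_selection ligand atoms (restricted to heavy atoms).
#' @param fit_selection fit atoms; default `"name CA"`.
#' @param reference_frame 0-based reference frame (default 0).
#' @return numeric vector of RMSDs (Angstrom), one per frame.
#' @export
ligand_rmsd_series <- function(traj, ligand_selection,
                               fit_selection = "name CA",
                               reference_frame = 0L) {
  if (reference_frame < 0L || reference_frame >= n_frames(traj)) {
    stop("reference_frame out of range: ", reference_frame)
  }
  topo <- traj$topology
  li <- selection_indices(topo, ligand_selection)
  li <- li[topo$atoms$heavy[li]]
  if (length(li) == 0L) stop("ligand selection has no heavy atoms")
  fi <- selection_indices(topo, fit_selection)
  ref <- traj$coords[, , reference_frame + 1L]
  vapply(seq_len(n_frames(traj)), function(k) {
    fitted <- superpose(traj$coords[, , k], ref, fi)$coords
    coord_rmsd(fitted[li, , drop = FALSE], ref[li, , drop = FALSE])
  }, numeric(1))
}

#' First-passage escape time of a ligand-RMSD series
#'
#' The escape time is the time of the first frame whose RMSD reaches the
#' threshold (inclusive `>=`). If the threshold is never reached the record
#' is censored at the total simulated time. An optional persistence window
#' requires `persistence` consecutive frames at or above threshold (default
#' 1, i.e. plain first passage).
#'
#' @param series per-frame ligand RMSD (Angstrom), frame 0 first.
#' @param threshold RMSD threshold (Angstrom), default 4.0.
#' @param dt frame interval (ns).
#' @param persistence consecutive frames required above threshold.
#' @param replica optional replica id carried into the record.
#' @return an `EscapeRecord`: list with `replica`, `time` (ns), `censored`,
#'   `frame` (0-based or NA), `threshold`, `total_time` (ns).
#' @export
escape_time <- function(series, threshold = 4.0, dt, persistence = 1L,
                        replica = NA) {
  if (length(series) == 0L) stop("empty RMSD series")
  if (dt <= 0) stop("dt must be positive")
  stopifnot(persistence >= 1L)
  above <- series >= threshold
  hit <- NA_integer_
  if (persistence == 1L) {
    w <- which(above)
    if (length(w) > 0L) hit <- w[1]
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= persistence)
    if (length(ok) > 0L) hit <- ends[ok[1]] - r$lengths[ok[1]] + 1L
  }
  total <- (length(series) - 1L) * dt
  rec <- if (is.na(hit)) {
    list(replica = replica, time = total, censored = TRUE, frame = NA_integer_,
         threshold = threshold, total_time = total)
  } else {
    list(replica = replica, time = (hit - 1L) * dt, censored = FALSE,
         frame = hit - 1L, threshold = threshold, total_time = total)
  }
  structure(rec, class = "EscapeRecord")
}

#' Escape-time summary statistics over replicas
#'
#' Censored records (threshold never reached) are ranked above every
#' observed time, so order statistics are taken over all replicas with
#' censored values at `+Inf`. When an order statistic lands on a censored
#' rank it is reported as a lower bound `>= total_time`. For an even number
#' of replicas the median is the lower-middle order statistic — the value a
#' rank-based convention can report without interpolating into censored
#' territory.
#'
#' @param records list of `EscapeRecord`s.
#' @return list with `n_total`, `n_censored`, `median`, `q1`, `q3` (each a
#'   list of `value` ns and `censored` flag), and `times` (observed, sorted).
#' @export
escape_statistics <- function(records) {
  stopifnot(length(records) > 0L)
  thr <- unique(vapply(records, function(r) r$threshold, numeric(1)))
  if (length(thr) != 1L) stop("records mix escape thresholds: ",
                              paste(thr, collapse = ", "))
  times <- vapply(records, function(r) r$time, numeric(1))
  cens <- vapply(records, function(r) r$censored, logical(1))
  total <- max(vapply(records, function(r) r$total_time, numeric(1)))
  n <- length(records)
  ranked <- ifelse(cens, Inf, times)
  ord <- order(ranked)
  pick <- function(rank) {
    rank <- max(1L, min(n, rank))
    v <- ranked[ord][rank]
    if (is.infinite(v)) list(value = total, censored = TRUE)
    else list(value = v, censored = FALSE)
  }
  # lower-middle convention for even n; exact middle for odd n
  med_rank <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L
  list(n_total = n, n_censored = sum(cens),
       median = pick(med_rank),
       q1 = pick(ceiling(n / 4)),
       q3 = pick(ceiling(3 * n / 4)),
       times = sort(times[!cens]))
}

#' Boxplot of escape times across pose groups
#'
#' Standard 1.5 x IQR whisker convention; censored replicas are drawn at the
#' total simulated time and marked.
#'
#' @param groups named list; each element a list of `EscapeRecord`s.
#' @param file optional output file (png).
#' @return invisibly, the matrix of plotted values.
#' @export
escape_boxplot <- function(groups, file = NULL) {
  vals <- lapply(groups, function(recs)
    vapply(recs, function(r) r$time, numeric(1)))
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(vals, range = 1.5, ylab = "escape time (ns)",
                    main = "Time to leave the initial pose")
  invisible(vals)
}
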