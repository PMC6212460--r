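#' Cavity definition for water-exchange analysis
#'
#' Cavity membership is radial with hysteresis around the per-frame centroid
#' of the lining atoms: a water becomes *inside* when its distance to the
#' centroid drops to `r_in` or below and *outside* when it reaches `r_out`
#' or above; between the two radii the previous state persists (dead band).
#' Hysteresis is what makes "exchanged" well defined under thermal flicker
#' at the boundary.
#'
#' @param lining_selection selection of the cavity-lining heavy atoms.
#' @param r_in,r_out inner/outer radii in Angstrom, `r_out - r_in >= 0.5`.
#' @return a `CavityDefinition`.
#' @export
cavity_definition <- function(lining_selection, r_in = 6, r_out = 8) {
  if (r_out <= r_in) stop("r_out must exceed r_in")
  if (r_out - r_in < 0.5) stop("hysteresis band r_out - r_in must be >= 0.5 A")
  structure(list(lining = lining_selection, r_in = r_in, r_out = r_out),
            class = "CavityDefinition")
}

#' Per-water cavity occupancy with hysteresis
#'
#' @param traj a `Trajectory` whose topology contains the waters.
#' @param cavity_def a [cavity_definition()].
#' @param water_selection selection identifying one oxygen atom per water
#'   (default `"water and name OW"`).
#' @return an `OccupancySeries`: list with `inside` (n_frames x n_waters
#'   logical matrix), `water_ids` (residue numbers), `water_atoms` (atom
#'   indices), `distance` (matrix, Angstrom), `cavity_def`.
#' @export
occupancy_series <- function(traj, cavity_def,
                             water_selection = "water and name OW") {
  stopifnot(inherits(cavity_def, "CavityDefinition"))
  topo <- traj$topology
  wi <- selection_indices(topo, water_selection)
  if (length(wi) == 0L) stop("water selection is empty")
  wkey <- paste(topo$atoms$chain[wi], topo$atoms$resid[wi])
  if (anyDuplicated(wkey)) {
    stop("water selection must identify exactly one oxygen per water")
  }
  li <- selection_indices(topo, cavity_def$lining)
  li <- li[topo$atoms$heavy[li]]
  if (length(li) == 0L) stop("cavity lining selection is empty")
  nf <- n_frames(traj)
  nw <- length(wi)
  dist <- matrix(0, nf, nw)
  for (k in seq_len(nf)) {
    lc <- traj$coords[li, , k, drop = FALSE]; dim(lc) <- dim(lc)[1:2]
    dw <- traj$coords[wi, , k, drop = FALSE]; dim(dw) <- dim(dw)[1:2]
    ctr <- colMeans(lc)
    dist[k, ] <- sqrt((dw[, 1] - ctr[1])^2 + (dw[, 2] - ctr[2])^2 +
                        (dw[, 3] - ctr[3])^2)
  }
  inside <- matrix(FALSE, nf, nw)
  mid <- (cavity_def$r_in + cavity_def$r_out) / 2
  state <- dist[1, ] <= mid
  inside[1, ] <- state
  if (nf > 1L) for (k in 2:nf) {
    state <- ifelse(dist[k, ] <= cavity_def$r_in, TRUE,
                    ifelse(dist[k, ] >= cavity_def$r_out, FALSE, state))
    inside[k, ] <- state
  }
  structure(list(inside = inside, water_ids = topo$atoms$resid[wi],
                 water_atoms = wi, distance = dist, cavity_def = cavity_def,
                 times = traj$times),
            class = "OccupancySeries")
}

# Confirmed-dwell state filter: scan the run-length encoding left to right;
# a run shorter than min_residence never changes the confirmed state. The
# first run sets the initial state regardless of its length.
confirmed_transitions <- function(state, min_residence) {
  r <- rle(as.logical(state))
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  cur <- r$values[1]
  out_frames <- integer(0)
  out_dir <- character(0)
  if (length(r$values) > 1L) for (i in 2:length(r$values)) {
    if (r$lengths[i] >= min_residence && r$values[i] != cur) {
      out_frames <- c(out_frames, starts[i] - 1L)  # 0-based
      out_dir <- c(out_dir, if (r$values[i]) "entry" else "exit")
      cur <- r$values[i]
    }
  }
  list(frames = out_frames, directions = out_dir)
}

#' Detect water exchange events
#'
#' State stretches shorter than `min_residence_frames` are treated as
#' boundary flicker and do not produce events; surviving transitions are
#' emitted with the frame at which the confirmed state change begins.
#'
#' @param occupancy an `OccupancySeries` (or a logical frames x waters
#'   matrix).
#' @param min_residence_frames dwell (frames) required to confirm a state.
#' @return data.frame with `water`, `frame` (0-based), `direction`
#'   ("entry"/"exit").
#' @export
detect_exchange_events <- function(occupancy, min_residence_frames = 5L) {
  stopifnot(min_residence_frames >= 1L)
  inside <- if (inherits(occupancy, "OccupancySeries")) occupancy$inside
            else as.matrix(occupancy)
  ids <- if (inherits(occupancy, "OccupancySeries")) occupancy$water_ids
         else seq_len(ncol(inside))
  out <- lapply(seq_len(ncol(inside)), function(j) {
    tr <- confirmed_transitions(inside[, j], min_residence_frames)
    if (length(tr$frames) == 0L) return(NULL)
    data.frame(water = ids[j], frame = tr$frames, direction = tr$directions,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(water = integer(0), frame = integer(0),
                      direction = character(0))
  }
  out[order(out$frame, out$water), , drop = FALSE]
}

#' Assign exchange events to entrance channels
#'
#' Each event is labelled with the channel whose gate-residue heavy-atom
#' centroid is nearest to the water oxygen at the crossing frame; ties
#' closer than 0.01 Angstrom are left `unassigned` and excluded from the
#' channel fractions. Optionally a path-based vote over the `window` frames
#' straddling the crossing is used instead of the single crossing frame.
#'
#' @param events data.frame from [detect_exchange_events()].
#' @param traj the `Trajectory` the events came from.
#' @param occupancy the matching `OccupancySeries` (maps water ids to atoms).
#' @param gate_A_selection,gate_B_selection selections of the two gates'
#'   heavy atoms; must be disjoint and nonempty.
#' @param window odd number of frames for the majority vote (1 = crossing
#'   frame only, the default).
#' @return list with `events` (plus `channel`, `gate_distance` columns) and
#'   `fractions` (named: A, B, computed over assigned events),
#'   `n_unassigned`.
#' @export
assign_channels <- function(events, traj, occupancy,
                            gate_A_selection, gate_B_selection,
                            window = 1L) {
  topo <- traj$topology
  ga <- selection_indices(topo, gate_A_selection)
  gb <- selection_indices(topo, gate_B_selection)
  if (length(ga) == 0L && length(gb) == 0L) stop("both gate selections are empty")
  if (length(ga) == 0L || length(gb) == 0L) stop("a gate selection is empty")
  if (length(intersect(ga, gb)) > 0L) stop("gate selections must be disjoint")
  stopifnot(window >= 1L, window %% 2L == 1L)
  amap <- stats::setNames(occupancy$water_atoms, occupancy$water_ids)
  nf <- n_frames(traj)
  lab <- character(nrow(events))
  gd <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    ai <- amap[[as.character(events$water[i])]]
    frames <- events$frame[i] + seq(-(window - 1L) / 2, (window - 1L) / 2)
    frames <- frames[frames >= 0L & frames < nf]
    votes <- character(0)
    dmin <- Inf
    centroid_at <- function(idx, f1) {
      m <- traj$coords[idx, , f1, drop = FALSE]
      dim(m) <- dim(m)[1:2]
      colMeans(m)
    }
    for (f in frames) {
      w <- traj$coords[ai, , f + 1L]
      da <- sqrt(sum((centroid_at(ga, f + 1L) - w)^2))
      db <- sqrt(sum((centroid_at(gb, f + 1L) - w)^2))
      votes <- c(votes, if (abs(da - db) < 0.01) "unassigned"
                        else if (da < db) "A" else "B")
      dmin <- min(dmin, da, db)
    }
    tallied <- table(votes)
    lab[i] <- names(tallied)[which.max(tallied)]
    gd[i] <- dmin
  }
  events$channel <- lab
  events$gate_distance <- gd
  assigned <- events$channel %in% c("A", "B")
  fr <- c(A = sum(events$channel == "A"), B = sum(events$channel == "B"))
  fractions <- if (sum(assigned) > 0L) fr / sum(assigned) else fr * NA_real_
  list(events = events, fractions = fractions,
       n_unassigned = sum(!assigned))
}

#' Summary of a water-exchange analysis
#' @param assigned result of [assign_channels()].
#' @return list: `n_events`, `n_entries`, `n_exits`, `n_unique_waters`,
#'   `fraction_A`, `fraction_B`, `n_unassigned`.
#' @export
exchange_summary <- function(assigned) {
  ev <- assigned$events
  list(n_events = nrow(ev),
       n_entries = sum(ev$direction == "entry"),
       n_exits = sum(ev$direction == "exit"),
       n_unique_waters = length(unique(ev$water)),
       fraction_A = unname(assigned$fractions["A"]),
       fraction_B = unname(assigned$fractions["B"]),
       n_unassigned = assigned$n_unassigned)
}
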