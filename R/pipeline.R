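#' Pipeline configuration
#'
#' Bundles the paths, selections and cutoffs of a full analysis run. All
#' defaults are the field's standard values for this kind of analysis: 6 A
#' site cutoff, 4 A escape threshold, 2 A cluster cutoff, 5.5 A switch-off
#' frame filter, 4.5 A salt-bridge break, 10 degree map bins. The config
#' round-trips through JSON unchanged.
#'
#' @param paths named list (topology, trajectories, references, manifest...).
#' @param selections named list of selection expressions (ligand,
#'   hydroxyl_oxygen, bridge_carbon, cavity, gate_A, gate_B, salt_acidic,
#'   salt_basic, fit).
#' @param cutoffs named list; defaults
#'   `site = 6, escape = 4, cluster = 2, frame_filter = 5.5,
#'   salt_broken = 4.5, r_in = 6, r_out = 8`.
#' @param binning named list; defaults `d_theta = 10, d_phi = 10`.
#' @param seed integer seed for stochastic stages.
#' @param stride frame stride (default 1).
#' @return a `PipelineConfig`.
#' @export
pipeline_config <- function(paths = list(), selections = list(),
                            cutoffs = list(), binning = list(),
                            seed = 1L, stride = 1L) {
  def_cut <- list(site = 6, escape = 4, cluster = 2, frame_filter = 5.5,
                  salt_broken = 4.5, r_in = 6, r_out = 8)
  def_bin <- list(d_theta = 10, d_phi = 10)
  def_sel <- list(ligand = "resname LIG", hydroxyl_oxygen = "resname LIG and name O1",
                  bridge_carbon = "resname LIG and name C1",
                  cavity = "resname SCF", gate_A = "resname GTA",
                  gate_B = "resname GTB", fit = "name CA",
                  water = "water and name OW")
  cutoffs <- lapply(utils::modifyList(def_cut, cutoffs), as.numeric)
  binning <- lapply(utils::modifyList(def_bin, binning), as.numeric)
  selections <- utils::modifyList(def_sel, selections)
  if (any(unlist(cutoffs) <= 0)) stop("all cutoffs must be positive")
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  structure(list(paths = paths, selections = selections, cutoffs = cutoffs,
                 binning = binning, seed = as.integer(seed),
                 stride = as.integer(stride)),
            class = "PipelineConfig")
}

#' Serialize / deserialize a pipeline config
#' @param config a `PipelineConfig`.
#' @param path JSON file path.
#' @return `read_config` returns a `PipelineConfig`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(paths = as.list(x$paths), selections = as.list(x$selections),
                  cutoffs = as.list(x$cutoffs), binning = as.list(x$binning),
                  seed = x$seed, stride = x$stride)
}

# FNV-1a hash of the config's JSON serialization; provenance only.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_stage_csv <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cavitybind %s | stage: %s | seed: %d | config: %s",
                       as.character(utils::packageVersion("cavitybind")),
                       stage, config$seed, config_hash(config))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the synthetic demonstration pipeline
#'
#' Generates a toy complex and synthetic trajectories, then exercises every
#' analysis stage in dependency order, writing tidy CSVs and a JSON summary
#' into `out_dir`. Deterministic given `config$seed`: rerunning with the
#' same config yields byte-identical CSV outputs.
#'
#' @param config a `PipelineConfig`.
#' @param out_dir run directory (created).
#' @param stages character vector of stages to run; default all of
#'   `c("synth", "escape", "orient", "cluster", "water")`.
#' @param n_replicas escape replicas (default 23).
#' @param n_frames frames per replica (default 300).
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("synth", "escape", "orient", "cluster",
                                    "water"),
                         n_replicas = 23L, n_frames = 300L) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(package_version = as.character(utils::packageVersion("cavitybind")),
                  config_hash = config_hash(config), seed = config$seed,
                  stages = stages)
  ok <- FALSE
  on.exit(if (!ok) file.create(file.path(out_dir, "FAILED")))

  spec <- toy_complex_spec()
  cx <- make_toy_complex(spec, seed = config$seed)
  mixture <- orientation_mixture(theta = c(60, 120, 40),
                                 phi = c(150, -60, 10),
                                 kappa = c(50, 50, 50),
                                 weight = c(0.5, 0.3, 0.2))
  dt <- 0.1

  if ("synth" %in% stages) {
    write_structure(cx, file.path(out_dir, "toy_complex.pdb"))
  }

  sim <- simulate_binding_trajectory(cx, mixture, n_frames = n_frames,
                                     dt = dt, seed = config$seed)
  if ("escape" %in% stages) {
    set.seed(config$seed + 1L)
    # censored fraction mirrors the 11-of-23 scenario at any replica count
    n_cens <- as.integer(round(n_replicas * 11 / 23))
    esc_frames <- c(sample.int(n_frames - 20L, n_replicas - n_cens) + 10L,
                    rep(NA_integer_, n_cens))
    recs <- vector("list", n_replicas)
    for (r in seq_len(n_replicas)) {
      ef <- if (is.na(esc_frames[r])) NULL else esc_frames[r]
      s <- simulate_binding_trajectory(cx, mixture, n_frames = n_frames,
                                       dt = dt, escape_frame = ef,
                                       seed = config$seed + 100L + r)
      series <- ligand_rmsd_series(s$trajectory, config$selections$ligand,
                                   config$selections$fit)
      recs[[r]] <- escape_time(series, threshold = config$cutoffs$escape,
                               dt = dt, replica = r)
    }
    stats <- escape_statistics(recs)
    df <- data.frame(replica = seq_len(n_replicas),
                     time_ns = vapply(recs, `[[`, numeric(1), "time"),
                     censored = vapply(recs, `[[`, logical(1), "censored"))
    write_stage_csv(df, file.path(out_dir, "escape_records.csv"), config,
                    "escape")
    summary$escape <- list(n_total = stats$n_total,
                           n_censored = stats$n_censored,
                           median_ns = stats$median$value,
                           median_censored = stats$median$censored)
  }

  angles <- orientation_angles(sim$trajectory,
                               config$selections$hydroxyl_oxygen,
                               config$selections$bridge_carbon,
                               config$selections$fit)
  if ("orient" %in% stages) {
    write_stage_csv(angles, file.path(out_dir, "orientation_angles.csv"),
                    config, "orient")
    map <- build_orientation_map(angles, config$binning$d_theta,
                                 config$binning$d_phi)
    grid <- map_as_grid(map)
    write_stage_csv(grid, file.path(out_dir, "orientation_map.csv"), config,
                    "orient")
    summary$orient <- list(n = map$n,
                           mode = as.list(map_modes(map, 1L)[1, c("theta", "phi")]))
  }

  if ("cluster" %in% stages) {
    cl <- daura_cluster(sim$trajectory, config$selections$ligand,
                        config$selections$fit,
                        cutoff = config$cutoffs$cluster,
                        stride = config$stride)
    membership <- data.frame(
      frame = unlist(cl$members),
      cluster = rep(seq_along(cl$members), cl$sizes))
    membership <- membership[order(membership$frame), ]
    write_stage_csv(membership, file.path(out_dir, "cluster_membership.csv"),
                    config, "cluster")
    top <- rank_and_project(cl, angles, k = min(7L, length(cl$sizes)))
    write_stage_csv(top, file.path(out_dir, "cluster_top.csv"), config,
                    "cluster")
    summary$cluster <- list(n_clusters = length(cl$sizes),
                            sizes = utils::head(cl$sizes, 10),
                            cutoff = cl$cutoff)
  }

  if ("water" %in% stages) {
    sched <- default_water_schedule(n_events = 60L, n_waters = 30L,
                                    n_frames = 400L, frac_B = 0.63,
                                    seed = config$seed)
    wat <- simulate_water_trajectory(cx, n_waters = 30L, schedule = sched,
                                     n_frames = 400L, flicker_prob = 0.3,
                                     flicker_max_len = 2L,
                                     seed = config$seed)
    cav <- cavity_definition(config$selections$cavity,
                             r_in = config$cutoffs$r_in,
                             r_out = config$cutoffs$r_out)
    occ <- occupancy_series(wat$trajectory, cav, config$selections$water)
    ev <- detect_exchange_events(occ, min_residence_frames = 5L)
    asg <- assign_channels(ev, wat$trajectory, occ,
                           config$selections$gate_A, config$selections$gate_B)
    write_stage_csv(asg$events, file.path(out_dir, "water_events.csv"),
                    config, "water")
    summary$water <- exchange_summary(asg)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(summary)
}

#' Flatten an orientation map to a tidy grid table
#' @param map an `OrientationMap`.
#' @return data.frame: theta_lo, theta_hi, phi_lo, phi_hi, count, omega_sr,
#'   density.
#' @export
map_as_grid <- function(map) {
  nt <- nrow(map$counts); np <- ncol(map$counts)
  ti <- rep(seq_len(nt), np); pi_ <- rep(seq_len(np), each = nt)
  data.frame(theta_lo = map$theta_edges[ti], theta_hi = map$theta_edges[ti + 1L],
             phi_lo = map$phi_edges[pi_], phi_hi = map$phi_edges[pi_ + 1L],
             count = as.integer(map$counts), omega_sr = as.numeric(map$omega),
             density = as.numeric(map$density))
}

#' Build a deterministic exchange-event schedule
#'
#' Events are spread over waters and frames so that consecutive events of
#' one water are well separated, with a fixed fraction routed through
#' channel B.
#'
#' @param n_events total number of exchange events.
#' @param n_waters number of waters to spread events over.
#' @param n_frames trajectory length in frames.
#' @param frac_B fraction of events through channel B (default 0.63).
#' @param seed integer seed (shuffles the channel assignment order).
#' @param min_gap minimum frame gap between events of one water.
#' @return schedule data.frame for [simulate_water_trajectory()].
#' @export
default_water_schedule <- function(n_events, n_waters, n_frames,
                                   frac_B = 0.63, seed = 1L, min_gap = 20L) {
  per_water <- ceiling(n_events / n_waters)
  water <- rep(seq_len(n_waters), each = per_water)[seq_len(n_events)]
  ev_rank <- stats::ave(seq_len(n_events), water, FUN = seq_along)
  frame <- 10L + (ev_rank - 1L) * min_gap + (water %% 7L)
  if (any(frame >= n_frames)) stop("schedule does not fit in n_frames")
  direction <- ifelse(ev_rank %% 2L == 1L, "entry", "exit")
  n_b <- round(frac_B * n_events)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  channel <- rep("A", n_events)
  channel[sample.int(n_events, n_b)] <- "B"
  # a water's consecutive entry/exit keep their own channel labels; that is
  # fine for fraction bookkeeping (events, not unique waters, are counted)
  data.frame(water = water, frame = frame, direction = direction,
             channel = channel, stringsAsFactors = FALSE)
}
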