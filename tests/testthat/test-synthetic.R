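test_that("toy complex generation is deterministic and respects the cone cut", {
  spec <- toy_complex_spec(n_scaffold_atoms = 200)
  a <- make_toy_complex(spec, seed = 7)
  b <- make_toy_complex(spec, seed = 7)
  expect_identical(a$xyz, b$xyz)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(a, p1); write_structure(b, p2)
  expect_identical(readLines(p1), readLines(p2))  # same file bytes

  # direct cone-membership oracle: every kept scaffold atom is outside both
  # cones and removed count matches a from-scratch count over the lattice
  shell <- a$xyz[a$atoms$resname == "SCF", ]
  dirs <- shell / sqrt(rowSums(shell^2))
  ang_a <- acos(pmax(-1, pmin(1, dirs %*% spec$axis_A))) * 180 / pi
  ang_b <- acos(pmax(-1, pmin(1, dirs %*% spec$axis_B))) * 180 / pi
  expect_true(all(ang_a >= spec$half_angle_A & ang_b >= spec$half_angle_B))

  # half-angle 0 -> no gap in the shell
  full <- make_toy_complex(toy_complex_spec(n_scaffold_atoms = 200,
                                            half_angle_A = 0,
                                            half_angle_B = 0), seed = 1)
  expect_equal(sum(full$atoms$resname == "SCF"), 200L)

  expect_error(toy_complex_spec(channel_axis_B = c(1, 0.1, 0)), "20")
})

test_that("ligand template is rigid in every generated frame", {
  cx <- make_toy_complex(toy_complex_spec(n_scaffold_atoms = 60), seed = 1)
  mix <- orientation_mixture(theta = c(60, 120), phi = c(150, -60),
                             kappa = c(5, 5), weight = c(0.5, 0.5))
  sim <- simulate_binding_trajectory(cx, mix, n_frames = 40, dt = 0.1,
                                     escape_frame = 30, seed = 3)
  li <- which(cx$atoms$resname == "LIG")
  ref_d <- dist(cx$xyz[li, ])
  for (k in seq_len(40)) {
    d <- dist(sim$trajectory$coords[li, , k])
    expect_lt(max(abs(d - ref_d)), 1e-9)
  }
})

test_that("concentration limit: huge kappa pins draws to the mean direction", {
  cx <- make_toy_complex(toy_complex_spec(n_scaffold_atoms = 60), seed = 1)
  mix <- orientation_mixture(theta = 60, phi = 150, kappa = 1e6)
  sim <- simulate_binding_trajectory(cx, mix, n_frames = 200, dt = 0.1,
                                     seed = 11)
  ang <- orientation_angles(sim$trajectory, "resname LIG and name O1",
                            "resname LIG and name C1")
  expect_lt(max(abs(ang$theta - 60)), 0.5)
  expect_lt(max(abs(ang$phi - 150)), 0.5 / sin(60 * pi / 180) + 1e-9)
})

test_that("mixture component frequencies obey the binomial sampling bound", {
  cx <- make_toy_complex(toy_complex_spec(n_scaffold_atoms = 30), seed = 1)
  mix <- orientation_mixture(theta = c(60, 120), phi = c(150, -60),
                             kappa = c(50, 50), weight = c(0.7, 0.3))
  n <- 20000L
  sim <- simulate_binding_trajectory(cx, mix, n_frames = n, dt = 0.01,
                                     seed = 5)
  f1 <- mean(sim$truth$component == 1L)
  expect_lt(abs(f1 - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("kappa = 0 sampling is uniform on the sphere", {
  set.seed(42)
  u <- rvmf(1e5, c(0, 0, 1), kappa = 0)
  # chi-squared uniformity on solid-angle-equal bins: 10 equal-cos(theta)
  # slabs x 12 phi sectors
  zbin <- findInterval(u[, 3], seq(-1, 1, length.out = 11),
                       rightmost.closed = TRUE)
  pbin <- findInterval(atan2(u[, 2], u[, 1]),
                       seq(-pi, pi, length.out = 13),
                       rightmost.closed = TRUE)
  counts <- table(factor(zbin, levels = 1:10), factor(pbin, levels = 1:12))
  expected <- 1e5 / 120
  chi2 <- sum((counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.99, df = 119))
})

test_that("scheduled escape is recovered exactly by the downstream statistic", {
  cx <- make_toy_complex(toy_complex_spec(n_scaffold_atoms = 60), seed = 1)
  mix <- orientation_mixture(theta = 60, phi = 150, kappa = 100)
  sim <- simulate_binding_trajectory(cx, mix, n_frames = 200, dt = 0.1,
                                     escape_frame = 100, seed = 9)
  series <- ligand_rmsd_series(sim$trajectory, "resname LIG")
  rec <- escape_time(series, threshold = 4, dt = 0.1)
  expect_false(rec$censored)
  expect_identical(rec$frame, 100L)
  expect_equal(rec$time, 10.0)
  expect_error(simulate_binding_trajectory(cx, mix, n_frames = 10,
                                           escape_frame = 10, seed = 1),
               "escape_frame")
  expect_error(orientation_mixture(60, 150, kappa = -1), "kappa")
})

test_that("water generator realizes its schedule and flicker never changes counts", {
  cx <- make_toy_complex(toy_complex_spec(n_scaffold_atoms = 120), seed = 1)
  sched <- data.frame(water = c(1L, 1L, 2L), frame = c(20L, 60L, 40L),
                      direction = c("entry", "exit", "entry"),
                      channel = c("B", "B", "A"))
  for (fp in c(0, 1)) {
    wat <- simulate_water_trajectory(cx, 3L, sched, n_frames = 100,
                                     flicker_prob = fp, flicker_max_len = 2L,
                                     seed = 8)
    occ <- occupancy_series(wat$trajectory,
                            cavity_definition("resname SCF", 6, 8))
    ev <- detect_exchange_events(occ, min_residence_frames = 5L)
    expect_equal(nrow(ev), 3L)
    expect_equal(sort(table(ev$direction), decreasing = TRUE),
                 sort(table(sched$direction), decreasing = TRUE))
    if (fp == 0) {
      got <- ev[order(ev$water, ev$frame), ]
      want <- sched[order(sched$water, sched$frame), ]
      expect_identical(got$frame, want$frame)
      expect_identical(got$direction, want$direction)
    }
  }
  expect_error(simulate_water_trajectory(
    cx, 1L, data.frame(water = 1L, frame = c(10L, 12L),
                       direction = c("entry", "exit"), channel = "A"),
    n_frames = 50, flicker_max_len = 3L, seed = 1),
    "closer than")
})

test_that("generators do not disturb the caller's RNG stream", {
  cx <- make_toy_complex(toy_complex_spec(n_scaffold_atoms = 30), seed = 1)
  mix <- orientation_mixture(60, 150, 10)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_binding_trajectory(cx, mix, n_frames = 5, dt = 1, seed = 4))
  expect_identical(runif(1), before)
})
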