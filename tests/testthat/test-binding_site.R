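test_that("site definition respects the inclusive cutoff boundary", {
  sys <- prot_lig_system(rbind(c(5, 0, 0), c(7, 0, 0)),
                         rbind(c(0, 0, 0)))
  sd <- define_binding_site(sys, "resname LIG", cutoff = 6)
  expect_identical(sd$site, 1L)
  expect_identical(sd$n_pairs, 1L)
  expect_error(define_binding_site(sys, "resname LIG", cutoff = 0.5),
               "increase cutoff")
})

test_that("site membership equals the brute-force all-pairs filter", {
  set.seed(13)
  sys <- prot_lig_system(matrix(runif(45 * 3, -9, 9), 45, 3),
                         rbind(c(0, 0, 0), c(0, 0, 1.5), c(1.2, 0, 2.2),
                               c(-1.2, 0, 2.2), c(0, 1.4, -1)))
  lig <- which(sys$atoms$resname == "LIG")
  for (cutoff in c(4, 6, 8)) {
    sd <- define_binding_site(sys, "resname LIG", cutoff = cutoff)
    want <- setdiff(oracle_within(sys$xyz, lig, cutoff), lig)
    expect_identical(sd$site, want)
  }
})

test_that("drmsd matches the double-loop formula and its hand example", {
  # 1 ligand atom, 2 site atoms; reference distances (3, 4), model (4, 4)
  ref <- prot_lig_system(rbind(c(3, 0, 0), c(0, 4, 0)), rbind(c(0, 0, 0)))
  sd <- define_binding_site(ref, "resname LIG", cutoff = 6)
  model <- ref$xyz
  model[1, ] <- c(4, 0, 0)
  expect_equal(drmsd(model, sd), sqrt((1^2 + 0^2) / 2), tolerance = 1e-12)
  expect_equal(drmsd(ref$xyz, sd), 0)
})

test_that("drmsd equals the oracle on 100 random fixtures and is symmetric", {
  for (s in 1:100) {
    set.seed(s)
    n_site <- 20L
    sys <- prot_lig_system(matrix(runif(n_site * 3, -8, 8), n_site, 3),
                           matrix(runif(15, -2, 2), 5, 3))
    sd <- define_binding_site(sys, "resname LIG", cutoff = 50)
    expect_identical(length(sd$site), n_site)
    model <- sys$xyz + matrix(rnorm(nrow(sys$xyz) * 3, sd = 0.5),
                              nrow(sys$xyz), 3)
    got <- drmsd(model, sd)
    want <- oracle_drmsd(sys$xyz, model, sd$ligand, sd$site)
    expect_equal(got, want, tolerance = 1e-9)
    # symmetry: swap roles of reference and model
    swapped <- define_binding_site(molecular_system(sys$atoms, model),
                                   "resname LIG", cutoff = 50)
    expect_equal(drmsd(sys$xyz, swapped), got, tolerance = 1e-9)
  }
})

test_that("drmsd is invariant under rigid transforms of either structure", {
  set.seed(14)
  sys <- prot_lig_system(matrix(runif(30, -8, 8), 10, 3),
                         rbind(c(0, 0, 0), c(0, 0, 1.5)))
  sd <- define_binding_site(sys, "resname LIG", cutoff = 50)
  model <- sys$xyz + matrix(rnorm(36, sd = 0.3), 12, 3)
  base <- drmsd(model, sd)
  rot <- random_rotation(15)
  moved <- model %*% rot + matrix(rep(c(5, -1, 2), each = 12), 12, 3)
  expect_equal(drmsd(moved, sd), base, tolerance = 1e-9)
})

test_that("pairwise_site_rmsd fits, is symmetric, and reports fit semantics", {
  sys <- random_system(20, seed = 16)
  expect_equal(pairwise_site_rmsd(sys, sys), 0)
  rot <- random_rotation(17)
  moved <- molecular_system(sys$atoms,
                            sys$xyz %*% rot + matrix(rep(c(1, 2, 3), each = 20),
                                                     20, 3))
  expect_lt(pairwise_site_rmsd(sys, moved), 1e-9)
  expect_gt(pairwise_site_rmsd(sys, moved, fit = FALSE), 1)
  # symmetry within tolerance
  noisy <- molecular_system(sys$atoms, sys$xyz + matrix(rnorm(60, sd = 0.4),
                                                        20, 3))
  expect_equal(pairwise_site_rmsd(sys, noisy), pairwise_site_rmsd(noisy, sys),
               tolerance = 1e-6)
  # unmatched atoms dropped with a report
  sub <- molecular_system(sys$atoms[1:15, ], sys$xyz[1:15, ])
  expect_message(pairwise_site_rmsd(sys, sub), "dropped 5")
  expect_error(pairwise_site_rmsd(sys, molecular_system(sub$atoms[1:2, ],
                                                        sub$xyz[1:2, ])),
               "fewer than 3")
})

test_that("min_residue_distance matches brute force and the strict frame filter", {
  sys <- prot_lig_system(matrix(c(3, 0, 0), 1, 3), rbind(c(0, 0, 0)))
  co <- array(rep(sys$xyz, 4), dim = c(2, 3, 4))
  traj <- trajectory(sys, co, dt = 1)
  expect_equal(min_residue_distance(traj, "resname LIG", "resid 1"),
               rep(3, 4))
  expect_identical(filter_frames(c(6.0, 5.4, 5.5), 5.5), 1L)  # strict <
  # brute-force all-pairs oracle on a 30-atom fixture
  set.seed(18)
  big <- prot_lig_system(matrix(runif(75, -9, 9), 25, 3),
                         matrix(runif(15, -2, 2), 5, 3))
  co2 <- array(0, dim = c(30, 3, 3))
  for (k in 1:3) co2[, , k] <- big$xyz + rnorm(90, sd = 0.2)
  tr2 <- trajectory(big, co2, dt = 1)
  got <- min_residue_distance(tr2, "resname LIG", "resid 1:25")
  for (k in 1:3) {
    want <- min(as.matrix(dist(co2[, , k]))[26:30, 1:25])
    expect_equal(got[k], want, tolerance = 1e-12)
  }
})

test_that("salt-bridge monitor flags broken stretches", {
  sys <- prot_lig_system(matrix(c(0, 0, 0), 1, 3), rbind(c(3, 0, 0)))
  d_per_frame <- c(3, 5, 5, 3)
  co <- array(0, dim = c(2, 3, 4))
  for (k in 1:4) co[2, 1, k] <- d_per_frame[k]
  traj <- trajectory(sys, co, dt = 1)
  sb <- salt_bridge_series(traj, "resid 1", "resname LIG", broken_cutoff = 4.5)
  expect_equal(sb$distance, d_per_frame)
  expect_identical(sb$broken, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(sb$longest_broken_stretch, 2L)
  never <- salt_bridge_series(trajectory(sys, array(co[, , c(1, 4)],
                                                    dim = c(2, 3, 2)), dt = 1),
                              "resid 1", "resname LIG")
  expect_false(any(never$broken))
})

test_that("region RMSD recovers a constructed rigid displacement", {
  set.seed(19)
  n <- 30
  sys <- random_system(n, seed = 19)
  region <- 25:30
  co <- array(rep(sys$xyz, 5), dim = c(n, 3, 5))
  for (k in 2:5) co[region, 1, k] <- co[region, 1, k] + 5  # displaced 5 A
  traj <- trajectory(sys, co, dt = 1)
  # fit on the unmoved atoms so the displacement is measured cleanly
  got <- region_rmsd_series(traj, "resid 25:30", sys,
                            fit_selection = "resid 1:24")
  expect_equal(got[1], 0, tolerance = 1e-9)
  expect_equal(unclass(got[2:5]), rep(5, 4), tolerance = 0.05,
               ignore_attr = TRUE)
  # trajectory = repeated reference -> all zeros
  still <- trajectory(sys, array(rep(sys$xyz, 3), dim = c(n, 3, 3)), dt = 1)
  expect_lt(max(region_rmsd_series(still, "resid 25:30", sys, "all")), 1e-9)
  suppressWarnings(
    expect_error(region_rmsd_series(still, "resname ZZZ", sys, "all"),
                 "empty|no atoms"))
})
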