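test_that("PDB structures round-trip through write/read", {
  sys <- random_system(25, seed = 11)
  sys$atoms$resname[21:25] <- "SR1"
  sys$atoms$chain[21:25] <- "L"
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, p)
  back <- read_structure(p)
  expect_identical(back$atoms$name, sys$atoms$name)
  expect_identical(back$atoms$resid, sys$atoms$resid)
  expect_identical(back$atoms$chain, sys$atoms$chain)
  expect_identical(back$atoms$resname, sys$atoms$resname)
  expect_lt(max(abs(back$xyz - sys$xyz)), 5e-4 + 1e-12)  # format precision
  # HETATM ligand selectable by residue name
  expect_length(select_atoms(back, "resname SR1")$indices, 5L)
})

test_that("two chains with the same residue number stay distinct", {
  atoms <- make_atoms(4, resid = c(10L, 10L, 10L, 10L),
                      chain = c("A", "A", "B", "B"),
                      name = c("CA", "CB", "CA", "CB"))
  atoms$element <- c("C", "C", "C", "C")
  sys <- molecular_system(atoms, matrix(seq_len(12), 4, 3))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, p)
  back <- read_structure(p)
  expect_length(select_atoms(back, "resid 10 and chain A")$indices, 2L)
  expect_length(select_atoms(back, "resid 10 and chain B")$indices, 2L)
})

test_that("PDB altloc resolution keeps highest occupancy, ties prefer A", {
  lines <- c(
    "ATOM      1  CA AALA A   1      1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1      2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB BALA A   1      3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB AALA A   1      4.000   0.000   0.000  0.50 10.00           C",
    "END")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, p)
  sys <- read_structure(p)
  expect_equal(n_atoms(sys), 2L)
  expect_equal(sys$xyz[sys$atoms$name == "CA", 1], 2.0)  # occupancy winner
  expect_equal(sys$xyz[sys$atoms$name == "CB", 1], 4.0)  # tie -> altloc A
})

test_that("malformed PDB records raise a parse error naming the line", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      xxx.00   0.000   0.000",
               "END"), p)
  expect_error(read_structure(p), "line 1")
  expect_error(read_structure(p, format = "xyz"), "unsupported")
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("GRO structures round-trip at format precision", {
  sys <- random_system(12, seed = 3)
  p <- withr::local_tempfile(fileext = ".gro")
  write_structure(sys, p)
  back <- read_structure(p)
  expect_identical(back$atoms$name, sys$atoms$name)
  expect_lt(max(abs(back$xyz - sys$xyz)), 5e-3 + 1e-12)  # 0.001 nm precision
})

test_that("trajectories round-trip through multi-model PDB and DCD", {
  sys <- random_system(15, seed = 21)
  set.seed(22)
  coords <- array(rnorm(15 * 3 * 10, sd = 3), dim = c(15, 3, 10))
  traj <- trajectory(sys, coords, dt = 0.1)
  top <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, top)
  for (ext in c(".pdb", ".dcd")) {
    tp <- withr::local_tempfile(fileext = ext)
    write_trajectory(traj, tp)
    back <- suppressWarnings(read_trajectory(top, tp))
    expect_equal(n_frames(back), 10L)
    expect_equal(back$dt, 0.1, tolerance = 1e-6)
    tol <- if (ext == ".pdb") 5e-4 + 1e-9 else 1e-5
    expect_lt(max(abs(back$coords - traj$coords)), tol)
  }
})

test_that("a multi-model PDB with 3 MODELs gives 3 frames and stride works", {
  sys <- random_system(8, seed = 31)
  traj <- trajectory(sys, array(rep(sys$xyz, 3), dim = c(8, 3, 3)), dt = 0.5)
  top <- withr::local_tempfile(fileext = ".pdb")
  tp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, top)
  write_trajectory(traj, tp)
  expect_equal(n_frames(read_trajectory(top, tp)), 3L)
  expect_equal(n_frames(read_trajectory(top, tp, stride = 2)), 2L)
})

test_that("atom-count mismatches and truncated DCD files are structural errors", {
  sys <- random_system(10, seed = 41)
  traj <- trajectory(sys, array(rep(sys$xyz, 2), dim = c(10, 3, 2)), dt = 1)
  small <- random_system(9, seed = 42)
  top_small <- withr::local_tempfile(fileext = ".pdb")
  write_structure(small, top_small)
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(traj, dcd)
  expect_error(read_trajectory(top_small, dcd), "does not match")
  # truncate mid-frame
  sz <- file.size(dcd)
  raw <- readBin(dcd, "raw", n = sz - 30)
  writeBin(raw, dcd)
  top <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, top)
  expect_error(read_trajectory(top, dcd), "truncated|frame")
})

test_that("XTC input is rejected with a usage error", {
  sys <- random_system(3, seed = 5)
  top <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, top)
  expect_error(read_trajectory(top, "whatever.xtc"), "XTC")
})

test_that("selection grammar matches hand-picked and brute-force results", {
  np <- 45
  set.seed(77)
  prot <- matrix(runif(np * 3, -10, 10), np, 3)
  sys <- prot_lig_system(prot, rbind(c(0, 0, 0), c(0, 0, 1.5),
                                     c(1.5, 0, 2.4), c(-1.5, 0, 2.4),
                                     c(0, 1.4, -1)))
  expect_identical(select_atoms(sys, "resname LIG and heavy")$indices,
                   which(sys$atoms$resname == "LIG"))
  # boundary: within is inclusive at exactly R
  b <- prot_lig_system(rbind(c(5.99, 0, 0), c(6.01, 0, 0)),
                       rbind(c(0, 0, 0)))
  hit <- select_atoms(b, "within 6.0 of ( resname LIG and heavy )")$indices
  expect_identical(hit, c(1L, 3L))  # the 5.99 atom and the ligand itself
  # brute-force equivalence on a 50-atom fixture
  for (r in c(3, 6, 9)) {
    got <- select_atoms(sys, sprintf("within %g of ( resname LIG )", r))$indices
    expect_identical(got, oracle_within(sys$xyz,
                                        which(sys$atoms$resname == "LIG"), r))
  }
  # determinism: re-evaluating the expression reproduces indices
  s1 <- select_atoms(sys, "resid 1:10 or name O1")
  s2 <- select_atoms(sys, s1$expression)
  expect_identical(s1$indices, s2$indices)
  expect_warning(select_atoms(sys, "resname XYZ"), "no atoms")
  expect_error(select_atoms(sys, "resid 1:10 and"), "syntax|expected")
  expect_error(select_atoms(sys, "frobnicate 3"), "unknown keyword")
})

test_that("superpose is a true least-squares fit", {
  set.seed(88)
  a <- matrix(rnorm(30), 10, 3)
  # identical coordinates -> zero RMSD, identity transform
  f0 <- superpose(a, a)
  expect_lt(f0$rmsd, 1e-12)
  expect_lt(max(abs(f0$rotation - diag(3))), 1e-9)
  # rigid transform removed exactly
  rot <- random_rotation(99)
  b <- a %*% rot + matrix(rep(c(3, -2, 7), each = 10), 10, 3)
  expect_lt(superpose(b, a)$rmsd, 1e-10)
  # brute-force rotation-search oracle on a random 20-atom pair
  set.seed(100)
  m <- matrix(rnorm(60), 20, 3)
  r <- matrix(rnorm(60), 20, 3)
  expect_equal(superpose(m, r)$rmsd, oracle_min_rmsd(m, r), tolerance = 1e-3)
  expect_error(superpose(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_warning(superpose(line + 0.0, line), "collinear")
})

test_that("superpose RMSD is invariant under rigid transforms of the mobile set", {
  set.seed(101)
  m <- matrix(rnorm(45), 15, 3)
  r <- matrix(rnorm(45), 15, 3)
  base <- superpose(m, r)$rmsd
  for (s in 1:5) {
    rot <- random_rotation(200 + s)
    shifted <- m %*% rot + matrix(rep(rnorm(3, sd = 5), each = 15), 15, 3)
    expect_equal(superpose(shifted, r)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("trajectory invariants are enforced", {
  sys <- random_system(5, seed = 1)
  co <- array(0, dim = c(5, 3, 3))
  expect_error(trajectory(sys, co, times = c(0, 1, 1)), "strictly increasing")
  expect_error(trajectory(sys, co, times = c(0, 1, 2.5)), "constant dt")
  expect_error(trajectory(sys, co[1:4, , ], dt = 1), "atom count")
  tr <- trajectory(sys, co, dt = 1)
  expect_error(frame_coords(tr, 3), "out of range")
  jumpy <- co; jumpy[1, 1, 2] <- 50
  expect_warning(cavitybind:::check_frame_jumps(trajectory(sys, jumpy, dt = 1)),
                 "PBC")
})
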