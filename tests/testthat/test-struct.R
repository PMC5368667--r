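random_frame <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n), n, 3)
}

rigid_move <- function(x, angle = pi / 3, axis = c(0, 0, 1), shift = c(1, 2, 3)) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + s_ * K + (1 - c_) * (K %*% K)
  sweep(x %*% t(R), 2, shift, "+")
}

test_that("superposition removes rigid motions and matches hand values", {
  ref <- random_frame(10, 1)
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)

  mob <- rigid_move(ref, angle = pi / 2)
  fit <- superpose(ref, mob)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$fitted, ref, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # hand-calculable two-point case: optimal rotation leaves residuals +/- 1
  two_ref <- matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  two_mob <- matrix(c(-2, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(superpose(two_ref, two_mob)$rmsd, 1.0, tolerance = 1e-9)

  expect_error(superpose(ref, mob[1:5, ]), "mismatch")
  expect_error(superpose(ref[1, , drop = FALSE], ref[1, , drop = FALSE]),
               "degenerate")
})

make_traj <- function(frames, box = NULL, probe_rows = integer(0)) {
  n <- nrow(frames[[1]])
  atoms <- data.frame(name = rep("CA", n), element = "C", resid = "PRO",
                      resno = seq_len(n), stringsAsFactors = FALSE)
  atoms$resid[probe_rows] <- "PRB"
  atoms$name[probe_rows] <- "PRB"
  atoms$is_probe <- atoms$resid == "PRB"
  atoms$is_heavy <- TRUE
  trajectory(frames, atoms, box = box)
}

test_that("rmsd matrices are symmetric, zero-diagonal and oracle-exact", {
  f1 <- random_frame(8, 2)
  frames <- list(f1, rigid_move(f1), f1 + 0.1 * random_frame(8, 3),
                 f1 + 0.3 * random_frame(8, 4), rigid_move(f1, angle = 1))
  traj <- make_traj(frames)
  M <- rmsd_matrix(traj, selection = 1:8)
  expect_equal(diag(M), rep(0, 5))
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_equal(M[1, 2], 0, tolerance = 1e-9) # rigid motion
  # elementwise agreement with per-pair superpose calls and with the
  # quaternion oracle
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(M[i, j], superpose(frames[[i]], frames[[j]], 1:8)$rmsd,
                 tolerance = 1e-12)
    expect_lt(abs(M[i, j] - quaternion_rmsd(frames[[i]], frames[[j]])), 1e-7)
  }
  expect_error(rmsd_matrix(traj, selection = integer(0)), "empty")
})

test_that("duplicated frames cluster together and extremes behave", {
  f1 <- random_frame(6, 5)
  traj <- make_traj(list(f1, f1, f1 + 5))
  M <- rmsd_matrix(traj, selection = 1:6)
  expect_equal(M[1, 2], 0, tolerance = 1e-9)

  cl_all <- greedy_cluster(M, cutoff = 1e9)
  expect_equal(length(cl_all$centers), 1L)
  # at vanishing cutoff every frame is a singleton (pairwise RMSDs carry
  # numerical noise even for duplicated frames)
  cl_none <- greedy_cluster(M, cutoff = 0)
  expect_equal(length(cl_none$centers), 3L)
  expect_equal(sum(cl_none$sizes), 3L)

  one <- greedy_cluster(matrix(0, 1, 1), 0.2)
  expect_equal(one$labels, 1L)
  expect_equal(one$centers, 1L)

  expect_error(greedy_cluster(matrix(c(0, NA, NA, 0), 2, 2), 0.2), "NA")
})

test_that("two separated blocks give exactly two clusters", {
  # 6-frame matrix: frames 1-3 mutually close, 4-6 mutually close
  M <- matrix(1, 6, 6)
  M[1:3, 1:3] <- 0.1
  M[4:6, 4:6] <- 0.1
  diag(M) <- 0
  cl <- greedy_cluster(M, cutoff = 0.2)
  expect_equal(length(cl$centers), 2L)
  expect_equal(cl$labels[1:3], rep(cl$labels[1], 3))
  expect_equal(cl$labels[4:6], rep(cl$labels[4], 3))
  expect_false(cl$labels[1] == cl$labels[4])
  # members lie within the cutoff of their center
  for (i in 1:6) expect_lte(M[i, cl$centers[cl$labels[i]]], 0.2)
})

test_that("greedy clustering matches the exhaustive reference on random matrices", {
  set.seed(13)
  for (trial in 1:25) {
    n <- 20L
    base <- matrix(runif(n * n, 0, 0.5), n, n)
    M <- (base + t(base)) / 2
    diag(M) <- 0
    cutoff <- runif(1, 0.1, 0.4)
    got <- greedy_cluster(M, cutoff)
    ref <- greedy_reference(M, cutoff)
    expect_identical(got$labels, ref$labels)
    expect_identical(got$centers, ref$centers)
    expect_equal(sum(got$sizes), n)
  }
})

test_that("probe counts match constructed geometries", {
  # one probe fixed 0.3 nm from atom 1 in all frames, far from atom 2
  prot <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  probe <- c(0.3, 0, 0)
  frames <- replicate(10, rbind(prot, probe), simplify = FALSE)
  traj <- make_traj(frames, probe_rows = 3L)
  pm <- probe_density(traj, 0.5)
  expect_equal(pm$atoms$mean_count, c(1, 0))
  expect_equal(pm$n_frames, 10L)

  expect_error(probe_density(make_traj(frames[1], probe_rows = integer(0)),
                             0.5), "no probe")
  big_box <- make_traj(frames, box = c(0.8, 0.8, 0.8), probe_rows = 3L)
  expect_error(probe_density(big_box, 0.5), "half the smallest box")
})

test_that("probe density equals the brute-force recount on a synthetic run", {
  truth <- trajectory_truth(enrichment = 5, designated = c(1, 7, 22),
                            n_frames = 40, n_probes = 30, seed = 7)
  traj <- gen_trajectory(truth)
  pm <- probe_density(traj, 0.5)
  expect_equal(pm$atoms$mean_count, brute_probe_counts(traj, 0.5),
               tolerance = 1e-12)
})

test_that("probe density is invariant under global rigid motion", {
  truth <- trajectory_truth(enrichment = 1, n_frames = 20, n_probes = 15,
                            seed = 3)
  traj <- gen_trajectory(truth)
  traj$box <- NULL # aperiodic so the motion commutes with distances
  moved <- traj
  moved$frames <- lapply(traj$frames, rigid_move, angle = 1.1,
                         axis = c(1, 2, 0.5), shift = c(-4, 2, 9))
  expect_equal(probe_density(moved, 0.5)$atoms$mean_count,
               probe_density(traj, 0.5)$atoms$mean_count,
               tolerance = 1e-9)
})

test_that("designated atoms are enriched by roughly the target factor", {
  des <- c(1, 14, 27)
  truth <- trajectory_truth(enrichment = 5, designated = des,
                            n_frames = 200, seed = 7)
  pm <- probe_density(gen_trajectory(truth), 0.5)
  ratio <- mean(pm$atoms$mean_count[des]) / mean(pm$atoms$mean_count[-des])
  expect_gt(ratio, 3)
  expect_lt(ratio, 7)
})

test_that("per-atom counts converge as frames accumulate", {
  cv <- function(n_frames) {
    truth <- trajectory_truth(enrichment = 1, n_frames = n_frames, seed = 9)
    counts <- probe_density(gen_trajectory(truth), 0.5)$atoms$mean_count
    corners <- c(1, 3, 7, 9, 19, 21, 25, 27) # symmetry-equivalent atoms
    sd(counts[corners]) / mean(counts[corners])
  }
  expect_lt(cv(500), cv(50))
})

test_that("trajectories and score maps round-trip through PDB files", {
  truth <- trajectory_truth(enrichment = 5, designated = c(1, 14, 27),
                            n_frames = 5, seed = 2)
  traj <- gen_trajectory(truth)
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f), add = TRUE)
  write_trajectory_pdb(traj, f)
  back <- read_trajectory_pdb(f)
  expect_equal(length(back$frames), 5L)
  expect_equal(sum(back$atoms$is_probe), truth$n_probes)
  expect_equal(back$box, traj$box, tolerance = 1e-6)
  expect_equal(back$frames[[2]], traj$frames[[2]], tolerance = 1e-3,
               ignore_attr = TRUE)

  pm <- probe_density(traj, 0.5)
  fmap <- tempfile(fileext = ".pdb")
  on.exit(unlink(fmap), add = TRUE)
  write_map(traj, pm, fmap)
  scores <- read_map_scores(fmap)
  expect_equal(length(scores), sum(!traj$atoms$is_probe))
  # format precision: 2 decimals
  expect_equal(scores, round(pm$atoms$mean_count, 2), tolerance = 1e-9)
  expect_equal(which.max(scores), which.max(pm$atoms$mean_count))

  # uniform map: every temperature factor identical
  pm_u <- pm
  pm_u$atoms$mean_count <- rep(1, nrow(pm_u$atoms))
  write_map(traj, pm_u, fmap)
  expect_true(all(read_map_scores(fmap) == 1))

  # map not covering the structure
  pm_short <- pm
  pm_short$atoms <- pm_short$atoms[-1, ]
  expect_error(write_map(traj, pm_short, fmap), "cover")
})

test_that("the XYZ dialect reader reconstructs frames and probe flags", {
  f <- tempfile(fileext = ".xyz")
  on.exit(unlink(f))
  writeLines(c(
    "3", "frame 1",
    "CA 0.0 0.0 0.0", "CA 1.0 0.0 0.0", "PRB 0.3 0.0 0.0",
    "3", "frame 2",
    "CA 0.0 0.0 0.1", "CA 1.0 0.0 0.1", "PRB 0.3 0.0 0.1"), f)
  traj <- read_trajectory_xyz(f)
  expect_equal(length(traj$frames), 2L)
  expect_equal(sum(traj$atoms$is_probe), 1L)
  expect_equal(traj$frames[[2]][3, ], c(0.3, 0, 0.1))
})
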