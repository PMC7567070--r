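square_traj <- function(frames) {
  atoms <- trajmetrics:::new_atom_table(
    serial = 1:4, name = "CA", element = "C", resname = "ALA",
    resid = 1:4, chain = "A")
  md_trajectory(atoms, frames)
}

square_coords <- matrix(c(0, 0, 0, 2, 0, 0, 2, 2, 0, 0, 2, 1), 4, 3, byrow = TRUE)

test_that("a trajectory of identical frames has zero RMSD everywhere", {
  coords <- array(rep(square_coords, each = 5), c(5, 4, 3))
  tr <- square_traj(coords)
  r <- compute_rmsd(tr, selection = "calpha")
  expect_equal(r$data$rmsd, rep(0, 5), tolerance = 1e-9)
  expect_equal(r$mean_value, 0, tolerance = 1e-9)
})

test_that("a 2 A displacement of one of four equal-mass atoms gives RMSD 1 A unfitted", {
  coords <- array(rep(square_coords, each = 2), c(2, 4, 3))
  coords[2, 1, 1] <- coords[2, 1, 1] + 2
  tr <- square_traj(coords)
  r <- compute_rmsd(tr, selection = "calpha", fit = FALSE)
  expect_equal(r$data$rmsd, c(0, 1))  # 2 / sqrt(4)
  # mass weighting is equivalent here because all four masses are equal
  expect_equal(compute_rmsd(tr, "calpha", fit = FALSE, mass_weighted = FALSE)$data$rmsd,
               c(0, 1))
})

test_that("fitted RMSD equals the rotation-space minimisation oracle", {
  coords <- array(rep(square_coords, each = 2), c(2, 4, 3))
  coords[2, 1, 1] <- coords[2, 1, 1] + 2
  tr <- square_traj(coords)
  r <- compute_rmsd(tr, selection = "calpha", fit = TRUE)
  oracle <- numeric_min_rmsd_oracle(coords[2, , ], square_coords,
                                    weights = tr$atoms$mass)
  expect_equal(r$data$rmsd[2], oracle, tolerance = 1e-6)
  expect_lt(r$data$rmsd[2], 1)  # fitting can only lower the deviation
})

test_that("fitted RMSD is invariant under a rigid motion applied to every frame", {
  base <- build_ideal_helix(10)
  tr <- simulate_fluctuations(base, sigma = 0.4, n_frames = 20, seed = 2)
  r0 <- compute_rmsd(tr, "calpha")$data$rmsd
  withr::with_seed(13, {
    tf <- random_rigid_transform()
    moved <- apply_transform(tr, tf)
    expect_equal(compute_rmsd(moved, "calpha")$data$rmsd, r0, tolerance = 1e-6)
  })
})

test_that("the RMSD mean window restricts the reported average", {
  coords <- array(rep(square_coords, each = 3), c(3, 4, 3))
  coords[2, 1, 1] <- coords[2, 1, 1] + 2
  coords[3, 1, 1] <- coords[3, 1, 1] + 2
  tr <- square_traj(coords)
  r <- compute_rmsd(tr, "calpha", fit = FALSE, mean_window = c(1, 2))
  expect_equal(r$mean_value, 1)
  expect_error(compute_rmsd(tr, "calpha", mean_window = c(50, 60)), "no frames")
})

test_that("a static trajectory has zero RMSF", {
  base <- build_ideal_helix(6)
  tr <- simulate_fluctuations(base, sigma = 0, n_frames = 10, seed = 1)
  r <- compute_rmsf(tr, "calpha")
  expect_equal(r$data$rmsf, rep(0, 6), tolerance = 1e-10)
})

test_that("a +/-1 A square-wave oscillation gives RMSF exactly 1 A", {
  base <- build_ideal_helix(5)
  coords <- array(rep(base$coords, each = 4), c(4, 5, 3))
  coords[c(1, 3), 2, 1] <- coords[c(1, 3), 2, 1] + 1
  coords[c(2, 4), 2, 1] <- coords[c(2, 4), 2, 1] - 1
  tr <- md_trajectory(base$atoms, coords)
  r <- compute_rmsf(tr, "calpha", fit = FALSE)
  expect_equal(r$data$rmsf[2], 1)
  expect_equal(r$data$rmsf[-2], rep(0, 4))
})

test_that("isotropic Gaussian jitter recovers sigma * sqrt(3) within 2% at 1e4 frames", {
  base <- build_ideal_helix(10)
  tr <- simulate_fluctuations(base, sigma = 0.5, n_frames = 1e4, seed = 8)
  r <- compute_rmsf(tr, "calpha", fit = FALSE)
  expect_equal(mean(r$data$rmsf), 0.5 * sqrt(3), tolerance = 0.02)
})

test_that("the RMSF estimate converges to sigma*sqrt(3) at roughly 1/sqrt(F)", {
  base <- build_ideal_helix(10)
  truth <- 0.5 * sqrt(3)
  err <- vapply(c(1e2, 1e3, 1e4), function(f) {
    e <- vapply(1:5, function(s) {
      tr <- simulate_fluctuations(base, sigma = 0.5, n_frames = f, seed = 100 + s)
      abs(mean(compute_rmsf(tr, "calpha", fit = FALSE)$data$rmsf) - truth)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  slope <- coef(lm(log(err) ~ log(c(1e2, 1e3, 1e4))))[2]
  expect_lt(slope, -0.25)
  expect_gt(slope, -0.85)
})

test_that("RMSF windows select frames and reject out-of-range requests", {
  base <- build_ideal_helix(5)
  tr <- simulate_fluctuations(base, sigma = 0.3, n_frames = 50, dt = 1, seed = 3)
  r <- compute_rmsf(tr, "calpha", window = c(40, 49))
  expect_equal(r$averaging_time, 9)
  expect_error(compute_rmsf(tr, "calpha", window = c(500, 600)), "outside")
  expect_error(compute_rmsf(tr, "calpha", window = c(10, 10)), "at least 2")
})

test_that("B-factor conversion applies B = (8/3) pi^2 RMSF^2 exactly", {
  base <- build_ideal_helix(8)
  tr <- simulate_fluctuations(base, sigma = 0.4, n_frames = 200, seed = 6)
  prof <- compute_rmsf(tr, "calpha")
  b <- rmsf_to_bfactor(prof)
  expect_equal(b$data$bfactor, (8 / 3) * pi^2 * prof$data$rmsf^2)

  unit <- prof
  unit$data$rmsf <- rep(1, nrow(unit$data))
  expect_equal(rmsf_to_bfactor(unit)$data$bfactor,
               rep(8 * pi^2 / 3, nrow(unit$data)))  # ~26.319 A^2
  doubled <- prof
  doubled$data$rmsf <- 2 * prof$data$rmsf
  expect_equal(rmsf_to_bfactor(doubled)$data$bfactor, 4 * b$data$bfactor)
  zero <- prof
  zero$data$rmsf <- rep(0, nrow(zero$data))
  expect_equal(rmsf_to_bfactor(zero)$data$bfactor, rep(0, nrow(zero$data)))
})

test_that("tidy and glance expose RMSD/RMSF results as tibbles", {
  base <- build_ideal_helix(6)
  tr <- simulate_fluctuations(base, sigma = 0.2, n_frames = 10, seed = 9)
  r <- compute_rmsd(tr, "calpha")
  expect_s3_class(tidy(r), "tbl_df")
  expect_named(tidy(r), c("time", "rmsd"))
  expect_equal(glance(r)$mean_rmsd, r$mean_value)
  prof <- compute_rmsf(tr, "calpha")
  expect_s3_class(tidy(prof), "tbl_df")
  expect_equal(glance(rmsf_to_bfactor(prof))$n_atoms, 6L)
})
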