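test_that("MSD matches hand-computed values on a tiny path", {
  traj <- tibble::tibble(
    particle_id = 1L, t_s = c(0, 1, 2), x_um = c(0, 1, 2), y_um = 0
  )
  msd <- compute_msd(traj, max_lag_s = 2)
  expect_equal(msd$lag_s, c(1, 2))
  expect_equal(msd$msd_um2, c(1, 4))
  expect_equal(msd$n_pairs, c(2, 1))

  still <- tibble::tibble(particle_id = 1L, t_s = 0:9, x_um = 3, y_um = -2)
  expect_true(all(compute_msd(still, max_lag_s = 4)$msd_um2 == 0))
})

test_that("fast estimator equals the pairwise oracle bit for bit", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    dt <- 1 / 25
    x <- cumsum(rnorm(n, sd = 0.3))
    y <- cumsum(rnorm(n, sd = 0.3))
    k_max <- sample(1:(n - 1), 1)
    traj <- tibble::tibble(particle_id = 1L, t_s = (0:(n - 1)) * dt, x_um = x, y_um = y)
    fast <- compute_msd(traj, max_lag_s = k_max * dt)
    brute <- msd_brute(x, y, dt, k_max)
    expect_identical(fast$msd_um2, brute$msd_um2)
    expect_identical(fast$n_pairs, brute$n_pairs)
  }
})

test_that("ballistic MSD is exactly (v k dt)^2", {
  v <- 1.3
  dt <- 0.04
  traj <- tibble::tibble(
    particle_id = 1L, t_s = (0:100) * dt,
    x_um = v * (0:100) * dt * cos(0.7), y_um = v * (0:100) * dt * sin(0.7)
  )
  msd <- compute_msd(traj, max_lag_s = 1)
  expect_equal(msd$msd_um2, (v * msd$lag_s)^2, tolerance = 1e-12)
})

test_that("MSD rejects short or irregular trajectories and names the bad gap", {
  one <- tibble::tibble(particle_id = 1L, t_s = 0, x_um = 0, y_um = 0)
  expect_error(compute_msd(one), "at least 2")
  gap <- tibble::tibble(
    particle_id = 1L, t_s = c(0, 0.04, 0.08, 0.16, 0.20),
    x_um = 0, y_um = 0
  )
  expect_error(compute_msd(gap, max_lag_s = 0.08), "samples 3 and 4")
  traj <- tibble::tibble(particle_id = 1L, t_s = (0:9) / 25, x_um = 1:10, y_um = 0)
  expect_error(compute_msd(traj, max_lag_s = 1), "duration")
})

test_that("ensemble MSD averages across particles with s.e.m.", {
  base <- tibble::tibble(lag_s = c(0.04, 0.08), n_pairs = c(9L, 8L))
  curves <- dplyr::bind_rows(
    dplyr::mutate(base, particle_id = 1L, msd_um2 = c(1, 2)),
    dplyr::mutate(base, particle_id = 2L, msd_um2 = c(3, 2))
  )
  ens <- ensemble_msd(curves)
  expect_equal(ens$msd_um2, c(2, 2))
  # values {1, 3}: sd = sqrt(2), sem = sqrt(2)/sqrt(2) = 1
  expect_equal(ens$sem_um2, c(1, 0))
  expect_equal(ens$n_particles, c(2L, 2L))

  # identical curves: sem 0; single curve: sem undefined
  twin <- dplyr::bind_rows(
    dplyr::mutate(base, particle_id = 1L, msd_um2 = c(1, 2)),
    dplyr::mutate(base, particle_id = 2L, msd_um2 = c(1, 2))
  )
  expect_equal(ensemble_msd(twin)$sem_um2, c(0, 0))
  expect_warning(
    solo <- ensemble_msd(dplyr::mutate(base, particle_id = 1L, msd_um2 = c(1, 2))),
    "undefined"
  )
  expect_true(all(is.na(solo$sem_um2)))
  # unequal lag grids: intersection retained
  uneven <- dplyr::bind_rows(
    curves,
    tibble::tibble(particle_id = 3L, lag_s = 0.04, msd_um2 = 5, n_pairs = 4L)
  )
  expect_equal(ensemble_msd(uneven)$lag_s, 0.04)
})

test_that("20 Brownian particles stay within 3 sem of the diffusive line", {
  m <- ref_motion()
  trajs <- simulate_ensemble(20, 0, m$D_t, m$D_r, duration_s = 30, seed = 404)
  ens <- ensemble_msd(compute_msd(trajs, max_lag_s = 2))
  z <- (ens$msd_um2 - 4 * m$D_t * ens$lag_s) / ens$sem_um2
  expect_true(all(abs(z) < 3))
})
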