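test_that("simulator is deterministic under a seed and leaves the RNG alone", {
  a <- simulate_abp(1, 0.2, 0.18, duration_s = 2, seed = 7)
  b <- simulate_abp(1, 0.2, 0.18, duration_s = 2, seed = 7)
  expect_identical(a, b)
  set.seed(99)
  before <- .Random.seed
  simulate_abp(1, 0.2, 0.18, duration_s = 1, seed = 7)
  expect_identical(.Random.seed, before)
  ens1 <- simulate_ensemble(3, 1, 0.2, 0.18, duration_s = 1, seed = 5)
  ens2 <- simulate_ensemble(3, 1, 0.2, 0.18, duration_s = 1, seed = 5)
  expect_identical(ens1, ens2)
})

test_that("degenerate limits: stationary and ballistic motion", {
  st <- simulate_abp(0, 0, 1, duration_s = 2, seed = 1)
  expect_true(all(st$x_um == 0) && all(st$y_um == 0))
  expect_equal(st$t_s, (0:50) / 25)

  bal <- simulate_abp(1, 0, 1e-12, duration_s = 10, seed = 2)
  disp <- sqrt(bal$x_um^2 + bal$y_um^2)
  expect_equal(disp, bal$t_s, tolerance = 1e-6)
})

test_that("simulator rejects invalid rates", {
  expect_error(simulate_abp(-1, 0.2, 0.18), class = "micromotion_domain_error")
  expect_error(simulate_abp(1, -0.1, 0.18), class = "micromotion_domain_error")
  expect_error(simulate_abp(1, 0.2, 0), class = "micromotion_domain_error")
  expect_error(simulate_abp(1, 0.2, 0.18, fps = 0), class = "micromotion_domain_error")
})

test_that("Brownian ensemble recovers D_t within statistical tolerance", {
  m <- ref_motion()
  trajs <- simulate_ensemble(300, 0, m$D_t, m$D_r, duration_s = 10, seed = 31)
  ens <- ensemble_msd(compute_msd(trajs, max_lag_s = 1))
  slope <- ens$msd_um2 / (4 * ens$lag_s)
  z <- (ens$msd_um2 - 4 * m$D_t * ens$lag_s) / ens$sem_um2
  expect_true(all(abs(z) < 3))
  expect_equal(mean(slope), m$D_t, tolerance = 0.05)
})

test_that("halving the integration step leaves the ensemble MSD unchanged within error", {
  m <- ref_motion()
  t1 <- simulate_ensemble(150, 2, m$D_t, m$D_r,
    duration_s = 8, seed = 61, substeps = 10
  )
  t2 <- simulate_ensemble(150, 2, m$D_t, m$D_r,
    duration_s = 8, seed = 62, substeps = 20
  )
  e1 <- ensemble_msd(compute_msd(t1, max_lag_s = 2))
  e2 <- ensemble_msd(compute_msd(t2, max_lag_s = 2))
  z <- (e1$msd_um2 - e2$msd_um2) / sqrt(e1$sem_um2^2 + e2$sem_um2^2)
  expect_true(all(abs(z) < 4))
})

test_that("localization noise: identity at zero, reproducible, 4 sigma^2 plateau", {
  traj <- simulate_abp(1, 0.2, 0.2, duration_s = 2, seed = 3)
  expect_identical(add_localization_noise(traj, 0), traj)
  n1 <- add_localization_noise(traj, 0.05, seed = 11)
  n2 <- add_localization_noise(traj, 0.05, seed = 11)
  expect_identical(n1, n2)
  expect_error(add_localization_noise(traj, -0.1), class = "micromotion_domain_error")

  # stationary particle: MSD plateau at 4 sigma^2 = 0.01 um^2
  still <- tibble::tibble(
    particle_id = 1L, frame = 0:3999, t_s = (0:3999) / 25,
    x_um = 0, y_um = 0
  )
  noisy <- add_localization_noise(still, 0.05, seed = 12)
  msd <- compute_msd(noisy, max_lag_s = 1)
  expect_equal(mean(msd$msd_um2), 4 * 0.05^2, tolerance = 0.05)
})
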