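test_that("rate law reproduces its closed-form special cases", {
  kp <- kinetic_params(K_m_mM = 30)
  expect_equal(relative_rate(0, 0, kp), 0)
  expect_equal(relative_rate(0, 100, kp), 0)
  # half-saturation by construction
  expect_equal(relative_rate(30, 0, kp), 0.5)
  # competitive inhibitor at I = K_i: K_m(1+1) + K_m = 3 K_m
  kp_i <- kinetic_params(K_m_mM = 30, K_i_mM = 5)
  expect_equal(relative_rate(30, 5, kp_i), 1 / 3)
  # substrate inhibition at S = K_s = K_m: K_m + 2 K_m
  kp_s <- kinetic_params(K_m_mM = 30, K_s_mM = 30)
  expect_equal(relative_rate(30, 0, kp_s), 1 / 3)
  expect_error(relative_rate(-1, 0, kp), class = "micromotion_domain_error")
  expect_error(relative_rate(10, -1, kp), class = "micromotion_domain_error")
})

test_that("rate law reduces to Michaelis-Menten without inhibition", {
  kp <- kinetic_params(K_m_mM = 12.5)
  s_grid <- c(0.01, 0.1, 1, 5, 12.5, 50, 200, 1000)
  expect_equal(
    relative_rate(s_grid, 0, kp),
    s_grid / (12.5 + s_grid)
  )
})

test_that("rate is unimodal in substrate and decreasing in inhibitor", {
  kp <- kinetic_params(K_m_mM = 30, K_i_mM = 0.1, K_s_mM = 400)
  for (inhibitor in c(0, 0.5, 5)) {
    s_peak <- sqrt(30 * 400 * (1 + inhibitor / 0.1))
    below <- seq(1, s_peak, length.out = 50)
    above <- seq(s_peak, 10 * s_peak, length.out = 50)
    expect_true(all(diff(relative_rate(below, inhibitor, kp)) > 0))
    expect_true(all(diff(relative_rate(above, inhibitor, kp)) < 0))
  }
  i_grid <- seq(0, 20, length.out = 80)
  for (s in c(1, 30, 500)) {
    expect_true(all(diff(relative_rate(rep(s, 80), i_grid, kp)) < 0))
  }
  # without substrate inhibition, monotone nondecreasing in S
  kp_mm <- kinetic_params(K_m_mM = 30)
  expect_true(all(diff(relative_rate(seq(0, 2000, by = 10), 0, kp_mm)) >= 0))
})

test_that("speed coupling is linear in the rate and anchored at the preset maximum", {
  kp <- kinetic_params(K_m_mM = 30, speed_coupling = 2.07)
  expect_equal(speed_from_rate(0, kp), 0)
  expect_equal(speed_from_rate(1, kp), 2.07)
  kp2 <- kinetic_params(K_m_mM = 30, speed_coupling = 2.0)
  expect_equal(speed_from_rate(0.5, kp2), 1.0)
  rates <- runif(20)
  a <- 0.37
  expect_equal(
    speed_from_rate(a * rates * 0.9, kp2),
    a * speed_from_rate(rates * 0.9, kp2)
  )
  expect_error(speed_from_rate(1.5, kp), class = "micromotion_domain_error")
})

test_that("dose_response tabulates conditions and shows rise-then-fall for the urease preset", {
  kp <- urease_kinetics()
  one <- dose_response(tibble::tibble(substrate_mM = 30, inhibitor_mM = 0), kp)
  # S = K_m with the S^2/Ks term: 30/(30 + 30*(1 + 30/400))
  expect_equal(one$rate, 30 / (30 + 30 * (1 + 30 / 400)))
  two <- dose_response(
    tibble::tibble(substrate_mM = 100, inhibitor_mM = c(0, 1e6)),
    kp
  )
  expect_lt(two$true_speed_um_s[2], two$true_speed_um_s[1])

  sweep <- dose_response(
    tibble::tibble(substrate_mM = c(0, 1, 10, 50, 100, 200, 300), inhibitor_mM = 0),
    kp
  )
  d <- diff(sweep$true_speed_um_s)
  # strictly increasing up to the peak (~110 mM), then strictly decreasing
  expect_true(all(d[1:4] > 0))
  expect_true(all(d[5:6] < 0))
  expect_error(dose_response(tibble::tibble(substrate_mM = 1), kp))
})

test_that("activity readout is reproducible and non-negative", {
  a1 <- measure_activity(rep(0.5, 100), cv = 0.05, seed = 42)
  a2 <- measure_activity(rep(0.5, 100), cv = 0.05, seed = 42)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0))
  expect_equal(measure_activity(0.7, cv = 0), 0.7)
})

test_that("kinetic_params enforces its invariants", {
  expect_error(kinetic_params(K_m_mM = -1), class = "micromotion_domain_error")
  expect_error(kinetic_params(K_m_mM = 30, K_s_mM = 10), class = "micromotion_domain_error")
  expect_error(kinetic_params(K_m_mM = 30, speed_coupling = -2), class = "micromotion_domain_error")
  expect_s3_class(kinetic_params(K_m_mM = 30, K_s_mM = 30), "kinetic_params")
})
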