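test_that("mono-exponential simulation matches the closed-form identities", {
  p <- mono_exp_params(a0 = 286, aeq = 134, k_obs = 1e-3)

  cv0 <- simulate_mono_exponential(p, 0)
  expect_equal(cv0$substrate_mM, 286)
  expect_equal(cv0$product_mM, 0)

  # one half-life of the decaying term sits midway between A0 and Aeq
  cv_half <- simulate_mono_exponential(p, log(2) / 1e-3)
  expect_equal(cv_half$substrate_mM, 210, tolerance = 1e-12)

  # the decaying term is gone once k_obs * t >= 50
  cv_late <- simulate_mono_exponential(p, 50 / 1e-3)
  expect_equal(cv_late$substrate_mM, 134, tolerance = 1e-9)
})

test_that("parameter and time validation rejects bad inputs", {
  expect_error(mono_exp_params(-1, 0, 1), "a0")
  expect_error(mono_exp_params(100, 150, 1), "aeq")
  expect_error(mono_exp_params(100, 50, 0), "k_obs")
  expect_error(mono_exp_params(100, 50, NaN), "k_obs")
  expect_error(rate_constants(0, 1), "k_f")
  expect_error(rate_constants(1, -1), "k_r")
  p <- mono_exp_params(100, 50, 0.1)
  expect_error(simulate_mono_exponential(p, c(1, 1)), "strictly increasing")
  expect_error(simulate_mono_exponential(p, c(-1, 2)), "non-negative")
  expect_error(simulate_mass_action(-5, rate_constants(1, 1), 1), "a0")
  expect_error(equilibrium_product(100, -2), "K")
  expect_error(time_to_fraction(p, 1), "fraction")
  expect_error(time_to_fraction(p, 0), "fraction")
})

test_that("equilibrium product solves the squared-product equilibrium", {
  expect_identical(equilibrium_product(100, 0), 0)
  # quadratic-formula oracle: positive root of P^2 + K P - K A0 = 0
  quad_root <- function(a0, K) (-K + sqrt(K^2 + 4 * K * a0)) / 2
  expect_equal(equilibrium_product(100, 100), 50 * (sqrt(5) - 1),
               tolerance = 1e-12)
  expect_equal(equilibrium_product(286, 172.42), 152.0, tolerance = 1e-3)
  for (a0 in c(50, 286, 300)) {
    for (K in c(1e-6, 0.5, 15, 172.42, 1e4)) {
      p_eq <- equilibrium_product(a0, K)
      expect_equal(p_eq, quad_root(a0, K), tolerance = 1e-12)
      expect_true(p_eq >= 0 && p_eq < a0)
      # stationarity of the rate law: k_f (A0 - P) = k_r P^2 at P_eq
      expect_equal(p_eq^2, K * (a0 - p_eq), tolerance = 1e-9)
    }
  }
})

test_that("mass-action closed form satisfies its initial and limiting values", {
  rc <- rate_constants(k_f = 0.01, k_r = 1e-4) # K = 100 mM
  cv <- simulate_mass_action(100, rc, c(0, 10, 100, 1e5))
  expect_equal(cv$product_mM[1], 0)
  expect_equal(cv$product_mM[4], 61.80, tolerance = 1e-4)
  expect_equal(cv$product_mM[4], equilibrium_product(100, 100),
               tolerance = 1e-6)
})

test_that("closed-form mass action matches independent numerical integration", {
  skip_if_not_installed("deSolve")
  for (a0 in c(50, 300)) {
    for (K in c(1, 10, 100, 1000)) {
      k_f <- 0.01
      rc <- rate_constants(k_f, k_f / K)
      t95 <- log(20) / sqrt(k_f^2 + 4 * k_f * rc$k_r * a0)
      times <- c(0, 10^seq(log10(t95 / 50), log10(5 * t95), length.out = 12))
      cv <- simulate_mass_action(a0, rc, times)
      sol <- deSolve::ode(
        c(P = 0), times,
        function(t, y, parms) list(k_f * (a0 - y[1]) - rc$k_r * y[1]^2),
        NULL, rtol = 1e-10, atol = 1e-12
      )
      rel <- abs(cv$product_mM[-1] - sol[-1, 2]) / sol[-1, 2]
      expect_lt(max(rel), 1e-6)
    }
  }
})

test_that("simulated curves conserve mass and are monotone", {
  set.seed(42)
  for (i in 1:20) {
    a0 <- runif(1, 20, 400)
    aeq <- runif(1, 0, a0)
    k <- 10^runif(1, -5, -1)
    times <- sort(runif(15, 0, 5 * log(20) / k))
    times <- c(0, times[times > 0])
    cv1 <- simulate_mono_exponential(mono_exp_params(a0, aeq, k), times)
    expect_equal(cv1$substrate_mM + cv1$product_mM, rep(a0, length(times)),
                 tolerance = 1e-9)
    expect_true(all(diff(cv1$substrate_mM) <= 1e-12))
    expect_true(all(diff(cv1$product_mM) >= -1e-12))

    cv2 <- simulate_mass_action(a0, rate_constants(k, k / runif(1, 1, 500)),
                                times)
    expect_equal(cv2$substrate_mM + cv2$product_mM, rep(a0, length(times)),
                 tolerance = 1e-9)
    expect_true(all(diff(cv2$product_mM) >= -1e-12))
  }
})

test_that("mass action converges to irreversible mono-exponential as k_r -> 0", {
  a0 <- 120
  k_f <- 0.005
  times <- c(0, 50, 200, 600, 2000)
  mono <- simulate_mono_exponential(mono_exp_params(a0, 0, k_f), times)
  for (k_r in 10^c(-6, -8, -10)) {
    ma <- simulate_mass_action(a0, rate_constants(k_f, k_r), times)
    dev <- max(abs(ma$product_mM - mono$product_mM))
    expect_lt(dev, a0 * k_r / k_f * a0 + 1e-8) # vanishes linearly in k_r
  }
  ma <- simulate_mass_action(a0, rate_constants(k_f, 1e-12), times)
  expect_equal(ma$product_mM, mono$product_mM, tolerance = 1e-7)
})

test_that("time_to_fraction inverts the mono-exponential progress", {
  p <- mono_exp_params(286, 134, 0.01)
  expect_equal(time_to_fraction(p, 0.95), 299.5732, tolerance = 1e-4)
  expect_equal(time_to_fraction(p, 0.5), log(2) / 0.01, tolerance = 1e-12)
  expect_lt(time_to_fraction(p, 1e-9), 1e-4)
  # consistency: product at t95 is 95 % of its plateau
  t95 <- time_to_fraction(p, 0.95)
  cv <- simulate_mono_exponential(p, t95)
  expect_equal(cv$product_mM / (286 - 134), 0.95, tolerance = 1e-12)
})

test_that("optional acetone loss pulls the equilibrium toward more product", {
  rc <- rate_constants(0.01, 1e-4)
  times <- c(0, 100, 1000, 20000)
  base <- simulate_mass_action(100, rc, times)
  lossy <- simulate_mass_action(100, rc, times, acetone_loss = 1e-3)
  expect_equal(lossy$product_mM[1], 0)
  expect_gt(lossy$product_mM[4], base$product_mM[4])
  expect_true(all(lossy$substrate_mM + lossy$product_mM - 100 < 1e-6))
})
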