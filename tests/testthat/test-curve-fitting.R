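test_that("equilibrium constant and conversion reproduce the worked example", {
  eq <- estimate_equilibrium_constant(286, 152)
  expect_equal(eq$log_K, 2.24, tolerance = 0.005 / 2.24)
  expect_equal(conversion(286, 152), 53, tolerance = 0.01)

  # symmetric point: P = A0/2 gives K = A0/2
  expect_equal(estimate_equilibrium_constant(200, 100)$K, 100,
               tolerance = 1e-12)
  # hand arithmetic: 62^2 / 247
  eq2 <- estimate_equilibrium_constant(309, 62)
  expect_equal(eq2$K, 3844 / 247, tolerance = 1e-12)
  expect_equal(round(eq2$log_K, 2), 1.19)

  expect_error(estimate_equilibrium_constant(286, 286), "unbounded")
  expect_error(estimate_equilibrium_constant(286, 300), "unbounded")
  expect_equal(conversion(100, 0), 0)
  expect_equal(conversion(100, 100), 100)
  expect_error(conversion(100, 101), "p")
})

test_that("equilibrium-constant estimation inverts the equilibrium solver", {
  for (a0 in c(47, 286, 356)) {
    for (K in c(0.1, 15.6, 172.42, 3020)) {
      p_eq <- equilibrium_product(a0, K)
      expect_equal(estimate_equilibrium_constant(a0, p_eq)$K, K,
                   tolerance = 1e-9)
    }
  }
})

test_that("enantiomeric excess matches the reported stereochemistry rows", {
  r1 <- enantiomeric_excess(95, 5)
  expect_equal(r1$ee, 90)
  expect_identical(r1$configuration, "S")
  r2 <- enantiomeric_excess(50, 50)
  expect_equal(r2$ee, 0)
  expect_identical(r2$configuration, "racemic")
  r3 <- enantiomeric_excess(100, 0)
  expect_equal(r3$ee, 100)
  expect_identical(r3$configuration, "S")
  r4 <- enantiomeric_excess(0, 100)
  expect_identical(r4$configuration, "R")

  # invariance under scaling of raw isomer amounts
  set.seed(7)
  for (i in 1:10) {
    s <- runif(1, 0, 5); r <- runif(1, 0, 5); f <- runif(1, 0.1, 50)
    expect_equal(enantiomeric_excess(s, r)$ee,
                 enantiomeric_excess(f * s, f * r)$ee, tolerance = 1e-12)
  }
  expect_error(enantiomeric_excess(-1, 5), "fraction_s")
  expect_error(enantiomeric_excess(0, 0), "positive")
})

test_that("fitting noiseless mono-exponential data recovers the parameters", {
  set.seed(11)
  for (i in 1:12) {
    a0 <- runif(1, 30, 400)
    aeq <- runif(1, 0.05, 0.9) * a0
    k <- 10^runif(1, -4, -1)
    t95 <- log(20) / k
    times <- c(0, 10^seq(log10(t95 / 100), log10(5 * t95), length.out = 13))
    cv <- simulate_mono_exponential(mono_exp_params(a0, aeq, k), times)
    for (sp in c("substrate", "product")) {
      f <- fit_mono_exponential(cv, species = sp)
      expect_true(f$converged)
      expect_equal(f$params$a0, a0, tolerance = 1e-6)
      expect_equal(f$params$aeq, aeq, tolerance = 1e-5)
      expect_equal(f$params$k_obs, k, tolerance = 1e-5)
    }
  }
})

test_that("mono-exponential fit recovers the equilibrium of mass-action data", {
  # the shape is misspecified, but the plateau is model-independent
  K <- 172.4
  rc <- rate_constants(0.004, 0.004 / K)
  t95 <- log(20) / sqrt(rc$k_f^2 + 4 * rc$k_f * rc$k_r * 286)
  times <- c(0, 10^seq(1, log10(6 * t95), length.out = 17))
  cv <- simulate_mass_action(286, rc, times)
  f <- fit_mono_exponential(cv)
  expect_true(f$converged)
  expect_equal(f$params$aeq, 134, tolerance = 0.02)
  expect_equal(f$log_K_ex, log10(K), tolerance = 0.02)
})

test_that("the least-squares solution matches a zooming grid-search oracle", {
  set.seed(23)
  p <- mono_exp_params(a0 = 100, aeq = 40, k_obs = 0.02)
  times <- c(0, 10^seq(0.5, log10(5 * log(20) / 0.02), length.out = 14))
  cv <- simulate_mono_exponential(p, times)
  cv$substrate_mM <- cv$substrate_mM * (1 + rnorm(15, 0, 0.03))
  f <- fit_mono_exponential(cv, a0 = 100, fix_a0 = TRUE)
  oracle <- grid_search_oracle(cv$time_min, cv$substrate_mM, a0 = 100)
  sse_fit <- sum((f$data$observed - f$data$fitted)^2)
  expect_lte(sse_fit, oracle$sse + 1e-6)
  expect_equal(sse_fit, oracle$sse, tolerance = 1e-6)
  expect_equal(f$params$aeq, oracle$aeq, tolerance = 1e-3)
})

test_that("equilibrium flagging and K source options behave as documented", {
  p <- mono_exp_params(300, 150, 0.001)
  # sampled far short of 3 t95: flagged, but still converged
  early <- simulate_mono_exponential(p, c(0, 100, 300, 600, 1000, 1500))
  f_early <- fit_mono_exponential(early)
  expect_true(f_early$converged)
  expect_false(f_early$equilibrium_reached)

  t95 <- time_to_fraction(p, 0.95)
  full <- simulate_mono_exponential(
    p, c(0, 10^seq(1, log10(5 * t95), length.out = 14)))
  f_full <- fit_mono_exponential(full)
  expect_true(f_full$equilibrium_reached)

  # keq-from-last uses the final measured product instead of the plateau
  f_last <- fit_mono_exponential(full, keq_from = "last")
  p_last <- full$product_mM[nrow(full)]
  expect_equal(f_last$K_ex, p_last^2 / (f_last$params$a0 - p_last),
               tolerance = 1e-9)

  expect_error(fit_mono_exponential(full[1:3, ]), "4")
})

test_that("fit results round into a report row like a reactor table", {
  p <- mono_exp_params(286, 134, 0.002)
  t95 <- time_to_fraction(p, 0.95)
  cv <- simulate_mono_exponential(
    p, c(0, 10^seq(1, log10(5 * t95), length.out = 15)))
  row <- report_row(fit_mono_exponential(cv))
  expect_identical(row$C0, 286)
  expect_identical(row$C_inf, 152)
  expect_identical(row$conversion_pct, 53)
  expect_identical(row$log_K, 2.24)
  expect_equal(row$t95_h, round(t95 / 60, 1))
  g <- glance(fit_mono_exponential(cv))
  expect_equal(g$r_squared, 1, tolerance = 1e-9)
  td <- tidy(fit_mono_exponential(cv))
  expect_identical(td$term, c("A0", "Aeq", "k_obs"))
})

test_that("fitted log K tracks the generating value across noisy runs", {
  rec <- recovery_experiment(n_runs = 30, seed = 5)
  expect_true(all(rec$converged))
  expect_true(all(rec$conversion > 15 & rec$conversion < 95))
  expect_lt(median(rec$abs_error), 0.05)
  expect_lt(quantile(rec$abs_error, 0.9), 0.15)
})
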