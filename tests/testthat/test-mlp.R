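test_that("case splitting honours the 2:1:1 ratio deterministically", {
  cases <- tibble::tibble(time_min = seq_len(1000), product_mM = 1)
  s1 <- split_cases(cases, seed = 4)
  s2 <- split_cases(cases, seed = 4)
  expect_identical(s1$split, s2$split)
  counts <- table(s1$split)
  expect_true(abs(counts[["train"]] - 500) <= 1)
  expect_true(abs(counts[["validation"]] - 250) <= 1)
  expect_true(abs(counts[["test"]] - 250) <= 1)

  tiny <- split_cases(cases[1:4, ], seed = 1)
  expect_identical(as.integer(sort(table(tiny$split))), c(1L, 1L, 2L))
  expect_error(split_cases(cases[1:3, ], seed = 1), "4")
  expect_error(split_cases(cases, ratio = c(2, 1)), "ratio")
})

test_that("time truncation filters inclusively", {
  cases <- tibble::tibble(time_min = c(0, 10, 999, 1000, 1001, 5000))
  expect_identical(truncate_cases(cases)$time_min, c(0, 10, 999, 1000))
  expect_identical(nrow(truncate_cases(cases, 0)), 1L)
  expect_identical(truncate_cases(cases, Inf), cases)
  # survivor count equals a direct filter
  study <- default_study()
  expect_identical(nrow(truncate_cases(study$cases, 1000)),
                   sum(study$cases$time_min <= 1000))
})

test_that("min-max scaling round-trips exactly", {
  set.seed(9)
  mat <- cbind(a = runif(40, 50, 300), b = rnorm(40), c = rep(2, 40))
  y <- runif(40, 0, 250)
  sc <- ketokin:::fit_scaling(mat, y)
  expect_equal(ketokin:::scale_inputs(mat, sc) *
                 rep(sc$x_span, each = 40) + rep(sc$x_min, each = 40),
               mat, tolerance = 1e-12)
  expect_equal(ketokin:::descale_output(ketokin:::scale_output(y, sc), sc), y,
               tolerance = 1e-12)
  # constant column maps to zero, not NaN
  expect_true(all(is.finite(ketokin:::scale_inputs(mat, sc))))
})

test_that("backprop gradient matches central finite differences", {
  set.seed(13)
  for (act in c("identity", "logistic")) {
    for (i in 1:4) {
      n_in <- sample(2:4, 1)
      n_h <- sample(2:6, 1)
      dims <- ketokin:::mlp_dims(n_in, n_h)
      X <- matrix(runif(12 * n_in), 12, n_in)
      y <- runif(12)
      theta <- runif(dims$n_par, -1, 1)
      analytic <- ketokin:::mlp_loss_grad(theta, X, y, dims, act)$grad
      numeric <- fd_gradient(theta, X, y, dims, act)
      expect_equal(analytic, numeric, tolerance = 1e-5)
    }
  }
})

test_that("training is deterministic and respects the validation minimum", {
  study <- default_study()
  cfg <- mlp_config(n_epochs_phase1 = 30, n_epochs_phase2 = 40,
                    patience = 20, n_starts = 2, seed = 3)
  m1 <- train_mlp(study$cases, cfg)
  m2 <- train_mlp(study$cases, cfg)
  expect_identical(m1$theta, m2$theta)
  # the returned weights achieve the lowest validation error ever logged
  expect_lte(m1$best_val_error, min(m1$training_log$val_rmse))
})

test_that("a constant-output dataset is learned exactly", {
  set.seed(2)
  cases <- tibble::tibble(
    C0_mM = runif(60, 50, 300), descriptor = rnorm(60),
    time_min = runif(60, 0, 1000), product_mM = 80
  )
  m <- train_mlp(cases, mlp_config(n_epochs_phase2 = 30, n_starts = 1, seed = 1))
  pred <- suppressWarnings(predict(m, cases)$.pred) # some rows extrapolate
  expect_lt(sqrt(mean((pred - 80)^2)), 1e-2)
  expect_lt(diff(range(pred)), 5e-2)
})

test_that("the default network learns the synthetic study", {
  study <- default_study()
  m <- default_model()
  g <- glance(m, study$cases)
  expect_gt(g$r2_train, 0.85)
  expect_gt(g$r2_test, 0.85)
  # all predictions finite, far outside the range included
  wild <- tibble::tibble(C0_mM = c(5, 5000), descriptor = c(-100, 100),
                         time_min = c(0, 1e6))
  expect_warning(p <- predict(m, wild), "extrapolate")
  expect_true(all(is.finite(p$.pred)))
  expect_true(all(p$.extrapolated))

  # t = 0 anchors keep the zero-time prediction near zero product at a
  # representative (mean-input) point
  zero <- tibble::tibble(C0_mM = m$train_means[["C0_mM"]],
                         descriptor = m$train_means[["descriptor"]],
                         time_min = 0)
  p0 <- suppressWarnings(predict(m, zero)$.pred)
  expect_lte(abs(p0), 0.05 * zero$C0_mM)

  # predictions along a time grid are essentially monotone
  grid <- tibble::tibble(C0_mM = 300, descriptor = m$train_means[["descriptor"]],
                         time_min = 10^seq(0, 4, length.out = 40))
  pg <- suppressWarnings(predict(m, grid)$.pred)
  expect_gte(mean(diff(pg) >= -1e-8), 0.95)
})

test_that("scalar prediction interface matches the data-frame interface", {
  m <- default_model()
  one <- predict_product(m, C0 = 290, descriptor = 0, time = 500)
  df <- suppressWarnings(
    predict(m, tibble::tibble(C0_mM = 290, descriptor = 0, time_min = 500)))
  expect_equal(unname(as.numeric(one)), df$.pred)
})

test_that("sensitivity analysis is consistent and flags uninformative inputs", {
  study <- default_study()
  m <- default_model()
  sens <- sensitivity_analysis(m, study$cases)
  expect_identical(sens$input[1], "time_min")
  expect_true(all(sens$ratio >= 1 - 1e-6))
  # direct recomputation of one ratio
  mutated <- study$cases
  mutated$descriptor <- m$train_means[["descriptor"]]
  rmse <- function(pred) sqrt(mean((study$cases$product_mM - pred)^2))
  direct <- rmse(suppressWarnings(predict(m, mutated)$.pred)) /
    rmse(suppressWarnings(predict(m, study$cases)$.pred))
  expect_equal(sens$ratio[sens$input == "descriptor"], direct,
               tolerance = 1e-10)
})

test_that("response curves project the surface at the training means", {
  m <- default_model()
  rc <- response_curve(m, "descriptor")
  expect_identical(nrow(rc), 50L)
  expect_false(any(rc$.extrapolated))
  # stronger electron withdrawal (lower ddG) means more product
  expect_true(all(diff(rc$.pred) <= 1e-9))
  # a one-point grid at the means equals the plain prediction at the means
  at_means <- response_curve(m, "time_min",
                             grid = m$train_means[["time_min"]])
  nd <- tibble::tibble(C0_mM = m$train_means[["C0_mM"]],
                       descriptor = m$train_means[["descriptor"]],
                       time_min = m$train_means[["time_min"]])
  expect_equal(at_means$.pred, suppressWarnings(predict(m, nd)$.pred),
               tolerance = 1e-12)
  expect_error(response_curve(m, "bogus"), "one of")
})

test_that("external validation scores each held-out run separately", {
  study <- default_study()
  cases <- study$cases
  id4 <- names(which(table(study$series$runs$substrate_id) == 4))[1]
  cfg <- mlp_config(n_epochs_phase1 = 40, n_epochs_phase2 = 60,
                    patience = 30, n_starts = 1, seed = 2)
  ev <- external_validation(cases, id4, cfg)
  expect_identical(nrow(ev$runs), 4L)
  expect_true(all(is.finite(ev$runs$r_squared)))
  expect_error(external_validation(cases, "sub_99", cfg), "Unknown substrate")

  # holding out a descriptor-range edge substrate raises the flag
  edge_id <- study$panel$substrate_id[which.max(study$panel$ddg_alkoxy_kj_mol)]
  ev_edge <- external_validation(cases, edge_id, cfg)
  expect_true(any(ev_edge$runs$extrapolated))
})

test_that("a trained network survives the text-artifact round trip", {
  study <- default_study()
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".yml")
  write_mlp(m, path)
  m2 <- read_mlp(path)
  p1 <- suppressWarnings(predict(m, study$cases)$.pred)
  p2 <- suppressWarnings(predict(m2, study$cases)$.pred)
  expect_equal(p1, p2, tolerance = 1e-8)
  expect_identical(m2$config$log_time, m$config$log_time)
})
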