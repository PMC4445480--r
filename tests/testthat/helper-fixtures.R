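# Shared fixtures and independent oracles, built in code at test time.

# One default synthetic study (panel, series, case table) and one trained
# network, built lazily and reused across test files.
.fixture_env <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixture_env$study)) {
    gen <- generator_config(seed = 1)
    panel <- generate_panel(gen)
    series <- generate_reactor_series(panel, gen)
    cases <- split_cases(generate_case_table(panel, series), seed = 1)
    .fixture_env$study <- list(gen = gen, panel = panel, series = series,
                               cases = cases)
  }
  .fixture_env$study
}

default_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- train_mlp(default_study()$cases, mlp_config(seed = 1))
  }
  .fixture_env$model
}

# Independent OLS oracle: direct normal-equations solve.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2], fitted = drop(X %*% beta))
}

# Independent least-squares oracle for the two-parameter mono-exponential
# fit (A0 fixed): zooming grid search over (Aeq, k_obs).
grid_search_oracle <- function(times, obs, a0, n_grid = 41, n_zoom = 7) {
  sse_at <- function(aeq, k) {
    sum((aeq + (a0 - aeq) * exp(-k * times) - obs)^2)
  }
  aeq_lo <- 0; aeq_hi <- a0
  k_lo <- log(2) / max(times); k_hi <- log(2) / min(times[times > 0])
  best <- c(NA, NA, Inf)
  for (z in seq_len(n_zoom)) {
    aeqs <- seq(aeq_lo, aeq_hi, length.out = n_grid)
    ks <- exp(seq(log(k_lo), log(k_hi), length.out = n_grid))
    for (aeq in aeqs) for (k in ks) {
      s <- sse_at(aeq, k)
      if (s < best[3]) best <- c(aeq, k, s)
    }
    d_aeq <- (aeq_hi - aeq_lo) / (n_grid - 1)
    aeq_lo <- max(0, best[1] - 2 * d_aeq); aeq_hi <- min(a0, best[1] + 2 * d_aeq)
    lr <- (log(k_hi) - log(k_lo)) / (n_grid - 1)
    k_lo <- exp(log(best[2]) - 2 * lr); k_hi <- exp(log(best[2]) + 2 * lr)
  }
  list(aeq = best[1], k_obs = best[2], sse = best[3])
}

# Central finite-difference gradient for the MLP loss.
fd_gradient <- function(theta, X, y, dims, act, eps = 1e-6) {
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (ketokin:::mlp_loss_grad(up, X, y, dims, act, gradient = FALSE)$f -
       ketokin:::mlp_loss_grad(dn, X, y, dims, act, gradient = FALSE)$f) /
      (2 * eps)
  }, double(1))
}
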