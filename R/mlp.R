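# A small from-scratch multilayer-perceptron regressor for progress-curve
# prediction: product concentration as a function of initial loading, one
# electronic descriptor, and reaction time. Default architecture 3-5-1
# (logistic hidden layer, identity output), min-max input/output scaling
# computed on the training subset only, and a two-phase training protocol:
# plain back-propagation with momentum followed by Polak-Ribiere conjugate
# gradient with early stopping on the validation subset.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' MLP training configuration
#'
#' @param n_hidden Number of hidden neurons (2-10 is the sensible range for
#'   these data; the validation error is roughly flat from 5 up, hence the
#'   default).
#' @param inputs Names of the input columns in the case table.
#' @param output Name of the dependent-variable column (product
#'   concentration, mM).
#' @param output_activation `"identity"` (default) or `"logistic"`.
#' @param log_time Feed the time input as `log10(1 + t)` (default). Reactor
#'   sampling spans four decades of time; on a logarithmic axis progress
#'   curves are close to sigmoidal, which conditions the network far better
#'   than raw minutes. Scaling is still min-max on the training subset. The
#'   transform applies to the input column named `"time_min"`.
#' @param learning_rate,momentum Phase-1 back-propagation hyperparameters.
#' @param n_epochs_phase1 Epochs of gradient descent with momentum.
#' @param n_epochs_phase2 Epoch budget for the conjugate-gradient phase
#'   (175 for the full-time-span protocol; use 260 with time truncation).
#' @param patience Early-stopping patience (epochs without a new validation
#'   minimum) during phase 2.
#' @param n_starts Number of seeded random restarts; the restart with the
#'   lowest validation error is kept. Plays the role of the multi-candidate
#'   architecture searches common in neural QSAR workflows, at desk scale.
#' @param seed Integer seed for splitting, initialization and restarts.
#'
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(n_hidden = 5L,
                       inputs = c("C0_mM", "descriptor", "time_min"),
                       output = "product_mM",
                       output_activation = c("identity", "logistic"),
                       log_time = TRUE,
                       learning_rate = 0.1, momentum = 0.3,
                       n_epochs_phase1 = 100L, n_epochs_phase2 = 175L,
                       patience = 60L, n_starts = 5L, seed = 1L) {
  output_activation <- match.arg(output_activation)
  check_number(n_hidden, "n_hidden", lower = 1)
  check_number(learning_rate, "learning_rate", lower = 0, allow_lower = FALSE)
  check_number(momentum, "momentum", lower = 0, upper = 1)
  structure(
    list(n_hidden = as.integer(n_hidden), inputs = inputs, output = output,
         output_activation = output_activation, log_time = isTRUE(log_time),
         learning_rate = learning_rate, momentum = momentum,
         n_epochs_phase1 = as.integer(n_epochs_phase1),
         n_epochs_phase2 = as.integer(n_epochs_phase2),
         patience = as.integer(patience), n_starts = as.integer(n_starts),
         seed = as.integer(seed)),
    class = "mlp_config"
  )
}

#' Randomly split cases into training, validation and test subsets
#'
#' Uniform random assignment in the given ratio (default 2:1:1) with
#' largest-remainder rounding, deterministic for a given seed.
#'
#' @param cases A case table (data frame).
#' @param ratio Integer ratio of train:validation:test sizes.
#' @param seed Integer seed.
#'
#' @return `cases` with a `split` column
#'   (`"train"`, `"validation"`, `"test"`).
#' @export
split_cases <- function(cases, ratio = c(2, 1, 1), seed = 1L) {
  stopifnot(is.data.frame(cases))
  if (length(ratio) != 3L || any(ratio <= 0)) {
    abort("`ratio` must be three positive numbers (train:validation:test).")
  }
  n <- nrow(cases)
  if (n < 4L) {
    abort("At least 4 cases are required for a 3-way split.")
  }
  share <- n * ratio / sum(ratio)
  base <- floor(share)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  labels <- rep(c("train", "validation", "test"), times = base)
  cases$split <- with_seed(seed, sample(labels))
  cases
}

#' Restrict a case table to an early time window
#'
#' Keeps only cases with `time_min <= max_time` (boundary inclusive). With
#' the default 1000-minute cutoff this is the truncated-protocol dataset in
#' which slow and fast runs contribute comparable time spans; passing
#' `max_time = Inf` is the untruncated protocol.
#'
#' @param cases A case table with a `time_min` column.
#' @param max_time Cutoff in minutes (default 1000).
#'
#' @return The filtered case table.
#' @export
truncate_cases <- function(cases, max_time = 1000) {
  stopifnot(is.data.frame(cases), "time_min" %in% names(cases))
  if (!is.numeric(max_time) || length(max_time) != 1L || is.na(max_time) ||
      max_time < 0) {
    abort("`max_time` must be a single non-negative number (Inf allowed).")
  }
  dplyr::filter(cases, .data$time_min <= max_time)
}

# -- weight packing and the forward/backward pass --------------------------

mlp_dims <- function(n_in, n_hidden) {
  list(n_in = n_in, n_hidden = n_hidden,
       n_par = n_in * n_hidden + n_hidden + n_hidden + 1L)
}

unpack_theta <- function(theta, dims) {
  p <- dims$n_in; h <- dims$n_hidden
  i <- 0L
  W1 <- matrix(theta[seq_len(p * h)], p, h); i <- p * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- theta[i + seq_len(h)]; i <- i + h
  b2 <- theta[i + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(theta, X, dims, output_activation) {
  w <- unpack_theta(theta, dims)
  H <- sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  z2 <- drop(H %*% w$W2) + w$b2
  yhat <- if (output_activation == "logistic") sigmoid(z2) else z2
  list(yhat = yhat, H = H)
}

# mean squared error on scaled outputs and its exact gradient via backprop
mlp_loss_grad <- function(theta, X, y, dims, output_activation,
                          gradient = TRUE) {
  w <- unpack_theta(theta, dims)
  fw <- mlp_forward(theta, X, dims, output_activation)
  res <- fw$yhat - y
  f <- mean(res^2)
  if (!gradient) return(list(f = f))
  n <- length(y)
  dz2 <- 2 * res / n
  if (output_activation == "logistic") dz2 <- dz2 * fw$yhat * (1 - fw$yhat)
  gW2 <- drop(crossprod(fw$H, dz2))
  gb2 <- sum(dz2)
  dH <- outer(dz2, w$W2)
  dZ1 <- dH * fw$H * (1 - fw$H)
  gW1 <- crossprod(X, dZ1)
  gb1 <- colSums(dZ1)
  list(f = f, grad = c(as.vector(gW1), gb1, gW2, gb2))
}

# -- scaling ----------------------------------------------------------------

fit_scaling <- function(train_mat, train_y) {
  rng <- apply(train_mat, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  y_rng <- range(train_y)
  y_span <- diff(y_rng)
  if (y_span == 0) y_span <- 1
  list(x_min = rng[1, ], x_span = span, y_min = y_rng[1], y_span = y_span)
}

scale_inputs <- function(mat, scaling) {
  sweep(sweep(mat, 2, scaling$x_min, "-"), 2, scaling$x_span, "/")
}

scale_output <- function(y, scaling) (y - scaling$y_min) / scaling$y_span

descale_output <- function(y, scaling) y * scaling$y_span + scaling$y_min

# -- training ---------------------------------------------------------------

cases_matrix <- function(cases, inputs) {
  missing_cols <- setdiff(inputs, names(cases))
  if (length(missing_cols)) {
    abort(sprintf("Input columns missing from cases: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(cases[, inputs, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# optional monotone reparameterization of the time axis, applied to the raw
# input matrix before min-max scaling
apply_input_transforms <- function(mat, config) {
  if (isTRUE(config$log_time)) {
    j <- which(colnames(mat) == "time_min")
    if (length(j)) mat[, j] <- log10(1 + mat[, j])
  }
  mat
}

line_search <- function(f_only, theta, d, f0, slope0, alpha_prev) {
  # line minimization along d: bracket the minimum by doubling from the
  # previous accepted step, then refine with Brent's method
  phi <- function(a) f_only(theta + a * d)
  a <- alpha_prev
  fa <- phi(a)
  if (fa >= f0) {
    # shrink until some decrease is found (or give up)
    repeat {
      a <- a / 4
      if (a < 1e-12 * alpha_prev || a == 0) {
        return(list(alpha = 0, f = f0, ok = FALSE))
      }
      fa <- phi(a)
      if (fa < f0) break
    }
  }
  a_hi <- a
  f_hi <- fa
  for (k in seq_len(30)) { # expand while still descending
    a_try <- 2 * a_hi
    f_try <- phi(a_try)
    if (f_try >= f_hi) { a_hi <- a_try; break }
    a_hi <- a_try
    f_hi <- f_try
  }
  opt <- stats::optimize(phi, c(0, a_hi), tol = a_hi * 1e-3)
  if (opt$objective < f_hi) {
    list(alpha = opt$minimum, f = opt$objective, ok = TRUE)
  } else {
    list(alpha = a_hi / 2, f = f_hi, ok = TRUE)
  }
}

train_single_start <- function(Xtr, ytr, Xval, yval, dims, cfg, start_seed) {
  theta <- with_seed(start_seed, runif(dims$n_par, -0.5, 0.5))
  act <- cfg$output_activation
  f_grad <- function(th) mlp_loss_grad(th, Xtr, ytr, dims, act)
  f_only <- function(th) mlp_loss_grad(th, Xtr, ytr, dims, act, gradient = FALSE)$f
  val_rmse <- function(th) {
    sqrt(mean((mlp_forward(th, Xval, dims, act)$yhat - yval)^2))
  }

  log <- vector("list", 1L + cfg$n_epochs_phase1 + cfg$n_epochs_phase2)
  best <- list(theta = theta, val = val_rmse(theta), epoch = 0L)
  since_best <- 0L
  record <- function(epoch, phase, train_f, th) {
    v <- val_rmse(th)
    log[[epoch + 1L]] <<- tibble(epoch = epoch, phase = phase,
                                 train_rmse = sqrt(train_f), val_rmse = v)
    if (v < best$val) {
      best <<- list(theta = th, val = v, epoch = epoch)
      since_best <<- 0L
    } else {
      since_best <<- since_best + 1L
    }
  }
  record(0L, "init", f_only(theta), theta)

  # phase 1: back-propagation (full-batch gradient descent) with momentum
  velocity <- numeric(dims$n_par)
  for (e in seq_len(cfg$n_epochs_phase1)) {
    fg <- f_grad(theta)
    velocity <- cfg$momentum * velocity - cfg$learning_rate * fg$grad
    theta <- theta + velocity
    record(e, "backprop", mlp_loss_grad(theta, Xtr, ytr, dims, act,
                                        gradient = FALSE)$f, theta)
  }

  # phase 2: Polak-Ribiere conjugate gradient with validation early stopping
  fg <- f_grad(theta)
  g <- fg$grad
  d <- -g
  alpha_prev <- 1
  since_best <- 0L
  for (e in seq_len(cfg$n_epochs_phase2)) {
    slope0 <- sum(g * d)
    if (slope0 >= 0) { # not a descent direction: restart on the gradient
      d <- -g
      slope0 <- sum(g * d)
    }
    ls <- line_search(f_only, theta, d, fg$f, slope0, alpha_prev)
    if (!ls$ok) {
      d <- -g
      ls <- line_search(f_only, theta, d, fg$f, sum(g * d), alpha_prev)
      if (!ls$ok) break # no progress possible along the gradient
    }
    alpha_prev <- max(ls$alpha, 1e-8)
    theta <- theta + ls$alpha * d
    fg_new <- f_grad(theta)
    beta <- max(0, sum(fg_new$grad * (fg_new$grad - g)) / sum(g * g))
    d <- -fg_new$grad + beta * d
    g <- fg_new$grad
    fg <- fg_new
    record(cfg$n_epochs_phase1 + e, "conjugate_gradient", fg$f, theta)
    if (since_best >= cfg$patience) break
  }

  list(best = best, log = dplyr::bind_rows(log[!vapply(log, is.null, logical(1))]))
}

#' Train the progress-curve MLP
#'
#' Trains the multilayer perceptron on the training subset of a labeled case
#' table, monitoring the validation subset throughout and returning the
#' weights at the validation-error minimum. Training runs in two phases:
#' back-propagation (full-batch gradient descent with momentum) followed by
#' Polak-Ribiere conjugate-gradient minimization with early stopping. Several
#' seeded restarts are performed and the restart with the lowest validation
#' RMSE wins. All scaling (min-max to `[0, 1]`) is computed on the training
#' subset only.
#'
#' @param cases A case table; if it has no `split` column it is split
#'   2:1:1 with the config seed.
#' @param config An [mlp_config()].
#'
#' @return An object of class `mlp_regressor`.
#' @export
train_mlp <- function(cases, config = mlp_config()) {
  stopifnot(is.data.frame(cases), inherits(config, "mlp_config"))
  if (!"split" %in% names(cases)) cases <- split_cases(cases, seed = config$seed)
  if (!config$output %in% names(cases)) {
    abort(sprintf("Output column `%s` missing from cases.", config$output))
  }
  tr <- cases[cases$split == "train", , drop = FALSE]
  val <- cases[cases$split == "validation", , drop = FALSE]
  if (nrow(tr) == 0L || nrow(val) == 0L) {
    abort("Both training and validation subsets must be non-empty.")
  }
  Xtr_raw <- cases_matrix(tr, config$inputs)
  Xval_raw <- cases_matrix(val, config$inputs)
  ytr_raw <- tr[[config$output]]
  yval_raw <- val[[config$output]]
  if (any(!is.finite(Xtr_raw)) || any(!is.finite(ytr_raw))) {
    abort("Non-finite values in the training inputs/output.")
  }
  scaling <- fit_scaling(apply_input_transforms(Xtr_raw, config), ytr_raw)
  Xtr <- scale_inputs(apply_input_transforms(Xtr_raw, config), scaling)
  Xval <- scale_inputs(apply_input_transforms(Xval_raw, config), scaling)
  ytr <- scale_output(ytr_raw, scaling)
  yval <- scale_output(yval_raw, scaling)
  dims <- mlp_dims(length(config$inputs), config$n_hidden)

  starts <- lapply(seq_len(config$n_starts), function(s) {
    res <- train_single_start(Xtr, ytr, Xval, yval, dims, config,
                              start_seed = config$seed + 7919L * (s - 1L))
    if (!all(is.finite(res$best$theta))) {
      abort("Training diverged to non-finite weights; lower the learning rate.")
    }
    res$log$start <- s
    res
  })
  vals <- vapply(starts, function(s) s$best$val, double(1))
  winner <- which.min(vals)
  best <- starts[[winner]]$best

  structure(
    list(
      theta = best$theta, dims = dims, config = config, scaling = scaling,
      train_means = colMeans(Xtr_raw),
      train_ranges = apply(Xtr_raw, 2, range),
      best_val_error = best$val, best_epoch = best$epoch,
      winning_start = winner,
      training_log = dplyr::bind_rows(lapply(starts, function(s) s$log)),
      seed = config$seed
    ),
    class = "mlp_regressor"
  )
}

#' @export
print.mlp_regressor <- function(x, ...) {
  cat(sprintf(
    paste0("MLP %d-%d-1 progress-curve regressor (%s output)\n",
           "  inputs: %s\n",
           "  validation RMSE (scaled) %.4g at epoch %d (start %d of %d, seed %d)\n"),
    x$dims$n_in, x$dims$n_hidden, x$config$output_activation,
    paste(x$config$inputs, collapse = ", "),
    x$best_val_error, x$best_epoch, x$winning_start, x$config$n_starts, x$seed
  ))
  invisible(x)
}

#' Predict product concentrations from a trained MLP
#'
#' @param object A trained `mlp_regressor`.
#' @param new_data Data frame containing the model's input columns.
#' @param ... Unused.
#'
#' @return A tibble with `.pred` (mM) and `.extrapolated` (`TRUE` for rows
#'   with any input outside the training min-max range; a warning is also
#'   raised).
#' @export
predict.mlp_regressor <- function(object, new_data, ...) {
  X_raw <- cases_matrix(new_data, object$config$inputs)
  X <- scale_inputs(apply_input_transforms(X_raw, object$config),
                    object$scaling)
  out <- mlp_forward(object$theta, X, object$dims,
                     object$config$output_activation)$yhat
  lo <- object$train_ranges[1, ]
  hi <- object$train_ranges[2, ]
  extra <- rowSums(sweep(X_raw, 2, lo, "<") | sweep(X_raw, 2, hi, ">")) > 0
  if (any(extra)) {
    warn(sprintf("%d of %d predictions extrapolate beyond the training range.",
                 sum(extra), length(extra)))
  }
  tibble(.pred = descale_output(out, object$scaling), .extrapolated = extra)
}

#' Predict a single case
#'
#' Convenience scalar interface to [predict.mlp_regressor()].
#'
#' @param model A trained `mlp_regressor`.
#' @param C0 Initial substrate concentration (mM).
#' @param descriptor Electronic descriptor value.
#' @param time Reaction time (min).
#' @return Predicted product concentration (mM) with an `extrapolated`
#'   attribute.
#' @export
predict_product <- function(model, C0, descriptor, time) {
  nd <- tibble(C0_mM = C0, descriptor = descriptor, time_min = time)
  names(nd) <- model$config$inputs[seq_len(3)]
  p <- suppressWarnings(predict(model, nd))
  structure(p$.pred, extrapolated = p$.extrapolated)
}

#' Glance at a trained MLP
#'
#' Reports the R-squared between observed and predicted product
#' concentrations per split subset, plus the validation minimum.
#'
#' @param x A trained `mlp_regressor`.
#' @param cases The labeled case table to evaluate (typically the one used
#'   for training).
#' @param ... Unused.
#' @return A one-row tibble with `r2_train`, `r2_validation`, `r2_test`,
#'   `val_rmse_scaled`, `best_epoch`.
#' @method glance mlp_regressor
#' @export
glance.mlp_regressor <- function(x, cases, ...) {
  stopifnot(is.data.frame(cases), "split" %in% names(cases))
  r2s <- vapply(c("train", "validation", "test"), function(s) {
    sub <- cases[cases$split == s, , drop = FALSE]
    if (nrow(sub) < 2L) return(NA_real_)
    pred <- suppressWarnings(predict(x, sub)$.pred)
    r_squared(sub[[x$config$output]], pred)
  }, double(1))
  tibble(r2_train = r2s[[1]], r2_validation = r2s[[2]], r2_test = r2s[[3]],
         val_rmse_scaled = x$best_val_error, best_epoch = x$best_epoch)
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` between observed and predicted values.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return R-squared (can be negative for predictions worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  keep <- is.finite(observed) & is.finite(predicted)
  o <- observed[keep]; p <- predicted[keep]
  sst <- sum((o - mean(o))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((o - p)^2) / sst
}

#' Sensitivity analysis of a trained MLP
#'
#' For each input variable, predictions are recomputed with that variable
#' replaced by its training mean; the ratio of the resulting RMSE to the
#' baseline RMSE measures how much the network relies on the variable.
#' Ratios near 1 mark uninformative inputs; variables are ranked by ratio.
#'
#' @param model A trained `mlp_regressor`.
#' @param cases Evaluation case table (with the model's input and output
#'   columns).
#' @return A tibble with one row per input: `input`, `rmse`, `ratio`,
#'   `rank`, plus the baseline RMSE as an attribute.
#' @export
sensitivity_analysis <- function(model, cases) {
  stopifnot(inherits(model, "mlp_regressor"), is.data.frame(cases))
  y <- cases[[model$config$output]]
  base_pred <- suppressWarnings(predict(model, cases)$.pred)
  base_rmse <- sqrt(mean((y - base_pred)^2))
  rows <- purrr::map_dfr(seq_along(model$config$inputs), function(j) {
    nm <- model$config$inputs[j]
    mutated <- cases
    mutated[[nm]] <- model$train_means[[j]]
    pred <- suppressWarnings(predict(model, mutated)$.pred)
    tibble(input = nm, rmse = sqrt(mean((y - pred)^2)))
  })
  rows$ratio <- rows$rmse / base_rmse
  rows <- dplyr::arrange(rows, dplyr::desc(.data$ratio))
  rows$rank <- seq_len(nrow(rows))
  attr(rows, "baseline_rmse") <- base_rmse
  rows
}

#' Response curve of a trained MLP
#'
#' Predictions along a grid of one input variable with all other inputs held
#' at their training means: a two-dimensional projection of the fitted
#' response surface.
#'
#' @param model A trained `mlp_regressor`.
#' @param variable Name of the input to vary.
#' @param grid Numeric grid; defaults to 50 points across the training range
#'   of `variable`. Values beyond the training range are allowed but flagged.
#' @param n Grid size when `grid` is `NULL`.
#' @return A tibble with the grid values, `.pred`, and `.extrapolated`.
#' @export
response_curve <- function(model, variable, grid = NULL, n = 50L) {
  stopifnot(inherits(model, "mlp_regressor"))
  j <- match(variable, model$config$inputs)
  if (is.na(j)) {
    abort(sprintf("`variable` must be one of: %s.",
                  paste(model$config$inputs, collapse = ", ")))
  }
  if (is.null(grid)) {
    grid <- seq(model$train_ranges[1, j], model$train_ranges[2, j],
                length.out = n)
  }
  nd <- as.data.frame(matrix(rep(model$train_means, each = length(grid)),
                             nrow = length(grid)))
  names(nd) <- model$config$inputs
  nd[[variable]] <- grid
  p <- suppressWarnings(predict(model, nd))
  out <- tibble(!!variable := grid, .pred = p$.pred,
                .extrapolated = p$.extrapolated)
  class(out) <- c("mlp_response", class(out))
  attr(out, "variable") <- variable
  out
}

#' @method autoplot mlp_response
#' @export
autoplot.mlp_response <- function(object, ...) {
  v <- attr(object, "variable")
  ggplot2::ggplot(object, ggplot2::aes(.data[[v]], .data$.pred)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = v, y = "predicted product (mM)")
}

#' External validation on a held-out substrate
#'
#' Excludes every case of one substrate, trains the model on the remaining
#' substrates (fresh 2:1:1 split with the config seed), and scores the
#' held-out runs individually: R-squared between observed and predicted
#' product concentrations per run.
#'
#' @param cases A case table with `substrate_id` and `run_id` columns.
#' @param holdout_substrate_id Substrate to exclude and score.
#' @param config An [mlp_config()].
#' @return A list with `model` (trained on the remaining substrates) and
#'   `runs`, a tibble with one row per held-out run: `run_id`, `n_cases`,
#'   `r_squared`, `extrapolated` (whether any case left the training range).
#' @export
external_validation <- function(cases, holdout_substrate_id,
                                config = mlp_config()) {
  stopifnot(is.data.frame(cases),
            all(c("substrate_id", "run_id") %in% names(cases)))
  held <- cases[cases$substrate_id == holdout_substrate_id, , drop = FALSE]
  if (nrow(held) == 0L) {
    abort(sprintf("Unknown substrate id '%s'.", holdout_substrate_id))
  }
  rest <- cases[cases$substrate_id != holdout_substrate_id, , drop = FALSE]
  rest$split <- NULL
  rest <- split_cases(rest, seed = config$seed)
  model <- train_mlp(rest, config)
  runs <- purrr::map_dfr(split(held, held$run_id), function(run) {
    p <- suppressWarnings(predict(model, run))
    tibble(run_id = run$run_id[1], n_cases = nrow(run),
           r_squared = r_squared(run[[config$output]], p$.pred),
           extrapolated = any(p$.extrapolated))
  })
  list(model = model, runs = runs)
}
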