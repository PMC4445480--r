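# Plain-text I/O: progress-curve CSVs, descriptor tables, case tables, and
# a structured-text (YAML) artifact for trained networks.

#' Read a progress curve from CSV
#'
#' Expects columns `time_min` and `substrate_mM` (and optionally
#' `product_mM`; when absent or partially missing, product is filled in by
#' mass conservation against `a0`, which defaults to the first substrate
#' observation).
#'
#' @param path CSV file path.
#' @param a0 Nominal initial concentration (mM) used for conservation when
#'   the product column is missing.
#' @param substrate_id Optional label stored with the curve.
#' @return A `progress_curve` tibble.
#' @export
read_progress_curve <- function(path, a0 = NULL, substrate_id = NA_character_) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_min", "substrate_mM") %in% names(d))) {
    abort("Progress-curve CSV needs columns `time_min` and `substrate_mM`.")
  }
  if (is.null(a0)) a0 <- d$substrate_mM[1]
  if (!"product_mM" %in% names(d)) d$product_mM <- NA_real_
  fill <- is.na(d$product_mM)
  d$product_mM[fill] <- pmax(a0 - d$substrate_mM[fill], 0)
  ord <- order(d$time_min)
  new_progress_curve(d$time_min[ord], d$substrate_mM[ord], d$product_mM[ord],
                     substrate_id = substrate_id, a0 = a0)
}

#' Write a progress curve to CSV
#'
#' @param curve A progress-curve data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_progress_curve <- function(curve, path) {
  readr::write_csv(as_tibble(curve)[, c("time_min", "substrate_mM", "product_mM")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read or write a substrate descriptor table
#'
#' The CSV has columns `substrate_id`, `name`, `sigma_p`,
#' `ddg_alkoxy_kj_mol`, `log_k_calc`, `log_p`, `mr`; every column except
#' `substrate_id` may contain missing values.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_descriptor_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"substrate_id" %in% names(d)) {
    abort("Descriptor CSV needs a `substrate_id` column.")
  }
  if (anyNA(d$substrate_id)) abort("`substrate_id` must not be missing.")
  d
}

#' @param table A descriptor tibble.
#' @rdname read_descriptor_table
#' @export
write_descriptor_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Read or write an MLP case table
#'
#' Columns: `substrate_id`, `run_id`, `C0_mM`, `descriptor`, `time_min`,
#' `product_mM`, and optionally `split`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_case_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("substrate_id", "C0_mM", "descriptor", "time_min", "product_mM")
  if (!all(need %in% names(d))) {
    abort(sprintf("Case-table CSV needs columns %s.",
                  paste0("`", need, "`", collapse = ", ")))
  }
  d
}

#' @param table A case tibble.
#' @rdname read_case_table
#' @export
write_case_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Save or load a trained MLP as structured text
#'
#' The artifact is a YAML file holding the layer sizes, weights, scaling
#' parameters, seed, and training log, so that a trained network is fully
#' portable and reproducible without binary files.
#'
#' @param model A trained `mlp_regressor`.
#' @param path Output path (`.yml`).
#' @return `path` invisibly (`write_mlp`); the restored `mlp_regressor`
#'   (`read_mlp`).
#' @export
write_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp_regressor"))
  obj <- list(
    layer_sizes = c(model$dims$n_in, model$dims$n_hidden, 1L),
    inputs = model$config$inputs,
    output = model$config$output,
    output_activation = model$config$output_activation,
    log_time = model$config$log_time,
    theta = model$theta,
    scaling = lapply(model$scaling, as.numeric),
    train_means = as.numeric(model$train_means),
    train_ranges = list(min = as.numeric(model$train_ranges[1, ]),
                        max = as.numeric(model$train_ranges[2, ])),
    best_val_error = model$best_val_error,
    best_epoch = model$best_epoch,
    seed = model$seed,
    training_log = lapply(
      seq_len(nrow(model$training_log)),
      function(i) as.list(model$training_log[i, ])
    )
  )
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- yaml::read_yaml(path)
  dims <- mlp_dims(obj$layer_sizes[1], obj$layer_sizes[2])
  cfg <- mlp_config(n_hidden = obj$layer_sizes[2], inputs = obj$inputs,
                    output = obj$output,
                    output_activation = obj$output_activation,
                    log_time = isTRUE(obj$log_time),
                    seed = obj$seed)
  scaling <- obj$scaling
  scaling$x_min <- setNames(as.numeric(scaling$x_min), obj$inputs)
  scaling$x_span <- setNames(as.numeric(scaling$x_span), obj$inputs)
  ranges <- rbind(as.numeric(obj$train_ranges$min),
                  as.numeric(obj$train_ranges$max))
  colnames(ranges) <- obj$inputs
  structure(
    list(theta = as.numeric(obj$theta), dims = dims, config = cfg,
         scaling = scaling,
         train_means = setNames(as.numeric(obj$train_means), obj$inputs),
         train_ranges = ranges,
         best_val_error = obj$best_val_error, best_epoch = obj$best_epoch,
         winning_start = NA_integer_,
         training_log = dplyr::bind_rows(lapply(obj$training_log, as_tibble)),
         seed = obj$seed),
    class = "mlp_regressor"
  )
}
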