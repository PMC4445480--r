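# End-to-end orchestration: generate (or ingest) reactor runs, fit every
# progress curve, calibrate the descriptor relationships, train the
# progress-curve MLP, and collect validation, sensitivity and response
# tables into one seeded, hashable report bundle.

pipeline_fields <- c("seed", "out_dir", "generator", "fit", "training",
                     "max_time", "holdout", "verbose")

#' Pipeline configuration
#'
#' All stage parameters and the single global seed in one validated object.
#' The stage seeds (generator, split, training) all derive from `seed`, so a
#' pipeline run is reproducible from this object alone.
#'
#' @param seed Global integer seed.
#' @param out_dir Optional directory; when given, every report table is
#'   written there as CSV alongside a YAML run summary and model artifact.
#' @param generator A [generator_config()].
#' @param fit Options for the curve fits: a list with `species`
#'   (`"substrate"`/`"product"`) and `keq_from` (`"fit"`/`"last"`).
#' @param training An [mlp_config()].
#' @param max_time Optional case-table time cutoff in minutes (the
#'   truncated protocol; e.g. 1000); `NULL` trains on the full time span.
#' @param holdout Optional substrate id for external validation.
#' @param verbose Print stage progress.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            generator = generator_config(seed = seed),
                            fit = list(species = "substrate", keq_from = "fit"),
                            training = mlp_config(seed = seed),
                            max_time = NULL, holdout = NULL,
                            verbose = FALSE) {
  check_number(seed, "seed")
  if (!is.null(max_time)) check_number(max_time, "max_time", lower = 0)
  stopifnot(inherits(generator, "generator_config"),
            inherits(training, "mlp_config"),
            is.list(fit))
  bad <- setdiff(names(fit), c("species", "keq_from"))
  if (length(bad)) {
    abort(sprintf("Unknown fit option(s): %s.", paste(bad, collapse = ", ")))
  }
  fit <- modifyList(list(species = "substrate", keq_from = "fit"), fit)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, generator = generator,
         fit = fit, training = training, max_time = max_time,
         holdout = holdout, verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

#' Serialize or parse a pipeline configuration
#'
#' Round-trip safe YAML representation: `parse_pipeline_config()` rejects
#' unknown keys and restores the classed sub-configurations.
#'
#' @param config A [pipeline_config()].
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @return YAML text (serialize) or a `pipeline_config` (parse).
#' @export
serialize_pipeline_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  obj$generator <- unclass(obj$generator)
  obj$training <- unclass(obj$training)
  txt <- yaml::as.yaml(obj, precision = 17L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(path))
  }
  txt
}

#' @param text YAML text (or use `path`).
#' @rdname serialize_pipeline_config
#' @export
parse_pipeline_config <- function(text = NULL, path = NULL) {
  obj <- if (!is.null(path)) yaml::read_yaml(path) else yaml::yaml.load(text)
  bad <- setdiff(names(obj), pipeline_fields)
  if (length(bad)) {
    abort(sprintf("Unknown pipeline config key(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  gen <- do.call(generator_config, obj$generator %||% list())
  trn <- do.call(mlp_config, obj$training %||% list())
  pipeline_config(
    seed = obj$seed %||% 1L, out_dir = obj$out_dir, generator = gen,
    fit = obj$fit %||% list(), training = trn, max_time = obj$max_time,
    holdout = obj$holdout, verbose = obj$verbose %||% FALSE
  )
}

#' Run the full synthetic-study pipeline
#'
#' Generates a substrate panel and reactor series, fits every run's progress
#' curve, calibrates the descriptor relationships (sigma_p vs ddG_alkoxy,
#' ddG_alkoxy vs log K, and fitted log K_ex vs planted log K on the runs
#' that reached equilibrium), assembles the case table, trains the MLP
#' (truncating the time span first when `max_time` is set), and computes
#' per-split validation metrics, a sensitivity table, response curves, and
#' (when `holdout` is set) external validation. Every output is stamped
#' with the seed and a hash of the configuration.
#'
#' @param config A [pipeline_config()].
#'
#' @return A list of class `pipeline_result` with elements `fit_report`,
#'   `calibrations`, `model`, `validation`, `sensitivity`, `response`,
#'   `external`, `panel`, `cases`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  say("generating panel and reactor series (seed %d)", config$seed)
  gen <- config$generator
  gen$seed <- config$seed
  panel <- stage("generate", generate_panel(gen))
  series <- stage("generate", generate_reactor_series(panel, gen))

  say("fitting %d progress curves", length(series$curves))
  fit_report <- stage("fit", purrr::map2_dfr(
    series$curves, names(series$curves),
    function(cv, id) {
      f <- fit_mono_exponential(cv, species = config$fit$species,
                                keq_from = config$fit$keq_from)
      row <- if (f$converged) {
        dplyr::bind_cols(report_row(f),
                         tibble(r_squared = f$r_squared,
                                equilibrium_reached = f$equilibrium_reached))
      } else {
        tibble(C0 = NA_real_, C_inf = NA_real_, t95_h = NA_real_,
               conversion_pct = NA_real_, log_K = NA_real_,
               r_squared = NA_real_, equilibrium_reached = FALSE)
      }
      dplyr::bind_cols(
        tibble(run_id = id, substrate_id = attr(cv, "substrate_id"),
               regime = attr(cv, "regime"), converged = f$converged),
        row
      )
    }
  ))

  say("calibrating descriptor relationships")
  calibrations <- stage("calibrate", {
    eq <- dplyr::filter(fit_report,
                        .data$converged & .data$equilibrium_reached)
    eq <- dplyr::left_join(eq, panel[, c("substrate_id", "log_k_calc")],
                           by = "substrate_id")
    cals <- list(
      sigma_vs_ddg = fit_linear_calibration(
        panel$sigma_p, panel$ddg_alkoxy_kj_mol, "sigma_p", "ddg_alkoxy_kj_mol"),
      ddg_vs_logk = fit_linear_calibration(
        panel$ddg_alkoxy_kj_mol, panel$log_k_calc, "ddg_alkoxy_kj_mol",
        "log_k_calc"),
      logk_fit_vs_calc = if (nrow(eq) >= 3 && sd(eq$log_k_calc) > 0) {
        fit_linear_calibration(eq$log_k_calc, eq$log_K, "log_k_calc",
                               "log_K_ex")
      }
    )
    purrr::map_dfr(Filter(Negate(is.null), cals), glance)
  })

  say("assembling case table and training the MLP")
  cases <- stage("train", {
    ct <- generate_case_table(panel, series)
    if (!is.null(config$max_time)) ct <- truncate_cases(ct, config$max_time)
    split_cases(ct, seed = config$seed)
  })
  trn <- config$training
  trn$seed <- config$seed
  model <- stage("train", train_mlp(cases, trn))
  validation <- stage("validate", glance(model, cases))

  say("sensitivity and response analyses")
  sensitivity <- stage("sense", sensitivity_analysis(model, cases))
  response <- stage("response", dplyr::bind_rows(lapply(
    trn$inputs,
    function(v) {
      rc <- response_curve(model, v)
      tibble(variable = v, value = rc[[v]], .pred = rc$.pred)
    }
  )))

  external <- NULL
  if (!is.null(config$holdout)) {
    say("external validation holding out %s", config$holdout)
    external <- stage("validate",
                      external_validation(cases, config$holdout, trn)$runs)
  }

  result <- structure(
    list(fit_report = fit_report, calibrations = calibrations, model = model,
         validation = validation, sensitivity = sensitivity,
         response = response, external = external, panel = panel,
         cases = cases, seed = config$seed,
         config_hash = rlang::hash(serialize_pipeline_config(config))),
    class = "pipeline_result"
  )

  if (!is.null(config$out_dir)) write_pipeline_result(result, config)
  result
}

write_pipeline_result <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  readr::write_csv(result$fit_report, out("fit_report.csv"), progress = FALSE)
  readr::write_csv(result$calibrations, out("calibrations.csv"), progress = FALSE)
  readr::write_csv(result$validation, out("validation.csv"), progress = FALSE)
  readr::write_csv(result$sensitivity, out("sensitivity.csv"), progress = FALSE)
  readr::write_csv(result$response, out("response.csv"), progress = FALSE)
  if (!is.null(result$external)) {
    readr::write_csv(result$external, out("external_validation.csv"),
                     progress = FALSE)
  }
  write_descriptor_table(result$panel, out("panel.csv"))
  write_case_table(result$cases, out("cases.csv"))
  write_mlp(result$model, out("model.yml"))
  yaml::write_yaml(list(seed = result$seed, config_hash = result$config_hash,
                        config = yaml::yaml.load(
                          serialize_pipeline_config(config))),
                   out("run_summary.yml"))
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    paste0("Pipeline result (seed %d, config %s)\n",
           "  %d runs fitted (%d reached equilibrium), %d cases, ",
           "MLP test R^2 = %.3f\n"),
    x$seed, x$config_hash, nrow(x$fit_report),
    sum(x$fit_report$equilibrium_reached, na.rm = TRUE), nrow(x$cases),
    x$validation$r2_test
  ))
  invisible(x)
}
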