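# Substrate electronic descriptors and linear free-energy calibrations.
#
# Para-substituted acetophenones differ in the electron density at the
# carbonyl carbon; that effect is captured interchangeably by the Hammett
# sigma_p constant, by the computed free-energy change of alkoxide formation
# relative to acetophenone (ddG_alkoxy, kJ/mol; negative = more stabilized
# anion = electron-withdrawing substituent), and by the theoretical log K of
# the reduction. These descriptors are strongly collinear; the calibrations
# here quantify that collinearity and let one descriptor stand in for another.

#' Fit an ordinary least-squares calibration line
#'
#' Fits `y = slope * x + intercept` by ordinary least squares and reports the
#' Pearson correlation and its square, the standard linear free-energy
#' calibration between two substituent descriptors.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` must not be
#'   constant.
#' @param x_name,y_name Labels stored with the calibration.
#'
#' @return A `linear_calibration` object with fields `slope`, `intercept`,
#'   `r_squared`, `pearson_r`, `n`, `x_name`, `y_name`.
#' @examples
#' fit_linear_calibration(c(-0.37, 0, 0.23, 0.78), c(9, 0, -6, -20))
#' @export
fit_linear_calibration <- function(x, y, x_name = "x", y_name = "y") {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort("`x` and `y` must be numeric vectors of equal length.")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("At least 3 complete (x, y) pairs are required.")
  if (sd(x) == 0) abort("`x` is constant; the calibration slope is undefined.")
  fit <- lm(y ~ x)
  r <- if (sd(y) == 0) 0 else stats::cor(x, y)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r^2, pearson_r = r, n = length(x),
         x_name = x_name, y_name = y_name),
    class = "linear_calibration"
  )
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration %s -> %s (n = %d)\n  %s = %.4g * %s + %.4g,  R^2 = %.3f\n",
              x$x_name, x$y_name, x$n, x$y_name, x$slope, x$x_name,
              x$intercept, x$r_squared))
  invisible(x)
}

#' @param x A `linear_calibration` object.
#' @param ... Unused.
#' @rdname fit_linear_calibration
#' @return For `tidy()`: a two-row tibble of intercept and slope.
#' @method tidy linear_calibration
#' @export
tidy.linear_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}

#' @rdname fit_linear_calibration
#' @return For `glance()`: a one-row tibble with fit statistics.
#' @method glance linear_calibration
#' @export
glance.linear_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         pearson_r = x$pearson_r, n = x$n, x_name = x$x_name, y_name = x$y_name)
}

#' Predict from a linear calibration
#'
#' @param cal A `linear_calibration` from [fit_linear_calibration()].
#' @param x Numeric vector of descriptor values.
#' @return `slope * x + intercept`.
#' @export
predict_from_calibration <- function(cal, x) {
  stopifnot(inherits(cal, "linear_calibration"))
  cal$slope * x + cal$intercept
}

#' Look up a para-substituent Hammett constant
#'
#' Returns the tabulated sigma_p value for a para substituent. Values are the
#' standard compilation of Hansch, Leo and Taft (Chem. Rev. 1991, 91,
#' 165-195), shipped with the package as a data file; they are inputs to the
#' analysis, not results of it.
#'
#' @param substituent Substituent label, e.g. `"H"`, `"p-OH"`, `"p-NO2"`.
#' @return The sigma_p constant (dimensionless).
#' @examples
#' hammett_lookup("p-OH")  # -0.37
#' hammett_lookup("p-NO2") # +0.78
#' @export
hammett_lookup <- function(substituent) {
  tab <- hammett_table()
  i <- match(substituent, tab$substituent)
  if (is.na(i)) {
    abort(sprintf("Unknown substituent '%s'. Known labels: %s.",
                  substituent, paste(tab$substituent, collapse = ", ")))
  }
  tab$sigma_p[i]
}

#' @rdname hammett_lookup
#' @return For `hammett_table()`: the full tibble of tabulated constants.
#' @export
hammett_table <- function() {
  path <- system.file("extdata", "hammett_sigma_p.csv", package = "ketokin",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Backward descriptor elimination by validation error
#'
#' Greedy backward elimination over candidate descriptor columns of a case
#' table: at each round a small network is trained with the current
#' candidate set (alongside the always-present inputs, by default initial
#' concentration and time) and once per single-descriptor removal; the
#' removal that lowers the validation error the most (or raises it least) is
#' accepted if it stays within a parsimony margin of the current set's error,
#' and the procedure stops otherwise. The margin matters: a network simply
#' learns to ignore an uninformative input, so its removal changes the
#' validation error only within restart noise, while removing a genuinely
#' informative descriptor degrades the error several-fold. Each round trains
#' the baseline and all removals with the same seed, so comparisons are
#' paired.
#'
#' @param cases A case table (see [generate_case_table()]) containing a
#'   `split` column or enough rows to be split internally.
#' @param candidates Character vector (>= 1) of descriptor column names in
#'   `cases` to select among.
#' @param config Training configuration from [mlp_config()]; kept small by
#'   default since each round trains several networks.
#' @param base_inputs Columns always included as network inputs.
#' @param seed Integer seed controlling the split and the per-round training.
#' @param tol Relative parsimony margin: the best removal is accepted when
#'   its validation error is at most `(1 + tol)` times the current set's.
#'   Removing an informative descriptor typically degrades the validation
#'   error several-fold, removing an ignored one only within restart noise,
#'   so the default margin of 0.5 separates the two regimes.
#'
#' @return A list with `retained` (character vector) and `trace` (tibble of
#'   the elimination path: round, candidate set, validation error).
#' @export
select_descriptors <- function(cases, candidates,
                               config = mlp_config(n_epochs_phase2 = 80,
                                                   n_starts = 2),
                               base_inputs = c("C0_mM", "time_min"),
                               seed = 1L, tol = 0.5) {
  stopifnot(is.data.frame(cases))
  if (length(candidates) < 1L) abort("At least one candidate descriptor is required.")
  missing_cols <- setdiff(c(base_inputs, candidates), names(cases))
  if (length(missing_cols)) {
    abort(sprintf("Columns missing from `cases`: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (length(unique(cases$substrate_id)) < 2L) {
    abort("Descriptor selection needs cases from at least two substrates.")
  }
  if (length(candidates) == 1L) {
    return(list(retained = candidates,
                trace = tibble(round = integer(), dropped = character(),
                               val_error = double())))
  }
  if (!"split" %in% names(cases)) cases <- split_cases(cases, seed = seed)

  val_error_for <- function(cand_set, round_seed) {
    cfg <- config
    cfg$inputs <- c(base_inputs, cand_set)
    cfg$seed <- round_seed
    model <- train_mlp(cases, cfg)
    model$best_val_error
  }

  current <- candidates
  trace <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    if (length(current) == 1L) break
    # baseline and every single-removal trained with the same round seed, so
    # the comparison is paired and not dominated by restart variability
    round_seed <- seed + round
    base_err <- val_error_for(current, round_seed)
    errs <- vapply(seq_along(current), function(i) {
      val_error_for(current[-i], round_seed)
    }, double(1))
    best <- which.min(errs)
    trace[[round]] <- tibble(round = round, dropped = current[best],
                             val_error = errs[best], baseline = base_err,
                             accepted = errs[best] <= base_err * (1 + tol))
    if (errs[best] <= base_err * (1 + tol)) {
      current <- current[-best]
    } else {
      break
    }
  }
  list(retained = current,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble(round = integer(), dropped = character(), val_error = double()))
}
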