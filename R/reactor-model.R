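# Forward simulation of batch-reactor progress curves.
#
# Two parameterizations are supported:
#  * the mono-exponential pseudo-first-order approximation used to fit
#    experimental curves:  [A](t) = [A]_eq + ([A]_0 - [A]_eq) exp(-k_obs t)
#  * the mass-action scheme  ketone + IPA <=> alcohol + acetone  with the
#    cosubstrate folded into the pseudo-first-order forward rate and acetone
#    tracked stoichiometrically with the product, so that the equilibrium
#    constant is K = [alcohol]^2 / [ketone] (units of mM).

#' Mono-exponential kinetic parameters
#'
#' Bundles the three parameters of the pseudo-first-order reversible
#' progress-curve model: the initial substrate concentration `a0`, the
#' equilibrium substrate concentration `aeq`, and the observed relaxation
#' rate `k_obs` (the sum of the forward and reverse first-order rate
#' constants).
#'
#' @param a0 Initial substrate concentration (mM), > 0.
#' @param aeq Equilibrium substrate concentration (mM), in `[0, a0]`.
#' @param k_obs Observed rate constant (1/min), > 0.
#'
#' @return An object of class `mono_exp_params`.
#' @examples
#' mono_exp_params(a0 = 286, aeq = 134, k_obs = 0.005)
#' @export
mono_exp_params <- function(a0, aeq, k_obs) {
  check_number(a0, "a0", lower = 0, allow_lower = FALSE)
  check_number(aeq, "aeq", lower = 0, upper = a0)
  check_number(k_obs, "k_obs", lower = 0, allow_lower = FALSE)
  structure(
    list(a0 = as.double(a0), aeq = as.double(aeq), k_obs = as.double(k_obs)),
    class = "mono_exp_params"
  )
}

#' @export
print.mono_exp_params <- function(x, ...) {
  cat(sprintf(
    "Mono-exponential parameters: A0 = %.4g mM, Aeq = %.4g mM, k_obs = %.4g /min\n",
    x$a0, x$aeq, x$k_obs
  ))
  invisible(x)
}

#' Mass-action rate constants
#'
#' Rate constants of the reversible reduction written in mass-action form:
#' a pseudo-first-order forward rate `k_f` (isopropanol in vast excess is
#' folded in) and an effective second-order reverse rate `k_r` acting on the
#' product squared (acetone accumulates stoichiometrically with the alcohol).
#' The implied equilibrium constant `K = k_f / k_r` carries units of mM.
#'
#' @param k_f Forward rate constant (1/min), > 0.
#' @param k_r Reverse rate constant (1/(mM min)), > 0.
#'
#' @return An object of class `rate_constants` with an `equilibrium_K` field
#'   (mM).
#' @examples
#' rate_constants(k_f = 0.01, k_r = 1e-4)
#' @export
rate_constants <- function(k_f, k_r) {
  check_number(k_f, "k_f", lower = 0, allow_lower = FALSE)
  check_number(k_r, "k_r", lower = 0, allow_lower = FALSE)
  structure(
    list(k_f = as.double(k_f), k_r = as.double(k_r),
         equilibrium_K = as.double(k_f / k_r)),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf(
    "Mass-action rates: k_f = %.4g /min, k_r = %.4g /(mM min), K = %.4g mM\n",
    x$k_f, x$k_r, x$equilibrium_K
  ))
  invisible(x)
}

new_progress_curve <- function(times, substrate, product, substrate_id = NA_character_,
                               a0 = NA_real_, regime = NA_character_) {
  out <- tibble(
    time_min = as.double(times),
    substrate_mM = as.double(substrate),
    product_mM = as.double(product)
  )
  attr(out, "substrate_id") <- substrate_id
  attr(out, "a0") <- a0
  attr(out, "regime") <- regime
  class(out) <- c("progress_curve", class(out))
  out
}

#' Simulate a mono-exponential progress curve
#'
#' Evaluates the pseudo-first-order reversible model
#' `substrate(t) = aeq + (a0 - aeq) exp(-k_obs t)` at the requested times;
#' the product is obtained by mass conservation, `product = a0 - substrate`.
#'
#' @param params A [mono_exp_params()] object.
#' @param times Sample times in minutes; non-negative, strictly increasing.
#' @param substrate_id Optional substrate label stored with the curve.
#'
#' @return A `progress_curve` tibble with columns `time_min`, `substrate_mM`,
#'   `product_mM`.
#' @examples
#' simulate_mono_exponential(mono_exp_params(286, 134, 0.005), c(0, 60, 600))
#' @export
simulate_mono_exponential <- function(params, times, substrate_id = NA_character_) {
  stopifnot(inherits(params, "mono_exp_params"))
  times <- check_times(times)
  substrate <- params$aeq + (params$a0 - params$aeq) * exp(-params$k_obs * times)
  new_progress_curve(times, substrate, params$a0 - substrate,
                     substrate_id = substrate_id, a0 = params$a0)
}

#' Equilibrium product concentration under the squared-product constant
#'
#' Solves `P^2 = K (A0 - P)` for the unique non-negative root,
#' `P_eq = (-K + sqrt(K^2 + 4 K A0)) / 2`. This is the product concentration
#' at which the reversible reduction with stoichiometric acetone accumulation
#' stalls.
#'
#' @param a0 Initial substrate concentration (mM), > 0.
#' @param K Equilibrium constant (mM), >= 0.
#'
#' @return Equilibrium product concentration (mM), in `[0, a0)`.
#' @examples
#' equilibrium_product(286, 172.42) # ~152 mM
#' @export
equilibrium_product <- function(a0, K) {
  check_number(a0, "a0", lower = 0, allow_lower = FALSE)
  check_number(K, "K", lower = 0)
  if (K == 0) return(0)
  # form chosen to avoid cancellation for small K
  2 * K * a0 / (K + sqrt(K^2 + 4 * K * a0))
}

#' Simulate a mass-action progress curve
#'
#' Integrates `dP/dt = k_f (a0 - P) - k_r P^2`, `P(0) = 0`, in closed form.
#' The rate law factors through the two real roots of
#' `k_r P^2 + k_f P - k_f a0 = 0`; with `P1 > 0 > P2` and relaxation rate
#' `r = k_r (P1 - P2) = sqrt(k_f^2 + 4 k_f k_r a0)` the solution is the
#' logistic-type curve `P(t) = P1 (1 - e^{-rt}) / (1 - (P1/P2) e^{-rt})`.
#' Substrate follows by conservation. An optional first-order acetone loss
#' (evaporation during long runs) switches to numerical integration of the
#' extended scheme.
#'
#' @param a0 Initial substrate concentration (mM), > 0.
#' @param rc A [rate_constants()] object.
#' @param times Sample times in minutes; non-negative, strictly increasing.
#' @param substrate_id Optional substrate label stored with the curve.
#' @param acetone_loss First-order acetone loss rate (1/min), default 0 (off).
#'   When positive, acetone is tracked as a separate state and the system is
#'   integrated numerically.
#'
#' @return A `progress_curve` tibble.
#' @examples
#' simulate_mass_action(100, rate_constants(0.01, 1e-4), c(0, 100, 5000))
#' @export
simulate_mass_action <- function(a0, rc, times, substrate_id = NA_character_,
                                 acetone_loss = 0) {
  check_number(a0, "a0", lower = 0, allow_lower = FALSE)
  stopifnot(inherits(rc, "rate_constants"))
  times <- check_times(times)
  check_number(acetone_loss, "acetone_loss", lower = 0)

  if (acetone_loss > 0) {
    product <- integrate_with_acetone_loss(a0, rc, times, acetone_loss)
  } else {
    disc <- sqrt(rc$k_f^2 + 4 * rc$k_f * rc$k_r * a0)
    p1 <- (-rc$k_f + disc) / (2 * rc$k_r) # equilibrium root (> 0)
    p2 <- (-rc$k_f - disc) / (2 * rc$k_r) # negative root
    e <- exp(-disc * times)
    product <- p1 * (1 - e) / (1 - (p1 / p2) * e)
  }
  product <- pmin(pmax(product, 0), a0)
  new_progress_curve(times, a0 - product, product,
                     substrate_id = substrate_id, a0 = a0)
}

# RK4 with fixed fine steps; only used for the optional acetone-loss variant,
# where acetone no longer mirrors product and no closed form exists.
integrate_with_acetone_loss <- function(a0, rc, times, loss) {
  deriv <- function(state) {
    p <- state[1]; ac <- state[2]
    dp <- rc$k_f * (a0 - p) - rc$k_r * p * ac
    c(dp, dp - loss * ac)
  }
  r <- sqrt(rc$k_f^2 + 4 * rc$k_f * rc$k_r * a0)
  h_max <- 0.01 / max(r, loss)
  state <- c(0, 0)
  out <- numeric(length(times))
  t_now <- 0
  for (i in seq_along(times)) {
    span <- times[i] - t_now
    if (span > 0) {
      n_step <- max(1L, ceiling(span / h_max))
      h <- span / n_step
      for (s in seq_len(n_step)) {
        k1 <- deriv(state)
        k2 <- deriv(state + h / 2 * k1)
        k3 <- deriv(state + h / 2 * k2)
        k4 <- deriv(state + h * k3)
        state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t_now <- times[i]
    }
    out[i] <- state[1]
  }
  out
}

#' Time to reach a fraction of the final product concentration
#'
#' Under the mono-exponential model the product approaches its plateau as
#' `1 - exp(-k_obs t)`, so the time at which a fraction `f` of the final
#' product has formed is `-log(1 - f) / k_obs`. With `fraction = 0.95` this
#' is the t95 reaction time reported for each batch run.
#'
#' @param params A [mono_exp_params()] object.
#' @param fraction Fraction of the final product concentration, in (0, 1).
#'
#' @return Time in minutes.
#' @examples
#' time_to_fraction(mono_exp_params(286, 134, 0.01), 0.95) # ln(20)/0.01
#' @export
time_to_fraction <- function(params, fraction) {
  stopifnot(inherits(params, "mono_exp_params"))
  check_number(fraction, "fraction", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  -log1p(-fraction) / params$k_obs
}

#' @export
print.progress_curve <- function(x, ...) {
  id <- attr(x, "substrate_id")
  if (!is.na(id %||% NA_character_)) {
    cat(sprintf("Progress curve for %s (%d samples)\n", id, nrow(x)))
  }
  NextMethod()
}

#' Plot a progress curve
#'
#' @param object A `progress_curve` tibble.
#' @param ... Unused.
#' @return A ggplot showing substrate and product concentration against time.
#' @method autoplot progress_curve
#' @export
autoplot.progress_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("substrate_mM", "product_mM"),
                              names_to = "species", values_to = "conc_mM")
  long$species <- sub("_mM$", "", long$species)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$conc_mM,
                                     colour = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (min)", y = "concentration (mM)", colour = NULL)
}
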