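---
title: "Modelling whole-cell ketone reduction: reactor kinetics, free-energy descriptors, and a progress-curve network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-cell ketone reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ketokin)
library(dplyr)
```

## The system being modelled

A whole-cell biocatalyst (resting *E. coli* cells overproducing an
(S)-selective alcohol dehydrogenase) reduces para-substituted acetophenones
to chiral 1-arylethanols. The NADH consumed by the reduction is regenerated
in situ by oxidation of isopropanol (IPA) to acetone with the same enzyme.
Because IPA is present in vast excess (~10 M) while acetone accumulates
stoichiometrically with the alcohol, the overall reaction behaves as

$$\mathrm{ketone} + \mathrm{IPA} \rightleftharpoons \mathrm{alcohol} + \mathrm{acetone},$$

and batch reactors run until conversion stalls at a substrate-specific
equilibrium. `ketokin` packages the computational side of such a study:

1. forward simulation of reactor progress curves,
2. progress-curve fitting and equilibrium-constant estimation,
3. linear free-energy calibrations among electronic substituent descriptors,
4. a small multilayer-perceptron (MLP) regressor that predicts product
   concentration from initial loading, one electronic descriptor, and time,
5. a seeded synthetic-data generator that emulates the study design
   (9 substrates, 22 reactor runs at ~50 and ~300 mM) so that every stage is
   testable without laboratory data.

## Two kinetic models, deliberately inconsistent

Experimental progress curves are routinely fitted with the pseudo-first-order
reversible (mono-exponential) model

$$[A](t) = [A]_\mathrm{eq} + ([A]_0 - [A]_\mathrm{eq})\,
e^{-(k_1 + k_{-1})t},$$

while the equilibrium constant of the coupled system is defined through the
*squared* product concentration,

$$K \;=\; \frac{[\mathrm{alcohol}][\mathrm{acetone}]}{[\mathrm{ketone}]}
\;=\; \frac{P_\mathrm{eq}^2}{A_0 - P_\mathrm{eq}} \quad (\mathrm{mM}),$$

because acetone tracks the alcohol stoichiometrically. These two statements
are not mutually consistent: a first-order reverse step would imply
$K = P_\mathrm{eq}/A_\mathrm{eq}$. `ketokin` keeps both on purpose:

* `simulate_mono_exponential()` implements the fitting approximation;
* `simulate_mass_action()` implements the mass-action scheme
  $dP/dt = k_f (A_0 - P) - k_r P^2$, whose stationary point is exactly the
  squared-product equilibrium. It is solved in closed form (the rate law
  factors through the two real roots of $k_r P^2 + k_f P - k_f A_0$, giving
  a logistic-type solution with relaxation rate
  $r = \sqrt{k_f^2 + 4 k_f k_r A_0}$), and tests verify it against an
  independent stiff ODE integration to better than $10^{-6}$ relative error.

The synthetic generator uses mass action as the *generative truth* and the
fitter uses the mono-exponential *approximation*, so the analysis pipeline is
exercised against a subtly misspecified model — precisely the situation with
real reactor data. The equilibrium plateau is model-independent, which is why
the fitted equilibrium constants recover the planted values even though the
curve shape is approximate (the fitted $A_0$ is biased high by a fraction of
a percent; see the planted-run test).

Concentrations are millimolar throughout and $\log K$ is taken on the mM
scale; this choice reproduces the worked example of the reference batch run
($A_0 = 286$ mM, $P_\mathrm{eq} = 152$ mM $\Rightarrow \log K = 2.24$,
conversion 53 %). Time is minutes internally; report tables print hours.
An optional first-order acetone-loss term (`acetone_loss`, default off)
models evaporation during long runs; with it the closed form no longer
applies and a fixed-fine-step Runge–Kutta integration is used.

```{r worked}
estimate_equilibrium_constant(286, 152)
conversion(286, 152)
time_to_fraction(mono_exp_params(286, 134, 0.01), 0.95) # t95, minutes
```

## Curve fitting

`fit_mono_exponential()` estimates $(A_0, A_\mathrm{eq}, k_\mathrm{obs})$ by
nonlinear least squares (Levenberg–Marquardt via `minpack.lm`), with bounds
$A_0 > 0$, $0 \le A_\mathrm{eq} \le A_0$, $k_\mathrm{obs} > 0$ enforced by a
log/logit reparameterization rather than a constrained solver. Starting
values follow a convention that is robust for monotone curves: $A_0$ from
the first substrate observation (or the nominal loading), $A_\mathrm{eq}$
from the last, $k_\mathrm{obs}$ from the half-range crossing time.

Derived quantities: $K_\mathrm{ex}$ and $\log K_\mathrm{ex}$ (from the
fitted plateau by default, or from the last measured point with
`keq_from = "last"` — printed reactor tables are often ambiguous about which
was used), conversion, $t_{95} = \ln(20)/k_\mathrm{obs}$, $R^2$ and residual
SD. A fit is flagged `equilibrium_reached = FALSE` when the last sample is
earlier than $3\,t_{95}$ of the fitted curve, mirroring the practice of
excluding equilibrium constants from runs lacking points in the equilibrium
region; `report_row()` withholds $\log K$ for such runs. The product channel
alone does not identify $A_0$, so `species = "product"` requires a nominal
loading.

Stereochemical purity is summarised by `enantiomeric_excess()`:
fractions are normalised to 100 %, $ee = |\%S - \%R|$, and the major
configuration is reported (`"racemic"` at exact parity).

## Electronic descriptors

The para substituent's electronic effect enters as any one of three strongly
collinear descriptors: the Hammett constant $\sigma_p$ (tabulated
Hansch–Leo values ship with the package; `hammett_lookup("p-NO2")` gives
+0.78), the computed free-energy change of alkoxide formation relative to
the unsubstituted parent ($\Delta\Delta G^\mathrm{alkoxy}$, kJ/mol), and a
theoretical $\log K$. Sign conventions: electron-withdrawing substituents
stabilise the alkoxide ($\Delta\Delta G^\mathrm{alkoxy} < 0$) and shift the
equilibrium toward product, so the $\sigma_p \to \Delta\Delta G$ and
$\Delta\Delta G \to \log K$ calibrations both have negative slope.
Quantum-chemical computation of these descriptors is out of scope; they are
inputs (or simulated quantities), and `fit_linear_calibration()` /
`predict_from_calibration()` implement the ordinary least-squares
calibrations among them. Theoretical $\log K$ (1 M standard state) and
experimental $\log K_\mathrm{ex}$ (mM scale) are related only by linear
calibration, never equated.

`select_descriptors()` performs backward elimination over candidate
descriptor columns using the validation error of freshly trained small
networks. Two details matter. Comparisons are *paired* (baseline and every
single-removal trained with the same per-round seed), and a removal is
accepted within a relative *parsimony margin* (`tol`, default 0.5): a
network simply learns to ignore an uninformative input, so dropping it moves
the validation error only within restart noise (measured ratio 0.83–1.48
across seeds), whereas dropping a genuinely informative descriptor degrades
it severalfold (≥ 1.98 in the same experiment). A strict
improvement-only rule would keep pure-noise inputs about half the time.

## The progress-curve MLP

`train_mlp()` implements the network from scratch: configurable
$n_\mathrm{in}$–$n_h$–1 architecture (default 3-5-1: initial concentration,
one electronic descriptor, time), logistic hidden units, identity output by
default (logistic available), and min–max scaling to $[0,1]$ computed on the
training subset only. Cases are split 2:1:1 into
training/validation/test by uniform random assignment with largest-remainder
rounding (`split_cases()`), deterministic per seed.

Training is two-phase, following the era's neural QSAR workflow:

* **Phase 1** — 100 epochs of full-batch back-propagation with momentum
  (learning rate 0.1, momentum 0.3; conventional defaults, the protocol
  names the algorithms but no rates).
* **Phase 2** — Polak–Ribière conjugate gradient, one line minimisation
  (bracketing plus Brent refinement) per epoch, with a budget of 175 epochs
  for the full-time-span protocol and 260 for the time-truncated one, early
  stopping on the validation RMSE (patience 60), and the weights returned
  from the validation minimum across *all* logged epochs.

Five seeded restarts are trained and the restart with the lowest validation
error wins (`n_starts`) — a desk-scale stand-in for the multi-candidate
network searches of commercial packages. The analytic backprop gradient is
verified against central finite differences in the test suite.

Two representation choices deserve note:

* **Logarithmic time.** Reactor sampling spans four decades (minutes to
  hundreds of hours). Fed raw, min–max scaling collapses all early samples
  near zero and the optimization becomes so ill-conditioned that even a
  fully converged network (or a random forest) cannot represent the curves;
  on a $\log_{10}(1+t)$ axis progress curves are nearly sigmoidal and the
  same protocol fits them well. `log_time = TRUE` is therefore the default
  (scaling is still min–max on the training subset); set it to `FALSE` for
  raw minutes.
* **Time truncation.** `truncate_cases(cases, 1000)` restricts to the first
  1000 minutes — the protocol that makes fast (low-loading) and slow
  (high-loading) runs contribute comparable spans.

Interpretation tools: `sensitivity_analysis()` reports, per input, the
ratio of the RMSE with that input frozen at its training mean to the
baseline RMSE (ratios near 1 flag uninformative inputs; time dominates on
progress-curve models); `response_curve()` projects the fitted surface
along one input with the others at their training means (the descriptor
response falls with increasing $\Delta\Delta G^\mathrm{alkoxy}$, i.e.
electron-withdrawing substituents give more product);
`external_validation()` retrains without one substrate and scores each of
its runs separately by $R^2$, raising an extrapolation flag when the
held-out inputs leave the training range.

```{r mlp, eval = FALSE}
gen <- generator_config(seed = 1)
panel <- generate_panel(gen)
series <- generate_reactor_series(panel, gen)
cases <- split_cases(generate_case_table(panel, series), seed = 1)
model <- train_mlp(cases, mlp_config(seed = 1))
glance(model, cases)
sensitivity_analysis(model, cases)
autoplot(response_curve(model, "descriptor"))
```

## What the synthetic generator emulates — and what it does not

`generator_config()` encodes the emulated study conditions:

* nine substrates whose $\sigma_p$ values cover $[-0.4, 0.8]$ with both
  endpoints present and the unsubstituted reference pinned at
  $\sigma_p = 0$, $\Delta\Delta G = 0$;
* $\Delta\Delta G^\mathrm{alkoxy} = -25\,\sigma_p + \varepsilon$ kJ/mol with
  noise SD 2.9 kJ/mol, and $\log K = 2.24 - 0.08\,\Delta\Delta G +
  \varepsilon$ with noise SD 0.33. The slopes and the acetophenone anchor
  ($\log K = 2.24$ at $\Delta\Delta G = 0$) were chosen to reproduce the
  reported range of experimental equilibrium constants (about 1.1–3.5 in
  $\log_{10}$ mM); the noise SDs were calibrated once, over 400 panels, so
  that the *sample* correlations match the reported strengths
  ($R^2 \approx 0.94$ for $\sigma_p \leftrightarrow \Delta\Delta G$,
  $|r| \approx 0.93$ for $\Delta\Delta G \leftrightarrow \log K$) — the
  endpoint-anchored design inflates sample variance, so these SDs exceed
  what a naive population formula suggests;
* 22 runs mirroring the study's multiplicity: every substrate has at least
  one ~50 mM run, seven of nine also have ~300 mM runs, loadings jittered
  ±15 %;
* $t_{95}$ spanning 2–900 h. The study reports that electron-withdrawing
  substituents accelerate the reaction *and* shift its equilibrium, so
  $\log_{10} t_{95}$ is tied linearly to $\Delta\Delta G$ across that span,
  with lognormal run-to-run jitter (SD 0.15 $\log_{10}$, ≈40 % rate
  variability between replicate reactors — a realistic level for whole-cell
  batches). An independent log-uniform draw would make rates unpredictable
  from the descriptor and no progress-curve regressor could work;
* sampling at $t = 0$ plus 11–19 log-spaced points from 10 min to
  $\min(5\,t_{95}, 200\ \mathrm{h})$ — dense early, sparse late; the 200-h
  cap leaves the slowest high-loading runs short of equilibrium, exercising
  the fit-exclusion flag;
* 3 % multiplicative Gaussian measurement noise (HPLC dilution-series
  error), applied independently to the substrate and product channels,
  negatives clipped to zero. The $t = 0$ anchor is exact.

Ground truth (per-substrate descriptors, per-run $k_f$, $k_r$, $\log K$,
$t_{95}$) is stored with every generated object, which is what the recovery
experiments test against: over 100 seeded noisy runs with conversions
between 20 and 90 %, the median $|\hat{\log K} - \log K|$ is about 0.02 and
the 90th percentile about 0.05.

What passing these tests does **not** show about real data: the generator
has no chromatographic peak-shape artifacts, no enzyme deactivation over
multi-day runs, no acetone evaporation (unless the optional loss term is
switched on), no pH drift, and its noise is homoscedastic on the relative
scale. Real external-validation performance will therefore be worse than
the synthetic leave-one-substrate-out numbers, particularly for substrates
at the edge of the descriptor range, where prediction is extrapolation (the
synthetic experiment shows the same failure mode: interior holdouts score
$R^2 \approx 0.7$–0.86, edge holdouts can be arbitrarily bad).

## Numerical choices and scaled-down problem sizes

* The closed-form mass-action solution is written to avoid cancellation for
  small $K$ (`equilibrium_product()` uses the conjugate form
  $2KA_0/(K + \sqrt{K^2 + 4KA_0})$).
* Nonlinear fits report `converged = FALSE` with the solver's diagnostic
  rather than erroring; derived quantities are withheld.
* Tied validation errors in descriptor elimination resolve in favour of
  dropping (parsimony); ties in the split's largest-remainder rounding
  resolve toward the training subset.
* The leave-one-substrate-out experiment (`loso_experiment()`) extends the
  conjugate-gradient budget to 400 epochs (patience 150) and aggregates
  three training seeds per fold: transfer to an unseen substrate converges
  more slowly than in-sample fitting (validation minima land near epoch 500
  of the combined schedule), and fold medians over seeds remove
  restart-to-restart variability. Problem sizes throughout the tests — one
  22-run series, 50 generated panels, 100 recovery runs, three LOSO seeds —
  were chosen as the smallest sets at which the reported statistics
  stabilise to their second decimal.
* All randomness flows from explicit integer seeds; generation, splitting
  and training restore the caller's RNG state.

## Known limitations

* Separate forward and reverse rate constants are not estimable from a
  single progress curve (only $k_\mathrm{obs}$ and the plateau are); the
  package never reports them, matching the underlying study's own caveat.
* The mono-exponential fit's $A_0$ is biased by a fraction of a percent on
  mass-action data; equilibrium quantities are unaffected, but rate
  constants inherit the approximation.
* The MLP predicts a single product concentration; it does not enforce mass
  conservation or monotonicity, and can return small negative values near
  $t = 0$.
* Hidden-layer widths beyond ~10 are untested territory for these data
  sizes; the default of 5 follows the observation that validation error is
  flat from 5 upward.
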