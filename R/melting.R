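# Two-state CD melting analysis: a folded/unfolded equilibrium with linear
# state baselines, fitted simultaneously. Tm is not a free parameter but the
# derived ratio dH_unf/dS_unf of the fitted unfolding parameters.

#' CD melting curve
#'
#' @param T temperatures, K, strictly increasing, >= 30 points. A warning is
#'   issued when the curve does not extend at least 10 K beyond the apparent
#'   transition on each side (baselines poorly constrained).
#' @param signal CD ellipticity at 260 nm, arbitrary units (mdeg).
#' @param label construct name.
#' @return object of class `melting_curve`.
#' @export
melting_curve <- function(T, signal, label = "construct") {
  if (length(T) != length(signal))
    stop("T and signal must have equal length", call. = FALSE)
  if (length(T) < 30)
    stop("a melting curve needs >= 30 points", call. = FALSE)
  if (any(diff(T) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  .check_T(T)
  structure(list(T = T, signal = signal, label = as.character(label)),
            class = "melting_curve")
}

#' Two-state melting fit parameters
#'
#' Baselines are linear in temperature and parameterised as
#' `intercept + slope * (T - 273.15)` (intercept at 0 degC, slope per K).
#' `Tm` is the derived field `1000 * dH_unf / dS_unf`, exactly.
#'
#' @param dH_unf unfolding enthalpy, kJ/mol (> 0).
#' @param dS_unf unfolding entropy, J/(mol K) (> 0).
#' @param baseline_folded,baseline_unfolded numeric length-2 vectors
#'   `c(intercept, slope)` of the state baselines.
#' @param rmse root-mean-square residual of the fit (signal units).
#' @param flags character vector of quality flags.
#' @return object of class `melting_fit`.
#' @export
melting_fit <- function(dH_unf, dS_unf,
                        baseline_folded = c(0, 0),
                        baseline_unfolded = c(1, 0),
                        rmse = NA_real_, flags = character()) {
  if (!is.finite(dS_unf) || dS_unf <= 0)
    stop("dS_unf must be positive for an unfolding transition", call. = FALSE)
  if (!is.finite(dH_unf) || dH_unf <= 0)
    stop("dH_unf must be positive for an unfolding transition", call. = FALSE)
  structure(list(dH_unf = dH_unf, dS_unf = dS_unf,
                 Tm = tm_from_thermo(dH_unf, dS_unf),
                 baseline_folded = baseline_folded,
                 baseline_unfolded = baseline_unfolded,
                 rmse = rmse, flags = as.character(flags)),
            class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("Two-state melting fit: Tm = %.1f K (%.1f degC)\n",
              x$Tm, kelvin_to_celsius(x$Tm)))
  cat(sprintf("  dH_unf = %.0f kJ/mol, dS_unf = %.0f J/(mol K), rmse = %.3g\n",
              x$dH_unf, x$dS_unf, x$rmse))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Melting temperature from two-state parameters
#'
#' The two-state identity `Tm = 1000 * dH_unf / dS_unf` (temperature at which
#' the unfolding Gibbs energy vanishes).
#'
#' @param dH_unf unfolding enthalpy, kJ/mol.
#' @param dS_unf unfolding entropy, J/(mol K); must be positive.
#' @return melting temperature, K.
#' @export
tm_from_thermo <- function(dH_unf, dS_unf) {
  if (any(dS_unf <= 0)) stop("dS_unf must be positive", call. = FALSE)
  1000 * dH_unf / dS_unf
}

.baseline_eval <- function(b, T) b[1] + b[2] * (T - 273.15)

.fraction_folded <- function(T, dH_unf, dS_unf) {
  # f_folded = 1/(1 + exp(-dG_unf/RT)); plogis is the numerically stable form
  stats::plogis((dH_unf * 1000 - T * dS_unf) / (.const$R * T))
}

#' Two-state melting signal model
#'
#' `signal(T) = B_f(T) f_folded(T) + B_u(T) (1 - f_folded(T))` with
#' `f_folded = 1/(1 + exp(-dG_unf/(R T)))` and `dG_unf = dH_unf - T dS_unf`.
#' At `T = Tm` the signal lies exactly midway between the baselines.
#'
#' @param T temperatures, K.
#' @param fit a [melting_fit()] (or any list with the same fields).
#' @return model signal in the units of the data.
#' @export
two_state_signal <- function(T, fit) {
  .check_T(T)
  f <- .fraction_folded(T, fit$dH_unf, fit$dS_unf)
  .baseline_eval(fit$baseline_folded, T) * f +
    .baseline_eval(fit$baseline_unfolded, T) * (1 - f)
}

.melt_resid <- function(par, T, y) {
  f <- .fraction_folded(T, par[1], par[2])
  (par[3] + par[4] * (T - 273.15)) * f +
    (par[5] + par[6] * (T - 273.15)) * (1 - f) - y
}

#' Fit a two-state melting curve
#'
#' Six-parameter nonlinear least squares: unfolding enthalpy and entropy plus
#' intercept and slope of each state baseline, fitted simultaneously.
#' Baseline starts come from linear fits to the outer 20% of the temperature
#' range; the transition is multi-started over a grid of Tm guesses spanning
#' the interior of the curve, keeping the lowest residual sum.
#'
#' Flags: `"no_transition"` when the fitted enthalpy collapses to its lower
#' bound or Tm leaves the data range (pure-baseline signal);
#' `"broad_transition"` when the transition amplitude between the baselines
#' at Tm is below three times the fit rmse.
#'
#' @param curve a [melting_curve()].
#' @return a [melting_fit()] carrying a `fit` attribute with residuals and
#'   convergence info.
#' @export
fit_melting <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  T <- curve$T; y <- curve$signal
  n <- length(T)
  lo20 <- T <= stats::quantile(T, 0.2)
  hi20 <- T >= stats::quantile(T, 0.8)
  bf <- stats::coef(stats::lm(y[lo20] ~ I(T[lo20] - 273.15)))
  bu <- stats::coef(stats::lm(y[hi20] ~ I(T[hi20] - 273.15)))

  tm_guesses <- stats::quantile(T, c(0.3, 0.45, 0.6, 0.75))
  dH_guesses <- c(100, 300)
  lower <- c(1, 1, rep(-Inf, 4))
  upper <- c(2000, 20000, rep(Inf, 4))
  fits <- list()
  for (tm in tm_guesses) for (dH in dH_guesses) {
    st <- c(dH, 1000 * dH / tm, unname(bf), unname(bu))
    f <- try(minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                                fn = .melt_resid, T = T, y = y,
                                control = .lm_control()),
             silent = TRUE)
    if (!inherits(f, "try-error")) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) stop("melting fit failed from all starts", call. = FALSE)
  dev <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(dev)]]
  p <- best$par
  rmse <- sqrt(min(dev) / max(1, n - 6))

  flags <- character()
  tm_fit <- 1000 * p[1] / p[2]
  if (p[1] <= lower[1] * 1.01 || tm_fit < min(T) || tm_fit > max(T))
    flags <- c(flags, "no_transition")
  amp <- abs(.baseline_eval(p[5:6], tm_fit) - .baseline_eval(p[3:4], tm_fit))
  if (amp < 3 * rmse) flags <- c(flags, "broad_transition")
  if (!best$info %in% 1:4) flags <- c(flags, "non_convergent")
  if (min(T) > tm_fit - 10 || max(T) < tm_fit + 10)
    warning("curve spans less than 10 K beyond the transition on each side",
            call. = FALSE)

  out <- melting_fit(p[1], p[2], p[3:4], p[5:6], rmse = rmse, flags = flags)
  attr(out, "fit") <- list(label = curve$label, residuals = best$fvec,
                           deviance = min(dev), info = best$info,
                           converged = best$info %in% 1:4)
  out
}

#' Fraction unfolded from a baseline-corrected melting curve
#'
#' Baseline-corrects the observed signal and normalises it to the unfolded
#' fraction `(signal - B_f) / (B_u - B_f)`, clipped to `[0, 1]`. Temperatures
#' where the baselines are closer than three times the fit rmse carry no
#' information and are masked (`NA`). At `T = Tm` the model value is exactly
#' 0.5.
#'
#' @param curve the [melting_curve()].
#' @param fit its converged [fit_melting()] result.
#' @return data frame with columns `T` (K) and `fraction` in `[0, 1]`.
#' @export
fraction_unfolded <- function(curve, fit) {
  stopifnot(inherits(curve, "melting_curve"), inherits(fit, "melting_fit"))
  bf <- .baseline_eval(fit$baseline_folded, curve$T)
  bu <- .baseline_eval(fit$baseline_unfolded, curve$T)
  sep <- bu - bf
  frac <- pmin(pmax((curve$signal - bf) / sep, 0), 1)
  if (is.finite(fit$rmse))
    frac[abs(sep) < 3 * fit$rmse] <- NA_real_
  data.frame(T = curve$T, fraction = frac)
}
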