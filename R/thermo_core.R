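# Forward model of imino proton exchange in the EX2 regime:
# opening equilibrium (van't Hoff / Gibbs-Helmholtz), internal transfer
# (Eyring), external catalysis (linear in catalyst), dipolar offset.
# Units: enthalpies kJ/mol, entropies J/(mol K), temperatures K, rates 1/s.

# CODATA values; deliberately not user-overridable.
.const <- list(
  R  = 8.31446261815324, # gas constant, J/(mol K)
  kB = 1.380649e-23,     # Boltzmann constant, J/K
  h  = 6.62607015e-34    # Planck constant, J s
)

#' Physical constants used by the exchange model
#'
#' Returns the fixed CODATA values of the gas constant `R` (J mol^-1 K^-1),
#' the Boltzmann constant `kB` (J K^-1) and the Planck constant `h` (J s).
#' These are compile-time constants of the model and cannot be overridden.
#'
#' @return Named list with elements `R`, `kB`, `h`.
#' @export
physical_constants <- function() .const

#' Convert between Celsius and Kelvin
#'
#' File formats and reports use degrees Celsius; all model internals use
#' Kelvin with the exact 273.15 offset.
#'
#' @param T_C,T_K temperatures in degrees Celsius / Kelvin.
#' @return numeric vector of converted temperatures.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(T_K) T_K - 273.15

.check_T <- function(T) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be finite and positive (Kelvin)", call. = FALSE)
  invisible(T)
}

#' Equilibrium constant of base-pair opening
#'
#' Van't Hoff/Gibbs-Helmholtz form assuming temperature-independent opening
#' enthalpy and entropy: `K_Diss(T) = exp(-(dH - T dS) / (R T))`.
#'
#' @param T temperature, K.
#' @param dH opening (dissociation) enthalpy, kJ/mol.
#' @param dS opening entropy, J/(mol K).
#' @return dimensionless equilibrium constant, vectorised over the inputs.
#' @export
k_diss <- function(T, dH, dS) {
  .check_T(T)
  exp(-(dH * 1000 - T * dS) / (.const$R * T))
}

#' Gibbs energy of base-pair opening
#'
#' `dG = dH - T dS` with the entropy converted from J to kJ. At 293.15 K this
#' is the standard 20 degC stability used to rank base pairs.
#'
#' @inheritParams k_diss
#' @return Gibbs energy, kJ/mol.
#' @export
gibbs_energy <- function(T, dH, dS) {
  .check_T(T)
  dH - T * dS / 1000
}

#' Eyring transition-state rate
#'
#' `k(T) = (kB T / h) exp(-(dH_act - T dS_act) / (R T))`, evaluated in log
#' space so that extreme activation parameters underflow to 0 rather than
#' overflow.
#'
#' @param T temperature, K.
#' @param dH_act activation enthalpy, kJ/mol.
#' @param dS_act activation entropy, J/(mol K).
#' @return rate, 1/s.
#' @export
eyring_rate <- function(T, dH_act, dS_act) {
  .check_T(T)
  exp(log(.const$kB * T / .const$h) -
        (dH_act * 1000 - T * dS_act) / (.const$R * T))
}

#' External catalysis model
#'
#' Parameters describing proton transfer from the open state via a dissolved
#' basic catalyst (HPO4^2-), calibrated on the imino exchange of free
#' mononucleotides. The transfer rate is an Eyring-form rate from the NTP
#' transition-state parameters, scaled linearly by catalyst concentration
#' relative to the reference concentration `c_ref` and multiplied by the
#' dimensionless diffusion correction `d_dif`.
#'
#' The shipped defaults for `dH_tr_ntp`/`dS_tr_ntp` are nominal placeholders
#' chosen to give transfer rates of realistic magnitude (~1e5 1/s per mM at
#' 20 degC); replace them with experimentally determined NTP exchange
#' parameters before analysing real data.
#'
#' @param dH_tr_ntp NTP transition-state enthalpy, kJ/mol.
#' @param dS_tr_ntp NTP transition-state entropy, J/(mol K).
#' @param d_dif dimensionless diffusion correction factor (> 0).
#' @param c_ref reference catalyst concentration, mol/L, at which the NTP
#'   Eyring rate is taken; concentration scaling is `c_cat / c_ref`.
#' @param reference_species `"UTP"` or `"GTP"`.
#' @param unc named list of standard uncertainties of the above parameters,
#'   used by [mc_errors()] when noising catalysis inputs.
#' @return object of class `catalysis_model`.
#' @export
catalysis_model <- function(dH_tr_ntp = 30, dS_tr_ntp = -40,
                            d_dif = 1.0, c_ref = 1e-3,
                            reference_species = c("UTP", "GTP"),
                            unc = list()) {
  reference_species <- match.arg(reference_species)
  if (!is.finite(d_dif) || d_dif <= 0)
    stop("d_dif must be positive", call. = FALSE)
  if (!is.finite(c_ref) || c_ref <= 0)
    stop("c_ref must be positive", call. = FALSE)
  u <- list(dH_tr_ntp = 0, dS_tr_ntp = 0, d_dif = 0)
  u[names(unc)] <- unc
  structure(list(dH_tr_ntp = dH_tr_ntp, dS_tr_ntp = dS_tr_ntp,
                 d_dif = d_dif, c_ref = c_ref,
                 reference_species = reference_species, unc = u),
            class = "catalysis_model")
}

#' @export
print.catalysis_model <- function(x, ...) {
  cat(sprintf(
    "External catalysis model (%s reference)\n  dH_tr_ntp = %g kJ/mol, dS_tr_ntp = %g J/(mol K)\n  d_dif = %g, c_ref = %g mol/L\n",
    x$reference_species, x$dH_tr_ntp, x$dS_tr_ntp, x$d_dif, x$c_ref))
  invisible(x)
}

#' External proton-transfer rate
#'
#' Transfer rate from the open state via the external catalyst:
#' `k_Tr,ext(T, c) = d_dif * Eyring(T; NTP params) * c_cat / c_ref`.
#' Zero catalyst gives exactly zero.
#'
#' @param T temperature, K.
#' @param c_cat catalyst concentration, mol/L (>= 0).
#' @param cat a [catalysis_model()].
#' @return rate, 1/s.
#' @export
external_catalysis_rate <- function(T, c_cat, cat) {
  if (any(!is.finite(c_cat)) || any(c_cat < 0))
    stop("catalyst concentration must be non-negative", call. = FALSE)
  cat$d_dif * eyring_rate(T, cat$dH_tr_ntp, cat$dS_tr_ntp) * (c_cat / cat$c_ref)
}

#' Per-base-pair thermodynamic parameter set
#'
#' Container for the five-parameter description of one base pair: opening
#' enthalpy/entropy, internal transition-state activation enthalpy/entropy,
#' and the dipolar cross-relaxation offset `d` that dominates the apparent
#' exchange rate at low temperature. Monte Carlo errors (when available) are
#' stored alongside.
#'
#' @param label nucleobase identifier, e.g. `"G28"`; overlapped resonances
#'   fitted jointly carry a joint label such as `"U7/U37"`.
#' @param dH_diss,dS_diss opening enthalpy (kJ/mol) and entropy (J/(mol K)).
#' @param dH_tr_int,dS_tr_int internal transition-state activation parameters.
#' @param d dipolar cross-relaxation offset, 1/s (>= 0).
#' @param averaged logical; `TRUE` for a shared-parameter (averaged) fit of an
#'   overlapped pair.
#' @param err named list with elements `dH`, `dS`, `dG20` (Monte Carlo
#'   standard errors), `NA` until [mc_errors()] has run.
#' @param flags character vector of quality flags (e.g. `"not_determinable"`).
#' @return object of class `bp_thermo`.
#' @export
base_pair_thermo <- function(label, dH_diss, dS_diss,
                             dH_tr_int = 60, dS_tr_int = 0, d = 1,
                             averaged = grepl("/", label),
                             err = list(dH = NA_real_, dS = NA_real_,
                                        dG20 = NA_real_),
                             flags = character()) {
  if (!is.finite(dH_diss) || !is.finite(dS_diss))
    stop("dH_diss and dS_diss must be finite", call. = FALSE)
  if (!is.finite(d) || d < 0)
    stop("dipolar offset d must be non-negative", call. = FALSE)
  structure(list(label = as.character(label),
                 dH_diss = dH_diss, dS_diss = dS_diss,
                 dH_tr_int = dH_tr_int, dS_tr_int = dS_tr_int, d = d,
                 averaged = isTRUE(averaged), err = err,
                 flags = as.character(flags)),
            class = "bp_thermo")
}

#' @export
print.bp_thermo <- function(x, ...) {
  dg <- gibbs_energy(293.15, x$dH_diss, x$dS_diss)
  cat(sprintf("Base pair %s%s\n", x$label,
              if (x$averaged) " (averaged pair)" else ""))
  cat(sprintf("  dH_diss = %.1f kJ/mol, dS_diss = %.1f J/(mol K), dG(20 degC) = %.1f kJ/mol\n",
              x$dH_diss, x$dS_diss, dg))
  cat(sprintf("  dH_tr_int = %.1f kJ/mol, dS_tr_int = %.1f J/(mol K), d = %.2f 1/s\n",
              x$dH_tr_int, x$dS_tr_int, x$d))
  if (is.finite(x$err$dH))
    cat(sprintf("  MC errors: dH %.1f, dS %.1f, dG20 %.2f\n",
                x$err$dH, x$err$dS, x$err$dG20))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Observed exchange-rate series for one imino resonance
#'
#' Holds the (temperature, catalyst concentration, exchange rate, standard
#' error) observations consumed by [fit_base_pair()]. A stability fit needs
#' at least two distinct catalyst concentrations with at least four distinct
#' temperatures each; those requirements are enforced at fit time so that
#' partial series can still be read and inspected.
#'
#' @param label nucleobase identifier (joint labels mark averaged pairs).
#' @param T temperature, K.
#' @param c_cat catalyst concentration, mol/L.
#' @param k_ex observed exchange rate, 1/s.
#' @param sigma standard error of `k_ex`, 1/s (> 0).
#' @return object of class `exchange_series` with a data frame in `$data`.
#' @export
exchange_series <- function(label, T, c_cat, k_ex, sigma) {
  n <- length(T)
  if (!all(lengths(list(c_cat, k_ex, sigma)) == n))
    stop("T, c_cat, k_ex, sigma must have equal length", call. = FALSE)
  if (any(T <= 0)) stop("temperatures must be positive (K)", call. = FALSE)
  if (any(c_cat < 0)) stop("catalyst concentrations must be >= 0", call. = FALSE)
  if (any(k_ex < 0)) stop("exchange rates must be >= 0", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  d <- data.frame(T = T, c_cat = c_cat, k_ex = k_ex, sigma = sigma)
  structure(list(label = as.character(label), data = d,
                 averaged = grepl("/", label)),
            class = "exchange_series")
}

#' @export
print.exchange_series <- function(x, ...) {
  cat(sprintf("Exchange-rate series %s: %d rates, %d catalyst conc., T %.1f..%.1f degC\n",
              x$label, nrow(x$data), length(unique(x$data$c_cat)),
              kelvin_to_celsius(min(x$data$T)),
              kelvin_to_celsius(max(x$data$T))))
  invisible(x)
}

#' EX2 exchange-rate forward model
#'
#' The observable imino exchange rate for a hydrogen-bonded nucleobase in the
#' EX2 regime, composed from the opening equilibrium, the internal (Eyring)
#' and external (catalyst-linear) transfer pathways, and the dipolar
#' cross-relaxation offset:
#'
#' `k_ex(T, c) = (k_Tr,int(T) + k_Tr,ext(T, c)) / (1 + 1/K_Diss(T)) + d`
#'
#' In the limit of a fully open pair (`K_Diss -> Inf`) this tends to
#' `k_Tr,int + k_Tr,ext + d`; with no transfer it reduces to `d`.
#'
#' @param T temperature, K (vectorised).
#' @param c_cat catalyst concentration, mol/L (vectorised).
#' @param bp a [base_pair_thermo()].
#' @param cat a [catalysis_model()].
#' @return exchange rate, 1/s.
#' @export
exchange_rate_model <- function(T, c_cat, bp, cat) {
  .check_T(T)
  k_tr <- eyring_rate(T, bp$dH_tr_int, bp$dS_tr_int) +
    external_catalysis_rate(T, c_cat, cat)
  # open-state population 1/(1 + 1/K) = 1/(1 + exp(+dG/RT)); exp() may
  # overflow to Inf for very stable pairs, which correctly yields 0
  g <- (bp$dH_diss * 1000 - T * bp$dS_diss) / (.const$R * T)
  k_tr / (1 + exp(g)) + bp$d
}

#' Gibbs-energy trace over temperature
#'
#' Linear-in-temperature extrapolation of the opening Gibbs energy. Traces of
#' base pairs lying on a common compensation line intersect at the
#' compensation temperature, where all their stabilities coincide at the
#' line's offset.
#'
#' @param bp a [base_pair_thermo()].
#' @param T_grid temperatures, K.
#' @return data frame with columns `T` (K) and `dG` (kJ/mol).
#' @export
gibbs_curve <- function(bp, T_grid) {
  .check_T(T_grid)
  data.frame(T = T_grid, dG = gibbs_energy(T_grid, bp$dH_diss, bp$dS_diss))
}
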