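# Synthetic-data generators emulating the experimental design: a temperature
# series from -5 to 55 degC at two catalyst concentrations (2 and 29 mM
# HPO4^2-), inversion-recovery profiles underneath each rate, and a CD
# melting curve per construct. Noise is multiplicative Gaussian on rates
# (default 5%) and additive Gaussian on the CD signal, matching how errors
# are reported in each data type. Every generator is deterministic under the
# spec's seed.

#' Specification of a synthetic construct
#'
#' Bundles the ground truth of a simulated hairpin: per-base-pair
#' thermodynamic parameters (optionally drawn from a compensation line), the
#' external-catalysis model, the two-state melting truth, and the
#' experimental design grid.
#'
#' @param name construct name.
#' @param base_pairs data frame with columns `label`, `dH_diss`, `dS_diss`,
#'   `dH_tr_int`, `dS_tr_int`, `d`.
#' @param catalysis a [catalysis_model()].
#' @param eec optional list `(Tc, y0, scatter)` recording that the base-pair
#'   ladder was drawn from a compensation line (see [gen_eec_construct()]).
#' @param melting optional list `(dH_unf, dS_unf, baseline_folded,
#'   baseline_unfolded, noise_sd)` for [gen_melting_curve()].
#' @param design list of experimental-design settings; defaults follow the
#'   published protocol: `T_C = seq(-5, 55, by = 3)`, `c_cat_mM = c(2, 29)`,
#'   `noise_frac = 0.05` (relative rate noise), `t_m` log-spaced over
#'   0.002..3 s (12 points), `ir_noise = 0.01` (absolute on intensity
#'   ratios), `R1_H = 2`, `R1_W = 0.35` (1/s).
#' @param seed mandatory RNG seed; all generators derive their draws from it.
#' @param overlap optional list of length-2 character vectors naming base
#'   pairs whose resonances overlap (their profiles are summed).
#' @return object of class `construct_spec`.
#' @export
construct_spec <- function(name, base_pairs, catalysis = catalysis_model(),
                           eec = NULL, melting = NULL, design = list(),
                           seed, overlap = NULL) {
  stopifnot(is.data.frame(base_pairs),
            all(c("label", "dH_diss", "dS_diss", "dH_tr_int", "dS_tr_int",
                  "d") %in% names(base_pairs)))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  des <- list(T_C = seq(-5, 55, by = 3), c_cat_mM = c(2, 29),
              noise_frac = 0.05,
              t_m = exp(seq(log(0.002), log(3), length.out = 12)),
              ir_noise = 0.01, R1_H = 2, R1_W = 0.35,
              melt_T_C = seq(2, 98, by = 1))
  des[names(design)] <- design
  structure(list(name = name, base_pairs = base_pairs, catalysis = catalysis,
                 eec = eec, melting = melting, design = des,
                 seed = as.integer(seed), overlap = overlap),
            class = "construct_spec")
}

.bp_from_row <- function(row) {
  base_pair_thermo(row$label, row$dH_diss, row$dS_diss, row$dH_tr_int,
                   row$dS_tr_int, row$d)
}

#' Generate exchange-rate series for every base pair of a construct
#'
#' Evaluates the EX2 forward model on the design grid and applies
#' multiplicative Gaussian noise at the design's `noise_frac`; the recorded
#' standard error is the true relative error (`noise_frac * k_true`, floored
#' at a negligible positive value so that noiseless series remain valid
#' weighted-fit inputs).
#'
#' @param spec a [construct_spec()].
#' @return named list of [exchange_series()], one per base pair.
#' @export
gen_exchange_series <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  des <- spec$design
  grid <- expand.grid(T = celsius_to_kelvin(des$T_C),
                      c_cat = des$c_cat_mM * 1e-3)
  set.seed(spec$seed)
  out <- list()
  for (i in seq_len(nrow(spec$base_pairs))) {
    bp <- .bp_from_row(spec$base_pairs[i, ])
    k_true <- exchange_rate_model(grid$T, grid$c_cat, bp, spec$catalysis)
    noise <- stats::rnorm(nrow(grid)) * des$noise_frac
    k_obs <- pmax(k_true * (1 + noise), 0)
    sigma <- pmax(des$noise_frac * k_true, 1e-9 * pmax(k_true, 1))
    out[[bp$label]] <- exchange_series(bp$label, grid$T, grid$c_cat,
                                       k_obs, sigma)
  }
  out
}

#' Generate inversion-recovery profiles for a construct
#'
#' For every base pair and design condition, computes the true exchange rate
#' from the forward model and emits the corresponding inversion-recovery
#' intensity profile with additive Gaussian noise on the intensity ratios.
#' Pairs listed in the spec's `overlap` are additionally emitted as a summed
#' (averaged) profile under the joint label, emulating spectral overlap.
#'
#' @param spec a [construct_spec()].
#' @return list of [ir_profile()] objects.
#' @export
gen_ir_profiles <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  des <- spec$design
  grid <- expand.grid(T = celsius_to_kelvin(des$T_C),
                      c_cat = des$c_cat_mM * 1e-3)
  set.seed(spec$seed + 1L)
  profiles <- list()
  k_of <- function(label, T, c_cat) {
    row <- spec$base_pairs[spec$base_pairs$label == label, ]
    exchange_rate_model(T, c_cat, .bp_from_row(row), spec$catalysis)
  }
  emit <- function(label, dev, T, c_cat) {
    ratio <- 1 + dev + stats::rnorm(length(des$t_m)) * des$ir_noise
    profiles[[length(profiles) + 1]] <<-
      ir_profile(label, T, c_cat, des$t_m, ratio)
  }
  for (g in seq_len(nrow(grid))) {
    T <- grid$T[g]; cc <- grid$c_cat[g]
    for (label in spec$base_pairs$label) {
      dev <- ir_model(des$t_m, k_of(label, T, cc), des$R1_H, des$R1_W)
      emit(label, dev, T, cc)
    }
    for (pair in spec$overlap) {
      # equal-intensity resonances: the summed, renormalised profile has the
      # mean deviation of the two members
      dev <- (ir_model(des$t_m, k_of(pair[1], T, cc), des$R1_H, des$R1_W) +
              ir_model(des$t_m, k_of(pair[2], T, cc), des$R1_H, des$R1_W)) / 2
      emit(paste(pair, collapse = "/"), dev, T, cc)
    }
  }
  profiles
}

#' Generate a CD melting curve
#'
#' Two-state signal on the design's melting temperature grid plus additive
#' Gaussian noise of standard deviation `melting$noise_sd`.
#'
#' @param spec a [construct_spec()] whose `melting` truth is set.
#' @return a [melting_curve()].
#' @export
gen_melting_curve <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  m <- spec$melting
  if (is.null(m)) stop("spec carries no melting truth", call. = FALSE)
  fit <- melting_fit(m$dH_unf, m$dS_unf,
                     m$baseline_folded %||% c(0, -0.01),
                     m$baseline_unfolded %||% c(-12, 0.02))
  T <- celsius_to_kelvin(spec$design$melt_T_C)
  set.seed(spec$seed + 2L)
  noise <- stats::rnorm(length(T)) * (m$noise_sd %||% 0)
  melting_curve(T, two_state_signal(T, fit) + noise, label = spec$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct whose base pairs lie on a compensation line
#'
#' Draws `n` opening entropies uniformly over the span observed across
#' published hairpin base pairs (100..700 J/(mol K)) and places the
#' enthalpies on the compensation line `dH = Tc dS / 1000 + y0` plus
#' Gaussian scatter. Transition-state parameters and dipolar offsets are
#' assigned reasonable defaults. Used for compensation-recovery experiments
#' and for demonstrating the coincidence of compensation and melting
#' temperatures (pair it with a melting truth at `Tm = Tc`).
#'
#' @param n number of base pairs (labelled `BP1..BPn`).
#' @param Tc compensation temperature, K.
#' @param y0 offset, kJ/mol.
#' @param scatter SD of the enthalpy scatter about the line, kJ/mol.
#' @param seed RNG seed.
#' @param ... further arguments passed to [construct_spec()] (e.g. `design`,
#'   `catalysis`, `melting`).
#' @return a [construct_spec()] with the `eec` truth recorded.
#' @export
gen_eec_construct <- function(n, Tc, y0, scatter = 0, seed, ...) {
  set.seed(seed)
  dS <- sort(stats::runif(n, 100, 700))
  dH <- Tc * dS / 1000 + y0 + stats::rnorm(n, 0, scatter)
  bps <- data.frame(label = paste0("BP", seq_len(n)),
                    dH_diss = dH, dS_diss = dS,
                    dH_tr_int = 35, dS_tr_int = -30, d = 1.5)
  construct_spec(name = sprintf("eec-line-%dbp", n), base_pairs = bps,
                 eec = list(Tc = Tc, y0 = y0, scatter = scatter),
                 seed = seed + 1L, ...)
}
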