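# End-to-end self-validation: simulate a compensation-line construct under
# the standard experimental design, push every replicate through the global
# fit and Monte Carlo error machinery, and score parameter recovery against
# the generating truth.

#' Full-pipeline parameter-recovery experiment
#'
#' Generates a construct whose base pairs lie on a compensation line
#' (`dH = Tc dS/1000 + y0`), then for each replicate simulates exchange-rate
#' series on the standard design grid (temperature series at two catalyst
#' concentrations, multiplicative rate noise), fits every base pair globally,
#' estimates Monte Carlo errors, and refits the compensation line from the
#' fitted members.
#'
#' Scoring: a parameter counts as recovered when the fitted value lies within
#' twice its reported Monte Carlo error of the truth; the compensation
#' parameters are scored against twice their empirical standard error (the
#' standard deviation of the estimates over replicates — the Monte Carlo
#' estimate of the recovery's standard error).
#'
#' @param n_replicates number of simulated experiments.
#' @param n_members base pairs on the compensation line.
#' @param Tc,y0 generating compensation temperature (K) and offset (kJ/mol).
#' @param noise_frac relative rate noise of the simulated experiments.
#' @param seed master seed; construct and replicate seeds derive from it.
#' @param mc_iterations Monte Carlo iterations per replicate fit.
#' @param cfg optional [global_fit_config()] (its seed/mc settings are
#'   overridden per replicate).
#' @return list with `per_fit` (data frame: replicate, label, fitted values,
#'   MC errors, truth, hit flags), `coverage` (fraction of dH/dS values
#'   within 2 sigma), `eec` (data frame of per-replicate `Tc`, `y0`),
#'   `eec_summary` (means, empirical SEs, fractions within 2 empirical SEs
#'   of truth), and the generating `truth`.
#' @export
pipeline_recovery_experiment <- function(n_replicates = 50, n_members = 4,
                                         Tc = 322.55, y0 = 13,
                                         noise_frac = 0.05, seed = 20150504,
                                         mc_iterations = 100,
                                         cfg = global_fit_config()) {
  base <- gen_eec_construct(n_members, Tc = Tc, y0 = y0, scatter = 0,
                            seed = seed %% 1000000L + 17L,
                            catalysis = cfg$catalysis)
  truth <- base$base_pairs
  cfg$mc_iterations <- mc_iterations

  rows <- list(); eec_rows <- list()
  for (r in seq_len(n_replicates)) {
    spec <- construct_spec("replicate", truth, catalysis = cfg$catalysis,
                           design = list(noise_frac = noise_frac),
                           seed = seed %% 1000000L + 1000L * r)
    series <- gen_exchange_series(spec)
    fitted <- list()
    for (s in series) {
      fit <- fit_base_pair(s, cfg)
      cfg_r <- cfg
      cfg_r$seed <- seed %% 1000000L + 1000L * r +
        match(s$label, names(series))
      ens <- mc_errors(s, fit, cfg_r)
      tr <- truth[truth$label == s$label, ]
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, label = s$label,
        dH_hat = fit$dH_diss, dS_hat = fit$dS_diss,
        err_dH = unname(ens$errors["dH_diss"]),
        err_dS = unname(ens$errors["dS_diss"]),
        dH_true = tr$dH_diss, dS_true = tr$dS_diss,
        hit_dH = abs(fit$dH_diss - tr$dH_diss) <=
          2 * unname(ens$errors["dH_diss"]),
        hit_dS = abs(fit$dS_diss - tr$dS_diss) <=
          2 * unname(ens$errors["dS_diss"]))
      fitted[[s$label]] <- fit
    }
    ef <- fit_eec(fitted)
    eec_rows[[r]] <- data.frame(replicate = r, Tc = ef$Tc, y0 = ef$y0)
  }
  per_fit <- do.call(rbind, rows)
  eec <- do.call(rbind, eec_rows)
  se_Tc <- stats::sd(eec$Tc); se_y0 <- stats::sd(eec$y0)
  list(per_fit = per_fit,
       coverage = mean(c(per_fit$hit_dH, per_fit$hit_dS)),
       eec = eec,
       eec_summary = list(
         Tc_mean = mean(eec$Tc), Tc_se = se_Tc,
         y0_mean = mean(eec$y0), y0_se = se_y0,
         frac_Tc_within_2se = mean(abs(eec$Tc - Tc) <= 2 * se_Tc),
         frac_y0_within_2se = mean(abs(eec$y0 - y0) <= 2 * se_y0)),
       truth = truth, Tc = Tc, y0 = y0)
}

#' Type-I calibration of the compensation validity test
#'
#' Simulates the pure statistical-compensation artifact: member (dH, dS)
#' values drawn from a single error ellipse whose long axis has the slope of
#' the harmonic-mean experimental temperature, with matching per-member
#' Monte Carlo ensembles. Reports how often the validity test wrongly calls
#' the artifact "genuine".
#'
#' @param n_replicates number of simulated member sets.
#' @param n_members members per set.
#' @param T_obs experimental temperatures, K.
#' @param sd_dH enthalpy spread of the error ellipse, kJ/mol.
#' @param seed RNG seed.
#' @return list with `type1` (fraction of "genuine" verdicts) and
#'   `verdicts`.
#' @export
eec_type1_calibration <- function(n_replicates = 100, n_members = 5,
                                  T_obs = celsius_to_kelvin(seq(-5, 55, 3)),
                                  sd_dH = 15, seed = 20150504) {
  T_hm <- length(T_obs) / sum(1 / T_obs)
  S_err <- tcrossprod(c(sd_dH, sd_dH * 1000 / T_hm)) + diag(c(0.3, 3))^2
  L <- chol(S_err)
  draw <- function(n, mu)
    matrix(stats::rnorm(n * 2), n) %*% L + matrix(mu, n, 2, byrow = TRUE)
  set.seed(seed)
  verdicts <- vapply(seq_len(n_replicates), function(r) {
    centers <- draw(n_members, c(120, 350))
    df <- data.frame(label = paste0("B", seq_len(n_members)),
                     dH_diss = centers[, 1], dS_diss = centers[, 2])
    ens <- lapply(seq_len(n_members), function(i) {
      s <- draw(400, c(df$dH_diss[i], df$dS_diss[i]))
      structure(list(label = df$label[i],
                     samples = data.frame(dH_diss = s[, 1],
                                          dS_diss = s[, 2]),
                     corr_HS = stats::cor(s[, 1], s[, 2])),
                class = "mc_ensemble")
    })
    names(ens) <- df$label
    eec_validity_test(df, ens, fit_eec(df), T_obs)$verdict
  }, character(1))
  list(type1 = mean(verdicts == "genuine"), verdicts = verdicts)
}
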