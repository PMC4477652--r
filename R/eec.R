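# Enthalpy-entropy compensation (EEC) across the base pairs of a construct.
# A linear relation dH = Tc * dS + y0 across pairs means all member Gibbs
# energies coincide at the compensation temperature Tc, at the value y0.
# Because each individual fit produces strongly correlated (dH, dS)
# estimates, an apparent compensation line can arise purely from fitting
# error covariance ("statistical compensation"); the validity test guards
# against that artifact.

.thermo_frame <- function(thermos) {
  if (is.data.frame(thermos)) {
    stopifnot(all(c("label", "dH_diss", "dS_diss") %in% names(thermos)))
    df <- thermos
    if (is.null(df$err_dH)) df$err_dH <- NA_real_
    if (is.null(df$err_dS)) df$err_dS <- NA_real_
    return(df[, c("label", "dH_diss", "dS_diss", "err_dH", "err_dS")])
  }
  do.call(rbind, lapply(thermos, function(b) {
    stopifnot(inherits(b, "bp_thermo"))
    data.frame(label = b$label, dH_diss = b$dH_diss, dS_diss = b$dS_diss,
               err_dH = b$err$dH, err_dS = b$err$dS)
  }))
}

#' Fit the enthalpy-entropy compensation line
#'
#' Ordinary least squares of the opening enthalpy (kJ/mol) on the opening
#' entropy (kJ/(mol K)) across the selected base pairs. The slope is the
#' compensation temperature `Tc` (K) and the intercept the offset `y0`
#' (kJ/mol), interpretable as an average stacking enthalpy. An
#' MC-error-weighted variant (`weighted = TRUE`, weights `1/err_dH^2`) is
#' available; the unweighted fit is the default and reproduces published
#' compensation parameters from published tables.
#'
#' With fewer than three members, or when the entropy spread is below three
#' times the mean Monte Carlo entropy error, no line is identifiable and the
#' verdict is `"insufficient spread"`.
#'
#' @param thermos list of [base_pair_thermo()] objects, or a data frame with
#'   columns `label`, `dH_diss`, `dS_diss` (optionally `err_dH`, `err_dS`).
#' @param members optional character vector restricting the fit to a label
#'   subset.
#' @param weighted logical; weight by inverse squared MC enthalpy errors.
#' @return object of class `eec_fit`: `members`, `Tc` (K), `y0` (kJ/mol),
#'   `se_Tc`, `se_y0`, `r2`, `verdict` (`"untested"` until
#'   [eec_validity_test()] runs, or `"insufficient spread"`), `slope_GH`
#'   (display-only Gibbs-enthalpy slope `1 - 293.15/Tc`), `data`.
#' @export
fit_eec <- function(thermos, members = NULL, weighted = FALSE) {
  df <- .thermo_frame(thermos)
  if (!is.null(members)) {
    missing <- setdiff(members, df$label)
    if (length(missing))
      stop("members not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    df <- df[match(members, df$label), ]
  }
  df <- df[is.finite(df$dH_diss) & is.finite(df$dS_diss), ]
  df <- df[order(df$label), ]  # member-order invariance
  out <- list(members = df$label, Tc = NA_real_, y0 = NA_real_,
              se_Tc = NA_real_, se_y0 = NA_real_, r2 = NA_real_,
              verdict = "untested", slope_GH = NA_real_, weighted = weighted,
              data = df)
  if (nrow(df) < 3) {
    out$verdict <- "insufficient spread"
    return(structure(out, class = "eec_fit"))
  }
  w <- if (weighted) {
    if (any(!is.finite(df$err_dH)) || any(df$err_dH <= 0))
      stop("weighted fit requires finite positive err_dH for all members",
           call. = FALSE)
    1 / df$err_dH^2
  } else NULL
  fit <- stats::lm(dH_diss ~ I(dS_diss / 1000), data = df, weights = w)
  co <- stats::coef(fit)
  # exactly collinear members trigger R's "essentially perfect fit" caveat,
  # which is the expected situation for synthetic line constructs
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  out$Tc <- unname(co[2]); out$y0 <- unname(co[1])
  out$se_Tc <- unname(se[2]); out$se_y0 <- unname(se[1])
  out$r2 <- suppressWarnings(summary(fit)$r.squared)
  out$slope_GH <- 1 - 293.15 / out$Tc
  out$df_resid <- fit$df.residual
  if (all(is.finite(df$err_dS)) &&
      stats::sd(df$dS_diss) < 3 * mean(df$err_dS))
    out$verdict <- "insufficient spread"
  structure(out, class = "eec_fit")
}

#' @export
print.eec_fit <- function(x, ...) {
  cat(sprintf("EEC fit over %d members: ", length(x$members)))
  if (is.finite(x$Tc))
    cat(sprintf("Tc = %.1f K (%.1f degC) +/- %.1f, y0 = %.1f +/- %.1f kJ/mol, r2 = %.4f\n",
                x$Tc, kelvin_to_celsius(x$Tc), x$se_Tc, x$y0, x$se_y0, x$r2))
  else cat("no line fitted\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

# 1-sigma extent of an MC ensemble projected on the unit vector u in the
# (dS [kJ/(mol K)], dH [kJ/mol]) plane
.project_ensemble <- function(ens, u) {
  x <- cbind(ens$samples$dS_diss / 1000, ens$samples$dH_diss) %*% u
  c(center = mean(x), sd = stats::sd(x))
}

#' Validity test of an observed compensation line
#'
#' Two checks distinguish genuine compensation from the statistical artifact:
#' \describe{
#'   \item{ellipse separation}{the 1-sigma Monte Carlo ellipses of the
#'     members, projected onto the fitted line direction, must not mutually
#'     overlap: a line threaded through overlapping ellipses carries no
#'     information beyond the per-fit error covariance.}
#'   \item{harmonic-mean temperature (Krug-style)}{a spurious compensation
#'     slope produced by fitting error covariance concentrates near the
#'     harmonic mean of the experimental temperatures; the confidence
#'     interval of `Tc` must therefore exclude that harmonic mean.}
#' }
#' The verdict is `"genuine"` only if both applicable checks pass.
#'
#' @param thermos the member [base_pair_thermo()] list (or data frame).
#' @param ensembles named list of [mc_errors()] ensembles, one per member;
#'   members without an ensemble skip the separation check (with a notice).
#' @param fit the [fit_eec()] result under test.
#' @param T_obs experimental temperatures (K) underlying the individual fits.
#' @param conf confidence level of the `Tc` interval (default 0.95).
#' @return list with `verdict`, `krug` (`T_hm`, `ci`, `pass`), `separation`
#'   (`assessed`, `n_overlaps`, `pass`), and the updated `fit`.
#' @export
eec_validity_test <- function(thermos, ensembles, fit, T_obs, conf = 0.95) {
  stopifnot(inherits(fit, "eec_fit"))
  if (fit$verdict == "insufficient spread" || length(fit$members) < 3 ||
      !is.finite(fit$Tc)) {
    fit$verdict <- "insufficient spread"
    return(list(verdict = fit$verdict, krug = NULL, separation = NULL,
                fit = fit))
  }
  # (b) Krug-style harmonic-mean test
  T_hm <- length(T_obs) / sum(1 / T_obs)
  tq <- stats::qt(1 - (1 - conf) / 2, df = fit$df_resid)
  ci <- fit$Tc + c(-1, 1) * tq * fit$se_Tc
  krug_pass <- T_hm < ci[1] || T_hm > ci[2]
  krug <- list(T_hm = T_hm, ci = ci, pass = krug_pass)

  # (a) pairwise ellipse separation along the fitted line
  have <- intersect(fit$members, names(ensembles))
  separation <- list(assessed = FALSE, n_overlaps = NA_integer_, pass = NA)
  if (length(have) < length(fit$members)) {
    message("ellipse-separation check skipped: Monte Carlo ensembles ",
            "missing for ", paste(setdiff(fit$members, have), collapse = ", "))
    sep_ok <- TRUE
  } else {
    u <- c(1, fit$Tc) / sqrt(1 + fit$Tc^2)
    proj <- t(vapply(ensembles[fit$members], .project_ensemble, numeric(2),
                     u = u))
    ord <- order(proj[, "center"])
    gaps <- diff(proj[ord, "center"])
    touch <- proj[ord, "sd"][-length(ord)] + proj[ord, "sd"][-1]
    n_overlaps <- sum(gaps < touch)
    separation <- list(assessed = TRUE, n_overlaps = n_overlaps,
                       pass = n_overlaps == 0)
    sep_ok <- n_overlaps == 0
  }
  verdict <- if (krug_pass && sep_ok) "genuine"
             else "not distinguishable from statistical compensation"
  fit$verdict <- verdict
  list(verdict = verdict, krug = krug, separation = separation, fit = fit)
}

#' Construct-to-construct thermodynamic differences
#'
#' Matches base pairs of two constructs by label and reports the differences
#' (`b - a`) of opening enthalpy, entropy, Gibbs energy at 20 degC and the
#' entropic term `T ddS` at 20 degC. The identity
#' `ddG20 = ddH - 293.15 ddS / 1000` holds exactly for every record.
#' Unmatched labels are reported via a message and the `"unmatched"`
#' attribute, never dropped silently.
#'
#' @param a,b construct result sets: lists of [base_pair_thermo()] or data
#'   frames with `label`, `dH_diss`, `dS_diss`.
#' @return data frame of class `delta_delta` with columns `label`, `ddH`
#'   (kJ/mol), `ddS` (J/(mol K)), `ddG20`, `TddS20` (kJ/mol).
#' @export
delta_delta <- function(a, b) {
  fa <- .thermo_frame(a); fb <- .thermo_frame(b)
  shared <- intersect(fa$label, fb$label)
  unmatched <- union(setdiff(fa$label, fb$label), setdiff(fb$label, fa$label))
  if (length(unmatched))
    message("labels without a counterpart: ", paste(unmatched, collapse = ", "))
  ia <- match(shared, fa$label); ib <- match(shared, fb$label)
  ddH <- fb$dH_diss[ib] - fa$dH_diss[ia]
  ddS <- fb$dS_diss[ib] - fa$dS_diss[ia]
  out <- data.frame(label = shared, ddH = ddH, ddS = ddS,
                    ddG20 = ddH - 293.15 * ddS / 1000,
                    TddS20 = 293.15 * ddS / 1000)
  attr(out, "unmatched") <- unmatched
  class(out) <- c("delta_delta", class(out))
  out
}

#' Gibbs energies of the members at the compensation temperature
#'
#' Evaluates each member's linear Gibbs-energy trace at `Tc`. For members on
#' an exact compensation line all values equal `y0`; the residual spread at
#' `Tc` (compared with the spread at 20 degC) quantifies how sharply the
#' stabilities equalise at the compensation temperature.
#'
#' @param thermos member set (list of [base_pair_thermo()] or data frame).
#' @param fit a [fit_eec()] result with finite `Tc`.
#' @return list with `table` (label, `dG_Tc`, `dG_20`), `spread_Tc`,
#'   `spread_20` (standard deviations, kJ/mol), `Tc`, `y0`.
#' @export
gibbs_equalization_report <- function(thermos, fit) {
  stopifnot(inherits(fit, "eec_fit"))
  if (!is.finite(fit$Tc)) stop("fit carries no compensation line", call. = FALSE)
  df <- .thermo_frame(thermos)
  df <- df[df$label %in% fit$members, ]
  tab <- data.frame(label = df$label,
                    dG_Tc = gibbs_energy(fit$Tc, df$dH_diss, df$dS_diss),
                    dG_20 = gibbs_energy(293.15, df$dH_diss, df$dS_diss))
  list(table = tab,
       spread_Tc = if (nrow(tab) > 1) stats::sd(tab$dG_Tc) else 0,
       spread_20 = if (nrow(tab) > 1) stats::sd(tab$dG_20) else 0,
       Tc = fit$Tc, y0 = fit$y0)
}
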