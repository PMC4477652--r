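# Independent oracles and small fixture builders. The oracle re-composes the
# EX2 observable directly from the textbook relations (opening equilibrium,
# Eyring transfer, catalyst-linear external transfer, dipolar offset) with
# its own constants, so it shares no code path with exchange_rate_model().

oracle_kex <- function(T, c_cat, dH, dS, dHt, dSt, d, cat) {
  Rg <- 8.31446261815324; kB <- 1.380649e-23; h <- 6.62607015e-34
  K <- exp(-(dH * 1000 - T * dS) / (Rg * T))
  k_int <- (kB * T / h) * exp(-(dHt * 1000 - T * dSt) / (Rg * T))
  k_ntp <- (kB * T / h) *
    exp(-(cat$dH_tr_ntp * 1000 - T * cat$dS_tr_ntp) / (Rg * T))
  k_ext <- cat$d_dif * k_ntp * c_cat / cat$c_ref
  (k_int + k_ext) / (1 + 1 / K) + d
}

# bivariate normal draws via Cholesky (enough for ensemble fixtures)
mvrnorm2 <- function(n, mu, S) {
  L <- chol(S)
  matrix(stats::rnorm(n * 2), n) %*% L + matrix(mu, n, 2, byrow = TRUE)
}

# hand-built MC ensemble with a prescribed (dH, dS) covariance
fake_ensemble <- function(label, dH, dS, S, n = 400) {
  s <- mvrnorm2(n, c(dH, dS), S)
  structure(list(label = label,
                 samples = data.frame(dH_diss = s[, 1], dS_diss = s[, 2],
                                      dH_tr_int = 0, dS_tr_int = 0, d = 0),
                 errors = c(dH_diss = stats::sd(s[, 1]),
                            dS_diss = stats::sd(s[, 2])),
                 corr_HS = stats::cor(s[, 1], s[, 2]),
                 n = n, n_failed = 0L),
            class = "mc_ensemble")
}

# exchange series simulated from known truth on the standard design grid
sim_series <- function(label, dH, dS, dHt = 35, dSt = -30, d = 1.5,
                       cat = catalysis_model(), noise = 0, seed = 1,
                       T_C = seq(-5, 55, by = 3), c_mM = c(2, 29)) {
  bp <- base_pair_thermo(label, dH, dS, dHt, dSt, d)
  TK <- celsius_to_kelvin(T_C)
  grid <- expand.grid(T = TK, c_cat = c_mM * 1e-3)
  k <- exchange_rate_model(grid$T, grid$c_cat, bp, cat)
  set.seed(seed)
  k_obs <- if (noise > 0) pmax(k * (1 + stats::rnorm(length(k)) * noise), 0) else k
  sigma <- pmax(noise * k, 1e-9 * pmax(k, 1))
  exchange_series(label, grid$T, grid$c_cat, k_obs, sigma)
}

log_tm_grid <- function(n = 12, lo = 0.002, hi = 3)
  exp(seq(log(lo), log(hi), length.out = n))
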