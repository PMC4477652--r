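# Compensation-line fitting, the validity test against the statistical
# artifact, construct comparison, and Gibbs equalisation at Tc.

test_that("exactly collinear members are recovered to machine precision", {
  Tc <- 322.55; y0 <- 13
  dS <- c(120, 280, 450, 620)
  thermos <- lapply(seq_along(dS), function(i)
    base_pair_thermo(paste0("B", i), Tc * dS[i] / 1000 + y0, dS[i]))
  fit <- fit_eec(thermos)
  expect_equal(fit$Tc, Tc, tolerance = 1e-12)
  expect_equal(fit$y0, y0, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # member ordering is irrelevant
  fit_rev <- fit_eec(rev(thermos))
  expect_equal(fit_rev$Tc, fit$Tc)
  expect_equal(fit_rev$members, fit$members)

  # unknown member subset is an error, a valid subset restricts the fit
  expect_error(fit_eec(thermos, members = c("B1", "nope")), "not found")
  expect_length(fit_eec(thermos, members = c("B1", "B2", "B3"))$members, 3)
})

test_that("the compensation slope is recovered without bias as noise vanishes", {
  Tc <- 310
  ests <- vapply(1:20, function(r) {
    spec <- gen_eec_construct(6, Tc = Tc, y0 = 10, scatter = 0.01,
                              seed = 400 + r)
    fit_eec(data.frame(label = spec$base_pairs$label,
                       dH_diss = spec$base_pairs$dH_diss,
                       dS_diss = spec$base_pairs$dS_diss))$Tc
  }, numeric(1))
  expect_lt(abs(mean(ests) - Tc), 1)
})

test_that("insufficient spread is declared for thin member sets", {
  two <- lapply(1:2, function(i) base_pair_thermo(paste0("B", i),
                                                 100 + i, 300))
  expect_identical(fit_eec(two)$verdict, "insufficient spread")

  # spread below three mean entropy errors
  df <- data.frame(label = paste0("B", 1:4),
                   dH_diss = c(100, 101, 100.5, 100.2),
                   dS_diss = c(300, 303, 301, 302),
                   err_dH = rep(5, 4), err_dS = rep(30, 4))
  expect_identical(fit_eec(df)$verdict, "insufficient spread")
})

test_that("validity test certifies genuine compensation and rejects the artifact", {
  T_obs <- celsius_to_kelvin(seq(-5, 55, by = 3))
  T_hm <- length(T_obs) / sum(1 / T_obs)

  # positive control: wide ladder on a line far from the harmonic mean,
  # tight well-separated ellipses
  Tc <- 322.55; y0 <- 13
  S_fit <- tcrossprod(c(2, 2 * 1000 / Tc)) + diag(c(0.05, 0.5))^2
  set.seed(501)
  dS <- seq(100, 700, length.out = 5)
  dH <- Tc * dS / 1000 + y0 + rnorm(5, 0, 0.5)
  df <- data.frame(label = paste0("B", 1:5), dH_diss = dH, dS_diss = dS)
  ens <- lapply(1:5, function(i)
    fake_ensemble(df$label[i], dH[i], dS[i], S_fit))
  names(ens) <- df$label
  v <- eec_validity_test(df, ens, fit_eec(df), T_obs)
  expect_identical(v$verdict, "genuine")
  expect_true(v$krug$pass)
  expect_true(v$separation$pass)

  # negative control: members drawn from one error ellipse whose long axis
  # slope equals the harmonic-mean temperature (pure statistical
  # compensation); type-I rate of "genuine" verdicts stays below 5%
  sd_dH <- 15
  S_err <- tcrossprod(c(sd_dH, sd_dH * 1000 / T_hm)) + diag(c(0.3, 3))^2
  set.seed(502)
  verdicts <- vapply(1:100, function(r) {
    centers <- mvrnorm2(5, c(120, 350), S_err)
    dfn <- data.frame(label = paste0("B", 1:5), dH_diss = centers[, 1],
                      dS_diss = centers[, 2])
    ensn <- lapply(1:5, function(i)
      fake_ensemble(dfn$label[i], dfn$dH_diss[i], dfn$dS_diss[i], S_err))
    names(ensn) <- dfn$label
    eec_validity_test(dfn, ensn, fit_eec(dfn), T_obs)$verdict
  }, character(1))
  expect_lt(mean(verdicts == "genuine"), 0.05)

  # two members only: no verdict beyond insufficient spread
  v2 <- eec_validity_test(df[1:2, ], ens[1:2], fit_eec(df[1:2, ]), T_obs)
  expect_identical(v2$verdict, "insufficient spread")

  # missing ensembles: separation check skipped with a notice
  expect_message(
    v3 <- eec_validity_test(df, ens[1:3], fit_eec(df), T_obs),
    "skipped")
  expect_false(v3$separation$assessed)
})

test_that("delta_delta honours its arithmetic identity and matching contract", {
  a <- hsp17_table("hsp17"); b <- hsp17_table("hsp17rep")
  a <- a[is.finite(a$dH_diss), ]; b <- b[is.finite(b$dH_diss), ]
  expect_message(dd <- delta_delta(a, b), "without a counterpart")
  expect_true(all(c("U37", "U7/U37") %in% attr(dd, "unmatched")))
  # the 20 degC identity holds exactly for every emitted record
  expect_equal(dd$ddG20, dd$ddH - 293.15 * dd$ddS / 1000)
  expect_equal(dd$TddS20, 293.15 * dd$ddS / 1000)

  # identical inputs: all differences are zero
  dd0 <- delta_delta(a, a)
  expect_true(all(abs(c(dd0$ddH, dd0$ddS, dd0$ddG20)) == 0))
})

test_that("member stabilities equalise at the compensation temperature", {
  Tc <- 322.55; y0 <- 13
  dS <- c(120, 280, 450, 620)
  exact <- lapply(seq_along(dS), function(i)
    base_pair_thermo(paste0("B", i), Tc * dS[i] / 1000 + y0, dS[i]))
  fit <- fit_eec(exact)
  rep_exact <- gibbs_equalization_report(exact, fit)
  expect_equal(rep_exact$table$dG_Tc, rep(y0, 4), tolerance = 1e-10)
  expect_equal(rep_exact$spread_Tc, 0, tolerance = 1e-10)

  # published stem-II members: tighter at Tc than at 20 degC
  t1 <- hsp17_table("hsp17")
  fit1 <- fit_eec(t1, members = eec_members("hsp17"))
  rep1 <- gibbs_equalization_report(t1[is.finite(t1$dH_diss), ], fit1)
  expect_lt(rep1$spread_Tc, rep1$spread_20)

  # single member: trivially its own value, zero spread
  rep_one <- gibbs_equalization_report(exact[1], fit)
  expect_equal(nrow(rep_one$table), 1)
  expect_equal(rep_one$spread_Tc, 0)
})
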