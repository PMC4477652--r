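# Forward-model layer: opening equilibrium, Eyring transfer, external
# catalysis, and their EX2 composition.

test_that("opening equilibrium constant follows the van't Hoff form", {
  # dG = 0 forces K = 1, however it is decomposed
  expect_equal(k_diss(310, dH = 310 * 0.5, dS = 500), 1)
  expect_equal(k_diss(293.15, 0, 0), 1)

  # direct scalar evaluation with published G28 parameters (frozen oracle)
  expect_equal(k_diss(293.15, 193.5, 561.9), 7.4497221483074e-06,
               tolerance = 1e-12)

  # strictly increasing in T whenever dH > 0
  Tg <- seq(263, 333, by = 1)
  expect_true(all(diff(k_diss(Tg, 100, 300)) > 0))
  expect_true(all(diff(k_diss(Tg, 193.5, 561.9)) > 0))

  expect_error(k_diss(-5, 100, 300), "positive")
})

test_that("gibbs_energy does the unit bookkeeping of the tables", {
  expect_equal(gibbs_energy(293.15, 193.5, 561.9), 28.779015)
  expect_equal(gibbs_energy(293.15, 277.8, 781.2), 48.79122)
  expect_equal(gibbs_energy(293.15, 0, 0), 0)
  # consistency with the equilibrium constant: K = exp(-dG/RT)
  dG <- gibbs_energy(293.15, 148.4, 416.1)
  expect_equal(k_diss(293.15, 148.4, 416.1),
               exp(-dG * 1000 / (physical_constants()$R * 293.15)),
               tolerance = 1e-12)
})

test_that("eyring_rate reproduces the attempt frequency and survives extremes", {
  # zero activation barrier leaves the kB T / h prefactor
  expect_equal(eyring_rate(293.15, 0, 0), 6108254896003.48, tolerance = 1e-9)
  # frozen log-space oracle value
  expect_equal(eyring_rate(293.15, 60, -50), 0.30437207570389,
               tolerance = 1e-12)
  # infinite barrier underflows to zero instead of overflowing
  expect_equal(eyring_rate(293.15, 1e6, 0), 0)
  expect_true(is.finite(eyring_rate(400, 5, 200)))
})

test_that("external catalysis is linear in catalyst and term-wise correct", {
  cat <- catalysis_model(dH_tr_ntp = 28, dS_tr_ntp = -35, d_dif = 1.3,
                         c_ref = 1e-3)
  expect_equal(external_catalysis_rate(293.15, 0, cat), 0)
  r1 <- external_catalysis_rate(293.15, 2e-3, cat)
  expect_equal(external_catalysis_rate(293.15, 4e-3, cat), 2 * r1)
  # term-by-term: d_dif x Eyring(NTP) x c/c_ref
  expect_equal(r1, 1.3 * eyring_rate(293.15, 28, -35) * 2e-3 / 1e-3,
               tolerance = 1e-14)
  expect_error(external_catalysis_rate(293.15, -1e-3, cat), "non-negative")
})

test_that("exchange_rate_model has the EX2 limits and stays above the offset", {
  cat <- catalysis_model()
  # fully open pair: transfer-limited rate plus offset
  open_bp <- base_pair_thermo("open", dH_diss = -100, dS_diss = 0, 40, -20, 2)
  expect_equal(exchange_rate_model(293.15, 2e-3, open_bp, cat),
               eyring_rate(293.15, 40, -20) +
                 external_catalysis_rate(293.15, 2e-3, cat) + 2,
               tolerance = 1e-12)
  # no transfer at all: the dipolar offset remains
  closed <- base_pair_thermo("x", 120, 300, dH_tr_int = 290, dS_tr_int = -400,
                             d = 1.7)
  expect_equal(exchange_rate_model(273.15, 0, closed, cat), 1.7,
               tolerance = 1e-6)

  bp <- base_pair_thermo("G28", 193.5, 561.9, 35, -30, 1.5)
  TK <- celsius_to_kelvin(seq(-5, 55, by = 3))
  # non-decreasing in catalyst at fixed T; never below d
  k_lo <- exchange_rate_model(TK, 2e-3, bp, cat)
  k_hi <- exchange_rate_model(TK, 29e-3, bp, cat)
  expect_true(all(k_hi >= k_lo))
  expect_true(all(k_lo >= bp$d))
})

test_that("exchange_rate_model equals the independent composition oracle", {
  set.seed(99)
  for (i in 1:100) {
    dH <- runif(1, 30, 300); dS <- runif(1, 50, 800)
    dHt <- runif(1, 10, 100); dSt <- runif(1, -100, 50)
    d <- runif(1, 0, 5)
    cat <- catalysis_model(dH_tr_ntp = runif(1, 15, 45),
                           dS_tr_ntp = runif(1, -80, 0),
                           d_dif = runif(1, 0.5, 2))
    T <- runif(1, 268, 330); cc <- runif(1, 0, 0.05)
    bp <- base_pair_thermo("r", dH, dS, dHt, dSt, d)
    expect_equal(exchange_rate_model(T, cc, bp, cat),
                 oracle_kex(T, cc, dH, dS, dHt, dSt, d, cat),
                 tolerance = 1e-12)
  }
})

test_that("gibbs_curve traces cross at the closed-form temperature", {
  g27 <- base_pair_thermo("G27", 148.4, 416.1)
  g28 <- base_pair_thermo("G28", 193.5, 561.9)
  # crossing at (dH1 - dH2) / (dS1 - dS2)
  Tx <- 309.327846364883
  c27 <- gibbs_curve(g27, Tx); c28 <- gibbs_curve(g28, Tx)
  expect_equal(c27$dG, c28$dG, tolerance = 1e-12)

  # members of one compensation line all meet at (Tc, y0)
  Tc <- 322.55; y0 <- 13
  for (dS in c(150, 400, 650)) {
    bp <- base_pair_thermo("m", Tc * dS / 1000 + y0, dS)
    expect_equal(gibbs_curve(bp, Tc)$dG, y0, tolerance = 1e-12)
  }
  # zero entropy: flat trace at dH
  flat <- base_pair_thermo("f", 42, 0)
  expect_equal(gibbs_curve(flat, c(280, 300, 320))$dG, rep(42, 3))
})

test_that("domain types enforce their invariants", {
  expect_error(base_pair_thermo("x", NA, 100), "finite")
  expect_error(base_pair_thermo("x", 100, 300, d = -1), "non-negative")
  expect_true(base_pair_thermo("U7/U37", 80, 200)$averaged)
  expect_error(catalysis_model(d_dif = 0), "positive")
  expect_error(exchange_series("x", c(280, 290), c(1e-3, 1e-3),
                               c(1, 2), c(0, 0.1)), "sigma")
  expect_error(exchange_series("x", c(280, -1), c(1e-3, 1e-3),
                               c(1, 2), c(0.1, 0.1)), "positive")
})
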