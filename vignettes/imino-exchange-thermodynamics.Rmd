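---
title: "Base-pair thermodynamics from imino proton exchange: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-pair thermodynamics from imino proton exchange: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnathermo)
```

## The exchange model and its assumptions

An imino proton (the N–H of guanine or uracil) exchanges with water only
from the open state of its base pair. In the EX2 regime the pair opens and
closes many times before a transfer succeeds, so the pair equilibrates
(`K_Diss`) before exchange and the observable rate factorises:

$$k_\mathrm{ex}(T, c) \;=\; \frac{k_\mathrm{Tr,int}(T) + k_\mathrm{Tr,ext}(T, c)}
{1 + 1/K_\mathrm{Diss}(T)} \;+\; d$$

with

* `K_Diss(T) = exp(-(ΔH_diss − T ΔS_diss)/(RT))` — van't Hoff/Gibbs–Helmholtz
  form under the assumption that opening enthalpy and entropy are
  temperature-independent (no heat-capacity term; the linearity of the
  van't Hoff plot produced by `van_t_hoff_points()` is the empirical check);
* `k_Tr,int(T) = (k_B T/h) exp(-(ΔH^‡ − T ΔS^‡)/(RT))` — internal catalysis
  by neighbouring-base acceptor groups, an Eyring rate;
* `k_Tr,ext(T, c) = d_dif · k_NTP(T) · c/c_ref` — external catalysis by a
  dissolved base (HPO₄²⁻ here), calibrated on the exchange of free
  mononucleotides and linear in catalyst concentration;
* `d` — a dipolar cross-relaxation contribution that is not chemical
  exchange; it appears as the low-temperature plateau of every rate profile.

`exchange_rate_model()` composes these pieces; the open-state population
`1/(1 + exp(+ΔG/RT))` and the Eyring exponent are evaluated in forms that
underflow gracefully for very stable pairs and extreme activation
parameters.

Assumptions worth keeping in mind: EX2 kinetics (diagnosed operationally by
`ex2_consistency_check()`: one parameter set must explain both catalyst
concentrations, and rates must actually respond to the catalyst — saturated,
concentration-independent exchange is the EX1 signature); catalyst access
unhindered by structure; monomeric hairpins (no bimolecular corrections).

### External-catalysis parameters

The NTP transition-state enthalpy/entropy, the diffusion correction factor
`d_dif` and the reference concentration are configuration inputs
(`catalysis_model()`). The shipped defaults (`ΔH = 30` kJ/mol,
`ΔS = −40` J/(mol K), `d_dif = 1`, `c_ref = 1` mM) are nominal placeholders
that give external transfer rates of realistic magnitude (~10⁵ s⁻¹ per mM
at 20 °C); for real data they must be replaced by experimentally determined
values for UTP/GTP under the buffer in use. All synthetic-data tests inject
known values, so no correctness claim rests on the defaults. Concentration
scaling is taken as linear; only HPO₄²⁻ catalysis is modelled (at pH 6.8 the
OH⁻ pathway is comparatively minor and is not separated out).

## Inversion-recovery fitting

Water magnetization is inverted and its transfer to the imino proton is
followed over the mixing time; assuming perfect inversion,

$$\frac{I(t_m)}{I(0)} - 1 = -2 k_\mathrm{ex}
\frac{e^{-R_{1,H} t_m} - e^{-R_{1,W} t_m}}{R_{1,W} - R_{1,H}}$$

`ir_model()` switches to the analytic limit `−2 k_ex t_m e^{−R_1 t_m}` when
the two relaxation rates come within a relative 10⁻⁶ of each other, so the
surface is continuous. The expression is exactly symmetric in
`R1_H ↔ R1_W`; the two rates are therefore not identifiable from profile
shape alone, and results are reported under the convention `R1_W ≤ R1_H`
(water relaxes more slowly than an exchange-broadened imino proton in this
regime), with the option to pin `R1_W` from configuration. Fits are
unweighted least squares (profile intensities carry no per-point errors),
multi-started from five log-spaced `k_ex` guesses. Overlapped resonances
are fitted jointly on their summed profile, yielding an average rate under
a joint label that the downstream stability fit treats as a
shared-stability (averaged) pair.

The reported `sigma_kex` comes from the local Gauss–Newton covariance at
the optimum. With a dozen or two mixing times the ±2σ interval has the
finite-sample coverage of a t-statistic (~92–94%), not the asymptotic 95%;
the property tests score coverage accordingly.

## The global base-pair fit

`fit_base_pair()` minimises the 1/σ²-weighted residuals of the exchange
model jointly over both catalyst-concentration series. Five parameters are
free per base pair: `ΔH_diss`, `ΔS_diss`, `ΔH^‡_int`, `ΔS^‡_int`, `d`.
Choices:

* **Optimizer** — bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), with
  bounds `ΔH_diss ∈ [0, 600]` kJ/mol, `ΔS_diss ∈ [0, 1600]` J/(mol K),
  `ΔH^‡ ∈ [0, 300]`, `ΔS^‡ ∈ [−500, 500]`, `d ∈ [0, 20]` s⁻¹ — generous
  margins around the spread published for RNA hairpin base pairs.
* **Initialisation** — a van't Hoff linearisation of the high-rate points
  (with `d` pinned near the low-temperature plateau and the external rate
  as the transfer estimate) seeds `(ΔH, ΔS)`; seven deterministic start
  variations preserve the implied ΔG(20 °C) while scaling the enthalpy,
  and the lowest-residual fit wins. On noiseless synthetic data the round
  trip is exact to optimizer tolerance (~10⁻¹⁵ relative).
* **Degenerate inputs** — fewer than two concentrations is refused; fewer
  than four temperatures per concentration is refused; a span under 15 K is
  flagged `weak_identifiability`; a series whose rate amplitude stays below
  four median standard errors is flagged `not_determinable` (its stability
  is reported only as an upper limit, mirroring how terminal base pairs
  behave in practice).

### Monte Carlo errors

Reported errors are sample standard deviations over an ensemble of refits
in which every rate is Gaussian-noised by its own standard error and every
catalysis parameter by its declared uncertainty (`mc_errors()`; warm-started
from the best fit; an iteration count of at least 100 is required for
reported errors, and more than 20% non-convergent refits aborts with a
diagnostic). A 68% percentile interval is reported alongside as a
robustness check. The (ΔH, ΔS) sample covariance defines the 1σ confidence
ellipse; its extreme tilt (within-fit correlation typically > 0.99) is
exactly the error covariance that makes the statistical-compensation
artifact dangerous, which is why the ellipses are carried forward into the
compensation analysis.

## Enthalpy–entropy compensation

`fit_eec()` regresses ΔH (kJ/mol) on ΔS (kJ/(mol K)) by ordinary least
squares: the slope is the compensation temperature `Tc` (K), the intercept
`y0` (kJ/mol) an approximation of the average stacking enthalpy. Unweighted
regression is the default because it reproduces published compensation
parameters from published tables; an MC-error-weighted variant sits behind
a flag. The package deliberately reports only the EEC fit quantitatively;
the Gibbs–enthalpy correlation slope is derived (`1 − 293.15/Tc`) for
display.

`eec_validity_test()` certifies a line as `"genuine"` only if (a) the
members' 1σ ellipses, projected on the line direction, are mutually
separated — a line threaded through overlapping ellipses carries no
information beyond per-fit error covariance — and (b) the confidence
interval of `Tc` excludes the harmonic mean of the experimental
temperatures, where artifact slopes concentrate (a Krug-style check; the
exact historical test statistics vary, and this implementation is the
documented stand-in, flagged as such in reports). Entropy spread below
three mean MC errors yields `"insufficient spread"` instead of a verdict
either way. Calibration: on constructed artifact data (members drawn from
one ellipse with slope at the harmonic-mean temperature) the false
"genuine" rate is below 5%; on-line positive controls with separated
ellipses are certified essentially always (`eec_type1_calibration()`).

## Two-state melting

`fit_melting()` fits six parameters simultaneously: `ΔH_unf`, `ΔS_unf` and
one linear baseline per state (the standard reading of a linear
temperature-dependent CD baseline; intercepts are quoted at 0 °C, slopes
per K). `Tm = 1000·ΔH_unf/ΔS_unf` is a derived identity, never a free
parameter. Multi-start runs over a grid of Tm guesses with baseline seeds
from the outer 20% of the temperature range. A transition amplitude below
three times the fit rmse is flagged `broad_transition`; a fitted Tm
outside the data range (or an enthalpy collapsing to its bound) is flagged
`no_transition`. Unweighted raw data are fitted. Fraction unfolded is the
baseline-corrected, normalised signal clipped to [0, 1], masked where the
baselines are closer than three rmse.

## Synthetic data: what it does and does not emulate

The generators copy the experimental design: temperatures from −5 to 55 °C
in 3 °C steps at 2 and 29 mM HPO₄²⁻, multiplicative Gaussian rate noise
(default 5%, the recorded σ being the true relative error), additive noise
on inversion-recovery ratios (1%) and on CD signals, and compensation-line
constructs with entropies drawn uniformly over 100–700 J/(mol K) — the span
published for hairpin base pairs. Overlapped-resonance scenarios emit the
summed profile of two members.

Passing recovery tests on these data shows that the estimators are
consistent and their error bars calibrated *under the model's own
assumptions*. They do not probe: non-EX2 kinetics beyond one EX1-like
negative control, heat-capacity effects, baseline nonlinearity, peak
integration errors, or temperature-calibration drift — all of which real
data may contain.

## Numerical and design choices

* 20 °C is 293.15 K everywhere; files carry °C, internals Kelvin; energies
  kJ/mol, entropies J/(mol K), exponents evaluated in consistent J units.
* Physical constants are fixed CODATA values, not user-overridable.
* Every stochastic routine takes an explicit seed (default 20150504);
  generators require one.
* The validation harness (`pipeline_recovery_experiment()`) runs 50
  replicates of a 4-member compensation construct at the standard design —
  a problem size that keeps a full self-validation under a minute on one
  CPU while giving binomial resolution of a few percent on coverage. Its
  compensation recovery is scored against twice the *empirical* standard
  error (the SD of the estimate over replicates), the Monte Carlo estimate
  of the recovery's standard error, which is better determined than a
  per-replicate regression SE on two residual degrees of freedom.
* The shared-stability fit flags divergence via the reduced chi-square
  exceeding its 99.9% quantile: a single stability that cannot explain the
  averaged rates of a genuinely heterogeneous pair shows up as gross
  misfit (only when the two members differ in enthalpy enough to have
  distinct temperature onsets; near-parallel stability curves average
  benignly, which is precisely the regime in which averaging is justified).

## Known limitations

* Stabilities of pairs whose resonances broaden away before four usable
  temperatures are accessible are upper limits, not estimates.
* The NTP catalysis defaults are placeholders (see above).
* The compensation validity test controls the classic artifact; it cannot
  rule out subtler shared systematics (e.g. a common mis-set catalysis
  model biasing all members coherently).
* Single apparent two-state melting is assumed; overlapping transitions
  are fitted as one broad transition and flagged, not deconvolved.
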