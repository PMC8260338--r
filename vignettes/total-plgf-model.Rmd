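---
title: "Computing total PlGF from free PlGF and sFlt-1: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing total PlGF from free PlGF and sFlt-1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plgfbind)
```

## The binding model

Serum PlGF partitions between a free pool, which is what automated
immunoassays report, and a pool complexed with its decoy receptor sFlt-1.
The package treats this as a classic 1:1 drug–receptor equilibrium. In
molar units (pmol/L), with free ligand $D$, total receptor $R_t$ (the
measured sFlt-1, free plus complexed), complex $DR$ and dissociation
constant $K_D$:

$$K_D = \frac{D\,(R_t - DR)}{DR}, \qquad
  DR = \frac{D\,R_t}{K_D + D}, \qquad
  \text{total PlGF} = D + DR.$$

Assumptions, stated explicitly:

* **1:1 stoichiometry.** One sFlt-1 binds one PlGF; no receptor
  dimerization.
* **No competing ligands.** VEGF also binds sFlt-1; a competitive
  multi-ligand model would need assays and affinities that routine panels
  do not provide, and the two-parameter model predicts measured totals
  well across very different clinical states. This is a deliberate
  simplification, not an oversight.
* **Measured sFlt-1 is the total receptor pool** ($R_t$), with no
  correction for epitope masking by bound ligand.
* **Heating is a perfect total-PlGF assay.** Thermal dissociation destroys
  sFlt-1 without degrading PlGF, so the post-heating readout equals
  $D + DR$ in mass units.

Mass concentrations (pg/mL, the only unit accepted at the I/O boundary)
convert to pmol/L via fixed molecular weights: 34 kDa for PlGF, 100 kDa
for sFlt-1 (`mass_to_molar()`, `molar_to_mass()`). Whether 34 kDa refers
to the assay-detected monomer or homodimer is not resolved by the source
material; the constant is taken at face value, and all published
group-level values are consistent with it.

## Estimating $K_D$

When a sample has both free (unheated) and total (heated) PlGF, the
complex is $DR = \text{molar}(total - free)$ and $K_D$ follows directly
(`kd_from_sample()`). A sample is usable only if $total > free$ (some
complex exists) and the implied complex is below the receptor pool;
`estimate_mean_kd()` applies this filter, counts exclusions, and returns
the arithmetic mean with SEM $= s/\sqrt{n}$. The arithmetic mean matches
the study-style summary; a geometric mean is available
(`type = "geometric"`) because per-sample $K_D$ values are right-skewed,
but it is not the default. The package default `DEFAULT_KD = 50` pmol/L is
the cohort-mean estimate and sits inside the independently reported
Flt-1 ligand affinity range (≈20–200 pmol/L); every function accepts an
override.

## The inverse quadratic

Simulation and the spike experiment need free from total. Substituting
the occupancy into $T = D + DR$ gives

$$D^2 + (K_D + R_t - T)\,D - K_D\,T = 0,$$

whose unique non-negative root is taken in the cancellation-free form
$D = 2 K_D T \,/\, (b + \sqrt{b^2 + 4 K_D T})$ when $b = K_D + R_t - T > 0$
— important when $K_D \ll R_t$, where the naive $(-b+\sqrt{\cdot})/2$ loses
precision. Closed forms are verified against a brute-force bisection
solver of the mass-action balance to $10^{-6}$ relative on 1000 random
states in the test suite.

## In-silico spike experiment

`equilibrate_after_spike()` mimics the wet validation design: ligand is
added (default 1693 pg/mL of final mixture), the new total re-equilibrates
with sFlt-1, the pre-heating readout is the equilibrium free ligand and
the post-heating readout is the full new total. In high-imbalance serum
(ratio ≥ 85) most of the spike is sequestered — the detected free
increase is far below the added amount — while heating recovers
endogenous + added exactly. `spike_recovery()` is the corresponding
bookkeeping quotient.

## Statistics

The study-style statistical toolbox mirrors common clinical-research
practice:

* `compare_two()` gates on Shapiro–Wilk at $\alpha = 0.05$ per group (the
  global significance threshold; the gate level is not separately
  specified in the source and is exposed as `alpha_normality`): Student
  t when both groups pass, Mann–Whitney U otherwise. The Mann–Whitney
  p-value is exact — full enumeration of all $\binom{n_1+n_2}{n_1}$
  assignments — when both groups have $n \le 8$, else the normal
  approximation with tie correction. Setting `alpha_normality = 1` forces
  the nonparametric branch.
* `compare_groups()` runs ANOVA or Kruskal–Wallis under the same gate,
  with Bonferroni-corrected pairwise follow-ups (t or Mann–Whitney per
  pair). Dunn's rank z-test is available (`posthoc = "dunn"`); which post
  hoc the original analyses used is ambiguous, so neither is asserted as
  canonical.
* `spearman_correlation()` returns exact permutation p-values for
  $n \le 10$ (all $n!$ permutations, chunked by first element to bound
  memory) and the t-approximation above that.
* `identity_line_fit()` reads "not different from the line of identity"
  as: OLS of predicted on measured with 95% CIs; compatible iff the slope
  CI contains 1 and the intercept CI contains 0. This is the simplest
  defensible operationalization; it is not claimed to be the test the
  original authors ran.
* `median_iqr()` uses inclusive linear interpolation (`quantile` type 7),
  chosen so the simulator's parameterization and the summaries match.

Ratio cutoffs are inclusive: sFlt-1/free-PlGF $\le 38$ is "low",
$\ge 85$ is "high". `classify_pe()` and `classify_hellp()` implement the
ISSHP 2001/2013 definitions exactly as restated in the clinical source
(not the full guideline documents, and not the 15-item Swansea score for
AFLP, which is out of scope).

## The synthetic-cohort generator

No patient-level data are deposited for studies of this kind, so the
package ships a generator that emulates the published *statistical*
structure:

* **Marginals.** Each (group, marker) is log-normal with
  $\mu = \ln(\text{median})$ and
  $\sigma = \ln(q_3/q_1) / (2 \times 0.674490)$, so the implied median and
  quartile *ratio* match the printed values exactly. Log-normal was chosen
  because every printed marker distribution is positive and
  right-skewed. Note a structural limitation: log-normal quartiles are
  log-symmetric about the median, so when a printed IQR is asymmetric in
  that sense (e.g. AFLP free PlGF, 208 [106–293]), the individual
  endpoints are approximated, not reproduced — only the median and the
  $q_3/q_1$ ratio are exact.
* **Registry.** `group_registry()` hard-codes the printed group
  parameters (four pregnancy groups antepartum, AFLP postpartum total
  PlGF, healthy-nonpregnant and liver-failure references; the reference
  groups are stored under the "antepartum" slot meaning "as sampled").
  Where no IQR was printed, $\sigma$ is borrowed from the same group's
  free-PlGF entry if that has a printed IQR, else from its sFlt-1 entry —
  a declared invention, recorded per row in `sigma_source`. The registry
  serializes to JSON (`write_registry()`/`read_registry()`) for user
  overrides.
* **Modes.** `marginal` draws markers independently (used for
  distribution-fidelity checks); `mechanistic_from_free` and
  `mechanistic_from_total` draw two markers and derive the third through
  the binding model, then apply multiplicative log-normal measurement
  noise (unit mean, default CV 5%, typical of automated immunoassays)
  independently per reported value. Noise 0 yields exactly
  model-consistent cohorts. Medians do not commute with the nonlinear
  model, so mechanistic cohorts intentionally do **not** reproduce all
  three printed medians at once; fidelity checks use marginal mode.
* **Postpartum decay.** First-order decay toward a nonpregnant floor,
  $x(d) = \text{floor} + (x_0 - \text{floor})\,2^{-d/h}$, with floors at
  the nonpregnant reference medians (sFlt-1 76, PlGF 16 pg/mL) and
  half-lives $h_{\text{sFlt-1}} = 0.85$ d, $h_{\text{PlGF}} = 0.58$ d.
  The half-lives are package inventions constrained only by the published
  day-2 bounds (sFlt-1 down by >80%, total PlGF <10% remaining); the
  shape of the decay between day 0 and day 2 is not informed by data.
* **Determinism.** Every stochastic function takes a `seed`; identical
  configuration and seed give bit-identical output.

What passing tests show — and what they do not: the generator reproduces
published group-level summaries and the model's internal consistency; it
does not reproduce between-marker correlation beyond the mechanistic
link, gestational-age dependence, assay floor/ceiling effects, or any
patient-level feature of real cohorts. Agreement of predicted and
measured totals on synthetic data is a *self-consistency* check of the
implementation, not a re-demonstration of the clinical finding.

## Numerical choices and problem sizes

Tolerances: unit conversions are exact inverses to $10^{-12}$ relative;
model round-trips (predict/invert, $K_D$ recovery) to $10^{-9}$;
closed-form vs bisection agreement to $10^{-6}$. Degenerate inputs are
classed errors rather than NaNs: zero free PlGF with zero $K_D$
(undefined occupancy), total $\le$ free ($K_D$ not estimable), complex
exceeding the receptor pool (inconsistent with 1:1 binding), zero-variance
inputs to correlation or regression. The identity-line compatibility check
carries a $10^{-8}$-scale slack so an exact fit with a zero-width CI
counts as containing the identity.

Problem sizes used by the checks: 42-sample cohorts for estimator
round-trips (matching the published estimation cohort), 100 000 draws for
marginal-median fidelity (sampling error ≈0.5%, well inside the 2%
acceptance band), 200 replicate seeds for the noisy-correlation summary,
1000 random states for the equilibrium-oracle sweep. These sizes keep the
whole suite under half a minute on a laptop while leaving comfortable
statistical margins.

## Known limitations

* The model ignores VEGF competition and PlGF isoform heterogeneity
  (assays mainly detect free PlGF-1); both are documented simplifications.
* A single cohort-level $K_D$ is applied to all samples; per-condition
  affinity differences would be absorbed into prediction error.
* The ISSHP classifications implement the restated criteria only; they
  are not a diagnostic device.
* Postpartum trajectories are phenomenological; do not use them to infer
  clearance kinetics.
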