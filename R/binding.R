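# Core 1:1 equilibrium model  sFlt-1 + PlGF <=> sFlt-1-PlGF.
#
# In receptor-pharmacology notation the measured sFlt-1 is the total
# receptor pool [R]_total, free PlGF is the unbound ligand [D], and the
# complex is [DR], with K_D = [D][R]/[DR]. Measured sFlt-1 includes both
# free and complexed receptor; stoichiometry is 1:1; VEGF competition is
# deliberately ignored (the two-parameter model is the point).
#
# All closed forms below are in molar units (pmol/L); the pg/mL wrappers
# convert at the boundary with the fixed 34/100 kDa molecular weights.

#' Default sFlt-1/PlGF dissociation constant (pmol/L)
#'
#' The package-wide default K_D of 50 pmol/L, the cohort-mean estimate from
#' paired free/total PlGF measurements. Overridable in every function that
#' takes a `kd` argument.
#' @export
DEFAULT_KD <- 50

#' Equilibrium receptor occupancy
#'
#' Complex concentration at equilibrium given free ligand, total receptor and
#' K_D: `DR = D * R_total / (KD + D)`. This is the rearrangement of
#' `KD = D * (R_total - DR) / DR`. Vectorized; all quantities in pmol/L.
#'
#' @param d_free Free ligand concentration (pmol/L).
#' @param r_total Total receptor concentration (pmol/L).
#' @param kd Dissociation constant (pmol/L).
#' @return Complex concentration `DR` in pmol/L, always in `[0, r_total]`.
#'   At `d_free = kd` exactly half the receptors are occupied; at `kd = 0`
#'   (with `d_free > 0`) occupancy is complete.
#' @examples
#' occupancy(50, 100, 50)              # half-occupancy: 50
#' occupancy(6.1176, 777.62, 50)       # AFLP medians in molar units
#' @export
occupancy <- function(d_free, r_total, kd) {
  check_nonneg(d_free, "d_free")
  check_nonneg(r_total, "r_total")
  check_nonneg(kd, "kd")
  if (any(kd + d_free == 0)) {
    stop_plgf("occupancy undefined when kd = 0 and d_free = 0", "undefined_occupancy")
  }
  d_free * r_total / (kd + d_free)
}

#' Predict total PlGF from free PlGF and sFlt-1
#'
#' The central calculation: total PlGF is the measured free PlGF plus the
#' sFlt-1-bound fraction predicted by the equilibrium model,
#' `total = free + MW_PlGF/1000 * occupancy(molar(free), molar(sflt1), kd)`.
#' Inputs and output in pg/mL; `kd` in pmol/L. Vectorized.
#'
#' @param free_plgf Free PlGF (pg/mL), the unheated immunoassay readout.
#' @param sflt1 sFlt-1 (pg/mL).
#' @param kd Dissociation constant (pmol/L); default [DEFAULT_KD].
#' @return Predicted total PlGF (pg/mL), always `>= free_plgf`; equal only
#'   when `sflt1 = 0` or `free_plgf = 0`.
#' @examples
#' predict_total_plgf(208, 77762, kd = 50)  # AFLP medians -> 3090.3 pg/mL
#' predict_total_plgf(349, 2518)            # no-PE medians
#' @export
predict_total_plgf <- function(free_plgf, sflt1, kd = DEFAULT_KD) {
  check_nonneg(free_plgf, "free_plgf")
  check_nonneg(sflt1, "sflt1")
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop_plgf("kd must be strictly positive (pmol/L)", "domain_error")
  }
  d <- mass_to_molar(free_plgf, "plgf")
  r <- mass_to_molar(sflt1, "sflt1")
  free_plgf + molar_to_mass(occupancy(d, r, kd), "plgf")
}

#' Per-sample dissociation constant from paired free/total PlGF
#'
#' Inverts the equilibrium relation on one sample in which both free PlGF
#' (unheated) and total PlGF (after thermal dissociation of the complex) were
#' measured. The complex is `DR = molar(total - free)` and
#' `KD = D * (R_total - DR) / DR`. A sample is estimable only when
#' `total > free` (some complex exists) and the implied complex does not
#' exceed the receptor pool. Vectorized.
#'
#' @param free_plgf Free PlGF (pg/mL).
#' @param total_plgf Measured total PlGF (pg/mL), must exceed `free_plgf`.
#' @param sflt1 sFlt-1 (pg/mL), strictly positive.
#' @return K_D in pmol/L (strictly positive).
#' @examples
#' kd_from_sample(208, 3090.3, 77762)  # ~50 pmol/L
#' @export
kd_from_sample <- function(free_plgf, total_plgf, sflt1) {
  check_nonneg(free_plgf, "free_plgf")
  check_nonneg(total_plgf, "total_plgf")
  check_nonneg(sflt1, "sflt1")
  if (any(total_plgf <= free_plgf)) {
    stop_plgf("total PlGF must exceed free PlGF for K_D estimation",
              "not_estimable")
  }
  if (any(sflt1 <= 0)) {
    stop_plgf("sflt1 must be strictly positive for K_D estimation",
              "not_estimable")
  }
  d <- mass_to_molar(free_plgf, "plgf")
  dr <- mass_to_molar(total_plgf - free_plgf, "plgf")
  r <- mass_to_molar(sflt1, "sflt1")
  if (any(dr >= r)) {
    stop_plgf("implied complex exceeds total sFlt-1; sample inconsistent with 1:1 binding",
              "inconsistent_sample")
  }
  d * (r - dr) / dr
}

#' Cohort-mean dissociation constant
#'
#' Applies [kd_from_sample()] to every sample with a usable free/total pair
#' and summarizes. Samples lacking a total-PlGF measurement, with
#' `total <= free`, with `sflt1 = 0`, or whose implied complex exceeds the
#' receptor pool are excluded and counted, mirroring the study's inclusion
#' rule (free and total available, total higher than free).
#'
#' @param samples Data frame with columns `free_plgf_pg_ml`,
#'   `total_plgf_pg_ml`, `sflt1_pg_ml` (as produced by [read_samples()] or
#'   [simulate_group()]).
#' @param type `"arithmetic"` (default; mean +/- SEM, the study's summary) or
#'   `"geometric"`.
#' @return Object of class `kd_estimate`: list with `per_sample_kd` (pmol/L),
#'   `mean_kd`, `sem_kd` (sample SD / sqrt(n)), `n_used`, `n_excluded`,
#'   `type`.
#' @examples
#' coh <- simulate_group("aflp", n = 10, mode = "mechanistic_from_free",
#'                       noise_cv = 0, seed = 1)
#' estimate_mean_kd(coh)
#' @export
estimate_mean_kd <- function(samples, type = c("arithmetic", "geometric")) {
  type <- match.arg(type)
  if (!is.data.frame(samples) || nrow(samples) == 0L) {
    stop_plgf("samples must be a non-empty data frame", "input_error")
  }
  need <- c("free_plgf_pg_ml", "total_plgf_pg_ml", "sflt1_pg_ml")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop_plgf(paste("missing columns:", paste(miss, collapse = ", ")),
              "input_error")
  }
  free <- samples$free_plgf_pg_ml
  total <- samples$total_plgf_pg_ml
  r <- samples$sflt1_pg_ml
  usable <- !is.na(free) & !is.na(total) & !is.na(r) & total > free & r > 0
  # implied complex must stay below the receptor pool (molar comparison)
  usable[usable] <- (total[usable] - free[usable]) / 34 < r[usable] / 100
  n_used <- sum(usable)
  if (n_used == 0L) {
    stop_plgf("no sample has total PlGF above free PlGF; K_D not estimable",
              "no_estimable_samples")
  }
  kd <- kd_from_sample(free[usable], total[usable], r[usable])
  mean_kd <- if (type == "arithmetic") mean(kd) else exp(mean(log(kd)))
  sem_kd <- if (n_used > 1L) stats::sd(kd) / sqrt(n_used) else 0
  structure(
    list(per_sample_kd = kd, mean_kd = mean_kd, sem_kd = sem_kd,
         n_used = n_used, n_excluded = nrow(samples) - n_used, type = type),
    class = "kd_estimate"
  )
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("sFlt-1/PlGF dissociation constant (%s mean)\n", x$type))
  cat(sprintf("  K_D = %.4g +/- %.2g pmol/L (mean +/- SEM)\n", x$mean_kd, x$sem_kd))
  cat(sprintf("  samples used: %d, excluded: %d\n", x$n_used, x$n_excluded))
  invisible(x)
}

#' Free PlGF from total PlGF, sFlt-1 and K_D
#'
#' Algebraic inversion of [predict_total_plgf()]. In molar units the free
#' ligand D solves `D^2 + D*(KD + R - T) - KD*T = 0` (T = total ligand,
#' R = total receptor); the unique non-negative root is taken via the
#' numerically stable quadratic form, avoiding cancellation when `KD << R`.
#' Vectorized; inputs/outputs in pg/mL except `kd` (pmol/L).
#'
#' @param total_plgf Total PlGF (pg/mL).
#' @param sflt1 sFlt-1 (pg/mL).
#' @param kd Dissociation constant (pmol/L), strictly positive.
#' @return Free PlGF (pg/mL) such that
#'   `predict_total_plgf(result, sflt1, kd) == total_plgf`.
#' @examples
#' free_from_total(3090.3, 77762, kd = 50)  # ~208 pg/mL
#' @export
free_from_total <- function(total_plgf, sflt1, kd = DEFAULT_KD) {
  check_nonneg(total_plgf, "total_plgf")
  check_nonneg(sflt1, "sflt1")
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop_plgf("kd must be strictly positive (pmol/L)", "domain_error")
  }
  t_m <- mass_to_molar(total_plgf, "plgf")
  r_m <- mass_to_molar(sflt1, "sflt1")
  d_m <- solve_free_ligand(t_m, r_m, kd)
  molar_to_mass(d_m, "plgf")
}

# positive root of D^2 + b*D - kd*t = 0 with b = kd + r - t, in the
# cancellation-free form: when b > 0 use D = 2*kd*t / (b + sqrt(disc))
solve_free_ligand <- function(t_m, r_m, kd) {
  b <- kd + r_m - t_m
  disc <- b * b + 4 * kd * t_m
  if (any(disc < 0)) {
    stop_plgf("negative discriminant in free-ligand quadratic (internal error)",
              "internal_error")
  }
  sq <- sqrt(disc)
  d <- ifelse(b > 0, 2 * kd * t_m / (b + sq), (sq - b) / 2)
  # exact zeros (t = 0) must come out exactly zero
  ifelse(t_m == 0, 0, pmax(d, 0))
}

#' Re-equilibrate a sample after an in-silico ligand spike
#'
#' Models the spike-recovery design: recombinant PlGF is added to serum, the
#' mixture re-equilibrates with sFlt-1, and free PlGF is read before heating
#' while total PlGF is read after heating (heating destroys sFlt-1 and
#' releases all bound PlGF without affecting PlGF itself). New total ligand
#' is `endogenous total + added`; the free readout is the equilibrium free
#' ligand at that total.
#'
#' @param sflt1 sFlt-1 (pg/mL).
#' @param free_plgf Free PlGF before the spike (pg/mL).
#' @param added_plgf Amount of ligand added (pg/mL of final mixture).
#' @param total_plgf Endogenous total PlGF (pg/mL); if `NULL`, predicted from
#'   `free_plgf` and `sflt1` via [predict_total_plgf()].
#' @param kd Dissociation constant (pmol/L).
#' @return Object of class `binding_state`: list with molar fields `d_free`,
#'   `r_total`, `dr`, `kd` (pmol/L) and mass readouts
#'   `detected_free_pg_ml` (pre-heating) and `total_after_heat_pg_ml`
#'   (post-heating, equals endogenous total + added regardless of sFlt-1).
#'   Mass conservation `d_free + dr == molar total` holds at equilibrium.
#' @examples
#' equilibrate_after_spike(sflt1 = 30000, free_plgf = 36, added_plgf = 1693)
#' @export
equilibrate_after_spike <- function(sflt1, free_plgf, added_plgf,
                                    total_plgf = NULL, kd = DEFAULT_KD) {
  check_nonneg(added_plgf, "added_plgf")
  if (is.null(total_plgf) || is.na(total_plgf)) {
    total_plgf <- predict_total_plgf(free_plgf, sflt1, kd)
  }
  check_nonneg(total_plgf, "total_plgf")
  t_new <- total_plgf + added_plgf
  d_mass <- free_from_total(t_new, sflt1, kd)
  d_m <- mass_to_molar(d_mass, "plgf")
  r_m <- mass_to_molar(sflt1, "sflt1")
  t_m <- mass_to_molar(t_new, "plgf")
  structure(
    list(d_free = d_m, r_total = r_m, dr = t_m - d_m, kd = kd,
         detected_free_pg_ml = d_mass, total_after_heat_pg_ml = t_new),
    class = "binding_state"
  )
}

#' @export
print.binding_state <- function(x, ...) {
  cat("sFlt-1/PlGF equilibrium binding state\n")
  cat(sprintf("  free ligand [D]      = %.4g pmol/L (%.4g pg/mL detected)\n",
              x$d_free, x$detected_free_pg_ml))
  cat(sprintf("  complex [DR]         = %.4g pmol/L\n", x$dr))
  cat(sprintf("  total receptor [R]t  = %.4g pmol/L\n", x$r_total))
  cat(sprintf("  K_D = %.4g pmol/L; total after heating = %.4g pg/mL\n",
              x$kd, x$total_after_heat_pg_ml))
  invisible(x)
}
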