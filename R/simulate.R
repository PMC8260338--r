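# Synthetic-cohort generator. Marker marginals are log-normal,
# parameterized so that the distribution's median and IQR reproduce the
# published group statistics exactly; mechanistic modes additionally
# enforce the binding-model link between the three markers.

Z075 <- 0.674490  # standard normal upper quartile

#' Log-normal parameters from a median and interquartile range
#'
#' For X ~ LogNormal(mu, sigma): median = exp(mu) and
#' q3/q1 = exp(2 * sigma * z_0.75), so `mu = ln(median)` and
#' `sigma = ln(q3/q1) / (2 * 0.674490)`. The implied distribution reproduces
#' the input median and quartiles exactly.
#'
#' @param median,q1,q3 Positive values with `q1 <= median <= q3`.
#' @return Named numeric vector `c(mu, sigma)` (mu in ln pg/mL).
#' @examples
#' lognormal_from_median_iqr(59, 39, 97)   # HELLP free PlGF
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (any(!is.finite(c(median, q1, q3))) || q1 <= 0 ||
      q1 > median || median > q3) {
    stop_plgf("need 0 < q1 <= median <= q3", "input_error")
  }
  c(mu = log(median), sigma = log(q3 / q1) / (2 * Z075))
}

#' Default group parameter registry
#'
#' Published group medians (and IQRs where printed) for sFlt-1, free PlGF and
#' total PlGF, in pg/mL, with the implied log-normal parameters. Groups:
#' `no_pe`, `pe`, `hellp`, `aflp` (antepartum pregnancy groups; `aflp` also
#' has a postpartum total-PlGF entry), `healthy` (nonpregnant reference) and
#' `liver_failure` (nonpregnant acute liver failure).
#'
#' Where no IQR was printed, sigma is borrowed from the same group's free
#' PlGF entry if that one has a printed IQR, otherwise from the group's
#' sFlt-1 entry; `sigma_source` records which. Missing quartiles are then
#' filled in analytically from (mu, sigma).
#'
#' @return Data frame with columns `group`, `timepoint`, `marker`, `median`,
#'   `q1`, `q3`, `mu`, `sigma`, `sigma_source`.
#' @export
group_registry <- function() {
  reg <- data.frame(
    group = c("no_pe", "pe", "hellp", "aflp", "healthy", "liver_failure",
              "no_pe", "pe", "hellp", "aflp", "healthy",
              "no_pe", "pe", "hellp", "aflp", "aflp", "liver_failure"),
    timepoint = c(rep("antepartum", 15), "postpartum", "antepartum"),
    marker = c(rep("sflt1", 6), rep("free_plgf", 5), rep("total_plgf", 6)),
    median = c(2518, 8772, 14572, 77762, 76, 446,
               349, 117, 59, 208, 16,
               354, 435, 344, 2054, 163, 22),
    q1 = c(1744, 6410, 5641, 45044, 67, 211,
           NA, NA, 39, 106, 14,
           NA, NA, NA, NA, NA, 12),
    q3 = c(3903, 10736, 20056, 116657, 84, 1414,
           NA, NA, 97, 293, 18,
           NA, NA, NA, NA, NA, 51),
    stringsAsFactors = FALSE
  )
  reg$mu <- log(reg$median)
  reg$sigma <- NA_real_
  reg$sigma_source <- "printed_iqr"
  own <- !is.na(reg$q1) & !is.na(reg$q3)
  reg$sigma[own] <- log(reg$q3[own] / reg$q1[own]) / (2 * Z075)
  for (i in which(!own)) {
    donor <- which(own & reg$group == reg$group[i] & reg$marker == "free_plgf")
    src <- "free_plgf"
    if (length(donor) == 0L) {
      donor <- which(own & reg$group == reg$group[i] & reg$marker == "sflt1")
      src <- "sflt1"
    }
    if (length(donor) == 0L) {
      stop_plgf("no sigma donor for registry row", "internal_error")
    }
    reg$sigma[i] <- reg$sigma[donor[1L]]
    reg$sigma_source[i] <- paste0("borrowed_", src)
  }
  reg$q1[!own] <- exp(reg$mu[!own] - Z075 * reg$sigma[!own])
  reg$q3[!own] <- exp(reg$mu[!own] + Z075 * reg$sigma[!own])
  reg
}

#' Write / read the simulator parameter registry as JSON
#'
#' Users can dump the default registry, edit medians/IQRs, and feed the
#' edited table back to [simulate_group()] via `registry`.
#'
#' @param registry Registry data frame (default [group_registry()]).
#' @param path File path.
#' @return `read_registry` returns the registry data frame.
#' @export
write_registry <- function(path, registry = group_registry()) {
  jsonlite::write_json(registry, path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  reg <- jsonlite::fromJSON(path)
  need <- c("group", "timepoint", "marker", "median", "mu", "sigma")
  miss <- setdiff(need, names(reg))
  if (length(miss)) {
    stop_plgf(paste("registry missing columns:", paste(miss, collapse = ", ")),
              "config_error")
  }
  reg
}

registry_row <- function(registry, group, marker, timepoint) {
  i <- which(registry$group == group & registry$marker == marker &
               registry$timepoint == timepoint)
  if (length(i) == 0L) {
    stop_plgf(sprintf("no registry entry for group '%s', marker '%s', timepoint '%s'",
                      group, marker, timepoint), "config_error")
  }
  registry[i[1L], ]
}

# multiplicative log-normal measurement noise with unit mean and the given CV
apply_noise <- function(x, cv) {
  if (cv == 0) return(x)
  s <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), -s^2 / 2, s))
}

#' Simulate one diagnosis group
#'
#' Three modes:
#' * `marginal` — every available marker drawn independently from its
#'   log-normal marginal; reproduces the published medians/IQRs and is the
#'   mode used for distribution-fidelity checks. The three markers of one
#'   sample are *not* mutually consistent under the binding model.
#' * `mechanistic_from_free` — sFlt-1 and free PlGF drawn from their
#'   marginals, total PlGF derived via [predict_total_plgf()] at `kd`.
#' * `mechanistic_from_total` — sFlt-1 and total PlGF drawn, free PlGF
#'   derived via [free_from_total()].
#'
#' In the mechanistic modes multiplicative log-normal measurement noise of
#' coefficient of variation `noise_cv` is applied independently to each
#' reported value after the model link is formed; `noise_cv = 0` gives
#' exactly model-consistent cohorts. Identical `seed` gives identical output.
#'
#' @param group Group label present in the registry.
#' @param n Number of samples.
#' @param mode Simulation mode (see above).
#' @param timepoint `"antepartum"` (default) or `"postpartum"`.
#' @param kd Dissociation constant (pmol/L) for the mechanistic link.
#' @param noise_cv Measurement-noise CV (fraction, default 0.05); applied in
#'   mechanistic modes only.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param registry Parameter registry (default [group_registry()]).
#' @return Sample data frame with columns `sample_id`, `group`, `timepoint`,
#'   `day_postpartum`, `sflt1_pg_ml`, `free_plgf_pg_ml`, `total_plgf_pg_ml`.
#' @examples
#' simulate_group("aflp", n = 5, mode = "mechanistic_from_free",
#'                noise_cv = 0, seed = 42)
#' @export
simulate_group <- function(group, n,
                           mode = c("mechanistic_from_free", "marginal",
                                    "mechanistic_from_total"),
                           timepoint = "antepartum", kd = DEFAULT_KD,
                           noise_cv = 0.05, seed = NULL,
                           registry = group_registry()) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || n < 1) stop_plgf("n must be >= 1", "config_error")
  if (noise_cv < 0) stop_plgf("noise_cv must be >= 0", "config_error")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(marker) {
    row <- registry_row(registry, group, marker, timepoint)
    stats::rlnorm(n, row$mu, row$sigma)
  }
  has_entry <- function(marker) {
    any(registry$group == group & registry$marker == marker &
          registry$timepoint == timepoint)
  }
  if (mode == "marginal") {
    sflt1 <- if (has_entry("sflt1")) draw("sflt1") else NA_real_
    free <- if (has_entry("free_plgf")) draw("free_plgf") else NA_real_
    total <- if (has_entry("total_plgf")) draw("total_plgf") else NA_real_
    if (all(is.na(c(sflt1[1L], free[1L], total[1L])))) {
      stop_plgf("no marker distributions for this group/timepoint", "config_error")
    }
  } else if (mode == "mechanistic_from_free") {
    sflt1 <- draw("sflt1")
    free <- draw("free_plgf")
    total <- predict_total_plgf(free, sflt1, kd)
    sflt1 <- apply_noise(sflt1, noise_cv)
    free <- apply_noise(free, noise_cv)
    total <- apply_noise(total, noise_cv)
  } else {
    sflt1 <- draw("sflt1")
    total <- draw("total_plgf")
    free <- free_from_total(total, sflt1, kd)
    sflt1 <- apply_noise(sflt1, noise_cv)
    free <- apply_noise(free, noise_cv)
    total <- apply_noise(total, noise_cv)
  }
  data.frame(
    sample_id = sprintf("%s_%s_%04d", group, substr(timepoint, 1, 4), seq_len(n)),
    group = group,
    timepoint = timepoint,
    day_postpartum = if (timepoint == "postpartum") 0L else NA_integer_,
    sflt1_pg_ml = rep_len(sflt1, n),
    free_plgf_pg_ml = rep_len(free, n),
    total_plgf_pg_ml = rep_len(total, n),
    stringsAsFactors = FALSE
  )
}

#' Default postpartum decay parameters
#'
#' Exponential decay toward a nonpregnant floor:
#' `value(d) = floor + (antepartum - floor) * 2^(-d / half_life)`.
#' Half-lives (days) are chosen so that at day 2 sFlt-1 retains < 20% and
#' PlGF < 10% of the antepartum excess; floors are the nonpregnant reference
#' medians (sFlt-1 76 pg/mL, PlGF 16 pg/mL).
#' @return Named list with `half_life` and `floor`, each a named vector for
#'   `sflt1` and `plgf`.
#' @export
postpartum_defaults <- function() {
  list(half_life = c(sflt1 = 0.85, plgf = 0.58),
       floor = c(sflt1 = 76, plgf = 16))
}

#' Simulate postpartum decay of an antepartum cohort
#'
#' Each antepartum sample is carried forward to each requested postpartum
#' day under first-order decay toward the nonpregnant floor. Both free and
#' total PlGF decay with the PlGF half-life toward the PlGF floor.
#'
#' @param ante Antepartum sample data frame (see [simulate_group()]).
#' @param days Non-negative integer vector of postpartum days.
#' @param half_life,floor Named vectors as in [postpartum_defaults()].
#' @return Sample data frame with `timepoint = "postpartum"` and
#'   `day_postpartum` set; `nrow(ante) * length(days)` rows.
#' @examples
#' ante <- simulate_group("aflp", 3, noise_cv = 0, seed = 1)
#' simulate_postpartum(ante, days = c(0, 2))
#' @export
simulate_postpartum <- function(ante, days,
                                half_life = postpartum_defaults()$half_life,
                                floor = postpartum_defaults()$floor) {
  if (!is.data.frame(ante) || nrow(ante) == 0L) {
    stop_plgf("ante must be a non-empty sample data frame", "input_error")
  }
  if (any(days < 0) || any(!is.finite(days))) {
    stop_plgf("days must be non-negative", "input_error")
  }
  decay <- function(x, d, marker) {
    fl <- floor[[marker]]
    fl + (x - fl) * 2^(-d / half_life[[marker]])
  }
  out <- lapply(days, function(d) {
    pp <- ante
    pp$timepoint <- "postpartum"
    pp$day_postpartum <- as.integer(d)
    pp$sample_id <- sprintf("%s_pp%02d", ante$sample_id, as.integer(d))
    pp$sflt1_pg_ml <- decay(ante$sflt1_pg_ml, d, "sflt1")
    if ("free_plgf_pg_ml" %in% names(pp)) {
      pp$free_plgf_pg_ml <- decay(ante$free_plgf_pg_ml, d, "plgf")
    }
    if ("total_plgf_pg_ml" %in% names(pp)) {
      pp$total_plgf_pg_ml <- decay(ante$total_plgf_pg_ml, d, "plgf")
    }
    pp
  })
  do.call(rbind, out)
}

#' In-silico spike experiment over a cohort
#'
#' Adds a fixed amount of ligand to every sample, re-equilibrates with
#' sFlt-1 via [equilibrate_after_spike()], and reports the pre-heating
#' (free) and post-heating (total) readouts, optionally with measurement
#' noise. The default spike of 1693 pg/mL matches the published validation
#' design.
#'
#' @param cohort Sample data frame; samples without `total_plgf_pg_ml` get it
#'   predicted at `kd` first.
#' @param added Spike amount (pg/mL of final mixture), default 1693.
#' @param kd Dissociation constant (pmol/L).
#' @param noise_cv Measurement-noise CV applied to both readouts (default 0).
#' @param seed Optional integer seed for the noise.
#' @return Data frame: `sample_id`, `sflt1_pg_ml`, `free_before_spike`,
#'   `endogenous_total`, `added`, `detected_free_before_heat`,
#'   `detected_total_after_heat`.
#' @examples
#' coh <- simulate_group("aflp", 3, noise_cv = 0, seed = 7)
#' simulate_spike_experiment(coh, added = 1693)
#' @export
simulate_spike_experiment <- function(cohort, added = 1693, kd = DEFAULT_KD,
                                      noise_cv = 0, seed = NULL) {
  check_nonneg(added, "added")
  if (!is.null(seed)) set.seed(seed)
  total <- cohort$total_plgf_pg_ml
  if (is.null(total)) total <- rep(NA_real_, nrow(cohort))
  fill <- is.na(total)
  total[fill] <- predict_total_plgf(cohort$free_plgf_pg_ml[fill],
                                    cohort$sflt1_pg_ml[fill], kd)
  t_new <- total + added
  detected_free <- free_from_total(t_new, cohort$sflt1_pg_ml, kd)
  data.frame(
    sample_id = cohort$sample_id,
    sflt1_pg_ml = cohort$sflt1_pg_ml,
    free_before_spike = free_from_total(total, cohort$sflt1_pg_ml, kd),
    endogenous_total = total,
    added = added,
    detected_free_before_heat = apply_noise(detected_free, noise_cv),
    detected_total_after_heat = apply_noise(t_new, noise_cv),
    stringsAsFactors = FALSE
  )
}
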