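test_that("log-normal parameterization reproduces the median and IQR", {
  # HELLP free PlGF 59 [39-97] pg/mL
  p <- lognormal_from_median_iqr(59, 39, 97)
  expect_equal(unname(p["mu"]), log(59), tolerance = 1e-9)     # 4.0775
  expect_equal(unname(p["sigma"]), 0.67544, tolerance = 1e-4)
  # the implied distribution preserves the median and the quartile ratio
  # exactly; its quartiles are log-symmetric about the median, so the
  # endpoints themselves are recovered exactly only for log-symmetric input
  z <- 0.674490  # the parameterization's declared upper-quartile constant
  q <- exp(p["mu"] + z * p["sigma"] * c(-1, 0, 1))
  expect_equal(unname(q[2]), 59, tolerance = 1e-9)
  expect_equal(unname(q[3] / q[1]), 97 / 39, tolerance = 1e-9)
  sym <- lognormal_from_median_iqr(60, 30, 120)
  expect_equal(unname(exp(sym["mu"] + z * sym["sigma"] * c(-1, 0, 1))),
               c(30, 60, 120), tolerance = 1e-9)
  # the rounded z matches qnorm(0.75) to ~1e-6, so true quartiles agree too
  expect_equal(qlnorm(c(0.25, 0.5, 0.75), sym["mu"], sym["sigma"]),
               c(30, 60, 120), tolerance = 1e-5, ignore_attr = TRUE)
  # degenerate point mass
  expect_equal(unname(lognormal_from_median_iqr(5, 5, 5)["sigma"]), 0)
  expect_error(lognormal_from_median_iqr(10, -1, 20), class = "plgfbind_input_error")
  expect_error(lognormal_from_median_iqr(10, 12, 20), class = "plgfbind_input_error")
})

test_that("the registry carries the printed parameters and valid sigmas", {
  reg <- group_registry()
  expect_true(all(reg$sigma >= 0))
  expect_true(all(reg$q1 <= reg$median & reg$median <= reg$q3))
  expect_equal(reg$mu, log(reg$median))
  pick <- function(g, m, tp = "antepartum") {
    reg[reg$group == g & reg$marker == m & reg$timepoint == tp, ]
  }
  expect_equal(pick("aflp", "sflt1")$median, 77762)
  expect_equal(pick("aflp", "sflt1")$q3, 116657)
  expect_equal(pick("hellp", "free_plgf")$q1, 39)
  expect_equal(pick("no_pe", "free_plgf")$median, 349)
  expect_equal(pick("aflp", "total_plgf", "postpartum")$median, 163)
  expect_equal(pick("healthy", "free_plgf")$median, 16)
  expect_equal(pick("liver_failure", "total_plgf")$median, 22)
  # borrowed spreads come from the declared donors
  expect_equal(pick("no_pe", "free_plgf")$sigma_source, "borrowed_sflt1")
  expect_equal(pick("aflp", "total_plgf")$sigma_source, "borrowed_free_plgf")
  expect_equal(pick("aflp", "total_plgf")$sigma, pick("aflp", "free_plgf")$sigma)
})

test_that("identical seeds give bit-identical cohorts", {
  a <- simulate_group("pe", 25, mode = "mechanistic_from_free", seed = 51)
  b <- simulate_group("pe", 25, mode = "mechanistic_from_free", seed = 51)
  expect_identical(a, b)
  c <- simulate_group("pe", 25, mode = "mechanistic_from_free", seed = 52)
  expect_false(identical(a$sflt1_pg_ml, c$sflt1_pg_ml))
})

test_that("noise-free mechanistic cohorts satisfy the equilibrium invariant", {
  for (mode in c("mechanistic_from_free", "mechanistic_from_total")) {
    coh <- simulate_group("aflp", 40, mode = mode, kd = 50, noise_cv = 0,
                          seed = 53)
    d <- mass_to_molar(coh$free_plgf_pg_ml, "plgf")
    r <- mass_to_molar(coh$sflt1_pg_ml, "sflt1")
    dr <- mass_to_molar(coh$total_plgf_pg_ml - coh$free_plgf_pg_ml, "plgf")
    expect_equal(50 * dr, d * (r - dr), tolerance = 1e-9)
    expect_equal(estimate_mean_kd(coh)$mean_kd, 50, tolerance = 1e-9)
    expect_equal(estimate_mean_kd(coh)$n_excluded, 0L)
  }
})

test_that("marginal-mode quartiles track the registry parameters", {
  reg <- group_registry()
  coh <- simulate_group("hellp", 20000, mode = "marginal", seed = 54)
  row <- reg[reg$group == "hellp" & reg$marker == "free_plgf", ]
  q <- quantile(coh$free_plgf_pg_ml, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(q[2], row$median, tolerance = 0.03)
  # empirical quartiles track the analytic quartiles of the fitted log-normal
  expect_equal(q[1], exp(row$mu - 0.674490 * row$sigma), tolerance = 0.03)
  expect_equal(q[3], exp(row$mu + 0.674490 * row$sigma), tolerance = 0.03)
  # marginal draws are independent: no mechanistic link
  expect_false(all(coh$total_plgf_pg_ml >= coh$free_plgf_pg_ml))
})

test_that("measurement noise has the configured coefficient of variation", {
  set.seed(55)
  base <- simulate_group("pe", 4000, mode = "mechanistic_from_free",
                         noise_cv = 0, seed = 56)
  noisy <- simulate_group("pe", 4000, mode = "mechanistic_from_free",
                          noise_cv = 0.05, seed = 56)
  ratio <- noisy$total_plgf_pg_ml / base$total_plgf_pg_ml
  expect_equal(mean(ratio), 1, tolerance = 0.01)       # unit-mean noise
  expect_equal(sd(ratio) / mean(ratio), 0.05, tolerance = 0.1)
})

test_that("unknown groups and missing marker distributions are config errors", {
  expect_error(simulate_group("nope", 5), class = "plgfbind_config_error")
  # liver_failure has no free-PlGF entry, so the from-free mode cannot run
  expect_error(simulate_group("liver_failure", 5, mode = "mechanistic_from_free"),
               class = "plgfbind_config_error")
  # but marginal mode works off sflt1 + total
  lf <- simulate_group("liver_failure", 5, mode = "marginal", seed = 57)
  expect_true(all(is.na(lf$free_plgf_pg_ml)))
  expect_true(all(lf$total_plgf_pg_ml > 0))
})

test_that("postpartum decay starts at the antepartum value and obeys the bounds", {
  ante <- simulate_group("aflp", 30, mode = "mechanistic_from_free",
                         noise_cv = 0, seed = 58)
  d0 <- simulate_postpartum(ante, days = 0)
  expect_equal(d0$sflt1_pg_ml, ante$sflt1_pg_ml)
  expect_equal(d0$total_plgf_pg_ml, ante$total_plgf_pg_ml)
  expect_true(all(d0$timepoint == "postpartum" & d0$day_postpartum == 0))

  d2 <- simulate_postpartum(ante, days = 2)
  fl <- postpartum_defaults()$floor
  sflt_excess <- (d2$sflt1_pg_ml - fl["sflt1"]) / (ante$sflt1_pg_ml - fl["sflt1"])
  plgf_excess <- (d2$total_plgf_pg_ml - fl["plgf"]) /
    (ante$total_plgf_pg_ml - fl["plgf"])
  expect_true(all(sflt_excess < 0.20))
  expect_true(all(plgf_excess < 0.10))

  # decay is monotone across days toward the floor
  traj <- simulate_postpartum(ante[1, ], days = 0:6)
  expect_true(all(diff(traj$sflt1_pg_ml) < 0))
  expect_true(all(traj$sflt1_pg_ml > fl["sflt1"]))
  expect_error(simulate_postpartum(ante, days = -1), class = "plgfbind_input_error")
})

test_that("the in-silico spike reproduces the recovery design", {
  coh <- simulate_group("aflp", 15, mode = "mechanistic_from_free",
                        noise_cv = 0, seed = 59)
  # no spike: the table reproduces the unspiked cohort
  tab0 <- simulate_spike_experiment(coh, added = 0)
  expect_equal(tab0$detected_free_before_heat, coh$free_plgf_pg_ml,
               tolerance = 1e-9)
  expect_equal(tab0$detected_total_after_heat, coh$total_plgf_pg_ml,
               tolerance = 1e-9)

  # high-ratio serum sequesters part of the spike; heating recovers all of it
  tab <- simulate_spike_experiment(coh, added = 1693)
  increase <- tab$detected_free_before_heat - tab$free_before_spike
  expect_true(all(increase < 1693))
  expect_equal(tab$detected_total_after_heat, tab$endogenous_total + 1693)
  expect_equal(spike_recovery(1693, tab$endogenous_total,
                              tab$detected_total_after_heat),
               rep(1, nrow(tab)))

  # low-ratio serum (healthy nonpregnant sFlt-1) passes the spike through
  low <- simulate_group("healthy", 15, mode = "mechanistic_from_free",
                        noise_cv = 0, seed = 60)
  tab_low <- simulate_spike_experiment(low, added = 1693)
  inc_low <- tab_low$detected_free_before_heat - tab_low$free_before_spike
  expect_true(all(inc_low > 0.95 * 1693))
})

test_that("registry round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_registry(path)
  back <- read_registry(path)
  reg <- group_registry()
  expect_equal(back$median, reg$median)
  expect_equal(back$sigma, reg$sigma, tolerance = 1e-12)
  # an edited registry drives the simulator
  back$median[back$group == "aflp" & back$marker == "sflt1"] <- 50000
  back$mu <- log(back$median)
  coh <- simulate_group("aflp", 5000, mode = "marginal", seed = 61,
                        registry = back)
  expect_equal(median(coh$sflt1_pg_ml), 50000, tolerance = 0.05)
})
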