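# Method-comparison statistics: measured (post-heating) vs predicted total
# PlGF, and the spike-recovery bookkeeping.

#' Spearman rank correlation with exact small-sample p-value
#'
#' Spearman's rho on average ranks (ties allowed). The p-value is the exact
#' two-sided permutation probability (all n! rank assignments enumerated) for
#' n <= 10, and the t-approximation `t = rho*sqrt((n-2)/(1-rho^2))` on n-2
#' degrees of freedom for larger n.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values.
#' @return Object of class `comparison_result` with fields `statistic_name`
#'   (`"spearman_rho"`), `statistic`, `p_value`, `n`, `method_notes`.
#' @examples
#' spearman_correlation(1:5, c(1, 3, 2, 5, 4))
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_plgf("x and y must have equal length", "input_error")
  n <- length(x)
  if (n < 3) stop_plgf("need at least 3 paired observations", "input_error")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_plgf("missing or non-finite values are not allowed", "input_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_plgf("constant input: rank correlation undefined", "input_error")
  }
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    p <- spearman_perm_p(rx, ry)
    notes <- "exact permutation p (all rank permutations enumerated)"
  } else {
    p <- spearman_t_p(rho, n)
    notes <- "t-approximation p on n-2 df"
  }
  comparison_result("spearman_rho", rho, p, n, notes)
}

# two-sided exact permutation p for |rho| >= |observed|; chunked over the
# first element so memory stays ~ (n-1)! columns
spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  obs <- abs(stats::cor(rx, ry))
  sub <- perm_matrix(n - 1L)              # (n-1) x (n-1)! of indices 1..n-1
  cx <- rx - mean(rx)
  denom <- sqrt(sum(cx^2)) * stats::sd(ry) * sqrt(n - 1)
  count <- 0
  total <- 0
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    perm_y <- rbind(ry[first], matrix(ry[rest][sub], nrow = n - 1L))
    rho_perm <- as.vector(crossprod(cx, perm_y)) / denom
    count <- count + sum(abs(rho_perm) >= obs - 1e-12)
    total <- total + ncol(perm_y)
  }
  count / total
}

spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# all permutations of 1..n as an n x n! integer matrix (n <= 9 in practice)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  cols <- ncol(sub)
  out <- matrix(0L, n, n * cols)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[, (i - 1L) * cols + seq_len(cols)] <-
      rbind(rep.int(i, cols), matrix(rest[sub], nrow = n - 1L))
  }
  out
}

#' Ordinary least-squares fit against the line of identity
#'
#' Regresses predicted on measured values and asks whether the relationship
#' is compatible with the identity line: the fit is identity-compatible when
#' the 95% CI of the slope contains 1 and the 95% CI of the intercept
#' contains 0.
#'
#' @param measured Measured values (e.g. post-heating total PlGF, pg/mL).
#' @param predicted Predicted values (same units), equal length >= 3.
#' @param conf_level Confidence level for the CIs (default 0.95).
#' @return Object of class `identity_fit`: list with `slope`, `slope_ci`,
#'   `intercept`, `intercept_ci`, `identity_compatible`, `n`.
#' @examples
#' m <- c(100, 300, 700, 1500, 2900)
#' identity_line_fit(m, m * 1.01)
#' @export
identity_line_fit <- function(measured, predicted, conf_level = 0.95) {
  if (length(measured) != length(predicted)) {
    stop_plgf("measured and predicted must have equal length", "input_error")
  }
  if (length(measured) < 3) stop_plgf("need at least 3 pairs", "input_error")
  if (stats::sd(measured) == 0) {
    stop_plgf("measured values have zero variance; slope not fittable",
              "not_fittable")
  }
  fit <- stats::lm(predicted ~ measured)
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  slope_ci <- unname(ci["measured", ])
  intercept_ci <- unname(ci["(Intercept)", ])
  # numerical slack so an exact fit (degenerate zero-width CI) still counts
  # as containing slope 1 / intercept 0
  tol_s <- 1e-8 * max(1, abs(slope))
  tol_i <- 1e-8 * max(1, max(abs(measured)))
  structure(
    list(slope = slope, slope_ci = slope_ci,
         intercept = intercept, intercept_ci = intercept_ci,
         identity_compatible =
           slope_ci[1L] <= 1 + tol_s && slope_ci[2L] >= 1 - tol_s &&
           intercept_ci[1L] <= tol_i && intercept_ci[2L] >= -tol_i,
         n = length(measured), conf_level = conf_level),
    class = "identity_fit"
  )
}

#' @export
print.identity_fit <- function(x, ...) {
  cat(sprintf("identity-line fit (n = %d)\n", x$n))
  cat(sprintf("  slope     %.4g  [%.4g, %.4g]\n", x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4g  [%.4g, %.4g] pg/mL\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  compatible with identity: %s\n", x$identity_compatible))
  invisible(x)
}

#' Spike recovery fraction
#'
#' Recovery of a known ligand spike: the post-heating measurement divided by
#' the expected total (added + endogenous total). A value of 1 means the
#' heated assay recovered the spike perfectly.
#'
#' @param added Amount of ligand added (pg/mL).
#' @param endogenous_total Endogenous total ligand before the spike (pg/mL).
#' @param measured_total_after_heating Post-heating measurement (pg/mL).
#' @return Recovery fraction (dimensionless).
#' @examples
#' spike_recovery(2221, 270, 2372)
#' @export
spike_recovery <- function(added, endogenous_total, measured_total_after_heating) {
  check_nonneg(added, "added")
  check_nonneg(endogenous_total, "endogenous_total")
  check_nonneg(measured_total_after_heating, "measured_total_after_heating")
  denom <- added + endogenous_total
  if (any(denom <= 0)) {
    stop_plgf("added + endogenous_total must be positive", "input_error")
  }
  measured_total_after_heating / denom
}

# shared constructor for test-result objects
comparison_result <- function(statistic_name, statistic, p_value, n,
                              method_notes = "") {
  structure(
    list(statistic_name = statistic_name, statistic = statistic,
         p_value = p_value, n = n, method_notes = method_notes),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (n = %s)\n",
              x$statistic_name, x$statistic, x$p_value,
              paste(x$n, collapse = "+")))
  if (nzchar(x$method_notes)) cat(" ", x$method_notes, "\n")
  if (!is.null(x$posthoc)) {
    cat("  pairwise (Bonferroni-corrected):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a comparison result to a JSON string or CSV row
#'
#' @param x A `comparison_result`.
#' @param format `"json"` or `"csv"` (single header-less row:
#'   statistic_name, statistic, p_value, n, method_notes).
#' @return A character scalar.
#' @export
format_comparison <- function(x, format = c("json", "csv")) {
  format <- match.arg(format)
  core <- list(statistic_name = x$statistic_name, statistic = x$statistic,
               p_value = x$p_value, n = sum(x$n), method_notes = x$method_notes)
  if (format == "json") {
    as.character(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA))
  } else {
    paste(core$statistic_name, format(core$statistic, digits = 15),
          format(core$p_value, digits = 15), core$n,
          shQuote(core$method_notes), sep = ",")
  }
}
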