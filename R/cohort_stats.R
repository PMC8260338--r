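# Descriptive and inferential statistics used in the study: median/IQR
# summaries, Shapiro-Wilk-gated two-group and multi-group tests, ratio
# cutoffs, postpartum percent-remaining, ISSHP clinical classifications.

#' Median and interquartile range of one group
#'
#' Quartiles use linear interpolation between order statistics (the
#' "inclusive" convention, `stats::quantile` type 7).
#'
#' @param values Non-empty numeric vector.
#' @param group Optional group label carried into the output.
#' @return One-row data frame: `group`, `n`, `median`, `q1`, `q3`.
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))
#' @export
median_iqr <- function(values, group = NA_character_) {
  if (length(values) == 0L || any(!is.finite(values))) {
    stop_plgf("values must be non-empty and finite", "input_error")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(group = group, n = length(values),
             median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Tidy median/IQR summary table for a cohort
#'
#' Long-format summary (group, marker, n, median, q1, q3) over the standard
#' marker columns of a sample table.
#'
#' @param samples Sample data frame (see [read_samples()]).
#' @param markers Marker columns to summarize.
#' @return Data frame, one row per (group, marker) with any non-missing data.
#' @export
summarize_cohort <- function(samples,
                             markers = c("sflt1_pg_ml", "free_plgf_pg_ml",
                                         "total_plgf_pg_ml")) {
  if (!is.data.frame(samples) || nrow(samples) == 0L) {
    stop_plgf("samples must be a non-empty data frame", "input_error")
  }
  groups <- if ("group" %in% names(samples)) unique(samples$group) else NA_character_
  out <- list()
  for (g in groups) {
    sub <- if (is.na(g)) samples else samples[samples$group == g, , drop = FALSE]
    for (m in intersect(markers, names(samples))) {
      v <- sub[[m]][!is.na(sub[[m]])]
      if (length(v) == 0L) next
      row <- median_iqr(v, group = if (is.na(g)) "all" else g)
      row$marker <- m
      out[[length(out) + 1L]] <- row[, c("group", "marker", "n", "median", "q1", "q3")]
    }
  }
  do.call(rbind, out)
}

#' Two-group comparison with a Shapiro-Wilk normality gate
#'
#' If the Shapiro-Wilk test accepts normality (p > `alpha_normality`) in both
#' groups, a Student t test (equal variances) is run; otherwise a
#' Mann-Whitney U test. The Mann-Whitney p-value is exact (full enumeration
#' of group assignments) when both groups have n <= 8, else the normal
#' approximation with tie correction. Constant (zero-variance) groups are
#' routed to the Mann-Whitney branch.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @param alpha_normality Shapiro-Wilk acceptance threshold (default 0.05).
#' @return A `comparison_result`; `method_notes` records which branch ran.
#' @examples
#' compare_two(c(1, 2, 3), c(100, 101, 102))  # exact MWU p = 0.1
#' @export
compare_two <- function(a, b, alpha_normality = 0.05) {
  for (v in list(a, b)) {
    if (length(v) < 3 || any(!is.finite(v))) {
      stop_plgf("each group needs >= 3 finite values", "input_error")
    }
  }
  if (groups_normal(list(a, b), alpha_normality)) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    comparison_result("student_t", unname(tt$statistic), tt$p.value,
                      c(length(a), length(b)),
                      "Student t test (Shapiro-Wilk accepted normality in both groups)")
  } else {
    mw <- mann_whitney_u(a, b)
    comparison_result("mann_whitney_U", mw$u, mw$p, c(length(a), length(b)),
                      paste0("Mann-Whitney U (", mw$method,
                             "); Shapiro-Wilk rejected normality"))
  }
}

groups_normal <- function(groups, alpha) {
  all(vapply(groups, function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }, logical(1)))
}

# Mann-Whitney U with exact enumeration for small groups. U counts, over all
# (a_i, b_j) pairs, how often a_i > b_j (+1/2 per tie); equivalently
# U = rank-sum(a) - n1(n1+1)/2 on pooled average ranks.
mann_whitney_u <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p_lo <- mean(u_all <= u + 1e-9)
    p_hi <- mean(u_all >= u - 1e-9)
    list(u = u, p = min(1, 2 * min(p_lo, p_hi)),
         method = "exact enumeration of all group assignments")
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u, p = 1, method = "degenerate (all tied)"))
    z <- (u - mu) / sqrt(sigma2)
    list(u = u, p = 2 * stats::pnorm(-abs(z)),
         method = "normal approximation with tie correction")
  }
}

#' Multi-group comparison with post hoc pairwise tests
#'
#' Normality-gated omnibus test over >= 3 groups: one-way ANOVA when the
#' Shapiro-Wilk test accepts normality in every group, Kruskal-Wallis
#' otherwise. Pairwise follow-up uses [compare_two()] (t or Mann-Whitney per
#' pair) with Bonferroni correction by default; `posthoc = "dunn"` gives
#' Dunn's z tests on the pooled Kruskal-Wallis ranks instead.
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each n >= 3).
#' @param alpha_normality Shapiro-Wilk acceptance threshold (default 0.05).
#' @param posthoc `"pairwise"` (default) or `"dunn"`.
#' @return A `comparison_result` whose `posthoc` field is a data frame with
#'   columns `group1`, `group2`, `p_raw`, `p_adjusted`.
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
compare_groups <- function(groups, alpha_normality = 0.05,
                           posthoc = c("pairwise", "dunn")) {
  posthoc <- match.arg(posthoc)
  if (!is.list(groups) || length(groups) < 3) {
    stop_plgf("need >= 3 groups", "input_error")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  for (v in groups) {
    if (length(v) < 3 || any(!is.finite(v))) {
      stop_plgf("each group needs >= 3 finite values", "input_error")
    }
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (groups_normal(groups, alpha_normality)) {
    fit <- stats::aov(values ~ labels)
    tab <- summary(fit)[[1L]]
    res <- comparison_result("anova_F", tab$`F value`[1L], tab$`Pr(>F)`[1L],
                             lengths(groups),
                             "one-way ANOVA (all groups passed Shapiro-Wilk)")
  } else {
    kw <- stats::kruskal.test(values, labels)
    res <- comparison_result("kruskal_wallis_H", unname(kw$statistic),
                             kw$p.value, lengths(groups),
                             "Kruskal-Wallis (Shapiro-Wilk rejected normality)")
  }
  pairs <- utils::combn(names(groups), 2)
  if (posthoc == "pairwise") {
    p_raw <- apply(pairs, 2, function(gg) {
      compare_two(groups[[gg[1L]]], groups[[gg[2L]]], alpha_normality)$p_value
    })
  } else {
    p_raw <- dunn_p(values, labels, pairs)
  }
  res$posthoc <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                            p_raw = p_raw,
                            p_adjusted = stats::p.adjust(p_raw, "bonferroni"))
  res
}

# Dunn's z on pooled ranks with tie correction
dunn_p <- function(values, labels, pairs) {
  rk <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rk <- tapply(rk, labels, mean)
  n_g <- tapply(rk, labels, length)
  apply(pairs, 2, function(gg) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[gg[1L]]] + 1 / n_g[[gg[2L]]]))
    z <- (mean_rk[[gg[1L]]] - mean_rk[[gg[2L]]]) / se
    2 * stats::pnorm(-abs(z))
  })
}

#' Classify the sFlt-1/free-PlGF ratio against the clinical cutoffs
#'
#' The angiogenic-imbalance index sFlt-1/free PlGF: ratios <= 38 predict the
#' short-term absence of preeclampsia ("low"), ratios >= 85 flag high risk of
#' adverse outcomes ("high"); in between is "intermediate". Both cutoffs are
#' inclusive. Vectorized.
#'
#' @param sflt1 sFlt-1 (pg/mL).
#' @param free_plgf Free PlGF (pg/mL), strictly positive.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @examples
#' ratio_classify(c(3800, 6000, 77762), c(100, 100, 208))
#' @export
ratio_classify <- function(sflt1, free_plgf) {
  check_nonneg(sflt1, "sflt1")
  if (any(!is.finite(free_plgf)) || any(free_plgf <= 0)) {
    stop_plgf("ratio undefined: free_plgf must be strictly positive",
              "undefined_ratio")
  }
  ratio <- sflt1 / free_plgf
  factor(ifelse(ratio <= 38, "low", ifelse(ratio >= 85, "high", "intermediate")),
         levels = c("low", "intermediate", "high"))
}

#' Percent of the antepartum level remaining postpartum
#'
#' @param antepartum Antepartum level (pg/mL), strictly positive.
#' @param postpartum Postpartum level (pg/mL).
#' @return Percentage `100 * postpartum / antepartum`. Vectorized.
#' @examples
#' percent_remaining(2054, 163)  # ~7.9% of total PlGF left after delivery
#' @export
percent_remaining <- function(antepartum, postpartum) {
  check_nonneg(postpartum, "postpartum")
  if (any(!is.finite(antepartum)) || any(antepartum <= 0)) {
    stop_plgf("antepartum level must be strictly positive", "input_error")
  }
  100 * postpartum / antepartum
}

#' Preeclampsia classification (ISSHP 2001, as restated by the study)
#'
#' New-onset hypertension is systolic BP >= 140 or diastolic BP >= 90 mm Hg
#' at or after 20 weeks' gestation; preeclampsia additionally requires
#' proteinuria by any of: protein-to-creatinine ratio >= 30 mg/mmol,
#' >= 300 mg/24 h, or dipstick >= 2+. Hypertension without proteinuria is
#' gestational hypertension.
#'
#' @param sbp,dbp Blood pressure (mm Hg). Required.
#' @param ga_weeks Gestational age at measurement (weeks). Required.
#' @param proteinuria_pcr Protein/creatinine ratio (mg/mmol), or `NA`.
#' @param proteinuria_24h 24-hour protein (mg/24 h), or `NA`.
#' @param dipstick Urine dipstick grade 0-4, or `NA`.
#' @return One of `"none"`, `"gestational_hypertension"`, `"preeclampsia"`.
#' @examples
#' classify_pe(sbp = 150, dbp = 95, ga_weeks = 32, proteinuria_pcr = 35)
#' @export
classify_pe <- function(sbp, dbp, ga_weeks, proteinuria_pcr = NA,
                        proteinuria_24h = NA, dipstick = NA) {
  if (any(is.na(c(sbp, dbp, ga_weeks)))) {
    stop_plgf("sbp, dbp and ga_weeks are required", "incomplete_record")
  }
  if (ga_weeks <= 0 || ga_weeks >= 45) {
    stop_plgf("ga_weeks must lie in (0, 45)", "incomplete_record")
  }
  hypertensive <- (sbp >= 140 || dbp >= 90) && ga_weeks >= 20
  if (!hypertensive) return("none")
  proteinuric <- isTRUE(proteinuria_pcr >= 30) ||
    isTRUE(proteinuria_24h >= 300) ||
    isTRUE(dipstick >= 2)
  if (proteinuric) "preeclampsia" else "gestational_hypertension"
}

#' HELLP classification (ISSHP 2013, as restated by the study)
#'
#' Three criteria: (1) platelets < 100 x 10^9/L; (2) ALT or AST >= 2x the
#' upper limit of normal; (3) LDH >= 2x the upper reference limit or
#' > 650 IU/L. All three give HELLP syndrome; exactly two give partial
#' HELLP.
#'
#' @param platelets Platelet count (10^9/L). Required.
#' @param alt,ast Transaminases (IU/L); at least one required.
#' @param ldh Lactate dehydrogenase (IU/L). Required.
#' @param uln_alt,uln_ast,uln_ldh Upper limits of normal (IU/L) for the
#'   corresponding assays; required alongside the measurement they scale.
#' @return One of `"none"`, `"partial_hellp"`, `"hellp"`.
#' @examples
#' classify_hellp(platelets = 90, alt = 120, uln_alt = 40,
#'                ldh = 700, uln_ldh = 250)
#' @export
classify_hellp <- function(platelets, alt = NA, ast = NA, ldh,
                           uln_alt = NA, uln_ast = NA, uln_ldh = NA) {
  if (is.na(platelets) || is.na(ldh)) {
    stop_plgf("platelets and ldh are required", "incomplete_record")
  }
  if (is.na(alt) && is.na(ast)) {
    stop_plgf("at least one of alt/ast is required", "incomplete_record")
  }
  if ((!is.na(alt) && is.na(uln_alt)) || (!is.na(ast) && is.na(uln_ast))) {
    stop_plgf("upper limit of normal required for each supplied transaminase",
              "incomplete_record")
  }
  if (is.na(uln_ldh) && ldh <= 650) {
    # without an LDH ULN the >650 absolute arm still decides, but only
    # when it fires; otherwise the record is not classifiable
    stop_plgf("uln_ldh required when ldh <= 650", "incomplete_record")
  }
  low_platelets <- platelets < 100
  enzymes <- isTRUE(alt >= 2 * uln_alt) || isTRUE(ast >= 2 * uln_ast)
  high_ldh <- isTRUE(ldh >= 2 * uln_ldh) || ldh > 650
  k <- sum(low_platelets, enzymes, high_ldh)
  if (k == 3L) "hellp" else if (k == 2L) "partial_hellp" else "none"
}
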