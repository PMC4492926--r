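# Outcome analysis of the four-arm trial: arm tabulations, 2x2 odds
# ratios with Wald intervals, chi-squared heterogeneity, proportions,
# logistic regression by IRLS, and the design power calculation.

new_arm_outcome_table <- function(management, correctness) {
  totals_m <- rowSums(management)
  totals_c <- rowSums(correctness)
  if (!isTRUE(all.equal(totals_m, totals_c))) {
    stop("management and correctness counts imply different arm totals",
         call. = FALSE)
  }
  structure(list(management = management, correctness = correctness,
                 totals = totals_m),
            class = "arm_outcome_table")
}

#' @export
print.arm_outcome_table <- function(x, ...) {
  cat("Arm outcome table (n =", sum(x$totals), ")\n\nManagement:\n")
  print(x$management)
  cat("\nPost-test probability answer:\n")
  print(x$correctness)
  invisible(x)
}

#' Tabulate respondent records into an arm outcome table
#'
#' Classifies each record's management choice ([classify_management()]) and
#' post-test answer ([score_posttest_answer()]) and counts by arm.
#'
#' @param records Data frame with columns `arm`, `management`,
#'   `posttest_answer` (the schema written by [write_cohort()]).
#' @param key Correct post-test answer in percent.
#' @param margin Scoring margin in percentage points.
#' @return An `"arm_outcome_table"` (management and correctness count
#'   matrices plus arm totals).
#' @export
tabulate_arms <- function(records, key = 86, margin = 1) {
  arms <- trial_arms()
  if (nrow(records) > 0 && !all(records$arm %in% arms)) {
    bad <- unique(records$arm[!records$arm %in% arms])
    stop("unknown arm label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  arm <- factor(records$arm, levels = arms)
  mgmt <- factor(classify_management(records$management),
                 levels = MANAGEMENT_LEVELS)
  status <- factor(score_posttest_answer(records$posttest_answer, key, margin),
                   levels = CORRECTNESS_LEVELS)
  management <- unclass(table(arm, mgmt))
  correctness <- unclass(table(arm, status))
  dimnames(management) <- list(arms, MANAGEMENT_LEVELS)
  dimnames(correctness) <- list(arms, CORRECTNESS_LEVELS)
  new_arm_outcome_table(management, correctness)
}

#' Odds ratio with Wald confidence interval
#'
#' OR for events in group A versus group B, dichotomised as event versus
#' everything else. The log-scale standard error is the square root of the
#' summed reciprocal cell counts; the interval is exp(log OR -/+ z * se).
#' If any of the four cells is zero, the Haldane correction (add 0.5 to
#' every cell) is applied and flagged.
#'
#' @param event_a,total_a Event count and group size in group A.
#' @param event_b,total_b Event count and group size in group B (reference).
#' @param conf_level Confidence level (default 0.95, z = 1.96).
#' @return An object of class `"odds_ratio_result"` with fields
#'   `odds_ratio`, `log_or`, `se_log`, `ci_low`, `ci_high`,
#'   `continuity_corrected`.
#' @examples
#' odds_ratio(142, 218, 142, 255)  # 1.49 (1.02, 2.16)
#' @export
odds_ratio <- function(event_a, total_a, event_b, total_b, conf_level = 0.95) {
  counts <- c(event_a, total_a, event_b, total_b)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      event_a > total_a || event_b > total_b || total_a == 0 || total_b == 0) {
    stop("need totals > 0 and 0 <= events <= totals", call. = FALSE)
  }
  cells <- c(a = event_a, c = total_a - event_a,
             b = event_b, d = total_b - event_b)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  if (any(cells == 0)) {
    stop("degenerate 2x2 table even after continuity correction", call. = FALSE)
  }
  log_or <- log(cells[["a"]] / cells[["c"]]) - log(cells[["b"]] / cells[["d"]])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(odds_ratio = exp(log_or), log_or = log_or, se_log = se,
                 ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
                 continuity_corrected = corrected),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f, %.2f)%s\n", x$odds_ratio, x$ci_low,
              x$ci_high,
              if (x$continuity_corrected) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Per-arm odds ratios against the reference arm
#'
#' Dichotomises the chosen outcome as target category versus all other
#' categories (including blank) and computes [odds_ratio()] of each
#' non-reference arm against the text-summary arm.
#'
#' @param table An `"arm_outcome_table"`.
#' @param outcome `"treat"` (management family) or `"correct"` (answer
#'   family).
#' @param reference Reference arm (default `"text"`).
#' @return Data frame with one row per comparison arm: `arm`, `events`,
#'   `total`, `odds_ratio`, `ci_low`, `ci_high`.
#' @export
arm_odds_ratios <- function(table, outcome = c("treat", "correct"),
                            reference = "text") {
  stopifnot(inherits(table, "arm_outcome_table"))
  outcome <- match.arg(outcome)
  counts <- if (outcome == "treat") table$management else table$correctness
  arms <- rownames(counts)
  stopifnot(reference %in% arms)
  others <- setdiff(arms, reference)
  rows <- lapply(others, function(a) {
    or <- odds_ratio(counts[a, outcome], table$totals[[a]],
                     counts[reference, outcome], table$totals[[reference]])
    data.frame(arm = a, events = counts[a, outcome],
               total = table$totals[[a]], odds_ratio = or$odds_ratio,
               ci_low = or$ci_low, ci_high = or$ci_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-squared test of homogeneity
#'
#' The classic statistic sum (O - E)^2 / E over an r x c count table with
#' expectations from the product of margins; df = (r - 1)(c - 1). No
#' continuity correction.
#'
#' @param table Numeric matrix of counts with all expected cells > 0.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) == 0) {
    stop("table must hold non-negative counts with a positive total",
         call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    stop("zero expected cell; collapse empty rows/columns before testing",
         call. = FALSE)
  }
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Format a p-value for reporting
#'
#' Three significant figures with a "<0.001" display floor.
#'
#' @param p Numeric p-value.
#' @return Character scalar.
#' @export
format_p <- function(p) {
  if (p < 0.001) "<0.001" else formatC(signif(p, 3), format = "fg")
}

#' Proportion answering correctly
#'
#' @param table An `"arm_outcome_table"`.
#' @param arm One arm name or `"overall"`.
#' @return List with `count`, `total`, `percent` (exact) and `percent_1dp`
#'   (rounded half up to one decimal place, the reporting convention).
#' @examples
#' proportion_correct(reference_outcome_counts(), "pmp")  # 87/218, 39.9%
#' @export
proportion_correct <- function(table, arm = "overall") {
  stopifnot(inherits(table, "arm_outcome_table"))
  if (identical(arm, "overall")) {
    count <- sum(table$correctness[, "correct"])
    total <- sum(table$totals)
  } else {
    stopifnot(arm %in% rownames(table$correctness))
    count <- table$correctness[arm, "correct"]
    total <- table$totals[[arm]]
  }
  if (total == 0) stop("zero total: no respondents in ", arm, call. = FALSE)
  pct <- 100 * count / total
  list(count = as.integer(count), total = as.integer(total),
       percent = pct, percent_1dp = round_half_up(pct, 1))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit via Newton scoring on the working
#' response, the standard IRLS scheme. Written out rather than delegated so
#' that the closed-form 2x2 odds ratios and the regression route stay
#' independent checks of one another. Supports case weights so aggregated
#' count data fit exactly.
#'
#' @param y Binary outcome vector (0/1 or logical).
#' @param x Design matrix including the intercept column.
#' @param weights Optional non-negative case weights (default 1).
#' @param tol Convergence tolerance on the score (gradient) max-norm.
#' @param max_iter Iteration cap.
#' @return An object of class `"logistic_fit"`: `coefficients`, `se`,
#'   `vcov`, `converged`, `iterations`, `gradient_norm`, `deviance`,
#'   `separation_suspected`.
#' @export
logistic_irls <- function(y, x, weights = NULL, tol = 1e-8, max_iter = 25) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(y) == nrow(x), length(weights) == length(y),
            all(weights >= 0), all(y >= 0 & y <= 1))
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient", call. = FALSE)
  beta <- rep(0, ncol(x))
  converged <- FALSE
  grad_norm <- Inf
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- weights * mu * (1 - mu)
    grad <- drop(crossprod(x, weights * (y - mu)))
    grad_norm <- max(abs(grad))
    if (grad_norm < tol) {
      converged <- TRUE
      break
    }
    xtwx <- crossprod(x, x * w)
    beta <- beta + solve(xtwx, grad)
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- weights * mu * (1 - mu)
  vcov <- solve(crossprod(x, x * w))
  dev <- -2 * sum(weights * (y * log(pmax(mu, 1e-300)) +
                               (1 - y) * log(pmax(1 - mu, 1e-300))))
  separation <- !converged || any(abs(beta) > 15)
  if (!converged) {
    warning("IRLS did not converge in ", max_iter,
            " iterations (possible separation)", call. = FALSE)
  } else if (separation) {
    warning("possible separation: a fitted log-odds ratio exceeds 15",
            call. = FALSE)
  }
  names(beta) <- colnames(x)
  structure(list(coefficients = beta,
                 se = sqrt(diag(vcov)),
                 vcov = vcov, converged = converged, iterations = iter,
                 gradient_norm = grad_norm, deviance = dev,
                 separation_suspected = separation),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (%s in %d IRLS iterations)\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(data.frame(estimate = x$coefficients, se = x$se,
                   odds_ratio = exp(x$coefficients)))
  invisible(x)
}

#' Arm-effect logistic regression from an outcome table
#'
#' Expands the table into aggregated binomial rows, codes the arm as a
#' 4-level factor with the text arm as reference, and fits by
#' [logistic_irls()]. With a saturated one-factor model the exponentiated
#' coefficients equal the stratum 2x2 odds ratios, which is how the
#' regression route cross-checks the closed form.
#'
#' @param table An `"arm_outcome_table"`.
#' @param outcome `"treat"` or `"correct"` (target vs all other
#'   categories).
#' @param reference Reference arm.
#' @return A `"logistic_fit"`; coefficient names are `(Intercept)` and
#'   `arm<name>`.
#' @export
fit_arm_logistic <- function(table, outcome = c("treat", "correct"),
                             reference = "text") {
  stopifnot(inherits(table, "arm_outcome_table"))
  outcome <- match.arg(outcome)
  counts <- if (outcome == "treat") table$management else table$correctness
  arms <- rownames(counts)
  events <- counts[, outcome]
  nonevents <- table$totals - events
  arm_f <- factor(rep(arms, 2), levels = c(reference, setdiff(arms, reference)))
  y <- rep(c(1, 0), each = length(arms))
  w <- c(events, nonevents)
  x <- stats::model.matrix(~arm_f)
  colnames(x) <- sub("arm_f", "arm", colnames(x))
  keep <- w > 0
  logistic_irls(y[keep], x[keep, , drop = FALSE], weights = w[keep])
}

#' Design power specification
#'
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param n_per_arm Respondents per arm (>= 2).
#' @param baseline_p Reference-arm event probability.
#' @return Object of class `"power_spec"`.
#' @export
power_spec <- function(alpha = 0.05, power = 0.80, n_per_arm = 200,
                       baseline_p = 0.5) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, n_per_arm >= 2)
  baseline_p <- as_proportion(baseline_p, name = "baseline_p",
                              open_low = TRUE, open_high = TRUE)
  structure(list(alpha = alpha, power = power,
                 n_per_arm = as.integer(n_per_arm), baseline_p = baseline_p),
            class = "power_spec")
}

#' Minimal detectable difference between two proportions
#'
#' Normal-approximation two-sample formula:
#' (z\[1 - alpha/2\] + z\[power\]) * sqrt(2 p (1 - p) / n), the difference in
#' event probability a two-arm comparison of `n_per_arm` per group detects
#' at the stated power and two-sided significance.
#'
#' @param spec A [power_spec()], or alpha when giving arguments directly.
#' @param power,n_per_arm,baseline_p Used when `spec` is a bare alpha.
#' @return Detectable difference as a proportion.
#' @examples
#' detectable_difference(power_spec(0.05, 0.8, 200, 0.5))  # ~0.140
#' @export
detectable_difference <- function(spec, power = 0.80, n_per_arm = 200,
                                  baseline_p = 0.5) {
  if (!inherits(spec, "power_spec")) {
    spec <- power_spec(alpha = spec, power = power, n_per_arm = n_per_arm,
                       baseline_p = baseline_p)
  }
  z <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  p <- spec$baseline_p
  z * sqrt(2 * p * (1 - p) / spec$n_per_arm)
}

#' Power achieved for a stated difference between two proportions
#'
#' Inverse of [detectable_difference()] under the same normal
#' approximation.
#'
#' @param difference Difference in event probability between arms.
#' @param spec A [power_spec()] (its `power` field is ignored).
#' @return Achieved power.
#' @export
power_for_difference <- function(difference, spec) {
  stopifnot(inherits(spec, "power_spec"))
  p <- spec$baseline_p
  se <- sqrt(2 * p * (1 - p) / spec$n_per_arm)
  stats::pnorm(difference / se - stats::qnorm(1 - spec$alpha / 2))
}

#' Full outcome analysis of a respondent cohort
#'
#' Tabulates records, computes both families of per-arm odds ratios, the
#' chi-squared heterogeneity test on correct-vs-not, and overall/per-arm
#' correct proportions.
#'
#' @param records Respondent data frame, or an `"arm_outcome_table"`.
#' @param key,margin Scoring parameters (ignored when a table is given).
#' @return List of class `"trial_analysis"`: `table`, `or_treat`,
#'   `or_correct`, `heterogeneity`, `overall`, `per_arm`, `margin`.
#' @export
analyze_trial <- function(records, key = 86, margin = 1) {
  table <- if (inherits(records, "arm_outcome_table")) {
    records
  } else {
    tabulate_arms(records, key = key, margin = margin)
  }
  correct_vs_not <- cbind(correct = table$correctness[, "correct"],
                          other = table$totals - table$correctness[, "correct"])
  per_arm <- lapply(rownames(table$correctness), function(a) {
    proportion_correct(table, a)
  })
  names(per_arm) <- rownames(table$correctness)
  structure(list(table = table,
                 or_treat = arm_odds_ratios(table, "treat"),
                 or_correct = arm_odds_ratios(table, "correct"),
                 heterogeneity = chi_squared(correct_vs_not),
                 overall = proportion_correct(table, "overall"),
                 per_arm = per_arm,
                 margin = margin),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("Trial analysis (margin +/-%g%%)\n", x$margin))
  cat(sprintf("Overall correct: %d/%d (%.1f%%)\n", x$overall$count,
              x$overall$total, x$overall$percent_1dp))
  cat(sprintf("Heterogeneity chi-squared %.1f on %d df, p %s\n",
              x$heterogeneity$statistic, x$heterogeneity$df,
              format_p(x$heterogeneity$p_value)))
  cat("\nOR (treat vs other):\n")
  print(x$or_treat, digits = 3)
  cat("\nOR (correct vs other):\n")
  print(x$or_correct, digits = 3)
  invisible(x)
}
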