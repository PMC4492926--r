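test_that("odds ratios reproduce the printed 2x2 examples", {
  treat_pmp <- odds_ratio(142, 218, 142, 255)
  expect_equal(round_half_up(treat_pmp$odds_ratio, 2), 1.49)
  expect_equal(round_half_up(treat_pmp$ci_low, 2), 1.02)
  expect_equal(round_half_up(treat_pmp$ci_high, 2), 2.16)
  expect_false(treat_pmp$continuity_corrected)

  correct_nomo <- odds_ratio(50, 194, 30, 255)
  expect_equal(round_half_up(correct_nomo$odds_ratio, 2), 2.60)
  expect_equal(round_half_up(correct_nomo$ci_low, 2), 1.58)
  expect_equal(round_half_up(correct_nomo$ci_high, 2), 4.29)

  identity <- odds_ratio(10, 20, 10, 20)
  expect_equal(identity$odds_ratio, 1)
  expect_true(identity$ci_low <= 1 && 1 <= identity$ci_high)

  # Wald interval structure
  expect_equal(treat_pmp$ci_low,
               exp(treat_pmp$log_or - stats::qnorm(0.975) * treat_pmp$se_log))
  expect_equal(treat_pmp$se_log, sqrt(1 / 142 + 1 / 76 + 1 / 142 + 1 / 113))
})

test_that("zero cells trigger the Haldane correction or an error", {
  zed <- odds_ratio(0, 20, 10, 20)
  expect_true(zed$continuity_corrected)
  expect_true(is.finite(zed$odds_ratio) && zed$odds_ratio > 0)
  expect_error(odds_ratio(5, 4, 3, 10))
  expect_error(odds_ratio(5, 0, 3, 10))
})

test_that("chi-squared matches brute force and stats::chisq.test", {
  flat <- matrix(c(5, 5, 5, 5), 2)
  res <- chi_squared(flat)
  expect_equal(res$statistic, oracle_chisq_stat(flat))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(7)
  for (rep in 1:20) {
    r <- sample(2:4, 1)
    cc <- sample(2:3, 1)
    tab <- matrix(rpois(r * cc, 8) + 1, r, cc)
    res <- chi_squared(tab)
    expect_equal(res$statistic, oracle_chisq_stat(tab), tolerance = 1e-12)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
  expect_error(chi_squared(matrix(c(0, 0, 1, 2), 2)), "zero expected")
})

test_that("correct-answer proportions match the printed per-arm values", {
  ref <- reference_outcome_counts()
  expect_equal(proportion_correct(ref, "text")$percent_1dp, 11.8)
  expect_equal(proportion_correct(ref, "nomogram")$percent_1dp, 25.8)
  expect_equal(proportion_correct(ref, "pmp")$percent_1dp, 39.9)
  expect_equal(proportion_correct(ref, "nft")$percent_1dp, 35.3)
  overall <- proportion_correct(ref, "overall")
  expect_identical(overall$count, 240L)
  expect_identical(overall$total, 874L)
})

test_that("tabulation matches a brute-force group-by and ignores order", {
  model <- default_cohort_model()
  records <- sample_cohort(model, seed = 11)
  tab <- tabulate_arms(records)
  # brute force recount of one family
  status <- score_posttest_answer(records$posttest_answer, 86, 1)
  for (a in trial_arms()) {
    expect_equal(unname(tab$correctness[a, "correct"]),
                 sum(records$arm == a & status == "correct"))
  }
  expect_equal(unname(tab$totals), as.vector(table(factor(records$arm,
                                                          trial_arms()))))
  # permutation invariance
  set.seed(3)
  shuffled <- records[sample.int(nrow(records)), ]
  expect_identical(tabulate_arms(shuffled), tab)
  # empty input
  empty <- tabulate_arms(records[0, ])
  expect_true(all(empty$management == 0) && all(empty$correctness == 0))
  bad <- records
  bad$arm[1] <- "armX"
  expect_error(tabulate_arms(bad), "unknown arm")
})

test_that("IRLS agrees with glm on simulated covariate data", {
  set.seed(2024)
  n <- 800
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  beta_true <- c(-0.5, 0.8, -1.1)
  y <- rbinom(n, 1, plogis(drop(x %*% beta_true)))
  fit <- logistic_irls(y, x)
  ref <- stats::glm.fit(x, y, family = stats::binomial())
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-8)
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-8)
  ref_se <- sqrt(diag(chol2inv(chol(crossprod(x, x * ref$weights)))))
  expect_equal(unname(fit$se), ref_se, tolerance = 1e-6)
  expect_error(logistic_irls(y, cbind(x, x[, 2])), "rank deficient")
})

test_that("IRLS recovers known coefficients within 2 SE at n = 5000", {
  set.seed(55)
  n <- 5000
  x <- cbind(1, rnorm(n), runif(n, -1, 1))
  beta_true <- c(0.2, 0.5, -0.7)
  y <- rbinom(n, 1, plogis(drop(x %*% beta_true)))
  fit <- logistic_irls(y, x)
  expect_true(all(abs(fit$coefficients - beta_true) < 2 * fit$se))
})

test_that("intercept-only fit on balanced outcomes is zero", {
  y <- rep(c(0, 1), 50)
  fit <- logistic_irls(y, matrix(1, 100, 1))
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-12)
})

test_that("saturated arm-factor regression equals the closed-form ORs", {
  ref <- reference_outcome_counts()
  for (outcome in c("treat", "correct")) {
    fit <- fit_arm_logistic(ref, outcome)
    expect_true(fit$converged)
    ors <- arm_odds_ratios(ref, outcome)
    expect_equal(unname(exp(fit$coefficients[paste0("arm", ors$arm)])),
                 ors$odds_ratio, tolerance = 1e-6)
  }
})

test_that("separation is flagged, not silent", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- cbind(1, y)  # perfectly separating covariate
  expect_warning(fit <- logistic_irls(y, x), "separation")
  expect_true(fit$separation_suspected)
})

test_that("detectable difference: closed form, design sweep, inversion", {
  spec <- power_spec(0.05, 0.8, 200, 0.5)
  dd <- detectable_difference(spec)
  z <- stats::qnorm(0.975) + stats::qnorm(0.8)
  expect_equal(dd, z * sqrt(2 * 0.25 / 200), tolerance = 1e-12)
  expect_equal(dd, 0.14008, tolerance = 1e-4)

  # plugging the difference back returns the requested power
  expect_equal(power_for_difference(dd, spec), 0.8, tolerance = 1e-6)

  # more power demands a larger detectable difference
  powers <- seq(0.5, 0.95, by = 0.05)
  dds <- vapply(powers, function(pw) {
    detectable_difference(power_spec(power = pw))
  }, numeric(1))
  expect_true(all(diff(dds) > 0))
  expect_error(power_spec(n_per_arm = 1), "n_per_arm")
})

test_that("p-value formatting uses 3 significant figures with a floor", {
  expect_identical(format_p(0.0004), "<0.001")
  expect_identical(format_p(0.0435678), "0.0436")
  expect_identical(format_p(0.5), "0.5")
})
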