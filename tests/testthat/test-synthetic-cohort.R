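test_that("default model restates the reference margins", {
  model <- default_cohort_model()
  expect_equal(model$n, 874L)
  expect_equal(unname(model$arm_probs["text"]), 255 / 874)
  expect_equal(unname(model$correctness_probs["pmp", "correct"]), 87 / 218)
  expect_equal(rowSums(model$management_probs), rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(rowSums(model$correctness_probs), rep(1, 4),
               ignore_attr = TRUE)
})

test_that("model validation rejects broken probability vectors", {
  model <- default_cohort_model()
  expect_error(cohort_model(n = 10, arm_probs = c(text = 0.5, nomogram = 0.5,
                                                  pmp = 0.5, nft = 0.5),
                            management_probs = model$management_probs,
                            correctness_probs = model$correctness_probs),
               "sum to 1")
  bad_mgmt <- model$management_probs
  bad_mgmt[1, 1] <- bad_mgmt[1, 1] + 0.1
  expect_error(cohort_model(n = 10, arm_probs = model$arm_probs,
                            management_probs = bad_mgmt,
                            correctness_probs = model$correctness_probs),
               "sum to 1")
})

test_that("sampling is deterministic for a fixed seed", {
  model <- default_cohort_model()
  a <- sample_cohort(model, seed = 42)
  b <- sample_cohort(model, seed = 42)
  expect_identical(a, b)
  c <- sample_cohort(model, seed = 43)
  expect_false(identical(a, c))
  expect_equal(nrow(a), 874)
  expect_true(all(a$arm %in% trial_arms()))
  expect_true(all(a$confidence %in% 1:5))
  # numeric answers stay in range; blanks allowed
  num <- suppressWarnings(as.numeric(a$posttest_answer))
  expect_true(all(is.na(num) | (num >= 0 & num <= 100)))
  expect_true(all(a$posttest_answer[is.na(num)] == ""))
})

test_that("cohort moments track the generating model", {
  model <- default_cohort_model()
  records <- sample_cohort(model, seed = 20120710)
  tab <- tabulate_arms(records)
  # overall correct fraction within 3 Monte-Carlo SE of 240/874
  p_ref <- 240 / 874
  mc_se <- sqrt(p_ref * (1 - p_ref) / model$n)
  p_hat <- proportion_correct(tab, "overall")$percent / 100
  expect_lt(abs(p_hat - p_ref), 3 * mc_se)
  # tutorial uptake near its calibrated marginal probability
  up <- mean(records$tutorial_uptake == "yes")
  expect_lt(abs(up - model$tutorial_uptake), 3 * 0.0163)
  # quiz totals near the knowledge model mean
  key <- default_quiz_key()
  totals <- rowSums(vapply(1:4, function(q) {
    score_posttest_answer(records[[paste0("q", q)]],
                          c(key$q1, key$q2, key$q3, key$q4)[q]) == "correct"
  }, logical(nrow(records)))) +
    (records$q5 == "Ruling out")
  expect_lt(abs(mean(totals) - model$knowledge_mean),
            3 * model$knowledge_sd / sqrt(model$n))
})

test_that("large-sample management proportions converge to the model", {
  model <- default_cohort_model()
  model$n <- 100000L
  records <- sample_cohort(model, seed = 5)
  tab <- tabulate_arms(records)
  props <- tab$management / tab$totals
  expect_true(all(abs(props - model$management_probs) < 0.01))
})

test_that("exact-table cohort tabulates to the reference counts", {
  model <- default_cohort_model()
  cohort <- sample_exact_table(model)
  ref <- reference_outcome_counts()
  tab <- tabulate_arms(cohort)
  expect_equal(tab$management, ref$management)
  expect_equal(tab$correctness, ref$correctness)
  expect_equal(tab$totals, ref$totals)
  # permuting records leaves the analysis unchanged
  set.seed(9)
  shuffled <- cohort[sample.int(nrow(cohort)), ]
  expect_equal(analyze_trial(shuffled)$or_correct, analyze_trial(cohort)$or_correct)
  # non-integral probabilities are refused
  broken <- model
  broken$n <- 873L
  expect_error(sample_exact_table(broken), "integer counts")
})

test_that("cohort CSV and model JSON round-trip", {
  model <- default_cohort_model()
  records <- sample_cohort(model, seed = 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(records, csv)
  back <- read_cohort(csv)
  expect_equal(nrow(back), nrow(records))
  expect_identical(back$posttest_answer, records$posttest_answer)
  expect_identical(tabulate_arms(back), tabulate_arms(records))

  js <- withr::local_tempfile(fileext = ".json")
  write_cohort_model(model, js)
  model2 <- read_cohort_model(js)
  expect_equal(model2$arm_probs, model$arm_probs)
  expect_equal(model2$management_probs, model$management_probs)
  expect_equal(model2$knowledge_sd, model$knowledge_sd)
  expect_identical(sample_cohort(model2, seed = 8), records)
})

test_that("tutorial-uptake coefficient is recoverable on one large cohort", {
  model <- default_cohort_model()
  model$n <- 10000L
  records <- sample_cohort(model, seed = 314)
  key <- default_quiz_key()
  totals <- rowSums(vapply(1:4, function(q) {
    score_posttest_answer(records[[paste0("q", q)]],
                          c(key$q1, key$q2, key$q3, key$q4)[q]) == "correct"
  }, logical(nrow(records)))) +
    (records$q5 == "Ruling out")
  x <- cbind(1, score = totals, conf = records$confidence)
  fit <- logistic_irls(records$tutorial_uptake == "yes", x)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["score"]] - log(1.18)),
            2 * fit$se[[2]])
})
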