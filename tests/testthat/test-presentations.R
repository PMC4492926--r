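test_that("frequency tree reproduces the 1000-patient reference cohort", {
  tr <- frequency_tree(1000, 0.5, vignette_accuracy())
  expect_equal(tr$diseased, 500L)
  expect_equal(tr$nondiseased, 500L)
  expect_equal(tr$tp, 300L)
  expect_equal(tr$fn, 200L)
  expect_equal(tr$fp, 50L)
  expect_equal(tr$tn, 450L)

  perfect <- frequency_tree(10, 0.5, test_accuracy(1, 1))
  expect_equal(c(perfect$tp, perfect$fn, perfect$fp, perfect$tn),
               c(5L, 0L, 0L, 5L))
})

test_that("largest-remainder apportionment matches the brute-force optimum", {
  for (n in 1:40) {
    for (pre in c(0.1, 0.3, 0.5, 0.77)) {
      tr <- frequency_tree(n, pre, vignette_accuracy())
      # branch sums hold exactly
      expect_identical(tr$diseased + tr$nondiseased, tr$total)
      expect_identical(tr$tp + tr$fn, tr$diseased)
      expect_identical(tr$fp + tr$tn, tr$nondiseased)
      # each 2-way split is the minimal-|error| integer allocation
      expect_identical(tr$diseased, oracle_split2(n * pre, n))
      expect_identical(tr$tp, oracle_split2(tr$diseased * 0.6, tr$diseased))
      expect_identical(tr$fp, oracle_split2(tr$nondiseased * 0.1, tr$nondiseased))
    }
  }
  expect_error(frequency_tree(0, 0.5, vignette_accuracy()), "positive integer")
})

test_that("tree posteriors divide the stated margins", {
  tr <- frequency_tree(1000, 0.5, vignette_accuracy())
  expect_equal(tree_posterior(tr, "positive"), 300 / 350)
  expect_equal(tree_posterior(tr, "negative"), 200 / 650)
  perfect <- frequency_tree(10, 0.5, test_accuracy(1, 1))
  expect_equal(tree_posterior(perfect, "positive"), 1)
  # a perfect test has no false negatives and no true... the negative
  # margin is tn only, so fn/(fn+tn) = 0, not an error
  expect_equal(tree_posterior(perfect, "negative"), 0)
  all_neg <- frequency_tree(10, 0.5, test_accuracy(0, 1))
  expect_error(tree_posterior(all_neg, "positive"), "no such test results")
})

test_that("nomogram geometry: line ordinates and the 86% readback", {
  g <- nomogram_geometry(0.5, vignette_accuracy())
  expect_equal(unname(g$line["left"]), 0)
  expect_equal(unname(g$line["middle"]), log10(6) / 2)
  expect_equal(unname(g$line["right"]), log10(6))

  # reading the right axis recovers the whole-percent answer
  post <- odds_to_prob(10^g$line[["right"]])
  expect_equal(round_half_up(100 * post), 86)

  # LR 1: horizontal line through zero
  flat <- nomogram_geometry(0.5, test_accuracy(0.5, 0.5))
  expect_equal(unname(flat$line), c(0, 0, 0))

  # axis ranges cover the classic nomogram
  expect_equal(range(g$left_axis$probability), c(0.001, 0.99))
  expect_equal(range(g$middle_axis$lr), c(0.001, 1000))
  expect_error(nomogram_geometry(1, vignette_accuracy()), "pretest")
})

test_that("nomogram line points are collinear for random priors and LRs", {
  set.seed(421)
  pres <- runif(1000, 0.01, 0.99)
  lrs <- 10^runif(1000, -2.5, 2.5)
  for (i in seq_len(1000)) {
    left <- -log10(pres[i] / (1 - pres[i]))
    post <- pres[i] / (1 - pres[i]) * lrs[i]
    right <- log10(post)
    middle <- log10(lrs[i]) / 2
    # with axes at x = 0, 1/2, 1 collinearity means the middle ordinate
    # is the mean of the outer two
    expect_equal(middle, (left + right) / 2, tolerance = 1e-9)
  }
  # and the constructed geometry obeys the same identity
  g <- nomogram_geometry(0.37, test_accuracy(0.7, 0.8))
  expect_equal(unname(g$line["middle"]),
               unname((g$line["left"] + g$line["right"]) / 2),
               tolerance = 1e-12)
})

test_that("probability-modifying plot curves bracket the prior and increase", {
  pm <- pmp_curves(vignette_accuracy())
  expect_equal(pm$post_positive[pm$pretest_grid == 0.5], 6 / 7)
  expect_equal(pm$post_positive[pm$pretest_grid == 0.2], 0.60)
  expect_true(all(pm$post_positive >= pm$pretest_grid))
  expect_true(all(pm$post_negative <= pm$pretest_grid))
  expect_true(all(diff(pm$post_positive) > 0))
  expect_true(all(diff(pm$post_negative) > 0))

  flat <- pmp_curves(test_accuracy(0.5, 0.5), grid_step = 0.01)
  expect_equal(flat$post_positive, flat$pretest_grid)
  expect_equal(flat$post_negative, flat$pretest_grid)
  expect_error(pmp_curves(vignette_accuracy(), grid_step = 0.02), "grid_step")
})

test_that("text summary quotes the computed numbers and picks the direction", {
  ts <- text_summary(vignette_accuracy(), disease = "Green syndrome")
  expect_match(ts$text, "sensitivity of 60%", fixed = TRUE)
  expect_match(ts$text, "specificity of 90%", fixed = TRUE)
  expect_match(ts$text, "positive likelihood ratio of 6", fixed = TRUE)
  expect_match(ts$text, "negative likelihood ratio of 0.44", fixed = TRUE)
  expect_match(ts$text, "greater potential to rule in Green syndrome")
  expect_identical(ts$direction, "rule_in")

  # LR- further from 1 than LR+: rule-out direction
  expect_identical(text_summary(quiz_accuracy())$direction, "rule_out")
  expect_match(text_summary(quiz_accuracy())$text, "rule out")

  tie <- text_summary(test_accuracy(0.5, 0.5))
  expect_identical(tie$direction, "similar")
  expect_match(tie$text, "similar potential")
})

test_that("all formats encode the same posterior (cross-format agreement)", {
  for (pre in c(0.1, 0.25, 0.5, 0.8)) {
    for (acc in list(vignette_accuracy(), quiz_accuracy(),
                     test_accuracy(0.7, 0.8))) {
      lr <- likelihood_ratios(acc)$lr_positive
      reference <- posttest_probability(pre, lr)$posttest
      tree <- frequency_tree(1e6, pre, acc)
      expect_equal(tree_posterior(tree, "positive"), reference,
                   tolerance = 1e-6)
      g <- nomogram_geometry(pre, acc)
      expect_equal(odds_to_prob(10^g$line[["right"]]), reference,
                   tolerance = 1e-9)
      pm <- pmp_curves(acc)
      expect_equal(pm$post_positive[abs(pm$pretest_grid - pre) < 1e-9],
                   reference, tolerance = 1e-9)
    }
  }
})
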