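# Odds-form Bayesian updating for dichotomous diagnostic tests.

#' Diagnostic test accuracy
#'
#' Bundles sensitivity (probability a diseased individual tests positive)
#' and specificity (probability a disease-free individual tests negative)
#' into a validated object used throughout the package.
#'
#' @param sensitivity,specificity Proportions in \[0, 1\] (or percents when
#'   `units = "percent"`).
#' @param units `"proportion"` for values in \[0, 1\], `"percent"` for values
#'   in \[0, 100\]. Units are always explicit, never guessed from magnitude.
#' @return An object of class `"test_accuracy"` with fields `sensitivity`
#'   and `specificity` as proportions.
#' @examples
#' test_accuracy(0.60, 0.90)
#' test_accuracy(60, 90, units = "percent")
#' @export
test_accuracy <- function(sensitivity, specificity,
                          units = c("proportion", "percent")) {
  units <- match.arg(units)
  sensitivity <- as_proportion(sensitivity, units, "sensitivity")
  specificity <- as_proportion(specificity, units, "specificity")
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "test_accuracy")
}

#' @export
print.test_accuracy <- function(x, ...) {
  cat(sprintf("Diagnostic test accuracy: sensitivity %s, specificity %s\n",
              fmt_percent(x$sensitivity), fmt_percent(x$specificity)))
  invisible(x)
}

# Convert a probability-like value to a proportion, validating its range.
as_proportion <- function(x, units = "proportion", name = "probability",
                          open_low = FALSE, open_high = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    stop(name, " must be numeric and non-missing", call. = FALSE)
  }
  if (identical(units, "percent")) x <- x / 100
  lo_bad <- if (open_low) x <= 0 else x < 0
  hi_bad <- if (open_high) x >= 1 else x > 1
  if (any(lo_bad | hi_bad)) {
    stop(name, " must lie in ", if (open_low) "(" else "[", "0, 1",
         if (open_high) ")" else "]",
         " (as a proportion); got ", paste(x[lo_bad | hi_bad], collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Convert between probability and odds
#'
#' @param p Probability in \[0, 1) for `prob_to_odds`.
#' @param odds Non-negative odds for `odds_to_prob`.
#' @return Odds (`prob_to_odds`) or probability (`odds_to_prob`).
#' @examples
#' prob_to_odds(0.5)       # 1
#' odds_to_prob(6)         # 6/7
#' @export
prob_to_odds <- function(p) {
  p <- as_proportion(p, name = "probability", open_high = TRUE)
  p / (1 - p)
}

#' @rdname prob_to_odds
#' @export
odds_to_prob <- function(odds) {
  if (!is.numeric(odds) || any(odds < 0, na.rm = TRUE)) {
    stop("odds must be non-negative", call. = FALSE)
  }
  ifelse(is.infinite(odds), 1, odds / (1 + odds))
}

#' Likelihood ratios of a diagnostic test
#'
#' LR+ = sensitivity / (1 - specificity); LR- = (1 - sensitivity) /
#' specificity. A test with specificity 1 (e.g. a gold-standard biopsy) has
#' an infinite positive likelihood ratio; this is represented explicitly by
#' `lr_positive = Inf` with `infinite_positive = TRUE` rather than an error,
#' because such tests are legitimate inputs.
#'
#' @param acc A [test_accuracy()] object.
#' @return An object of class `"likelihood_ratios"` with fields
#'   `lr_positive`, `lr_negative` and `infinite_positive`.
#' @examples
#' likelihood_ratios(test_accuracy(0.60, 0.90))  # LR+ 6, LR- 0.44
#' @export
likelihood_ratios <- function(acc) {
  stopifnot(inherits(acc, "test_accuracy"))
  sens <- acc$sensitivity
  spec <- acc$specificity
  if (spec == 0) {
    stop("degenerate test: specificity 0 makes the negative likelihood ratio undefined",
         call. = FALSE)
  }
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- (1 - sens) / spec
  structure(list(lr_positive = lr_pos,
                 lr_negative = lr_neg,
                 infinite_positive = is.infinite(lr_pos)),
            class = "likelihood_ratios")
}

#' @export
print.likelihood_ratios <- function(x, ...) {
  cat(sprintf("LR+ = %s, LR- = %s\n",
              if (x$infinite_positive) "infinite" else fmt_ratio(x$lr_positive),
              fmt_ratio(x$lr_negative)))
  invisible(x)
}

# Vectorised odds-form posterior; handles lr = 0 and lr = Inf.
post_prob <- function(pretest, lr) {
  post_odds <- pretest / (1 - pretest) * lr
  ifelse(is.infinite(post_odds), 1, post_odds / (1 + post_odds))
}

#' Post-test probability by Bayes' theorem in odds form
#'
#' Converts the pre-test probability to odds, multiplies by the likelihood
#' ratio of the observed result, and converts back. A whole-percent view
#' (round half up) is included because survey answers are whole percents.
#'
#' @param pretest Pre-test probability, strictly inside (0, 1) (or (0, 100)
#'   with `units = "percent"`). A prior of exactly 0 or 1 is already certain
#'   and cannot be updated.
#' @param lr Non-negative likelihood ratio to apply (`Inf` allowed).
#' @param units Units of `pretest`; see [test_accuracy()].
#' @return An object of class `"probability_update"` with fields `pretest`,
#'   `lr_applied`, `posttest` and `percent` (post-test probability rounded
#'   to the nearest whole percent, half up).
#' @examples
#' posttest_probability(0.50, 6)$percent  # 86
#' @export
posttest_probability <- function(pretest, lr, units = c("proportion", "percent")) {
  units <- match.arg(units)
  pretest <- as_proportion(pretest, units, "pretest")
  if (any(pretest <= 0 | pretest >= 1)) {
    stop("prior already certain: pretest probability must be strictly between 0 and 1",
         call. = FALSE)
  }
  if (!is.numeric(lr) || length(lr) != 1 || is.na(lr) || lr < 0) {
    stop("lr must be a single non-negative number", call. = FALSE)
  }
  post <- post_prob(pretest, lr)
  structure(list(pretest = pretest, lr_applied = lr, posttest = post,
                 percent = round_half_up(100 * post)),
            class = "probability_update")
}

#' @export
print.probability_update <- function(x, ...) {
  cat(sprintf("Pre-test %s x LR %s -> post-test %s (%d%%)\n",
              fmt_percent(x$pretest), fmt_ratio(x$lr_applied),
              fmt_percent(x$posttest), as.integer(x$percent)))
  invisible(x)
}

#' Predictive values at a stated prevalence
#'
#' PPV is the post-test probability of disease after a positive result when
#' the pre-test probability equals the prevalence; NPV is the probability of
#' no disease after a negative result.
#'
#' @param acc A [test_accuracy()] object.
#' @param prevalence Disease prevalence, strictly inside (0, 1).
#' @param units Units of `prevalence`.
#' @return An object of class `"predictive_values"` with fields `ppv`, `npv`
#'   and `prevalence`.
#' @examples
#' predictive_values(test_accuracy(0.6, 0.9), 0.5)$ppv  # 6/7
#' @export
predictive_values <- function(acc, prevalence, units = c("proportion", "percent")) {
  stopifnot(inherits(acc, "test_accuracy"))
  units <- match.arg(units)
  prev <- as_proportion(prevalence, units, "prevalence",
                        open_low = TRUE, open_high = TRUE)
  sens <- acc$sensitivity
  spec <- acc$specificity
  pos_den <- sens * prev + (1 - spec) * (1 - prev)
  neg_den <- spec * (1 - prev) + (1 - sens) * prev
  if (pos_den == 0 || neg_den == 0) {
    stop("degenerate accuracy/prevalence combination: no such test results occur",
         call. = FALSE)
  }
  structure(list(ppv = sens * prev / pos_den,
                 npv = spec * (1 - prev) / neg_den,
                 prevalence = prev),
            class = "predictive_values")
}

#' Recover accuracy from classification counts
#'
#' Inverse of the natural frequency tree: sensitivity = tp / (tp + fn),
#' specificity = tn / (fp + tn).
#'
#' @param tp,fn,fp,tn Non-negative integer counts of true positives, false
#'   negatives, false positives and true negatives.
#' @return A [test_accuracy()] object.
#' @examples
#' accuracy_from_counts(300, 200, 50, 450)  # sens 0.6, spec 0.9
#' @export
accuracy_from_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn == 0) stop("empty disease margin: tp + fn must be > 0", call. = FALSE)
  if (fp + tn == 0) stop("empty non-disease margin: fp + tn must be > 0", call. = FALSE)
  test_accuracy(tp / (tp + fn), tn / (fp + tn))
}

#' Round half up
#'
#' Commercial rounding: 85.5 rounds to 86, unlike base R's round-half-even.
#' Used for whole-percent answer views, where 85.714\% must display as 86.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# Display formatting shared by presentation text and print methods.
fmt_percent <- function(p, digits = 1) {
  paste0(formatC(round_half_up(100 * p, digits), format = "fg"), "%")
}

fmt_ratio <- function(x, digits = 2) {
  if (is.infinite(x)) return("infinite")
  formatC(round_half_up(x, digits), format = "fg")
}
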