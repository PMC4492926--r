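# The four presentation formats of diagnostic accuracy: text summary,
# Fagan's nomogram, probability-modifying plot, natural frequency tree.

#' Largest-remainder apportionment
#'
#' Distributes `total` integer units over targets proportional to `targets`
#' (which must sum to `total`): each cell gets its floor, remaining units go
#' to the largest fractional parts. Ties are broken in favour of earlier
#' cells (stable). Unlike independent rounding this preserves the margin
#' total exactly, which is what keeps every branch of a frequency tree
#' additive.
#'
#' @param targets Non-negative real expectations summing to `total`.
#' @param total Integer total to apportion.
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(targets, total) {
  stopifnot(all(targets >= 0), abs(sum(targets) - total) < 1e-8)
  fl <- floor(targets + 1e-9)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    # round fractional parts so float noise (0.1 * 5 != 0.5 exactly) cannot
    # decide a tie; genuine ties then break stably toward earlier cells
    frac <- round(targets - fl, 9)
    idx <- order(frac, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Natural frequency tree
#'
#' Branches a hypothetical cohort of `n` patients by disease status (at the
#' pre-test probability) then by test result (at the test's accuracy),
#' giving the joint frequencies that encode the Bayesian update as counts.
#' Expected counts are apportioned by [largest_remainder()] so that
#' `diseased + nondiseased = n`, `tp + fn = diseased` and `fp + tn =
#' nondiseased` hold exactly for any `n`.
#'
#' @param n Cohort size (>= 1).
#' @param pretest Pre-test probability in (0, 1).
#' @param acc A [test_accuracy()] object.
#' @param units Units of `pretest`.
#' @return An object of class `"frequency_tree"` with integer fields
#'   `total`, `diseased`, `nondiseased`, `tp`, `fn`, `fp`, `tn`.
#' @examples
#' frequency_tree(1000, 0.5, test_accuracy(0.6, 0.9))  # tp 300, fp 50
#' @export
frequency_tree <- function(n, pretest, acc, units = c("proportion", "percent")) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || abs(n - round(n)) > 1e-9) {
    stop("n must be a positive integer cohort size", call. = FALSE)
  }
  n <- as.integer(round(n))
  units <- match.arg(units)
  pretest <- as_proportion(pretest, units, "pretest", open_low = TRUE, open_high = TRUE)
  stopifnot(inherits(acc, "test_accuracy"))
  disease <- largest_remainder(c(n * pretest, n * (1 - pretest)), n)
  pos_d <- largest_remainder(disease[1] * c(acc$sensitivity, 1 - acc$sensitivity),
                             disease[1])
  pos_h <- largest_remainder(disease[2] * c(1 - acc$specificity, acc$specificity),
                             disease[2])
  structure(list(total = n,
                 diseased = disease[1], nondiseased = disease[2],
                 tp = pos_d[1], fn = pos_d[2],
                 fp = pos_h[1], tn = pos_h[2],
                 pretest = pretest, accuracy = acc),
            class = "frequency_tree")
}

#' @export
print.frequency_tree <- function(x, ...) {
  cat(sprintf(paste0("Natural frequency tree (n = %d)\n",
                     "  diseased %d: test+ %d, test- %d\n",
                     "  disease-free %d: test+ %d, test- %d\n"),
              x$total, x$diseased, x$tp, x$fn, x$nondiseased, x$fp, x$tn))
  invisible(x)
}

#' Posterior probability read off a frequency tree
#'
#' For a positive result: tp / (tp + fp), the fraction of test-positive
#' patients who are diseased. For a negative result: fn / (fn + tn).
#'
#' @param tree A [frequency_tree()].
#' @param result `"positive"` or `"negative"`.
#' @return Probability of disease given the stated result.
#' @examples
#' tr <- frequency_tree(1000, 0.5, test_accuracy(0.6, 0.9))
#' tree_posterior(tr, "positive")  # 300/350
#' @export
tree_posterior <- function(tree, result = c("positive", "negative")) {
  stopifnot(inherits(tree, "frequency_tree"))
  result <- match.arg(result)
  num <- if (result == "positive") tree$tp else tree$fn
  den <- if (result == "positive") tree$tp + tree$fp else tree$fn + tree$tn
  if (den == 0) {
    stop("no such test results in tree: the ", result, " margin is empty",
         call. = FALSE)
  }
  num / den
}

# Base-10 log odds: the scale on which the nomogram's outer axes live.
log_odds10 <- function(p) log10(p / (1 - p))

# Classic axis ranges: pre-test probability 0.1%-99%, LR 0.001-1000.
nomogram_prob_ticks <- function() {
  c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
    0.6, 0.7, 0.8, 0.9, 0.95, 0.98, 0.99)
}

nomogram_lr_ticks <- function() {
  c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1,
    2, 5, 10, 20, 50, 100, 200, 500, 1000)
}

#' Fagan nomogram geometry
#'
#' Three parallel axes at x = 0, 1/2 and 1. The left axis carries the
#' pre-test probability at ordinate -log10(odds), the right axis the
#' post-test probability at +log10(odds), and the middle axis the
#' likelihood ratio at log10(LR) / 2. This is the unique affine scaling
#' under which the Bayesian update
#' log-odds(post) = log-odds(pre) + log10(LR) is a straight line through
#' all three axes.
#'
#' @param pretest Pre-test probability in (0, 1).
#' @param acc A [test_accuracy()] object.
#' @param result Which result's likelihood ratio the overlay line applies.
#' @param units Units of `pretest`.
#' @return An object of class `"nomogram_geometry"`: tick tables
#'   `left_axis`, `middle_axis`, `right_axis` (value, ordinate), the overlay
#'   `line` ordinates (left, middle, right), and `pretest`, `lr`,
#'   `posttest`.
#' @examples
#' nomogram_geometry(0.5, test_accuracy(0.6, 0.9))$line
#' @export
nomogram_geometry <- function(pretest, acc, result = c("positive", "negative"),
                              units = c("proportion", "percent")) {
  units <- match.arg(units)
  result <- match.arg(result)
  pretest <- as_proportion(pretest, units, "pretest", open_low = TRUE, open_high = TRUE)
  stopifnot(inherits(acc, "test_accuracy"))
  lrs <- likelihood_ratios(acc)
  lr <- if (result == "positive") lrs$lr_positive else lrs$lr_negative
  post <- post_prob(pretest, lr)
  pt <- nomogram_prob_ticks()
  lt <- nomogram_lr_ticks()
  structure(list(
    left_axis = data.frame(probability = pt, ordinate = -log_odds10(pt)),
    middle_axis = data.frame(lr = lt, ordinate = log10(lt) / 2),
    right_axis = data.frame(probability = pt, ordinate = log_odds10(pt)),
    line = c(left = -log_odds10(pretest),
             middle = log10(lr) / 2,
             right = log_odds10(post)),
    pretest = pretest, lr = lr, posttest = post, result = result),
    class = "nomogram_geometry")
}

#' Probability-modifying plot curves
#'
#' Post-test probability as a function of pre-test probability, one curve
#' per test result, computed by odds-form Bayes on a regular grid. Reading
#' the plot is: vertical line up from the pre-test probability, horizontal
#' line across from the intersection with the relevant result curve.
#'
#' @param acc A [test_accuracy()] object.
#' @param grid_step Grid spacing in probability units; must be <= 0.01 so
#'   the curves resolve below the 1\% scoring margin. Default 0.001.
#' @return An object of class `"pmp_curves"` with fields `pretest_grid`,
#'   `post_positive`, `post_negative`.
#' @examples
#' pm <- pmp_curves(test_accuracy(0.6, 0.9))
#' pm$post_positive[pm$pretest_grid == 0.5]  # 6/7
#' @export
pmp_curves <- function(acc, grid_step = 0.001) {
  stopifnot(inherits(acc, "test_accuracy"))
  if (!is.numeric(grid_step) || length(grid_step) != 1 ||
      grid_step <= 0 || grid_step > 0.01) {
    stop("grid_step must lie in (0, 0.01]", call. = FALSE)
  }
  lrs <- likelihood_ratios(acc)
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  structure(list(pretest_grid = grid,
                 post_positive = post_prob(grid, lrs$lr_positive),
                 post_negative = post_prob(grid, lrs$lr_negative),
                 accuracy = acc),
            class = "pmp_curves")
}

#' Text summary of a diagnostic test
#'
#' The abstract-style sentence: sensitivity, specificity, both likelihood
#' ratios, and a closing clause saying whether the test has greater
#' potential to rule the diagnosis in (|log LR+| > |log LR-|), rule it out
#' (the reverse), or similar potential for both (tie).
#'
#' @param acc A [test_accuracy()] object.
#' @param disease Name of the condition used in the sentence.
#' @return An object of class `"text_summary"` with fields `text`,
#'   `accuracy`, `lrs` and `direction` (`"rule_in"`, `"rule_out"` or
#'   `"similar"`).
#' @examples
#' cat(text_summary(test_accuracy(0.6, 0.9))$text)
#' @export
text_summary <- function(acc, disease = "the disease") {
  stopifnot(inherits(acc, "test_accuracy"))
  lrs <- likelihood_ratios(acc)
  in_strength <- abs(log(lrs$lr_positive))
  out_strength <- abs(log(lrs$lr_negative))
  direction <- if (isTRUE(all.equal(in_strength, out_strength))) {
    "similar"
  } else if (in_strength > out_strength) "rule_in" else "rule_out"
  clause <- switch(direction,
    rule_in = sprintf("greater potential to rule in %s rather than to rule out %s",
                      disease, disease),
    rule_out = sprintf("greater potential to rule out %s rather than to rule in %s",
                       disease, disease),
    similar = sprintf("similar potential to rule in and to rule out %s", disease))
  txt <- sprintf(paste0(
    "The test has a sensitivity of %s and a specificity of %s. ",
    "It has a positive likelihood ratio of %s and a negative likelihood ",
    "ratio of %s suggesting that it has %s."),
    fmt_percent(acc$sensitivity), fmt_percent(acc$specificity),
    fmt_ratio(lrs$lr_positive), fmt_ratio(lrs$lr_negative), clause)
  structure(list(text = txt, accuracy = acc, lrs = lrs, direction = direction),
            class = "text_summary")
}

#' @export
print.text_summary <- function(x, ...) {
  cat(strwrap(x$text), sep = "\n")
  invisible(x)
}

#' Plain-list payload for JSON export
#'
#' Strips classes so a presentation payload can be serialised with
#' [jsonlite::toJSON()] and re-rendered elsewhere.
#'
#' @param x A payload built by [frequency_tree()], [nomogram_geometry()],
#'   [pmp_curves()] or [text_summary()].
#' @return A JSON string.
#' @export
payload_json <- function(x) {
  cls <- class(x)[1]
  lst <- strip_classes(x)
  lst$payload_type <- cls
  jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, dataframe = "columns")
}
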