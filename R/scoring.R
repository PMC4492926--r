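# Answer keys and correctness rules for the vignette question and the
# five-item baseline knowledge quiz.

BLANK_STRINGS <- c("", "na", "n/a", "don't know", "dont know", "don’t know",
                   "dk", "?")

# Lenient numeric parsing of survey answers: "86", "86%", "86.0" all parse;
# blank/don't-know strings are NA with blank = TRUE; other junk is NA with
# blank = FALSE (an attempt, not an abstention).
parse_answer <- function(raw) {
  raw_chr <- trimws(as.character(raw))
  blank <- is.na(raw) | tolower(raw_chr) %in% BLANK_STRINGS
  cleaned <- gsub("%", "", raw_chr, fixed = TRUE)
  value <- suppressWarnings(as.numeric(cleaned))
  value[blank] <- NA_real_
  list(value = value, blank = blank)
}

#' Score a post-test probability answer
#'
#' An answer is `"correct"` when it lies within `margin` percentage points
#' of the key (the margin absorbs plot-reading resolution: someone reading
#' a probability-modifying plot correctly may report 85 when the exact
#' answer is 86). Empty or "don't know" answers are `"blank"`. Numeric
#' answers outside \[0, 100\] are attempts, so they are classified
#' `"incorrect"` and flagged in the `out_of_range` attribute.
#'
#' @param answer Vector of raw answers (numbers or strings; `""`, `NA` and
#'   "don't know" count as blank).
#' @param key Correct answer in percent, in \[0, 100\].
#' @param margin Tolerance in percentage points; 1 by default, 3 for the
#'   wider sensitivity analysis.
#' @return Character vector of `"correct"`, `"incorrect"`, `"blank"`, with
#'   attribute `out_of_range` (logical vector).
#' @examples
#' score_posttest_answer(c(85, 84, NA), key = 86, margin = 1)
#' @export
score_posttest_answer <- function(answer, key, margin = 1) {
  if (!is.numeric(key) || length(key) != 1 || key < 0 || key > 100) {
    stop("key must be a single percent in [0, 100]", call. = FALSE)
  }
  if (!is.numeric(margin) || length(margin) != 1 || margin < 0) {
    stop("margin must be a single non-negative percent", call. = FALSE)
  }
  p <- parse_answer(answer)
  out_of_range <- !is.na(p$value) & (p$value < 0 | p$value > 100)
  status <- rep("incorrect", length(p$value))
  status[p$blank] <- "blank"
  ok <- !p$blank & !out_of_range & !is.na(p$value) &
    abs(p$value - key) <= margin + 1e-9
  status[ok] <- "correct"
  attr(status, "out_of_range") <- out_of_range
  status
}

#' Answer key for the baseline knowledge quiz
#'
#' The five questions about a described test ask for, in order: (1) the
#' percent of diseased patients missed (100 x (1 - sensitivity)); (2) the
#' probability of disease given a positive result (100 x PPV); (3) the
#' false positive rate (100 x (1 - specificity)); (4) the percent of
#' test-negative patients who still have the disease (100 x (1 - NPV));
#' (5) whether the test is more useful for ruling the diagnosis in or out,
#' decided by which likelihood ratio is further from 1 on the log scale.
#' PPV and NPV are explicit inputs because they depend on a prevalence the
#' accuracy pair alone does not determine.
#'
#' @param acc A [test_accuracy()] object.
#' @param ppv,npv Predictive values as proportions.
#' @param lrs Optional [likelihood_ratios()]; computed from `acc` if absent.
#' @return An object of class `"quiz_key"` with numeric fields `q1`-`q4`
#'   (percents) and `q5` (`"ruling_in"` or `"ruling_out"`; ties resolve to
#'   `"ruling_in"`).
#' @examples
#' quiz_key(test_accuracy(0.9, 0.5), ppv = 0.33, npv = 0.95)
#' @export
quiz_key <- function(acc, ppv, npv, lrs = likelihood_ratios(acc)) {
  stopifnot(inherits(acc, "test_accuracy"), inherits(lrs, "likelihood_ratios"))
  ppv <- as_proportion(ppv, name = "ppv")
  npv <- as_proportion(npv, name = "npv")
  q5 <- if (abs(log(lrs$lr_negative)) > abs(log(lrs$lr_positive))) {
    "ruling_out"
  } else {
    "ruling_in"
  }
  structure(list(q1 = 100 * (1 - acc$sensitivity),
                 q2 = 100 * ppv,
                 q3 = 100 * (1 - acc$specificity),
                 q4 = 100 * (1 - npv),
                 q5 = q5),
            class = "quiz_key")
}

#' Built-in quiz key
#'
#' Key for the trial's baseline quiz test: sensitivity 90\%, specificity
#' 50\%, PPV 33\%, NPV 95\% (so q1 = 10, q2 = 33, q3 = 50, q4 = 5,
#' q5 = ruling_out from LR+ 1.8, LR- 0.2).
#'
#' @return A [quiz_key()] object.
#' @export
default_quiz_key <- function() {
  quiz_key(test_accuracy(0.90, 0.50), ppv = 0.33, npv = 0.95)
}

normalise_q5 <- function(raw) {
  raw <- tolower(trimws(as.character(raw)))
  out <- rep("blank", length(raw))
  out[grepl("out", raw)] <- "ruling_out"
  out[grepl("in", raw) & !grepl("out", raw)] <- "ruling_in"
  out
}

#' Score a five-answer quiz attempt
#'
#' Questions 1-4 are numeric and scored like the vignette answer
#' ([score_posttest_answer()]) with the same +/- `margin`; question 5 is an
#' exact category match. Blanks never count as correct.
#'
#' @param answers Vector or list of exactly 5 raw answers (q1-q4 numeric-ish,
#'   q5 one of "Ruling in", "Ruling out", "Don't know" or blank).
#' @param key A [quiz_key()] object.
#' @param margin Margin in percentage points for q1-q4.
#' @return List with `status` (length-5 character vector of
#'   correct/incorrect/blank) and `total` (number correct, 0-5).
#' @examples
#' score_quiz(c(10, 33, 50, 5, "Ruling out"), default_quiz_key())$total  # 5
#' @export
score_quiz <- function(answers, key, margin = 1) {
  stopifnot(inherits(key, "quiz_key"))
  answers <- as.list(answers)
  if (length(answers) != 5) stop("exactly 5 answer slots required", call. = FALSE)
  status <- character(5)
  keys <- c(key$q1, key$q2, key$q3, key$q4)
  for (i in 1:4) {
    status[i] <- score_posttest_answer(answers[[i]], keys[i], margin)[1]
  }
  a5 <- normalise_q5(answers[[5]])
  status[5] <- if (a5 == "blank") "blank" else if (a5 == key$q5) "correct" else "incorrect"
  list(status = status, total = sum(status == "correct"))
}

#' Canonicalise a management choice
#'
#' Maps the survey's tick-box labels ("Treat", "Not treat", "Order brain
#' biopsy") to canonical categories; unrecognised or empty input is
#' `"blank"`.
#'
#' @param choice Character vector of raw choices.
#' @return Character vector over `"treat"`, `"biopsy"`, `"no_treat"`,
#'   `"blank"`.
#' @examples
#' classify_management(c("Treat", "Order brain biopsy", ""))
#' @export
classify_management <- function(choice) {
  raw <- tolower(trimws(as.character(choice)))
  out <- rep("blank", length(raw))
  out[grepl("biopsy", raw)] <- "biopsy"
  no_treat <- grepl("^(not?[ _]treat|do not treat|no[ _]?treatment)$", raw) |
    raw %in% c("no_treat", "not treat", "not_treat")
  out[no_treat] <- "no_treat"
  out[raw %in% c("treat", "treatment")] <- "treat"
  out
}

MANAGEMENT_LEVELS <- c("treat", "biopsy", "no_treat", "blank")
CORRECTNESS_LEVELS <- c("correct", "incorrect", "blank")
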