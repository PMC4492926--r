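# Synthetic respondent cohorts with the statistical structure the trial
# analysis assumes, so the full pipeline runs with no external data.

#' Cohort generating model
#'
#' All parameters of the respondent generator. The default
#' ([default_cohort_model()]) restates the reference trial's published
#' margins; arbitrary models can be built for what-if studies.
#'
#' @param n Cohort size.
#' @param arm_probs Named allocation probabilities over [trial_arms()].
#' @param management_probs 4 x 4 matrix, rows = arms, columns =
#'   treat/biopsy/no_treat/blank, each row summing to 1.
#' @param correctness_probs 4 x 3 matrix, rows = arms, columns =
#'   correct/incorrect/blank, each row summing to 1.
#' @param correct_values Whole-percent answers counted as correct at the
#'   +/-1 margin, with `correct_weights` probabilities.
#' @param correct_weights Probabilities over `correct_values`.
#' @param wrong_values Classic wrong answers (sensitivity 60, specificity
#'   90, false-positive rate 10, pre-test 50) with `wrong_weights`
#'   probabilities; with probability `wrong_uniform` a wrong answer is
#'   instead uniform over 0-100 excluding the correct band.
#' @param wrong_weights Probabilities over `wrong_values`.
#' @param wrong_uniform Probability a wrong answer is uniform noise.
#' @param demographics Named count vectors as in
#'   [reference_demographics()].
#' @param knowledge_mean,knowledge_sd Mean and SD of the 0-5 quiz total
#'   (beta-binomial when the SD is over-dispersed relative to binomial).
#' @param quiz_blank_rate Fraction of non-correct quiz answers left blank.
#' @param tutorial_log_or_score Log odds ratio of tutorial uptake per
#'   correct quiz answer.
#' @param tutorial_log_or_confidence Log odds ratio per confidence
#'   category.
#' @param tutorial_uptake Marginal uptake probability the intercept is
#'   calibrated to.
#' @param seed Default random seed for [sample_cohort()].
#' @return An object of class `"cohort_model"`.
#' @export
cohort_model <- function(n, arm_probs, management_probs, correctness_probs,
                         correct_values = c(85, 86, 87),
                         correct_weights = c(1, 1, 1) / 3,
                         wrong_values = c(60, 90, 10, 50),
                         wrong_weights = c(1, 1, 1, 1) / 4,
                         wrong_uniform = 0.2,
                         demographics = reference_demographics(),
                         knowledge_mean = 2.2, knowledge_sd = 1.3,
                         quiz_blank_rate = 0.15,
                         tutorial_log_or_score = log(1.18),
                         tutorial_log_or_confidence = log(1.22),
                         tutorial_uptake = 0.362,
                         seed = 1L) {
  check_simplex <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(what, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  stopifnot(n >= 1)
  arm_probs <- arm_probs[trial_arms()]
  check_simplex(arm_probs, "arm_probs")
  management_probs <- as.matrix(management_probs)[trial_arms(), MANAGEMENT_LEVELS]
  correctness_probs <- as.matrix(correctness_probs)[trial_arms(), CORRECTNESS_LEVELS]
  for (a in trial_arms()) {
    check_simplex(management_probs[a, ], paste0("management_probs[", a, ",]"))
    check_simplex(correctness_probs[a, ], paste0("correctness_probs[", a, ",]"))
  }
  check_simplex(correct_weights, "correct_weights")
  check_simplex(wrong_weights, "wrong_weights")
  structure(list(n = as.integer(n), arm_probs = arm_probs,
                 management_probs = management_probs,
                 correctness_probs = correctness_probs,
                 correct_values = correct_values,
                 correct_weights = correct_weights,
                 wrong_values = wrong_values, wrong_weights = wrong_weights,
                 wrong_uniform = wrong_uniform,
                 demographics = demographics,
                 knowledge_mean = knowledge_mean, knowledge_sd = knowledge_sd,
                 quiz_blank_rate = quiz_blank_rate,
                 tutorial_log_or_score = tutorial_log_or_score,
                 tutorial_log_or_confidence = tutorial_log_or_confidence,
                 tutorial_uptake = tutorial_uptake,
                 seed = as.integer(seed)),
            class = "cohort_model")
}

#' Default cohort model from the reference trial margins
#'
#' Restates the published margins as generator parameters: n = 874, arm
#' allocation at the observed split (255/194/218/207), per-arm management
#' and correctness probabilities at the published cell proportions, quiz
#' totals at mean 2.2 / SD 1.3, and a tutorial-uptake logistic model with
#' log odds ratios log(1.18) per correct quiz answer and log(1.22) per
#' confidence category, intercept calibrated to 36.2\% overall uptake.
#'
#' @return A [cohort_model()].
#' @export
default_cohort_model <- function() {
  ref <- reference_outcome_counts()
  cohort_model(
    n = sum(ref$totals),
    arm_probs = ref$totals / sum(ref$totals),
    management_probs = ref$management / ref$totals,
    correctness_probs = ref$correctness / ref$totals)
}

# Beta-binomial parameters matching a stated mean and SD for a 0..size
# total; collapses to plain binomial when the SD is at or below binomial.
betabinom_params <- function(mean, sd, size = 5) {
  p <- mean / size
  var_binom <- size * p * (1 - p)
  if (sd^2 <= var_binom + 1e-12) {
    return(list(type = "binomial", p = p))
  }
  rho <- (sd^2 / var_binom - 1) / (size - 1)
  ab <- (1 - rho) / rho
  list(type = "betabinomial", p = p, a = p * ab, b = (1 - p) * ab)
}

betabinom_pmf <- function(k, params, size = 5) {
  if (params$type == "binomial") {
    return(stats::dbinom(k, size, params$p))
  }
  choose(size, k) * beta(k + params$a, size - k + params$b) /
    beta(params$a, params$b)
}

# Solve the tutorial-model intercept so the marginal uptake over the
# model's (quiz total, confidence) distribution equals the target.
tutorial_intercept <- function(model) {
  kb <- betabinom_params(model$knowledge_mean, model$knowledge_sd)
  p_score <- betabinom_pmf(0:5, kb)
  conf_counts <- model$demographics$confidence
  p_conf <- conf_counts / sum(conf_counts)
  grid <- expand.grid(score = 0:5, conf = 1:5)
  w <- p_score[grid$score + 1] * p_conf[grid$conf]
  f <- function(b0) {
    sum(w * stats::plogis(b0 + model$tutorial_log_or_score * grid$score +
                            model$tutorial_log_or_confidence * grid$conf)) -
      model$tutorial_uptake
  }
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

sample_categorical <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Sample a synthetic respondent cohort
#'
#' Draws `model$n` respondent records: arm allocation, management choice
#' and answer-correctness category per the arm-specific multinomials;
#' numeric answers per the correct/wrong answer mixtures; demographics
#' independently from the marginal distributions; quiz totals from the
#' (beta-)binomial knowledge model with the correct items placed at
#' random; tutorial uptake from the logistic uptake model.
#'
#' @param model A [cohort_model()].
#' @param seed Integer seed (defaults to `model$seed`); fixed seed gives a
#'   byte-identical cohort.
#' @return Data frame with the respondent schema: `id`, `arm`,
#'   `posttest_answer`, `management`, `age_group`, `sex`, `status`,
#'   `postgrad_training`, `confidence`, `q1`..`q5`, `tutorial_uptake`.
#' @export
sample_cohort <- function(model, seed = model$seed) {
  stopifnot(inherits(model, "cohort_model"))
  set.seed(seed)
  n <- model$n
  arm <- sample_categorical(n, model$arm_probs)

  management <- character(n)
  status <- character(n)
  for (a in trial_arms()) {
    idx <- which(arm == a)
    management[idx] <- sample_categorical(length(idx), model$management_probs[a, ])
    status[idx] <- sample_categorical(length(idx), model$correctness_probs[a, ])
  }

  answer <- character(n)
  is_corr <- status == "correct"
  answer[is_corr] <- as.character(sample(model$correct_values, sum(is_corr),
                                         replace = TRUE,
                                         prob = model$correct_weights))
  is_wrong <- status == "incorrect"
  n_w <- sum(is_wrong)
  use_unif <- stats::runif(n_w) < model$wrong_uniform
  wrong <- sample(model$wrong_values, n_w, replace = TRUE,
                  prob = model$wrong_weights)
  band <- range(model$correct_values)
  unif_pool <- setdiff(0:100, seq(band[1], band[2]))
  wrong[use_unif] <- sample(unif_pool, sum(use_unif), replace = TRUE)
  answer[is_wrong] <- as.character(wrong)
  answer[status == "blank"] <- ""

  demo <- model$demographics
  age_group <- sample_categorical(n, demo$age_group)
  sex <- sample_categorical(n, demo$sex)
  prof <- sample_categorical(n, demo$status)
  postgrad <- sample_categorical(n, demo$postgrad_training)
  confidence <- as.integer(sample_categorical(n, demo$confidence))

  kb <- betabinom_params(model$knowledge_mean, model$knowledge_sd)
  p_i <- if (kb$type == "binomial") rep(kb$p, n) else stats::rbeta(n, kb$a, kb$b)
  total <- stats::rbinom(n, 5, p_i)
  key <- default_quiz_key()
  keys <- c(key$q1, key$q2, key$q3, key$q4)
  # Which `total[i]` of the 5 items are correct: rank a uniform draw per
  # row and take the smallest ranks (vectorised random subset).
  u <- matrix(stats::runif(n * 5), n, 5)
  ranks <- t(apply(u, 1, rank, ties.method = "first"))
  is_quiz_correct <- ranks <= total
  is_quiz_blank <- !is_quiz_correct &
    matrix(stats::runif(n * 5), n, 5) < model$quiz_blank_rate
  quiz <- matrix("", nrow = n, ncol = 5)
  right_q5 <- if (key$q5 == "ruling_out") "Ruling out" else "Ruling in"
  wrong_q5 <- if (key$q5 == "ruling_out") "Ruling in" else "Ruling out"
  for (q in 1:4) {
    pool <- setdiff(seq(0, 100, by = 5), keys[q])
    quiz[, q] <- as.character(sample(pool, n, replace = TRUE))
    quiz[is_quiz_correct[, q], q] <- as.character(keys[q])
    quiz[is_quiz_blank[, q], q] <- ""
  }
  quiz[, 5] <- wrong_q5
  quiz[is_quiz_correct[, 5], 5] <- right_q5
  quiz[is_quiz_blank[, 5], 5] <- ""

  b0 <- tutorial_intercept(model)
  p_up <- stats::plogis(b0 + model$tutorial_log_or_score * total +
                          model$tutorial_log_or_confidence * confidence)
  uptake <- ifelse(stats::runif(n) < p_up, "yes", "no")

  data.frame(id = sprintf("R%05d", seq_len(n)), arm = arm,
             posttest_answer = answer, management = display_management(management),
             age_group = age_group, sex = sex, status = prof,
             postgrad_training = postgrad, confidence = confidence,
             q1 = quiz[, 1], q2 = quiz[, 2], q3 = quiz[, 3], q4 = quiz[, 4],
             q5 = quiz[, 5], tutorial_uptake = uptake,
             stringsAsFactors = FALSE)
}

# Canonical category -> survey tick-box label, so the generator exercises
# the same raw-string classification path as real exports would.
display_management <- function(category) {
  c(treat = "Treat", biopsy = "Order brain biopsy",
    no_treat = "Not treat", blank = "")[category]
}

#' Deterministic cohort reproducing the reference counts exactly
#'
#' Places (rather than samples) records so that [tabulate_arms()] returns
#' the model's implied integer counts cell for cell; used by the
#' printed-value regression suite. Requires every `n * prob` to be
#' integral, as it is for [default_cohort_model()]. Management and answer
#' categories are placed independently within each arm (the joint
#' distribution is not published); all other fields are filled
#' deterministically by cycling.
#'
#' @param model A [cohort_model()] whose probabilities are count ratios.
#' @return Respondent data frame as from [sample_cohort()].
#' @export
sample_exact_table <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  as_counts <- function(x, what) {
    if (any(abs(x - round(x)) > 1e-6)) {
      stop("model ", what, " do not correspond to integer counts", call. = FALSE)
    }
    as.integer(round(x))
  }
  arm_n <- as_counts(model$n * model$arm_probs, "arm probabilities")
  rows <- lapply(seq_along(trial_arms()), function(k) {
    a <- trial_arms()[k]
    n_a <- arm_n[k]
    m_counts <- as_counts(n_a * model$management_probs[a, ],
                          "management probabilities")
    c_counts <- as_counts(n_a * model$correctness_probs[a, ],
                          "correctness probabilities")
    mgmt <- rep(MANAGEMENT_LEVELS, m_counts)
    ans <- rep(c("86", "60", ""), c_counts)
    data.frame(arm = a, posttest_answer = ans, management = display_management(mgmt),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  n <- nrow(records)
  demo <- model$demographics
  cycle <- function(values) values[(seq_len(n) - 1) %% length(values) + 1]
  data.frame(id = sprintf("R%05d", seq_len(n)), arm = records$arm,
             posttest_answer = records$posttest_answer,
             management = records$management,
             age_group = cycle(names(demo$age_group)),
             sex = cycle(names(demo$sex)), status = cycle(names(demo$status)),
             postgrad_training = cycle(names(demo$postgrad_training)),
             confidence = cycle(as.integer(names(demo$confidence))),
             q1 = "", q2 = "", q3 = "", q4 = "", q5 = "",
             tutorial_uptake = cycle(c("no", "yes")),
             stringsAsFactors = FALSE)
}

#' Write / read a respondent cohort CSV
#'
#' Plain CSV in the schema shared with [tabulate_arms()] and the CLI.
#' Reading preserves blank answers as empty strings.
#'
#' @param records Respondent data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the data frame.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, colClasses = "character", na.strings = NULL)
}

#' Serialise / load a cohort model as JSON
#'
#' @param model A [cohort_model()].
#' @param path File path.
#' @return `write_cohort_model` returns `path` invisibly;
#'   `read_cohort_model` returns the model.
#' @export
write_cohort_model <- function(model, path) {
  stopifnot(inherits(model, "cohort_model"))
  out <- unclass(model)
  # named vectors must serialise as JSON objects, not bare arrays, or the
  # category labels are lost on round trip
  out$arm_probs <- as.list(out$arm_probs)
  out$demographics <- lapply(out$demographics, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cohort_model
#' @export
read_cohort_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$arm_probs <- unlist(raw$arm_probs)
  raw$demographics <- lapply(raw$demographics, unlist)
  dimnames(raw$management_probs) <- list(trial_arms(), MANAGEMENT_LEVELS)
  dimnames(raw$correctness_probs) <- list(trial_arms(), CORRECTNESS_LEVELS)
  do.call(cohort_model, raw)
}
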