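# Built-in reference data: arm-level outcome counts and participant
# characteristics of the four-arm presentation trial this package models.
# These printed margins are the only individual-free inputs the original
# trial report makes public; everything individual-level is synthesised.

#' Trial arm labels
#'
#' The four presentation formats in reference-first order: text summary,
#' Fagan nomogram, probability-modifying plot (pmp), natural frequency
#' tree (nft).
#'
#' @return Character vector of length 4.
#' @export
trial_arms <- function() c("text", "nomogram", "pmp", "nft")

#' Reference arm-level outcome counts
#'
#' The trial's published per-arm tabulation: counts of management choices
#' (treat / biopsy / no treatment / blank) and of post-test probability
#' answer classifications (correct / incorrect / blank) for the 874
#' complete responses.
#'
#' @return An `"arm_outcome_table"`: list with integer matrices
#'   `management` (4 x 4) and `correctness` (4 x 3), and `totals` (named,
#'   per arm).
#' @export
reference_outcome_counts <- function() {
  arms <- trial_arms()
  management <- matrix(c(142, 79, 31, 3,
                         112, 56, 24, 2,
                         142, 57, 16, 3,
                         133, 55, 18, 1),
                       nrow = 4, byrow = TRUE,
                       dimnames = list(arms, MANAGEMENT_LEVELS))
  correctness <- matrix(c(30, 218, 7,
                          50, 137, 7,
                          87, 129, 2,
                          73, 129, 5),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(arms, CORRECTNESS_LEVELS))
  new_arm_outcome_table(management, correctness)
}

#' Reference participant characteristics
#'
#' Pooled demographic margins of the trial cohort (the four arms were
#' similar, so pooled margins are used by the synthetic generator). Some
#' items have fewer than 874 responses; counts are as published and
#' consumers should normalise.
#'
#' @return List of named integer count vectors: `age_group`, `sex`,
#'   `status`, `postgrad_training`, `confidence`.
#' @export
reference_demographics <- function() {
  list(
    age_group = c("20-29" = 147, "30-34" = 177, "35-39" = 173, "40-44" = 128,
                  "45-49" = 82, "50-54" = 73, "55-59" = 49, "60+" = 45),
    sex = c(male = 511, female = 363),
    status = c(gp = 93, consultant = 277, trainee_gp = 35,
               trainee_junior = 352, other = 111),
    postgrad_training = c(yes = 298, no = 562),
    confidence = c("1" = 70, "2" = 225, "3" = 365, "4" = 187, "5" = 15))
}

#' The hypothetical diagnostic scenario
#'
#' The fictitious "Green syndrome" vignette all respondents saw: pre-test
#' probability 50\%, and a blood test ("anti-celadon") with sensitivity
#' 60\% and specificity 90\%. The reference cohort for the natural
#' frequency tree has 1000 patients. Also records the invasive
#' gold-standard alternative (brain biopsy, sensitivity 95\%, specificity
#' 100\%) and the whole-percent correct answer (86).
#'
#' @return List with `pretest`, `accuracy`, `biopsy_accuracy`, `tree_n`,
#'   `correct_percent`, `disease`.
#' @export
green_syndrome_scenario <- function() {
  list(pretest = 0.5,
       accuracy = test_accuracy(0.60, 0.90),
       biopsy_accuracy = test_accuracy(0.95, 1.00),
       tree_n = 1000L,
       correct_percent = 86,
       disease = "Green syndrome")
}
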