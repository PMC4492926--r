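---
title: "Presenting diagnostic accuracy to clinicians: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presenting diagnostic accuracy to clinicians: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxtrial)
```

## The problem

Clinicians are asked routinely to turn a pre-test impression and a
dichotomous test result into a post-test probability of disease, and they
are known to do this badly when accuracy is reported as bare sensitivity
and specificity. dxtrial implements the computational content of a
four-arm randomised experiment on this question: the Bayesian arithmetic
itself, the four formats in which the same arithmetic can be shown to a
doctor, the rules for scoring a doctor's answers, the outcome statistics
of such a trial, and a synthetic respondent generator so that the whole
pipeline is runnable and testable without any individual-level data.

## The core model

Everything downstream encodes one identity, Bayes' theorem in odds form.
For a test with sensitivity $Se$ and specificity $Sp$,

$$LR^+ = \frac{Se}{1 - Sp}, \qquad LR^- = \frac{1 - Se}{Sp},$$

and for a pre-test probability $p$,

$$\mathrm{odds}(p) = \frac{p}{1-p}, \qquad
  \mathrm{odds}(p_{post}) = \mathrm{odds}(p) \times LR.$$

The worked scenario used throughout (a fictitious condition, "Green
syndrome", and a blood test with $Se = 0.60$, $Sp = 0.90$, prior $0.50$)
gives $LR^+ = 6$ and a positive-result posterior of $6/7 = 0.857$, i.e.
86 as a whole percent.

```{r}
acc <- test_accuracy(0.60, 0.90)
posttest_probability(0.5, likelihood_ratios(acc)$lr_positive)
```

The four presentation formats are four encodings of this identity:

* **Text summary** (`text_summary`): the abstract-style sentence with the
  four numbers and a rule-in/rule-out clause. The direction compares
  $|\log LR^+|$ with $|\log LR^-|$ — the likelihood ratio further from 1
  on the log scale moves the posterior further; an exact tie yields a
  "similar potential" phrasing.
* **Fagan nomogram** (`nomogram_geometry`): three parallel axes at
  $x = 0, \tfrac12, 1$. Plotting the prior at $-\log_{10}\mathrm{odds}$,
  the LR at $\tfrac12\log_{10} LR$ and the posterior at
  $+\log_{10}\mathrm{odds}$ makes the update a straight line; this is the
  unique affine scaling with that property, and the package asserts
  collinearity rather than assuming it.
* **Probability-modifying plot** (`pmp_curves`): the posterior as a curve
  over the prior, one curve per result.
* **Natural frequency tree** (`frequency_tree`): a hypothetical cohort
  (1000 patients by default) branched by disease then by result, so the
  posterior is a ratio of visible counts, $300/350$ in the worked
  scenario.

### Numerical choices

*Integer apportionment.* Tree counts use largest-remainder rounding at
each branching (floor everything, hand remaining units to the largest
fractional parts). Independent rounding of four cells can break
`tp + fn = diseased`; largest-remainder cannot. Fractional parts are
compared after rounding to 9 decimals so that binary float noise
($5 \times 0.1 \ne 0.5$ exactly) cannot decide a tie; genuine ties break
stably toward the earlier branch (disease before non-disease, positive
before negative).

*Whole-percent rounding is half-up.* The scenario's exact answer is
85.714..., displayed and keyed as 86; base R's round-half-even is not what
a survey key does. `round_half_up()` is exported and used for every
percent the package prints.

*Units are explicit.* Probabilities are accepted as proportions or
percents only through a `units` argument; nothing is guessed from
magnitude, because the source materials mix "50%" and "0.5" freely.

*Degenerate tests.* A gold-standard confirmatory test with $Sp = 1$ (the
scenario's brain biopsy) has an infinite $LR^+$; this is represented as
an explicit `Inf` with a flag, since such tests are legitimate inputs.
$Sp = 0$ makes $LR^-$ undefined and is an error.

## Scoring

A post-test answer is correct within ±1 percentage point of the key
(86), the margin absorbing read-off resolution — a careful reader of the
probability-modifying plot lands on 85. A ±3 margin reruns everything as
a sensitivity analysis. Blank and "don't know" are a third category,
never correct; numeric answers outside [0, 100] are attempts and score
incorrect (flagged out-of-range), not blank.

The five-question knowledge quiz (test with $Se$ 90%, $Sp$ 50%, PPV 33%,
NPV 95%) is keyed by the definitions: missed-disease rate 10, probability
of disease given positive 33, false-positive rate 50, disease given
negative 5, and "ruling out" for the direction question (its $LR^- = 0.2$
is further from 1 than $LR^+ = 1.8$). Two declared choices here: the
source states a scoring margin only for the vignette question, so q1–q4
default to the same ±1 (configurable); and the stated PPV/NPV imply a
prevalence near 0.21–0.22 that is never printed and cannot satisfy both
exactly, so `predictive_values()` takes prevalence as an explicit
argument and `quiz_key()` takes PPV/NPV as inputs rather than guessing.

## Trial analysis

`analyze_trial()` reproduces the outcome statistics from respondent
records or from an arm-level count table:

* **Odds ratios** dichotomise as target category versus *all* other
  categories including blanks (treat vs {biopsy, no-treat, blank};
  correct vs {incorrect, blank}), each arm against the text-summary
  reference, with the Wald interval
  $\exp(\log OR \pm 1.96\,\sqrt{\sum 1/n_{ij}})$ and the Haldane +0.5
  correction iff a cell is zero. This coding is adopted because it is the
  unique one that reproduces every published OR/CI pair at two decimals
  from the published counts — the regression suite asserts all six.
* **Heterogeneity** uses the Pearson chi-squared on the 4×2
  correct-vs-not table, written as the explicit double sum and checked
  in tests against both a brute-force oracle and `stats::chisq.test`.
* **Logistic regression** is a hand-written IRLS (tolerance $10^{-8}$ on
  the score max-norm, 25 iterations, case weights for aggregated data).
  With a saturated one-factor arm model its exponentiated coefficients
  must equal the closed-form 2×2 odds ratios to $10^{-6}$; that identity
  is the package's check that the published "logistic regression" odds
  ratios are the 2×2 ratios. Non-convergence and probable separation
  (|coefficient| > 15) warn and set flags rather than failing silently.
* **Power**: the design's minimal detectable difference uses the
  standard two-proportion normal approximation
  $(z_{1-\alpha/2} + z_{power})\sqrt{2p(1-p)/n}$; at $n = 200$ per arm,
  80% power, $\alpha = 0.05$ it gives 0.112–0.140 across baseline
  probabilities 0.2–0.8, matching the design claim of detectable
  differences of 11–15%. The exact formula behind that claim is not
  stated in the source; this standard one reproduces it and is adopted.

One published figure does not survive recomputation: the overall correct
proportion 240/874 is printed as 27.4%, but the fraction is 27.46%, which
rounds to 27.5 under any nearest-rounding rule. The package reports 27.5
and the tests assert the count and total exactly, treating the printed
last digit as a source-side rounding slip.

## The synthetic cohort

`sample_cohort()` emulates a cohort of 874 respondents randomised to the
four arms. The default model (`default_cohort_model()`) *is* the
published margins: allocation 255/194/218/207, per-arm management and
correctness multinomials at the published cell proportions, pooled
demographic margins, quiz totals at mean 2.2 / SD 1.3, and a
tutorial-uptake logistic model with log odds ratios $\log 1.18$ per
correct quiz answer and $\log 1.22$ per confidence category, intercept
calibrated by root-finding so the marginal uptake is 36.2%.

Where the source states no value, one realistic choice was made and
frozen:

* Correct answers are uniform on {85, 86, 87} (the ±1 band).
* Wrong answers are an 80/20 mixture of the classic confusions —
  reporting the sensitivity (60), the specificity (90), the
  false-positive rate (10) or the unchanged prior (50) — and uniform
  noise on 0–100 outside the correct band.
* 15% of non-correct quiz answers are blank.
* Quiz totals use a beta-binomial when the stated SD (1.3) exceeds the
  binomial SD at the stated mean, which it does; matching both moments
  needs the overdispersed family.

What the generator deliberately does **not** model: the joint
distribution of management choice and answer correctness within a
respondent (not published — the two are drawn independently per arm),
covariate–outcome dependence (demographics are independent of outcomes by
default, as the arms were well balanced), and the recruitment funnel. A
green test against synthetic data therefore establishes that the
analysis machinery is correct under the stated margins, not that it
would detect, say, confounding structure the generator never produces.
The observed unequal arm sizes are reproduced via the observed-allocation
probabilities, not via a mechanism: simple randomisation cannot be made
to *explain* a 29.2% arm, only to produce splits like it.

`sample_exact_table()` is the deterministic counterpart: it places,
rather than samples, records so the tabulation equals the published
counts cell for cell, and is what the printed-value regression suite and
`run_reproduction()` analyse.

## Reproduction pipeline

`run_reproduction()` (CLI: `dxtrial reproduce`) chains the stages:
scenario interpretation, all four presentation payloads and SVGs, the
exact-table analysis with the six OR/CI regression checks, and the power
sweep, emitting one JSON report plus markdown derived from it. Its
`passed` flag is true only if every printed value reproduced at two
decimals. Figure styling (colours, fonts, pixel dimensions) lives in a
JSON-loadable config and is excluded from every correctness assertion;
the SVG writer is deterministic byte-for-byte for fixed payload and
style, which the tests assert, and the nomogram's overlay endpoints are
parsed back out of the SVG and checked against the geometry.

## Known limitations

* Wald intervals only; no exact or profile-likelihood intervals.
* No multivariable adjustment on real data — the individual-level
  covariates are unpublished, so adjusted models exist only as parameter
  recovery exercises on synthetic cohorts.
* The quiz's PPV/NPV inconsistency is surfaced, not resolved.
* SVG output aims at faithful geometry, not pixel-faithful replication
  of any published artwork.
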