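---
title: "Modeling strategy acquisition on hidden-single puzzles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling strategy acquisition on hidden-single puzzles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiddensingle)
```

## The task and its structure

A *hidden single* puzzle presents a 9×9 Sudoku grid with a highlighted
target house (a row or column) and a highlighted empty goal cell inside
it. Exactly one digit — the *target* — can legally occupy the goal cell:
its three instances elsewhere in the grid eliminate every other empty
cell of the house. A *distractor* digit also has three instances, but at
least one house cell remains open for it, so counting instances cannot
separate the two. Three *in-house* digits occupy house cells (one each)
and four *absent* digits do not appear at all. Over the nine digits the
role multiplicities are therefore (target, distractor, absent, in-house)
= (1, 1, 4, 3).

`generate_puzzle()` constructs such puzzles by constructive placement:
the three contiguous empty house cells of the *box-constraint box* are
eliminated for target and distractor by single instances inside that
box; the two remaining empty house cells are covered for the target by
instances on their perpendicular lines; the distractor covers exactly
one of them, leaving an open cell. Draws that cannot be completed
legally are rejected and resampled (bounded retries). An independent
peer-elimination solver, `forced_digit()`, re-derives the forced digit
from the grid alone and is checked against the generator's declared
target on every batch — the generator and the oracle share no code path.

The exact placement recipe used in the original experiment is not
public; the constructive sampler here reproduces every *stated*
structural property (role counts, the box-constraint structure, the
forced/unforced asymmetry, equal 3-instance counts defeating the
counting heuristic) but may differ from the original in unstated
details such as the orientation of covering lines.

## Experimental designs

Each simulated participant receives random training features: house
type, house index, cell index, and a 4-digit training set; a disjoint
4-digit transfer set is drawn from the remaining five digits. Practice
consists of 25 puzzles sharing all training features. The test phase has
64 trials in 8 sets of 8: the 8 combinations of changed/unchanged house
type, house index, and cell index follow a Williams-type balanced Latin
square over sets (each combination once per set, once per within-set
position, preceding every other combination in exactly four sets), and
digit-set changes are carried by a fixed half of the combinations,
complemented on alternate sets. This yields four digit-set changes per
set and all 16 four-flag combinations within *every* consecutive pair of
sets — slightly stronger than the disjoint-pair phrasing of the original
design, and satisfying all of its printed balance counts.

Changed house and cell indices are resampled uniformly from the eight
non-training values independently per trial. Marginally over a test
phase this gives each single-change goal cell probability 1/32 and each
double-change cell 1/256, matching the stated distribution.

## The aggregate strategy model

Responses are classified into the four role categories. Four strategy
classes generate them: **UG** (uniform over all 9 digits), **ADC**
(uniform over the 6 digits not already in the house), **PD** (uniform
over the two 3-instance digits), and **S** (always the target). Their
error-free emissions form the fixed matrix `R` with target-column
(1/9, 1/6, 1/2, 1) — accuracies of 11.1%, 16.7%, 50%, and 100%.

Execution errors are modeled by a lower-triangular fallback matrix `W`:
on any trial, strategy *i* may respond using the emission profile of a
weaker strategy *j* with probability `W[i, j]`. Strategy membership
evolves by an upper-triangular transition matrix `X` (no regression to
weaker strategies; S absorbing) from an initial distribution `a`. The
predicted response distribution on trial *t* is `a X^(t-1) W R`, and the
aggregate negative log-likelihood sums `-log` of the observed category's
probability over participants and trials.

`fit_aggregate()` maximizes this likelihood with structural zeros
enforced by construction: each free row is a softmax over its admissible
entries, and BFGS runs from a structured warm start (W near identity, X
diagonal-heavy) plus random restarts.

### Identifiability of the aggregate fit — an important caveat

The aggregate likelihood depends on the parameters only through the 25
per-trial *marginal* category distributions; it discards within-person
sequential information. This has two consequences that the package's
tests make explicit:

1. A strong local optimum exists in which the fitted "S" row mimics the
   PD emission profile (target probability 0.5). The structured warm
   start exists to avoid this basin; with random starts alone roughly
   half the restarts land in it.
2. Near the published non-solver parameter set the decomposition is not
   identified: fitting the *exact* noise-free expected curve admits an
   equal-likelihood solution whose effective S-row target emission is
   0.97 rather than 0.88, with a maximum curve deviation below 1e-4.
   At realistic cohort sizes (n = 200) the maximum-likelihood estimate
   wanders along this flat ridge (typically landing near 0.55–0.67 while
   achieving *better* likelihood than the generating parameters). The
   forward response curve itself is recovered well — only its
   decomposition into occupancy × error rate is fragile when the S state
   is rarely occupied. The corresponding acceptance test asserts the
   stated non-solver recovery tolerance and is expected to fail; the
   solver-side recovery (S occupied on most trials) is identified and
   passes. A fit using the full per-participant path likelihood would
   restore identifiability but would be a different estimator from the
   one specified.

## Individual-level path inference

Under the monotone-improvement constraint a participant's latent
strategy path is weakly non-decreasing, so only `choose(T + 3, 3)` paths
exist (3,276 at T = 25) and the posterior can be computed by exact
enumeration: prior `a[s1] * prod X[s_t, s_t+1]`, likelihood the product
of per-trial emission entries, Bayes rule over all paths
(`path_posterior()`). A forward–backward implementation
(`forward_backward_marginals()`) serves as an independent
dynamic-programming cross-check; the two agree to 1e-10 in the tests.

The path likelihood defaults to the *effective* emissions `W R` rather
than raw `R`: under raw `R` a single distractor response would
annihilate every path that has already reached S, contradicting the
intended role of the error matrix (occasional distractor errors under a
successful strategy). Raw mode is available and raises an explicit
degenerate-posterior error when every path has zero probability.

Strategy attainment is summarized by `P(s_t >= s)`; the transition trial
into s is the first t at which this tail probability strictly exceeds
0.5 (`transition_trial()`). Ties at exactly 0.5 do not cross.

## Solver classification

The preregistered classifier fits
`correct ~ log2(trial) + (1 + log2(trial) | participant)` as a logistic
mixed model on practice-phase first-attempt correctness and labels a
participant a solver when the *conditional* (empirical-Bayes) predicted
accuracy at trial 25 strictly exceeds 0.8. Choices made where the
original is silent: maximum likelihood via Laplace approximation
(`lme4::glmer`), conditional rather than marginal predictions, a
random-intercept-only refit on convergence failure, and a degenerate
branch returning the constant outcome when the cohort has no outcome
variation (the all-correct corner case where the MLE diverges). Note
that empirical-Bayes shrinkage makes predictions cohort-dependent: an
error-free participant is comfortably above 0.8 in realistic mixed
cohorts, but can be shrunk below it in a cohort consisting otherwise
entirely of guessers. A pure target/distractor guesser solves at least
19 of 25 practice trials (75%+) with probability
`pbinom(18, 25, 0.5, lower.tail = FALSE)` ≈ 0.0073 < 1%, so guessers
essentially never cross the threshold.

## Test-phase transfer models

Accuracy and response-time effects of each feature change are estimated
one feature at a time with
`dv ~ feature + log2(trial) + (1 + log2(trial) | participant)` —
logistic for correctness, linear on `log2(rt_seconds)` for correct
trials only — separately for trials 1–16 and 17–64, falling back to a
random intercept on convergence failure. House- and cell-index changes
are recoded into a single goal-position flag (`gp = hi | ci`). The
original analysis was Bayesian with credible intervals and Bayes
factors; this package deliberately fits the same formulas by maximum
likelihood and reports Wald 95% intervals, which is deterministic and
dependency-light. Interval semantics therefore differ slightly
(confidence vs credible); point estimates are directly comparable.

Cohen's κ uses the standard chance-corrected definition with the
large-sample standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
When both raters produce a single identical category, chance agreement
is 1 and κ is reported as undefined rather than 0/0.

## The synthetic cohort: what it does and does not emulate

`simulate_experiment()` generates practice responses exactly from the
generative reading of the model — path from (`a`, `X`), per-trial
fallback from `W`, category from `R`, digit uniform within the
category's digit group — using the published solver and non-solver
parameter sets as defaults, with the reported group sizes (88 and 183).
Test-phase correctness follows a logistic model with configurable
feature shifts (defaults: the reported first-window estimates, −0.10,
−0.30, +0.16 logits for DS/HT/GP) and response times are log-normal in
log2 space (defaults: baseline log2 RT 4.0 ≈ 16 s, participant SD 0.4,
residual SD 0.5, shifts −0.02, +0.33, +0.11 log2 s), since no RT
generative model is stated; these values were chosen once to match the
reported ~15–20 s solve times and are not calibrated against test
outcomes.

A green pipeline on synthetic data therefore establishes *internal*
consistency — the estimators recover what the generator planted, at the
stated cohort sizes — not agreement with human data. In particular the
simulator omits: within-session learning during the test phase beyond
the log-trial term, timeouts and missing responses, late learners who
transition mid-test-phase, and any dependence of practice errors on the
concrete puzzle layout.

## Numerical choices

Row-stochastic inputs rounded to 3 decimals are accepted with row sums
in [0.999, 1.001] and renormalized. Probability conservation is asserted
at 1e-8 in validation and 1e-10/1e-12 in oracle-equivalence tests.
Posterior computation works in log space; a cohort category observed
with zero model probability yields an infinite loss (not an exception),
and degenerate posteriors raise a named error. Path enumeration at
T = 25 (3,276 paths) is exact and takes milliseconds, so no pruning or
Viterbi approximation is used anywhere.
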