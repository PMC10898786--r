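# hiddensingle

Tools for studying how people rapidly acquire an abstract reasoning
skill: solving Sudoku **hidden single** puzzles after a brief tutorial.
The package is aimed at computational cognitive scientists who want to
simulate, fit, and probe latent-strategy models of practice-phase
learning and transfer, without access to participant data.

## What it implements

**Puzzle engine.** Procedural generation of hidden-single puzzles with a
controlled digit-role structure — one *target* digit forced into the
goal cell, one *distractor* with equally many instances but an open
escape cell, three *in-house* and four *absent* digits — plus an
independent peer-elimination solver used as a generation oracle,
response classification into the four role categories, and
reconstruction of puzzle-specific explanatory feedback.

**Designs.** Per-participant training/transfer feature assignment, the
25-trial practice design, and the 64-trial transfer design: 8 sets of 8
with house-type/house-index/cell-index change combinations in a balanced
Latin square (once per set, once per position, 4-before/4-after
precedence) and 4 digit-set changes per set.

**Strategy model.** Four ordered strategy classes — uninformed guess
(UG), avoid direct contradictions (ADC), prevalent digits (PD),
successful (S) — with fixed emission matrix `R` whose target column is
(1/9, 1/6, 1/2, 1). The aggregate model predicts the trial-*t* response
distribution as

    P(r_t) = a X^(t-1) W R

with initial distribution `a`, upper-triangular transition matrix `X`
(monotone improvement, S absorbing), and lower-triangular error-fallback
matrix `W`. Fitting is by constrained maximum likelihood. Individual
participants are modeled by an exact HMM over the 3,276 weakly monotone
strategy paths at T = 25: path priors, likelihoods (effective `W R` or
raw `R` emissions), exact posteriors, top-k paths, per-trial marginals
`P(s_t = s)` and tails `P(s_t ≥ s)`, and transition trials
`t_x(s) = argmin_t P(s_t ≥ s) > 0.5`.

**Solver classifier.** The preregistered logistic mixed model
`correct ~ log2(trial) + (1 + log2(trial) | participant)`; a participant
is a *solver* when the predicted trial-25 accuracy exceeds 0.8.

**Transfer statistics.** Mixed-effects accuracy (logit) and response
time (log2 s) models per changed feature and trial window, goal-position
recoding, and Cohen's κ for rater agreement.

**Synthetic cohorts.** Full synthetic experiments (practice + test
phases, ground truth included) generated from the published solver and
non-solver parameter sets, so the entire pipeline is testable offline.

## Worked example

```r
library(hiddensingle)

p <- generate_puzzle("column", 7, 8, target = 1, distractor = 7,
                     in_house = c(2, 3, 5), seed = 42)
p
#> Hidden-single puzzle: column 7, cell 8 (goal at r8c7)
#> target 1, distractor 7, in-house {2,3,5}, absent {4,6,8,9}
#> . . . . . . . 7 1
#> . . . . . . . . .
#> . . . . . . . . .
#> . . . . . . 5 . .
#> . . . 1 . 7 . . .
#> . . . . . . . 1 .
#> 7 . . . . . 2 . .
#> . . . . . . . . .
#> . . . . . . 3 . .
forced_digit(p)
#> [1] 1
```

The independent solver confirms that only the declared target (1) is
forced into the goal cell; the distractor (7) still has an open cell.

Infer when a participant who erred on the first two practice trials
switched to a successful strategy:

```r
responses <- c(rep("distractor", 2), rep("target", 23))
post <- path_posterior(published_params("solver"), responses)
marg <- strategy_marginals(post)
round(marg$cumulative[1:6, "S"], 3)
#> 0.025 0.076 0.627 0.852 0.942 0.977
transition_trial(marg, "S")
#> [1] 3
```

`P(s_t ≥ S)` first exceeds 50% on trial 3: the two early distractor
responses are most plausibly prevalent-digit guesses, after which the
posterior favors an immediate transition to the successful strategy
(top path `PD -> S`, weight 0.42). Even a fully correct sequence keeps
some posterior mass on lucky early PD guesses, because target and
distractor responses are equally likely under PD.

A complete synthetic experiment and its analysis:

```r
bundle <- simulate_experiment(cohort_config(n_solvers = 20, n_nonsolvers = 40), seed = 1)
labels <- classify_practice(bundle$practice)   # solver / non_solver
fit    <- fit_aggregate(split(bundle$practice$category,
                              bundle$practice$participant_id))
effects <- fit_all_effects(bundle$test)        # DS/HT/GP x window x acc/RT
```

## Command line

Every pipeline stage is also a subcommand of `hs_main()` (wrapper script
in `inst/cli/hidden-single.R`), each writing a JSON run manifest:

```sh
Rscript inst/cli/hidden-single.R simulate-cohort --n-solvers 10 --n-nonsolvers 20 --seed 1 --out-dir sim/
Rscript inst/cli/hidden-single.R classify-solvers --responses sim/practice.csv --out sim/labels.csv
Rscript inst/cli/hidden-single.R fit-aggregate --responses sim/practice.csv --seed 1 --out sim/params.json
Rscript inst/cli/hidden-single.R fit-paths --responses sim/practice.csv --params sim/params.json --top-k 3 --out sim/paths.json
```

## Known limitations

The aggregate likelihood uses per-trial marginals only; where the S
state is rarely occupied (non-solver-like parameters) its occupancy ×
error-rate decomposition is not identified, although the fitted response
curve is. See the methods vignette (`vignettes/strategy-dynamics.Rmd`)
for the full analysis, all modeling assumptions, and the synthetic
generator's stated world.
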