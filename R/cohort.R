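# Synthetic behavioral cohorts: latent strategy paths, practice responses,
# test-phase correctness and response times, and full experiment bundles.

#' Cohort simulation configuration
#'
#' Defaults state the simulated world: group sizes follow the reported
#' cohort (88 solvers, 183 non-solvers), practice responses follow the
#' published solver/non-solver parameter sets, and test-phase effects
#' default to the reported first-window regression estimates (accuracy
#' shifts in logits, response-time shifts in log2 seconds). The baseline
#' response time of 16 s (log2 = 4) with 0.4 log2-s participant spread
#' and 0.5 log2-s trial noise approximates the reported ~15-20 s median
#' solve times.
#'
#' @param n_solvers,n_nonsolvers Group sizes.
#' @param T_practice Number of practice trials.
#' @param solver_params,nonsolver_params [hs_params] parameter sets.
#' @param acc_effects Named accuracy shifts (logits) for `ds`, `ht`, `gp`.
#' @param rt_effects Named response-time shifts (log2 s).
#' @param solver_acc,nonsolver_acc Baseline test-phase accuracy per group.
#' @param base_log2_rt Baseline log2 response time (seconds).
#' @param sd_participant,sd_noise Participant and residual SDs, log2 s.
#' @param acc_sd_participant Participant SD of the accuracy intercept,
#'   logits.
#' @return A list of class `hs_cohort_config`.
#' @export
cohort_config <- function(n_solvers = 88L, n_nonsolvers = 183L,
                          T_practice = 25L,
                          solver_params = published_params("solver"),
                          nonsolver_params = published_params("nonsolver"),
                          acc_effects = c(ds = -0.10, ht = -0.30, gp = 0.16),
                          rt_effects = c(ds = -0.02, ht = 0.33, gp = 0.11),
                          solver_acc = 0.955, nonsolver_acc = 0.5,
                          base_log2_rt = 4.0, sd_participant = 0.4,
                          sd_noise = 0.5, acc_sd_participant = 0.5) {
  stopifnot(n_solvers >= 0, n_nonsolvers >= 0,
            n_solvers + n_nonsolvers >= 1, T_practice >= 1)
  structure(
    list(n_solvers = as.integer(n_solvers),
         n_nonsolvers = as.integer(n_nonsolvers),
         T_practice = as.integer(T_practice),
         solver_params = solver_params, nonsolver_params = nonsolver_params,
         acc_effects = acc_effects, rt_effects = rt_effects,
         solver_acc = solver_acc, nonsolver_acc = nonsolver_acc,
         base_log2_rt = base_log2_rt, sd_participant = sd_participant,
         sd_noise = sd_noise, acc_sd_participant = acc_sd_participant),
    class = "hs_cohort_config"
  )
}

#' Sample a latent strategy path
#'
#' `s_1 ~ a`, `s_(t+1) ~ X[s_t, ]`; the structural zeros of `X` make
#' every sampled path weakly monotone.
#'
#' @param params An [hs_params] object.
#' @param T_len Path length.
#' @return Integer vector of strategy indices 1..4.
#' @export
sample_path <- function(params, T_len = 25L) {
  stopifnot(inherits(params, "hs_params"))
  path <- integer(T_len)
  path[1] <- sample.int(4L, 1L, prob = params$a)
  if (T_len > 1) {
    for (t in 2:T_len) {
      path[t] <- sample.int(4L, 1L, prob = params$X[path[t - 1], ])
    }
  }
  path
}

#' Sample responses along a strategy path
#'
#' Per trial the executed strategy falls back according to `W[s_t, ]`,
#' the response category is drawn from the fixed emission row of the
#' fallback strategy, and (when puzzles are supplied) a concrete digit
#' is drawn uniformly within that category's digit group, reproducing
#' the 3/9, 4/9, 1/9, 1/9 uniform-choice construction.
#'
#' @param params An [hs_params] object.
#' @param path Integer strategy path.
#' @param puzzles Optional list of `hs_puzzle`s, one per trial; when
#'   omitted digits are `NA`.
#' @return Data frame with `trial`, `category`, `digit`, `correct`.
#' @export
sample_responses <- function(params, path, puzzles = NULL) {
  T_len <- length(path)
  if (!is.null(puzzles)) stopifnot(length(puzzles) == T_len)
  R <- emission_matrix()
  cats <- character(T_len)
  digits <- rep(NA_integer_, T_len)
  for (t in seq_len(T_len)) {
    fallback <- sample.int(4L, 1L, prob = params$W[path[t], ])
    ci <- sample.int(4L, 1L, prob = R[fallback, ])
    cats[t] <- hs_categories()[ci]
    if (!is.null(puzzles)) {
      grp <- digits_in_category(puzzles[[t]], cats[t])
      digits[t] <- grp[sample.int(length(grp), 1L)]
    }
  }
  data.frame(trial = seq_len(T_len), category = cats, digit = digits,
             correct = cats == "target", stringsAsFactors = FALSE)
}

#' Simulate test-phase records for one participant
#'
#' Correctness follows a logistic model with the configured feature
#' shifts around the group baseline; response times are log-normal in
#' log2 space with a participant intercept and the configured feature
#' shifts. Timeouts are not simulated: every trial has a response time.
#'
#' @param config An `hs_cohort_config`.
#' @param design An `hs_test_design` (64 rows).
#' @param solver Logical: simulate a solver or a non-solver.
#' @return The design with `correct` and `rt_seconds` columns appended.
#' @export
sample_test_records <- function(config, design, solver = TRUE) {
  stopifnot(inherits(config, "hs_cohort_config"))
  base_acc <- if (solver) config$solver_acc else config$nonsolver_acc
  b_acc <- rnorm(1, 0, config$acc_sd_participant)
  b_rt <- rnorm(1, 0, config$sd_participant)
  eta <- qlogis(base_acc) + b_acc +
    config$acc_effects["ds"] * design$ds_changed +
    config$acc_effects["ht"] * design$ht_changed +
    config$acc_effects["gp"] * design$gp_changed
  mu <- config$base_log2_rt + b_rt +
    config$rt_effects["ds"] * design$ds_changed +
    config$rt_effects["ht"] * design$ht_changed +
    config$rt_effects["gp"] * design$gp_changed
  out <- design
  out$trial <- design$position
  out$correct <- rbinom(nrow(design), 1L, plogis(eta)) == 1L
  out$rt_seconds <- 2^(mu + rnorm(nrow(design), 0, config$sd_noise))
  out
}

#' Simulate a complete synthetic experiment
#'
#' For each participant: training features, a latent strategy path from
#' the group's parameter set, practice responses (with concrete digits
#' when `with_puzzles = TRUE`), a balanced test design, and simulated
#' test-phase correctness and response times. Ground truth (group
#' membership and latent paths) is returned alongside and is never used
#' by the analysis stages.
#'
#' @param config An `hs_cohort_config`.
#' @param seed Master seed; all stage randomness derives from it.
#' @param with_puzzles Generate concrete practice puzzles (slower;
#'   required only when digits matter).
#' @return A list of class `hs_experiment` with `practice` (data frame:
#'   participant_id, trial, category, digit, correct), `test` (data
#'   frame of design flags plus correct, rt_seconds), and `truth`
#'   (group, latent paths, features).
#' @export
simulate_experiment <- function(config = cohort_config(), seed = 1L,
                                with_puzzles = FALSE) {
  stopifnot(inherits(config, "hs_cohort_config"))
  set.seed(as.integer(seed))
  n <- config$n_solvers + config$n_nonsolvers
  groups <- rep(c("solver", "nonsolver"),
                c(config$n_solvers, config$n_nonsolvers))
  practice <- vector("list", n)
  test <- vector("list", n)
  paths <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("p%03d", i)
    params <- if (groups[i] == "solver") config$solver_params else config$nonsolver_params
    features <- assign_training_features()
    path <- sample_path(params, config$T_practice)
    puzzles <- if (with_puzzles) {
      build_practice_design(features, n = config$T_practice)
    }
    resp <- sample_responses(params, path, puzzles)
    resp <- cbind(participant_id = id, resp, stringsAsFactors = FALSE)
    design <- build_test_design(features)
    trec <- sample_test_records(config, design, solver = groups[i] == "solver")
    trec <- cbind(participant_id = id, trec, stringsAsFactors = FALSE)
    practice[[i]] <- resp
    test[[i]] <- trec
    paths[[i]] <- path
    feats[[i]] <- features
  }
  structure(
    list(
      practice = do.call(rbind, practice),
      test = do.call(rbind, test),
      truth = list(participant_id = sprintf("p%03d", seq_len(n)),
                   group = groups, paths = paths, features = feats)
    ),
    class = "hs_experiment"
  )
}
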