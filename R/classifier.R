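# Preregistered solver classifier: logistic mixed model on practice-phase
# first-attempt correctness with a log2(trial) learning-curve slope.

#' Fit the practice-phase learning-curve GLMM
#'
#' Logistic mixed model `correct ~ log2(trial) + (1 + log2(trial) |
#' participant_id)` fitted by maximum likelihood (Laplace approximation).
#' Trials are 1-based inside the log, so the intercept is trial-1
#' accuracy on the logit scale. If the random-slope model fails to
#' converge the model is refitted with a random intercept only; a cohort
#' with no outcome variation at all (complete separation in the limit)
#' is handled by a degenerate fit whose predictions equal the observed
#' constant outcome.
#'
#' @param records Data frame with columns `participant_id`, `trial`
#'   (1..25), and logical/0-1 `correct`.
#' @return An object of class `hs_classifier_fit` wrapping the lme4 fit,
#'   with elements `model`, `degenerate`, `random_slope`, `converged`.
#' @export
fit_practice_glmm <- function(records) {
  stopifnot(all(c("participant_id", "trial", "correct") %in% names(records)))
  records$correct <- as.integer(records$correct)
  records$participant_id <- factor(records$participant_id)
  if (length(unique(records$participant_id)) < 2) {
    stop("at least 2 participants are required")
  }
  records$log2_trial <- log2(records$trial)
  if (length(unique(records$correct)) == 1L) {
    # no variation: the MLE diverges; predictions tend to the constant
    out <- list(model = NULL, degenerate = TRUE,
                constant = records$correct[1],
                participants = levels(records$participant_id),
                random_slope = FALSE, converged = TRUE)
    class(out) <- "hs_classifier_fit"
    return(out)
  }
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             calc.derivs = FALSE)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::glmer(correct ~ log2_trial + (1 + log2_trial | participant_id),
                  data = records, family = stats::binomial(), control = ctrl)
    )),
    error = function(e) NULL
  )
  random_slope <- TRUE
  if (is.null(fit)) {
    random_slope <- FALSE
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(correct ~ log2_trial + (1 | participant_id),
                  data = records, family = stats::binomial(), control = ctrl)
    ))
  }
  conv <- length(fit@optinfo$conv$lme4) == 0
  out <- list(model = fit, degenerate = FALSE,
              participants = levels(records$participant_id),
              random_slope = random_slope, converged = conv)
  class(out) <- "hs_classifier_fit"
  out
}

#' Predicted accuracy at practice trial 25
#'
#' Conditional (empirical-Bayes) prediction: the inverse logit of the
#' fixed effects plus each participant's random intercept and slope,
#' evaluated at `log2(25)`.
#'
#' @param fit An `hs_classifier_fit`.
#' @param participant_id Participants to predict for (default: all in
#'   the fit).
#' @return Named numeric vector of predicted trial-25 accuracies.
#' @export
predict_trial25 <- function(fit, participant_id = NULL) {
  stopifnot(inherits(fit, "hs_classifier_fit"))
  ids <- if (is.null(participant_id)) fit$participants else as.character(participant_id)
  unknown <- setdiff(ids, fit$participants)
  if (length(unknown) > 0) {
    stop("unknown participant id(s): ", paste(unknown, collapse = ", "))
  }
  if (fit$degenerate) {
    p <- if (fit$constant == 1) 1 - 1e-6 else 1e-6
    return(setNames(rep(p, length(ids)), ids))
  }
  nd <- data.frame(participant_id = factor(ids, levels = fit$participants),
                   log2_trial = log2(25))
  p <- predict(fit$model, newdata = nd, type = "response")
  setNames(as.numeric(p), ids)
}

#' Classify participants into solvers and non-solvers
#'
#' A participant is a solver when their predicted accuracy on practice
#' trial 25 strictly exceeds the decision threshold (default 0.8).
#'
#' @param predictions Named vector of predicted trial-25 accuracies.
#' @param threshold Decision threshold (strict inequality).
#' @return Data frame with `participant_id`, `predicted_trial25`,
#'   `label` (`"solver"`/`"non_solver"`).
#' @export
classify_solvers <- function(predictions, threshold = 0.8) {
  stopifnot(all(predictions >= 0 & predictions <= 1))
  data.frame(
    participant_id = names(predictions),
    predicted_trial25 = as.numeric(predictions),
    label = ifelse(predictions > threshold, "solver", "non_solver"),
    stringsAsFactors = FALSE
  )
}

#' End-to-end solver classification
#'
#' Fits the learning-curve GLMM and applies the threshold rule.
#'
#' @inheritParams fit_practice_glmm
#' @inheritParams classify_solvers
#' @return As [classify_solvers()], with the fit attached as attribute
#'   `fit`.
#' @export
classify_practice <- function(records, threshold = 0.8) {
  fit <- fit_practice_glmm(records)
  labels <- classify_solvers(predict_trial25(fit), threshold)
  attr(labels, "fit") <- fit
  labels
}

#' Per-participant accuracy summaries
#'
#' @param records Data frame with `participant_id` and `correct`,
#'   optionally `phase`.
#' @param phase Optional phase filter (matched against a `phase`
#'   column when present).
#' @return Data frame with `participant_id`, `n_trials`, `accuracy`.
#' @export
summarize_accuracy <- function(records, phase = NULL) {
  stopifnot(all(c("participant_id", "correct") %in% names(records)))
  if (!is.null(phase) && "phase" %in% names(records)) {
    records <- records[records$phase == phase, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(data.frame(participant_id = character(0), n_trials = integer(0),
                      accuracy = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- aggregate(cbind(n_trials = correct, accuracy = correct) ~ participant_id,
                   data = transform(records, correct = as.numeric(correct)),
                   FUN = function(x) x, simplify = FALSE)
  data.frame(
    participant_id = as.character(agg$participant_id),
    n_trials = vapply(agg$n_trials, length, integer(1)),
    accuracy = vapply(agg$accuracy, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
}
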