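# Test-phase transfer analyses: goal-position recoding, accuracy and
# response-time mixed models per feature, and rater agreement.

#' Recode goal-position change
#'
#' House-index and cell-index changes are collapsed into a single
#' goal-position flag: `gp_changed = hi_changed | ci_changed`.
#'
#' @param records Data frame with logical columns `hi_changed`,
#'   `ci_changed`.
#' @return The same records with a `gp_changed` column.
#' @export
recode_goal_position <- function(records) {
  stopifnot(all(c("hi_changed", "ci_changed") %in% names(records)))
  records$gp_changed <- records$hi_changed | records$ci_changed
  records
}

feature_column <- function(feature = c("ds", "ht", "gp")) {
  feature <- match.arg(feature)
  paste0(feature, "_changed")
}

window_filter <- function(records, window = c("1-16", "17-64")) {
  window <- match.arg(window)
  rng <- if (window == "1-16") c(1L, 16L) else c(17L, 64L)
  records[records$trial >= rng[1] & records$trial <= rng[2], , drop = FALSE]
}

extract_estimate <- function(model, term, window, n_obs, sigma_scale = FALSE) {
  sm <- summary(model)$coefficients
  if (!term %in% rownames(sm)) stop("term not estimated: ", term)
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  data.frame(
    term = term, window = window,
    estimate = est,
    ci_low = est - qnorm(0.975) * se,
    ci_high = est + qnorm(0.975) * se,
    n_obs = n_obs,
    stringsAsFactors = FALSE
  )
}

fit_feature_mixed <- function(records, feature, window, dv) {
  col <- feature_column(feature)
  stopifnot(all(c("participant_id", "trial", col) %in% names(records)))
  d <- window_filter(records, window)
  if (nrow(d) == 0) stop("no observations in window ", window)
  if (length(unique(d[[col]])) < 2) {
    stop("feature '", feature, "' is constant in this window; effect inestimable")
  }
  d$participant_id <- factor(d$participant_id)
  d$log2_trial <- log2(d$trial)
  d$flag <- as.numeric(d[[col]])
  full <- as.formula(paste(dv, "~ flag + log2_trial + (1 + log2_trial | participant_id)"))
  simple <- as.formula(paste(dv, "~ flag + log2_trial + (1 | participant_id)"))
  if (dv == "correct") {
    d$correct <- as.integer(d$correct)
    ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                               calc.derivs = FALSE)
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::glmer(full, data = d, family = stats::binomial(), control = ctrl))),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      fit <- suppressWarnings(suppressMessages(
        lme4::glmer(simple, data = d, family = stats::binomial(), control = ctrl)))
    }
  } else {
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(full, data = d, control = ctrl, REML = FALSE))),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(simple, data = d, control = ctrl, REML = FALSE)))
    }
  }
  est <- extract_estimate(fit, "flag", window, nrow(d))
  est$term <- feature
  attr(est, "model") <- fit
  est
}

#' Accuracy transfer-effect model
#'
#' Logistic mixed model `correct ~ feature + log2(trial)` with a random
#' intercept and log2(trial) slope per participant (falling back to a
#' random intercept on convergence failure), fitted separately per trial
#' window. One feature is entered at a time; coefficients are in logits
#' with Wald 95% intervals.
#'
#' @param records Test-phase data frame with `participant_id`, `trial`,
#'   `correct`, and the `*_changed` flags (run
#'   [recode_goal_position()] first for the `gp` feature).
#' @param feature `"ds"`, `"ht"`, or `"gp"`.
#' @param window `"1-16"` or `"17-64"`.
#' @return One-row data frame: `term`, `window`, `estimate`, `ci_low`,
#'   `ci_high`, `n_obs`; the fitted model is attached as attribute
#'   `model`.
#' @export
fit_accuracy_model <- function(records, feature = c("ds", "ht", "gp"),
                               window = c("1-16", "17-64")) {
  feature <- match.arg(feature)
  window <- match.arg(window)
  stopifnot("correct" %in% names(records))
  fit_feature_mixed(records, feature, window, "correct")
}

#' Response-time transfer-effect model
#'
#' Linear mixed model on `log2(rt_seconds)` with the same fixed and
#' random structure as [fit_accuracy_model()]. Only correct trials with
#' a recorded response time enter the fit; coefficients are in log2
#' seconds.
#'
#' @inheritParams fit_accuracy_model
#' @export
fit_rt_model <- function(records, feature = c("ds", "ht", "gp"),
                         window = c("1-16", "17-64")) {
  feature <- match.arg(feature)
  window <- match.arg(window)
  stopifnot(all(c("correct", "rt_seconds") %in% names(records)))
  d <- records[as.logical(records$correct) & !is.na(records$rt_seconds), ,
               drop = FALSE]
  if (any(d$rt_seconds <= 0)) stop("rt_seconds must be positive")
  d$log2_rt <- log2(d$rt_seconds)
  fit_feature_mixed(d, feature, window, "log2_rt")
}

#' Run all transfer-effect models
#'
#' Convenience loop over the three features, both windows, and both
#' dependent variables.
#'
#' @param records Test-phase data frame (see [fit_accuracy_model()]).
#' @return Tidy data frame of estimates with a `dv` column.
#' @export
fit_all_effects <- function(records) {
  records <- recode_goal_position(records)
  out <- list()
  for (dv in c("accuracy", "rt")) {
    for (w in c("1-16", "17-64")) {
      for (f in c("ds", "ht", "gp")) {
        est <- if (dv == "accuracy") {
          fit_accuracy_model(records, f, w)
        } else {
          fit_rt_model(records, f, w)
        }
        est$dv <- dv
        attr(est, "model") <- NULL
        out[[length(out) + 1L]] <- est
      }
    }
  }
  do.call(rbind, out)
}

#' Cohen's kappa for interrater agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two
#' categorical raters, with a large-sample 95% confidence interval based
#' on the asymptotic standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param ratings_a,ratings_b Equal-length categorical vectors.
#' @return A list with `kappa`, `ci_low`, `ci_high`, `p_observed`,
#'   `p_expected`, `n`. When both raters use a single identical category
#'   chance agreement is 1 and kappa is undefined (`NA` with an
#'   explanatory `note`).
#' @export
#' @examples
#' # worked 2x2 table: 45/15/25/15 -> p_o = 0.6, p_e = 0.5, kappa = 0.2
#' a <- rep(c("x", "x", "y", "y"), c(45, 15, 25, 15))
#' b <- rep(c("x", "y", "x", "y"), c(45, 15, 25, 15))
#' cohen_kappa(a, b)$kappa
cohen_kappa <- function(ratings_a, ratings_b) {
  stopifnot(length(ratings_a) == length(ratings_b), length(ratings_a) > 0)
  a <- as.character(ratings_a)
  b <- as.character(ratings_b)
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  tab <- table(factor(a, lev), factor(b, lev))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    return(list(kappa = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_observed = po, p_expected = pe, n = n,
                note = "kappa undefined: chance agreement equals 1"))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = kappa,
       ci_low = kappa - qnorm(0.975) * se,
       ci_high = kappa + qnorm(0.975) * se,
       p_observed = po, p_expected = pe, n = n)
}
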