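#' Strategy classes and response categories
#'
#' Four strategy classes, ordered by expected accuracy: uninformed guess
#' (UG, any of the 9 digits), avoid direct contradictions (ADC, any of the
#' 6 digits not already in the target house), prevalent digits (PD, one of
#' the two digits with three instances), and successful (S, always the
#' target). Responses fall into four categories according to the role of
#' the submitted digit. The category order fixes the columns of the
#' emission matrix; the strategy order fixes its rows.
#'
#' @return Character vector of the four ordered levels.
#' @export
hs_strategies <- function() c("UG", "ADC", "PD", "S")

#' @rdname hs_strategies
#' @export
hs_categories <- function() c("in_house", "absent", "distractor", "target")

#' Fixed response emission matrix
#'
#' Row i gives the probability of each response category under strategy i,
#' assuming error-free execution. UG is uniform over all 9 digits, of which
#' 3 are in-house, 4 absent, 1 distractor, 1 target; ADC is uniform over
#' the 6 non-in-house digits; PD is uniform over the 2 prevalent digits;
#' S always selects the target. This matrix is a task constant and is not
#' fitted.
#'
#' @return A 4x4 row-stochastic matrix with strategies as rows and
#'   response categories as columns.
#' @export
#' @examples
#' emission_matrix()["S", ]
emission_matrix <- function() {
  R <- rbind(
    c(3 / 9, 4 / 9, 1 / 9, 1 / 9),
    c(0, 4 / 6, 1 / 6, 1 / 6),
    c(0, 0, 1 / 2, 1 / 2),
    c(0, 0, 0, 1)
  )
  dimnames(R) <- list(hs_strategies(), hs_categories())
  R
}

#' Effective emission matrix including execution errors
#'
#' The error (fallback) matrix `W` mixes each strategy's emissions with
#' those of weaker strategies: `W[i, j]` is the probability that strategy
#' i responds using strategy j's response distribution. The product `W R`
#' gives the effective per-strategy response probabilities.
#'
#' @param W A 4x4 lower-triangular row-stochastic fallback matrix.
#' @return The 4x4 row-stochastic matrix product `W %*% R`.
#' @export
effective_emissions <- function(W) {
  W <- validate_fallback(W)
  WR <- W %*% emission_matrix()
  dimnames(WR) <- list(hs_strategies(), hs_categories())
  WR
}

validate_fallback <- function(W) {
  stopifnot(is.matrix(W), all(dim(W) == 4))
  if (any(abs(W[upper.tri(W)]) > 0)) {
    stop("fallback matrix W must be lower triangular (no fallback onto stronger strategies)")
  }
  if (any(W < 0)) stop("fallback matrix W must be non-negative")
  rs <- rowSums(W)
  if (any(rs < 0.999 - 1e-12 | rs > 1.001 + 1e-12)) {
    stop("fallback matrix rows must sum to 1 within [0.999, 1.001]")
  }
  W <- W / rs
  dimnames(W) <- list(hs_strategies(), hs_strategies())
  W
}

validate_transition <- function(X) {
  stopifnot(is.matrix(X), all(dim(X) == 4))
  if (any(abs(X[lower.tri(X)]) > 0)) {
    stop("transition matrix X must be upper triangular (no regression to weaker strategies)")
  }
  if (any(X < 0)) stop("transition matrix X must be non-negative")
  rs <- rowSums(X)
  if (any(rs < 0.999 - 1e-12 | rs > 1.001 + 1e-12)) {
    stop("transition matrix rows must sum to 1 within [0.999, 1.001]")
  }
  X <- X / rs
  if (abs(X[4, 4] - 1) > 1e-12) stop("S must be absorbing: X[S, S] = 1")
  dimnames(X) <- list(hs_strategies(), hs_strategies())
  X
}

#' Aggregate model parameters
#'
#' Container for the aggregate strategy-dynamics model: initial strategy
#' distribution `a`, upper-triangular transition matrix `X` (strategies
#' never regress to weaker ones; S is absorbing), and lower-triangular
#' fallback matrix `W` (execution errors only fall back onto weaker
#' strategies). Rows rounded to 3 decimals are accepted (sums in
#' [0.999, 1.001]) and renormalized on construction.
#'
#' @param a Length-4 initial strategy probability vector.
#' @param X 4x4 upper-triangular row-stochastic transition matrix.
#' @param W 4x4 lower-triangular row-stochastic fallback matrix.
#' @return An object of class `hs_params`.
#' @export
hs_params <- function(a, X, W) {
  a <- as.numeric(a)
  stopifnot(length(a) == 4, all(a >= 0))
  sa <- sum(a)
  if (sa < 0.999 - 1e-12 || sa > 1.001 + 1e-12) {
    stop("initial distribution a must sum to 1 within [0.999, 1.001]")
  }
  a <- setNames(a / sa, hs_strategies())
  structure(
    list(a = a, X = validate_transition(X), W = validate_fallback(W)),
    class = "hs_params"
  )
}

#' @export
print.hs_params <- function(x, ...) {
  cat("Aggregate strategy-model parameters (UG < ADC < PD < S)\n")
  cat("a:\n"); print(round(x$a, 3))
  cat("X (transitions):\n"); print(round(x$X, 3))
  cat("W (error fallback):\n"); print(round(x$W, 3))
  cat("WR (effective emissions):\n"); print(round(effective_emissions(x$W), 3))
  invisible(x)
}

#' Published fitted parameter sets
#'
#' The reported maximum-likelihood parameter estimates for the solver and
#' non-solver groups, as printed to 3 decimals. These serve as defaults
#' for the synthetic-cohort generator and as priors for individual-level
#' path inference.
#'
#' @param group `"solver"` or `"nonsolver"`.
#' @return An [hs_params] object.
#' @export
published_params <- function(group = c("solver", "nonsolver")) {
  group <- match.arg(group)
  if (group == "solver") {
    hs_params(
      a = c(0.085, 0.241, 0.310, 0.365),
      X = rbind(
        c(0.000, 0.999, 0.000, 0.000),
        c(0, 0.106, 0.892, 0.001),
        c(0, 0, 0.783, 0.217),
        c(0, 0, 0, 1)
      ),
      W = rbind(
        c(1.000, 0, 0, 0),
        c(0.000, 1.000, 0, 0),
        c(0.000, 0.054, 0.946, 0),
        c(0.000, 0.000, 0.090, 0.910)
      )
    )
  } else {
    hs_params(
      a = c(0.109, 0.397, 0.463, 0.032),
      X = rbind(
        c(0.560, 0.001, 0.437, 0.002),
        c(0, 0.770, 0.229, 0.001),
        c(0, 0, 0.993, 0.007),
        c(0, 0, 0, 1)
      ),
      W = rbind(
        c(1.000, 0, 0, 0),
        c(0.109, 0.891, 0, 0),
        c(0.024, 0.038, 0.939, 0),
        c(0.016, 0.016, 0.185, 0.783)
      )
    )
  }
}

# map category labels (character or integer 1..4) to integer indices
category_index <- function(categories) {
  if (is.numeric(categories)) {
    idx <- as.integer(categories)
    if (any(is.na(idx)) || any(idx < 1L | idx > 4L)) stop("invalid category index")
    return(idx)
  }
  idx <- match(as.character(categories), hs_categories())
  if (any(is.na(idx))) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("invalid response category '%s' at position %d",
                 as.character(categories)[bad], bad))
  }
  idx
}
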