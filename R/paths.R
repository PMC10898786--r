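# Individual-level monotone-path HMM: exact enumeration of weakly
# non-decreasing strategy paths, path priors/likelihoods, posteriors,
# per-trial marginals, and transition trials.

#' Enumerate all weakly monotone strategy paths
#'
#' Under the monotonic-improvement constraint a latent strategy path is a
#' weakly non-decreasing sequence over the 4 ordered strategies, fully
#' described by how many trials are spent in each strategy. There are
#' `choose(T + 3, 3)` such paths (3,276 at T = 25).
#'
#' @param T_len Path length (number of trials).
#' @return An integer matrix, one row per path, entries 1..4 indexing
#'   strategies in the order UG, ADC, PD, S.
#' @export
enumerate_monotone_paths <- function(T_len) {
  T_len <- as.integer(T_len)
  stopifnot(T_len >= 1)
  rows <- vector("list", choose(T_len + 3L, 3L))
  k <- 0L
  for (n1 in 0:T_len) {
    for (n2 in 0:(T_len - n1)) {
      for (n3 in 0:(T_len - n1 - n2)) {
        n4 <- T_len - n1 - n2 - n3
        k <- k + 1L
        rows[[k]] <- rep(1:4, c(n1, n2, n3, n4))
      }
    }
  }
  matrix(unlist(rows), nrow = k, ncol = T_len, byrow = TRUE)
}

#' Prior probability of a strategy path
#'
#' `a[s1] * prod_t X[s_t, s_(t+1)]`. Non-monotone paths are rejected;
#' under the structural zeros of `X` the prior over all monotone paths of
#' a given length sums to 1.
#'
#' @param params An [hs_params] object.
#' @param path Integer vector of strategy indices 1..4 (or character
#'   labels).
#' @return Scalar probability.
#' @export
path_prior <- function(params, path) {
  stopifnot(inherits(params, "hs_params"))
  if (is.character(path)) path <- match(path, hs_strategies())
  path <- as.integer(path)
  if (any(is.na(path)) || any(path < 1L | path > 4L)) stop("invalid path")
  if (length(path) > 1 && any(diff(path) < 0)) {
    stop("path violates the monotonic improvement constraint")
  }
  p <- params$a[path[1]]
  if (length(path) > 1) {
    p <- p * prod(params$X[cbind(path[-length(path)], path[-1])])
  }
  unname(p)
}

#' Likelihood of a response sequence given a strategy path
#'
#' Product of per-trial emission entries. Mode `"effective"` (the
#' default) uses the error-adjusted emissions `W R`, so occasional
#' distractor responses remain possible under the successful strategy;
#' mode `"raw"` uses the error-free matrix `R`.
#'
#' @param params An [hs_params] object.
#' @param path Strategy path (indices or labels), length T.
#' @param responses Response categories, length T.
#' @param mode `"effective"` or `"raw"`.
#' @return Scalar probability.
#' @export
path_likelihood <- function(params, path, responses,
                            mode = c("effective", "raw")) {
  mode <- match.arg(mode)
  if (is.character(path)) path <- match(path, hs_strategies())
  path <- as.integer(path)
  resp <- category_index(responses)
  if (length(path) != length(resp)) {
    stop("path and responses must have the same length")
  }
  E <- if (mode == "effective") effective_emissions(params$W) else emission_matrix()
  prod(E[cbind(path, resp)])
}

#' Posterior over monotone strategy paths
#'
#' Exact Bayes rule over the enumerated monotone paths: each path's
#' weight is proportional to its prior under (`a`, `X`) times the
#' likelihood of the observed responses under the chosen emission mode.
#'
#' @inheritParams path_likelihood
#' @return An object of class `hs_path_posterior` with elements `paths`
#'   (matrix, one row per path), `weights` (posterior probabilities),
#'   `mode`, and `T_len`.
#' @export
path_posterior <- function(params, responses, mode = c("effective", "raw")) {
  mode <- match.arg(mode)
  resp <- category_index(responses)
  T_len <- length(resp)
  paths <- enumerate_monotone_paths(T_len)
  E <- if (mode == "effective") effective_emissions(params$W) else emission_matrix()
  logE <- log(E)
  logX <- log(params$X)
  loga <- log(params$a)
  logw <- apply(paths, 1, function(pp) {
    lp <- loga[pp[1]]
    if (T_len > 1) lp <- lp + sum(logX[cbind(pp[-T_len], pp[-1])])
    lp + sum(logE[cbind(pp, resp)])
  })
  if (all(!is.finite(logw))) {
    stop("degenerate posterior: all paths have zero probability ",
         "(responses impossible under the chosen emission mode)")
  }
  w <- exp(logw - max(logw[is.finite(logw)]))
  w[!is.finite(logw)] <- 0
  structure(
    list(paths = paths, weights = w / sum(w), mode = mode, T_len = T_len),
    class = "hs_path_posterior"
  )
}

#' Most probable strategy paths
#'
#' The top-k monotone paths by posterior weight (exact, since the
#' posterior enumerates all paths).
#'
#' @param posterior An `hs_path_posterior`.
#' @param k Number of paths to return.
#' @return A list with `paths` (k x T matrix) and `weights`.
#' @export
top_paths <- function(posterior, k = 3L) {
  stopifnot(inherits(posterior, "hs_path_posterior"))
  ord <- order(posterior$weights, decreasing = TRUE)[seq_len(min(k, length(posterior$weights)))]
  list(paths = posterior$paths[ord, , drop = FALSE],
       weights = posterior$weights[ord])
}

#' Per-trial strategy marginals and cumulative tail probabilities
#'
#' Marginalizes the path posterior: `marginal[t, s] = P(s_t = s)` and
#' `cumulative[t, s] = P(s_t >= s)` (probability of using a strategy at
#' least as effective as s on trial t).
#'
#' @param posterior An `hs_path_posterior`.
#' @return A list with `marginal` and `cumulative`, both T x 4 matrices
#'   with strategy-labelled columns.
#' @export
strategy_marginals <- function(posterior) {
  stopifnot(inherits(posterior, "hs_path_posterior"))
  T_len <- posterior$T_len
  marg <- matrix(0, T_len, 4, dimnames = list(NULL, hs_strategies()))
  for (s in 1:4) {
    marg[, s] <- colSums(posterior$weights * (posterior$paths == s))
  }
  cum <- t(apply(marg, 1, function(row) rev(cumsum(rev(row)))))
  dimnames(cum) <- dimnames(marg)
  list(marginal = marg, cumulative = cum)
}

#' Forward-backward strategy marginals
#'
#' Independent dynamic-programming computation of `P(s_t = s)` on the
#' constrained chain, used as a cross-check for the exhaustive
#' enumeration in [strategy_marginals()].
#'
#' @inheritParams path_posterior
#' @return A T x 4 matrix of per-trial strategy marginals.
#' @export
forward_backward_marginals <- function(params, responses,
                                       mode = c("effective", "raw")) {
  mode <- match.arg(mode)
  resp <- category_index(responses)
  T_len <- length(resp)
  E <- if (mode == "effective") effective_emissions(params$W) else emission_matrix()
  alpha <- matrix(0, T_len, 4)
  alpha[1, ] <- params$a * E[, resp[1]]
  if (T_len > 1) {
    for (t in 2:T_len) {
      alpha[t, ] <- as.numeric(alpha[t - 1, ] %*% params$X) * E[, resp[t]]
    }
  }
  beta <- matrix(0, T_len, 4)
  beta[T_len, ] <- 1
  if (T_len > 1) {
    for (t in (T_len - 1):1) {
      beta[t, ] <- as.numeric(params$X %*% (E[, resp[t + 1]] * beta[t + 1, ]))
    }
  }
  gamma <- alpha * beta
  norm <- rowSums(gamma)
  if (any(norm == 0)) stop("degenerate posterior in forward-backward pass")
  gamma <- gamma / norm
  dimnames(gamma) <- list(NULL, hs_strategies())
  gamma
}

#' First trial at which a strategy level is attained
#'
#' The transition trial into strategy s is the first trial t at which
#' the posterior probability of using a strategy at least as effective
#' as s strictly exceeds the threshold (default 50%).
#'
#' @param marginals Output of [strategy_marginals()] (or a cumulative
#'   T x 4 matrix).
#' @param s Strategy label or index.
#' @param threshold Crossing threshold (strict inequality).
#' @return Integer trial index, or `NA` if the threshold is never
#'   exceeded.
#' @export
transition_trial <- function(marginals, s, threshold = 0.5) {
  cum <- if (is.list(marginals)) marginals$cumulative else marginals
  if (is.character(s)) s <- match(s, hs_strategies())
  stopifnot(s %in% 1:4)
  hit <- which(cum[, s] > threshold)
  if (length(hit) == 0) NA_integer_ else hit[1]
}
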