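# Aggregate model and monotone-path HMM: constants, forward
# distributions, likelihood, enumeration, posteriors, marginals.

solver <- published_params("solver")
nonsolver <- published_params("nonsolver")

test_that("emission matrix encodes the four strategy accuracies", {
  R <- emission_matrix()
  expect_equal(rowSums(R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(R["S", ]), c(0, 0, 0, 1))
  expect_equal(unname(R[, "target"]), c(1 / 9, 1 / 6, 1 / 2, 1))
  expect_equal(unname(R["UG", ]), c(3, 4, 1, 1) / 9)
  expect_equal(unname(R["ADC", ]), c(0, 4, 1, 1) / 6)
})

test_that("effective emissions reproduce the published WR blocks to 3 decimals", {
  WsR <- effective_emissions(solver$W)
  expect_equal(round(unname(WsR["S", ]), 3), c(0, 0, 0.045, 0.955))
  expect_equal(round(unname(WsR["PD", ]), 3), c(0, 0.036, 0.482, 0.482))
  expect_equal(round(unname(WsR["ADC", ]), 3), c(0, 0.667, 0.167, 0.167))
  WnR <- effective_emissions(nonsolver$W)
  expect_equal(round(unname(WnR["S", ]), 3), c(0.005, 0.018, 0.097, 0.880))
  expect_equal(round(unname(WnR["PD", ]), 3), c(0.008, 0.036, 0.478, 0.478))
  expect_equal(round(unname(WnR["ADC", ]), 3), c(0.036, 0.642, 0.161, 0.161))
  # identity fallback leaves R unchanged
  expect_equal(effective_emissions(diag(4)), emission_matrix())
})

test_that("parameter validation enforces structural zeros and tolerances", {
  Wbad <- solver$W; Wbad[1, 2] <- 0.1
  expect_error(hs_params(solver$a, solver$X, Wbad), "lower triangular")
  Xbad <- solver$X; Xbad[2, 1] <- 0.1
  expect_error(hs_params(solver$a, Xbad, solver$W), "upper triangular")
  Xbad2 <- solver$X; Xbad2[1, ] <- c(0.2, 0.2, 0.2, 0.2)
  expect_error(hs_params(solver$a, Xbad2, solver$W), "sum to 1")
  # printed rows with 0.999 sums load and renormalize
  expect_equal(sum(solver$X[1, ]), 1)
})

test_that("forward response distribution follows a X^(t-1) W R", {
  expect_equal(response_distribution(solver, 1),
               setNames(as.numeric(solver$a %*% effective_emissions(solver$W)),
                        hs_categories()))
  absorbed <- hs_params(c(0, 0, 0, 1), solver$X, diag(4))
  for (t in c(1, 5, 20)) {
    expect_equal(unname(response_distribution(absorbed, t)), c(0, 0, 0, 1))
  }
  expect_error(response_distribution(solver, 0), "positive")
  curve <- response_curve(nonsolver, 25)
  expect_equal(rowSums(curve), rep(1, 25), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("forward distributions equal exhaustive path-enumeration mixtures (T <= 5)", {
  for (params in list(solver, nonsolver)) {
    WR <- effective_emissions(params$W)
    for (T_len in 1:5) {
      paths <- enumerate_monotone_paths(T_len)
      priors <- apply(paths, 1, function(pp) path_prior(params, pp))
      expect_equal(sum(priors), 1, tolerance = 1e-10)
      for (t in seq_len(T_len)) {
        mix <- colSums(priors * WR[paths[, t], , drop = FALSE])
        expect_equal(unname(mix), unname(response_distribution(params, t)),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("aggregate NLL reduces and adds correctly", {
  one <- list("distractor")
  p1 <- response_distribution(solver, 1)
  expect_equal(aggregate_nll(solver, one), -log(p1[["distractor"]]))
  cohort <- list(c("target", "distractor"), c("in_house", "target"))
  expect_equal(aggregate_nll(solver, c(cohort, cohort)),
               2 * aggregate_nll(solver, cohort))
  # zero-probability observation -> Inf, not an error
  expect_equal(aggregate_nll(hs_params(c(0, 0, 0, 1), solver$X, diag(4)),
                             list("in_house")), Inf)
  # matches brute-force matrix-power computation at T = 25
  set.seed(8)
  seqs <- lapply(1:5, function(i) sample(hs_categories(), 25, replace = TRUE))
  brute <- 0
  WR <- effective_emissions(solver$W)
  for (s in seqs) {
    for (t in 1:25) {
      Xp <- diag(4)
      if (t > 1) for (k in 1:(t - 1)) Xp <- Xp %*% solver$X
      p <- as.numeric(solver$a %*% Xp %*% WR)
      brute <- brute - log(p[match(s[t], hs_categories())])
    }
  }
  expect_equal(aggregate_nll(solver, seqs), brute, tolerance = 1e-9)
})

test_that("monotone path enumeration counts C(T+3, 3)", {
  expect_equal(nrow(enumerate_monotone_paths(1)), 4)
  expect_equal(nrow(enumerate_monotone_paths(2)), 10)
  expect_equal(nrow(enumerate_monotone_paths(25)), 3276)
  expect_equal(nrow(enumerate_monotone_paths(25)), choose(28, 3))
  # T = 2 brute force: 10 of the 16 pairs are non-decreasing
  pairs <- expand.grid(1:4, 1:4)
  expect_equal(sum(pairs[, 2] >= pairs[, 1]), 10)
  p2 <- enumerate_monotone_paths(2)
  expect_true(all(p2[, 2] >= p2[, 1]))
  expect_equal(anyDuplicated(p2), 0)
})

test_that("path priors respect the chain and reject non-monotone paths", {
  expect_equal(path_prior(solver, rep(4L, 25)), unname(solver$a["S"]))
  expect_error(path_prior(solver, c(3L, 2L)), "monotonic")
  expect_error(path_prior(solver, c(1L, 5L)), "invalid")
  expect_equal(path_prior(solver, c("UG", "ADC")),
               unname(solver$a["UG"] * solver$X["UG", "ADC"]))
})

test_that("path likelihoods multiply emission entries in both modes", {
  all_s <- rep(4L, 25)
  all_target <- rep("target", 25)
  expect_equal(path_likelihood(solver, all_s, all_target, mode = "raw"), 1)
  WsR <- effective_emissions(solver$W)
  expect_equal(path_likelihood(solver, all_s, all_target, mode = "effective"),
               WsR["S", "target"]^25)
  resp <- c(rep("target", 12), "in_house", rep("target", 12))
  expect_equal(path_likelihood(solver, all_s, resp, mode = "effective"), 0)
  expect_error(path_likelihood(solver, c(1L, 2L), "target"), "length")
})

test_that("path posterior equals brute-force Bayes rule at T = 3", {
  resp <- c("distractor", "target", "target")
  post <- path_posterior(solver, resp)
  expect_equal(sum(post$weights), 1, tolerance = 1e-12)
  paths <- enumerate_monotone_paths(3)
  num <- apply(paths, 1, function(pp) {
    path_prior(solver, pp) * path_likelihood(solver, pp, resp)
  })
  expect_equal(post$weights, num / sum(num), tolerance = 1e-12)
  # top path is well defined and monotone
  tp <- top_paths(post, 3)
  expect_equal(nrow(tp$paths), 3)
  expect_true(all(apply(tp$paths, 1, function(x) all(diff(x) >= 0))))
})

test_that("an error-free sequence keeps PD-start paths alive (lucky guesses)", {
  post <- path_posterior(solver, rep("target", 25))
  starts_pd <- post$paths[, 1] == 3
  expect_gt(sum(post$weights[starts_pd]), 0)
  # raw mode collapses onto S-only paths for error-free data
  post_raw <- path_posterior(solver, rep("target", 25), mode = "raw")
  expect_gt(sum(post_raw$weights[post_raw$paths[, 1] == 3]), 0)
})

test_that("raw mode errors when all paths are impossible", {
  # in_house response on every trial: zero under every strategy's raw row
  # except UG, but UG cannot persist under solver transitions (X[UG,UG]=0)
  expect_error(
    path_posterior(hs_params(c(0, 0, 0, 1), solver$X, solver$W),
                   rep("in_house", 3), mode = "raw"),
    "degenerate"
  )
})

test_that("strategy marginals agree with forward-backward and with enumeration", {
  set.seed(21)
  for (params in list(solver, nonsolver)) {
    for (T_len in c(1, 3, 5)) {
      resp <- sample(c("target", "distractor", "absent"), T_len, replace = TRUE)
      post <- path_posterior(params, resp)
      marg <- strategy_marginals(post)
      expect_equal(rowSums(marg$marginal), rep(1, T_len), tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(unname(marg$cumulative[, "UG"]), rep(1, T_len),
                   tolerance = 1e-12)
      fb <- forward_backward_marginals(params, resp)
      expect_equal(marg$marginal, fb, tolerance = 1e-10)
    }
  }
  # and at T = 25 on a realistic sequence
  resp25 <- c(rep("distractor", 3), rep("target", 22))
  marg25 <- strategy_marginals(path_posterior(solver, resp25))
  fb25 <- forward_backward_marginals(solver, resp25)
  expect_equal(marg25$marginal, fb25, tolerance = 1e-10)
})

test_that("prior-chain cumulative occupancy is monotone in t", {
  for (params in list(solver, nonsolver)) {
    occ <- matrix(0, 25, 4)
    v <- params$a
    for (t in 1:25) {
      occ[t, ] <- v
      v <- as.numeric(v %*% params$X)
    }
    cum <- t(apply(occ, 1, function(row) rev(cumsum(rev(row)))))
    for (s in 1:4) {
      expect_true(all(diff(cum[, s]) >= -1e-12))
    }
  }
})

test_that("transition trial is the first strict threshold crossing", {
  cum <- matrix(0, 4, 4)
  cum[, 4] <- c(0.2, 0.4, 0.51, 0.7)
  expect_equal(transition_trial(cum, "S"), 3)
  cum2 <- matrix(0.5, 4, 4)
  expect_true(is.na(transition_trial(cum2, "S")))
  cum3 <- matrix(0, 1, 4); cum3[1, 4] <- 0.6
  expect_equal(transition_trial(cum3, 4), 1)
})
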