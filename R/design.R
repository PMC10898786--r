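# Per-participant feature assignment, the 25-trial practice design, and
# the balanced Latin-square 64-trial transfer design.

#' Assign per-participant training and transfer features
#'
#' Draws a house type, house index, cell index, and a training set of 4
#' digits uniformly at random; the transfer set is 4 of the 5 remaining
#' digits, so the two sets are disjoint and exactly one digit of 1..9
#' appears in neither.
#'
#' @param seed Optional integer seed.
#' @return A list of class `hs_features` with fields `house_type`,
#'   `house_index`, `cell_index`, `train_digits`, `transfer_digits`.
#' @export
assign_training_features <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  train <- sort(sample(1:9, 4L))
  transfer <- sort(sample(setdiff(1:9, train), 4L))
  structure(
    list(
      house_type = sample(c("row", "column"), 1L),
      house_index = sample(1:9, 1L),
      cell_index = sample(1:9, 1L),
      train_digits = train,
      transfer_digits = transfer
    ),
    class = "hs_features"
  )
}

#' Build the practice-phase design
#'
#' All practice puzzles share the training house type, house index, and
#' cell index; on every trial the target and distractor are drawn
#' (distinct) from the training digit set and the three in-house digits
#' from the remaining seven digits, so only the hint layout and digit
#' roles vary.
#'
#' @param features An `hs_features` object.
#' @param n Number of practice trials (default 25).
#' @param seed Optional integer seed.
#' @return A list of `n` `hs_puzzle` objects.
#' @export
build_practice_design <- function(features, n = 25L, seed = NULL) {
  stopifnot(inherits(features, "hs_features"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    td <- sample(features$train_digits, 2L)
    inh <- sample(setdiff(1:9, td), 3L)
    generate_puzzle(features$house_type, features$house_index,
                    features$cell_index, target = td[1], distractor = td[2],
                    in_house = inh)
  })
}

# Balanced Latin square for the 8 house-type x house-index x cell-index
# change combinations: Williams construction, base row 1 2 8 3 7 4 6 5,
# subsequent rows cyclic shifts. Satisfies once-per-set, once-per-position,
# and 4-before/4-after precedence for every pair (verified in tests).
latin_square_8 <- function() {
  base <- c(1L, 2L, 8L, 3L, 7L, 4L, 6L, 5L)
  t(vapply(0:7, function(i) ((base - 1L + i) %% 8L) + 1L, integer(8)))
}

# The 8 flag combinations over (ht, hi, ci); combination k (1..8) encoded
# in binary with ht the fastest-varying bit.
combo_flags <- function() {
  data.frame(
    combo = 1:8,
    ht_changed = rep(c(FALSE, TRUE), 4),
    hi_changed = rep(rep(c(FALSE, TRUE), each = 2), 2),
    ci_changed = rep(c(FALSE, TRUE), each = 4)
  )
}

#' Build the balanced 64-trial test design
#'
#' 64 transfer trials arranged in 8 sets of 8. The 8 combinations of
#' house-type/house-index/cell-index change flags follow a balanced Latin
#' square over sets: each combination occurs once per set, once per
#' within-set position, and precedes every other combination in exactly
#' 4 sets. Digit-set changes are assigned to 4 of the 8 combinations and
#' complemented on alternate sets, so each set has exactly 4 digit-set
#' changes and any two consecutive sets jointly cover all 16 four-flag
#' combinations.
#'
#' @param features An `hs_features` object.
#' @param seed Optional integer seed (randomizes which combinations carry
#'   the digit-set change in odd sets).
#' @return A data frame of class `hs_test_design` with 64 rows: `position`,
#'   `set_index`, `set_position`, `combo`, and logical change flags
#'   `ds_changed`, `ht_changed`, `hi_changed`, `ci_changed`, `gp_changed`.
#' @export
build_test_design <- function(features, seed = NULL) {
  stopifnot(inherits(features, "hs_features"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  sq <- latin_square_8()
  ds_base <- sort(sample(1:8, 4L)) # combos with ds change in odd sets
  flags <- combo_flags()
  rows <- vector("list", 64L)
  pos <- 0L
  for (s in 1:8) {
    for (j in 1:8) {
      pos <- pos + 1L
      cmb <- sq[s, j]
      ds <- if (s %% 2L == 1L) cmb %in% ds_base else !(cmb %in% ds_base)
      rows[[pos]] <- data.frame(
        position = pos, set_index = s, set_position = j, combo = cmb,
        ds_changed = ds,
        ht_changed = flags$ht_changed[cmb],
        hi_changed = flags$hi_changed[cmb],
        ci_changed = flags$ci_changed[cmb]
      )
    }
  }
  out <- do.call(rbind, rows)
  out$gp_changed <- out$hi_changed | out$ci_changed
  class(out) <- c("hs_test_design", "data.frame")
  out
}

#' Realize a test trial as a concrete puzzle
#'
#' Unchanged features keep their training values. A changed house type is
#' flipped; a changed house index or cell index is resampled uniformly
#' from the 8 non-training values (independently per trial, which yields
#' the 1/32 per-cell marginal for single goal-position changes and 1/256
#' for double changes); a changed digit set switches target and
#' distractor sampling to the transfer set.
#'
#' @param features An `hs_features` object.
#' @param trial One row of an `hs_test_design` (or any list with the four
#'   `*_changed` flags).
#' @param seed Optional integer seed.
#' @param generate If `FALSE`, skip puzzle generation and return realized
#'   features only (useful for design-distribution checks).
#' @return A list with the realized `house_type`, `house_index`,
#'   `cell_index`, `target`, `distractor`, and the generated `puzzle`
#'   (`NULL` when `generate = FALSE`).
#' @export
realize_trial <- function(features, trial, seed = NULL, generate = TRUE) {
  stopifnot(inherits(features, "hs_features"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ht <- if (isTRUE(trial$ht_changed)) {
    setdiff(c("row", "column"), features$house_type)
  } else {
    features$house_type
  }
  hi <- if (isTRUE(trial$hi_changed)) {
    sample(setdiff(1:9, features$house_index), 1L)
  } else {
    features$house_index
  }
  ci <- if (isTRUE(trial$ci_changed)) {
    sample(setdiff(1:9, features$cell_index), 1L)
  } else {
    features$cell_index
  }
  dset <- if (isTRUE(trial$ds_changed)) features$transfer_digits else features$train_digits
  td <- sample(dset, 2L)
  inh <- sample(setdiff(1:9, td), 3L)
  puzzle <- if (generate) {
    generate_puzzle(ht, hi, ci, target = td[1], distractor = td[2],
                    in_house = inh)
  }
  list(house_type = ht, house_index = hi, cell_index = ci,
       target = td[1], distractor = td[2], puzzle = puzzle)
}

#' Tabulate a test design with realized features
#'
#' Convenience wrapper realizing every trial of a test design and
#' returning a flat table suitable for CSV export.
#'
#' @inheritParams realize_trial
#' @param design An `hs_test_design`.
#' @param with_puzzles If `TRUE`, attach the generated puzzles as an
#'   attribute `puzzles` and include the 81-character grid strings.
#' @return A data frame with one row per trial.
#' @export
realize_design <- function(features, design, seed = NULL,
                           with_puzzles = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  puzzles <- vector("list", nrow(design))
  out <- design
  out$house_type <- character(nrow(design))
  out$house_index <- integer(nrow(design))
  out$cell_index <- integer(nrow(design))
  out$target <- integer(nrow(design))
  out$distractor <- integer(nrow(design))
  if (with_puzzles) out$grid <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    rt <- realize_trial(features, design[i, ], generate = with_puzzles)
    out$house_type[i] <- rt$house_type
    out$house_index[i] <- rt$house_index
    out$cell_index[i] <- rt$cell_index
    out$target[i] <- rt$target
    out$distractor[i] <- rt$distractor
    if (with_puzzles) {
      out$grid[i] <- grid_to_string(rt$puzzle$grid)
      puzzles[[i]] <- rt$puzzle
    }
  }
  if (with_puzzles) attr(out, "puzzles") <- puzzles
  out
}
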