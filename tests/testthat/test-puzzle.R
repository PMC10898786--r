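# Puzzle engine: geometry, generation invariants, solving oracle, feedback.

test_that("houses enumerate correctly and intersect 3 boxes of 3 cells", {
  expect_equal(cells_of_house("row", 1),
               cbind(row = rep(1L, 9), col = 1:9))
  expect_equal(cells_of_house("column", 7),
               cbind(row = 1:9, col = rep(7L, 9)))
  for (ht in c("row", "column")) {
    for (hi in 1:9) {
      cells <- cells_of_house(ht, hi)
      expect_equal(nrow(unique(cells)), 9)
      boxes <- table(box_of(cells[, 1], cells[, 2]))
      expect_length(boxes, 3)
      expect_true(all(boxes == 3))
    }
  }
  expect_error(cells_of_house("row", 10), "house_index")
})

test_that("every cell has 20 peers and the relation is symmetric", {
  for (r in 1:9) {
    for (cc in 1:9) {
      expect_equal(nrow(peers(r, cc)), 20)
    }
  }
  expect_true(any(peers(1, 1)[, 1] == 3 & peers(1, 1)[, 2] == 3)) # same box
  expect_false(any(peers(1, 1)[, 1] == 4 & peers(1, 1)[, 2] == 4))
  set.seed(1)
  for (i in 1:25) {
    a <- c(sample(9, 1), sample(9, 1))
    b <- c(sample(9, 1), sample(9, 1))
    if (all(a == b)) next
    ab <- any(peers(a[1], a[2])[, 1] == b[1] & peers(a[1], a[2])[, 2] == b[2])
    ba <- any(peers(b[1], b[2])[, 1] == a[1] & peers(b[1], b[2])[, 2] == a[2])
    expect_equal(ab, ba)
  }
})

test_that("grid string serialization round-trips", {
  p <- generate_puzzle("row", 4, 2, 5, 9, c(1, 2, 3), seed = 11)
  s <- grid_to_string(p$grid)
  expect_equal(nchar(s), 81)
  expect_equal(string_to_grid(s), p$grid)
  expect_error(string_to_grid(paste(rep("x", 81), collapse = "")), "digits")
})

test_that("response classification partitions digits as (1,1,4,3)", {
  batch <- make_puzzle_batch(25, seed = 2)
  for (p in batch) {
    cats <- vapply(1:9, function(d) classify_response(p, d), character(1))
    counts <- table(factor(cats, levels = hs_categories()))
    expect_equal(unname(counts[c("target", "distractor", "absent", "in_house")]),
                 c(1L, 1L, 4L, 3L), ignore_attr = TRUE)
  }
  expect_error(classify_response(batch[[1]], 0), "1..9")
})

test_that("the tutorial example role structure is reproduced", {
  # column 7, cell 8, target 1, distractor 7, remaining training digits 3, 5
  p <- generate_puzzle("column", 7, 8, target = 1, distractor = 7,
                       in_house = c(2, 3, 5), seed = 42)
  expect_equal(classify_response(p, 1), "target")
  expect_equal(classify_response(p, 7), "distractor")
  expect_equal(classify_response(p, 4), "absent")
  expect_equal(classify_response(p, 2), "in_house")
  expect_equal(p$absent, c(4L, 6L, 8L, 9L))
})

test_that("generated puzzles satisfy every structural invariant", {
  batch <- make_puzzle_batch(200, seed = 3)
  for (p in batch) {
    expect_true(validate_puzzle(p))
    expect_equal(sum(p$grid > 0), 9)
    # oracle agreement: peer-elimination solver finds the declared target
    expect_equal(forced_digit(p), p$target)
    expect_false(is_forced(p, p$distractor))
    # goal sees no distractor instance
    locs <- which(p$grid == p$distractor, arr.ind = TRUE)
    expect_false(any(hiddensingle:::is_peer(p$goal[1], p$goal[2],
                                            locs[, 1], locs[, 2])))
  }
})

test_that("generation is deterministic given a seed", {
  p1 <- generate_puzzle("row", 3, 5, 2, 8, c(4, 6, 7), seed = 77)
  p2 <- generate_puzzle("row", 3, 5, 2, 8, c(4, 6, 7), seed = 77)
  p3 <- generate_puzzle("row", 3, 5, 2, 8, c(4, 6, 7), seed = 78)
  expect_equal(grid_to_string(p1$grid), grid_to_string(p2$grid))
  expect_false(grid_to_string(p1$grid) == grid_to_string(p3$grid))
})

test_that("removing a target instance breaks the forced-target cover", {
  p <- generate_puzzle("row", 6, 1, 9, 4, c(1, 2, 8), seed = 5)
  locs <- which(p$grid == p$target, arr.ind = TRUE)
  # remove the instance covering an empty house cell via its column
  broken <- p
  off_house <- locs[locs[, 1] != p$house_index, , drop = FALSE]
  # find one whose removal uncovers a house cell
  found <- FALSE
  for (i in seq_len(nrow(off_house))) {
    q <- p
    q$grid[off_house[i, 1], off_house[i, 2]] <- 0L
    if (!is_forced(q, q$target)) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("invalid generator inputs are rejected", {
  expect_error(generate_puzzle("row", 1, 1, 5, 5, c(1, 2, 3)), "distinct|!=")
  expect_error(generate_puzzle("row", 1, 1, 5, 6, c(5, 2, 3)), "disjoint")
})

test_that("feedback reports follow the per-category contracts", {
  batch <- make_puzzle_batch(20, seed = 6)
  for (p in batch) {
    fb_in <- compute_feedback(p, p$in_house[1])
    expect_equal(fb_in$category, "in_house")
    expect_length(fb_in$contradiction_cell, 2)
    expect_equal(p$grid[fb_in$contradiction_cell[1], fb_in$contradiction_cell[2]],
                 p$in_house[1])

    fb_t <- compute_feedback(p, p$target)
    expect_equal(fb_t$category, "target")
    expect_equal(nrow(fb_t$eliminated_cells), 8)
    expect_true(all(fb_t$eliminated_cells$reason %in%
                      c("filled", "box_constrained", "line_constrained")))
    expect_equal(sum(fb_t$eliminated_cells$reason == "filled"), 3)
    # the 3 box-constraint-box cells are always box-eliminated; the two
    # line-covered cells may incidentally be box-covered too
    expect_gte(sum(fb_t$eliminated_cells$reason == "box_constrained"), 3)

    fb_d <- compute_feedback(p, p$distractor)
    expect_gte(nrow(fb_d$open_cells), 1)
    dl <- which(p$grid == p$distractor, arr.ind = TRUE)
    for (i in seq_len(nrow(fb_d$open_cells))) {
      expect_false(any(hiddensingle:::is_peer(
        fb_d$open_cells[i, 1], fb_d$open_cells[i, 2], dl[, 1], dl[, 2])))
    }

    fb_a <- compute_feedback(p, p$absent[1])
    expect_equal(fb_a$category, "absent")
    expect_gte(nrow(fb_a$open_cells), 1)
    expect_true(all(fb_a$eliminated_cells$reason == "filled"))
  }
  expect_error(compute_feedback(batch[[1]], 10), "digit")
})
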