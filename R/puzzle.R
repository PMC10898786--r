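# Hidden-single puzzle engine: grid geometry, generation, solving oracle,
# response classification, and explanatory feedback.

#' Grid geometry helpers
#'
#' Coordinates are 1-based `(row, col)`; boxes are the nine 3x3 blocks,
#' indexed 0..8 in row-major order.
#'
#' @param row,col Cell coordinates in 1..9.
#' @return `box_of` returns the box index in 0..8.
#' @export
box_of <- function(row, col) {
  stopifnot(all(row >= 1 & row <= 9), all(col >= 1 & col <= 9))
  3L * ((as.integer(row) - 1L) %/% 3L) + (as.integer(col) - 1L) %/% 3L
}

#' Cells of a house
#'
#' A house is a full row or column. Cells are returned in cell-index
#' order: row houses left to right, column houses top to bottom, so the
#' k-th entry is the cell with cell index k.
#'
#' @param house_type `"row"` or `"column"`.
#' @param house_index House index in 1..9.
#' @return A 9x2 integer matrix with columns `row`, `col`.
#' @export
cells_of_house <- function(house_type = c("row", "column"), house_index) {
  house_type <- match.arg(house_type)
  house_index <- as.integer(house_index)
  if (is.na(house_index) || house_index < 1L || house_index > 9L) {
    stop("house_index must be in 1..9")
  }
  m <- if (house_type == "row") {
    cbind(row = rep(house_index, 9L), col = 1:9)
  } else {
    cbind(row = 1:9, col = rep(house_index, 9L))
  }
  m
}

#' Peers of a cell
#'
#' All cells sharing the cell's row, column, or 3x3 box, excluding the
#' cell itself (20 cells for every position).
#'
#' @param row,col Cell coordinates in 1..9.
#' @return An n x 2 integer matrix of peer coordinates.
#' @export
peers <- function(row, col) {
  stopifnot(row >= 1, row <= 9, col >= 1, col <= 9)
  all_cells <- cbind(row = rep(1:9, each = 9L), col = rep(1:9, 9L))
  b <- box_of(row, col)
  sel <- (all_cells[, 1] == row | all_cells[, 2] == col |
            box_of(all_cells[, 1], all_cells[, 2]) == b) &
    !(all_cells[, 1] == row & all_cells[, 2] == col)
  all_cells[sel, , drop = FALSE]
}

is_peer <- function(r1, c1, r2, c2) {
  (r1 == r2 | c1 == c2 | box_of(r1, c1) == box_of(r2, c2)) &
    !(r1 == r2 & c1 == c2)
}

#' Serialize and parse grids
#'
#' Grids travel as 81-character row-major strings with `.` for empty
#' cells (the standard one-line Sudoku dialect).
#'
#' @param grid A 9x9 integer matrix with 0 for empty cells.
#' @param s An 81-character grid string.
#' @return `grid_to_string` a character scalar; `string_to_grid` a 9x9
#'   integer matrix (0 = empty).
#' @export
grid_to_string <- function(grid) {
  stopifnot(is.matrix(grid), all(dim(grid) == 9))
  ch <- as.character(t(grid))
  ch[ch == "0"] <- "."
  paste(ch, collapse = "")
}

#' @rdname grid_to_string
#' @export
string_to_grid <- function(s) {
  stopifnot(is.character(s), length(s) == 1, nchar(s) == 81)
  ch <- strsplit(s, "")[[1]]
  v <- suppressWarnings(as.integer(ch))
  v[ch == "."] <- 0L
  if (any(is.na(v))) stop("grid string may contain only digits and '.'")
  matrix(v, nrow = 9, byrow = TRUE)
}

#' Check grid legality
#'
#' A grid is legal when no digit occurs twice within any row, column, or
#' box.
#'
#' @param grid 9x9 integer matrix, 0 = empty.
#' @return Logical scalar.
#' @export
grid_is_legal <- function(grid) {
  for (i in 1:9) {
    r <- grid[i, ]; r <- r[r > 0]
    if (anyDuplicated(r)) return(FALSE)
    cc <- grid[, i]; cc <- cc[cc > 0]
    if (anyDuplicated(cc)) return(FALSE)
    br <- 3L * ((i - 1L) %/% 3L) + 1L
    bc <- 3L * ((i - 1L) %% 3L) + 1L
    b <- grid[br:(br + 2L), bc:(bc + 2L)]
    b <- b[b > 0]
    if (anyDuplicated(b)) return(FALSE)
  }
  TRUE
}

new_puzzle <- function(grid, house_type, house_index, cell_index,
                       target, distractor, in_house, box_constraint_box,
                       seed = NA_integer_) {
  goal <- cells_of_house(house_type, house_index)[cell_index, ]
  absent <- setdiff(1:9, c(target, distractor, in_house))
  structure(
    list(
      grid = grid, house_type = house_type,
      house_index = as.integer(house_index),
      cell_index = as.integer(cell_index),
      goal = as.integer(goal),
      target = as.integer(target), distractor = as.integer(distractor),
      in_house = sort(as.integer(in_house)), absent = sort(as.integer(absent)),
      box_constraint_box = as.integer(box_constraint_box),
      seed = as.integer(seed)
    ),
    class = "hs_puzzle"
  )
}

#' @export
print.hs_puzzle <- function(x, ...) {
  cat(sprintf("Hidden-single puzzle: %s %d, cell %d (goal at r%dc%d)\n",
              x$house_type, x$house_index, x$cell_index, x$goal[1], x$goal[2]))
  cat(sprintf("target %d, distractor %d, in-house {%s}, absent {%s}\n",
              x$target, x$distractor,
              paste(x$in_house, collapse = ","),
              paste(x$absent, collapse = ",")))
  g <- x$grid
  for (i in 1:9) {
    line <- ifelse(g[i, ] == 0, ".", as.character(g[i, ]))
    cat(paste(line, collapse = " "), "\n")
  }
  invisible(x)
}

#' Classify a response digit into its role category
#'
#' Every digit 1..9 plays exactly one role per puzzle: the target (forced
#' into the goal cell, 3 instances), the distractor (3 instances, not
#' forced), an in-house digit (one instance inside the target house), or
#' an absent digit (no instances). Over the nine digits the multiplicity
#' of (target, distractor, absent, in-house) is (1, 1, 4, 3).
#'
#' @param puzzle An `hs_puzzle`.
#' @param digit Response digit in 1..9.
#' @return One of `"target"`, `"distractor"`, `"absent"`, `"in_house"`.
#' @export
classify_response <- function(puzzle, digit) {
  digit <- as.integer(digit)
  if (is.na(digit) || digit < 1L || digit > 9L) stop("digit must be in 1..9")
  if (digit == puzzle$target) "target"
  else if (digit == puzzle$distractor) "distractor"
  else if (digit %in% puzzle$in_house) "in_house"
  else "absent"
}

# digits of a puzzle belonging to one category
digits_in_category <- function(puzzle, category) {
  switch(category,
    target = puzzle$target,
    distractor = puzzle$distractor,
    in_house = puzzle$in_house,
    absent = puzzle$absent,
    stop("unknown category: ", category)
  )
}

house_state <- function(puzzle) {
  cells <- cells_of_house(puzzle$house_type, puzzle$house_index)
  vals <- puzzle$grid[cells]
  is_goal <- cells[, 1] == puzzle$goal[1] & cells[, 2] == puzzle$goal[2]
  list(cells = cells, vals = vals, is_goal = is_goal)
}

#' Is a digit forced into the goal cell?
#'
#' Independent peer-elimination oracle: digit `d` is forced into the goal
#' cell when every empty non-goal cell of the target house has a filled
#' peer containing `d` (so `d` can go nowhere else in the house) while
#' the goal cell itself has no peer containing `d`. For every valid
#' puzzle this holds for the target and fails for the distractor.
#'
#' @param puzzle An `hs_puzzle`.
#' @param digit Candidate digit in 1..9.
#' @return Logical scalar (`is_forced`); `forced_digit` returns the
#'   unique forced digit, or `NULL` when none is forced.
#' @export
is_forced <- function(puzzle, digit) {
  digit <- as.integer(digit)
  stopifnot(digit >= 1, digit <= 9)
  if (!grid_is_legal(puzzle$grid)) stop("inconsistent grid")
  hs <- house_state(puzzle)
  locs <- which(puzzle$grid == digit, arr.ind = TRUE)
  goal_sees <- nrow(locs) > 0 &&
    any(is_peer(puzzle$goal[1], puzzle$goal[2], locs[, 1], locs[, 2]))
  if (goal_sees) return(FALSE)
  open <- which(!hs$is_goal & hs$vals == 0L)
  for (k in open) {
    r <- hs$cells[k, 1]; cc <- hs$cells[k, 2]
    covered <- nrow(locs) > 0 && any(is_peer(r, cc, locs[, 1], locs[, 2]))
    if (!covered) return(FALSE)
  }
  TRUE
}

#' @rdname is_forced
#' @export
forced_digit <- function(puzzle) {
  hints <- c(puzzle$target, puzzle$distractor, puzzle$in_house)
  forced <- hints[vapply(hints, function(d) is_forced(puzzle, d), logical(1))]
  if (length(forced) == 0) return(NULL)
  if (length(forced) > 1) stop("multiple forced digits: invalid puzzle")
  as.integer(forced)
}

#' Validate all structural puzzle invariants
#'
#' Checks the full hidden-single contract: 9 filled cells (3 target, 3
#' distractor, 1 of each in-house digit), legality, the empty-cell
#' layout of the target house, role disjointness, the box-constraint
#' structure, a forced target, and an unforced distractor with at least
#' one open cell.
#'
#' @param puzzle An `hs_puzzle`.
#' @return `TRUE` invisibly, or an error describing the violated
#'   invariant.
#' @export
validate_puzzle <- function(puzzle) {
  g <- puzzle$grid
  roles <- c(puzzle$target, puzzle$distractor, puzzle$in_house, puzzle$absent)
  if (length(unique(roles)) != 9) stop("digit roles must partition 1..9")
  if (sum(g > 0) != 9) stop("grid must contain exactly 9 filled cells")
  if (sum(g == puzzle$target) != 3) stop("target must have 3 instances")
  if (sum(g == puzzle$distractor) != 3) stop("distractor must have 3 instances")
  for (d in puzzle$in_house) {
    if (sum(g == d) != 1) stop("each in-house digit must occur exactly once")
  }
  for (d in puzzle$absent) {
    if (any(g == d)) stop("absent digits must not appear")
  }
  if (!grid_is_legal(g)) stop("grid has a duplicate within a house")
  hs <- house_state(puzzle)
  if (g[puzzle$goal[1], puzzle$goal[2]] != 0L) stop("goal cell must be empty")
  inh_vals <- sort(hs$vals[hs$vals > 0])
  if (!identical(inh_vals, as.integer(sort(puzzle$in_house)))) {
    stop("target house must contain exactly the in-house digits")
  }
  # in-house digits appear only inside the house
  for (d in puzzle$in_house) {
    loc <- which(g == d, arr.ind = TRUE)
    on_house <- any(hs$cells[, 1] == loc[1, 1] & hs$cells[, 2] == loc[1, 2])
    if (!on_house) stop("in-house digit found outside the target house")
  }
  open <- which(!hs$is_goal & hs$vals == 0L)
  if (length(open) != 5) stop("target house must have 5 empty non-goal cells")
  bcb <- puzzle$box_constraint_box
  in_bcb <- box_of(hs$cells[open, 1], hs$cells[open, 2]) == bcb
  if (sum(in_bcb) != 3) {
    stop("box-constraint box must contain 3 empty house cells")
  }
  # no target/distractor instance peers the goal
  for (d in c(puzzle$target, puzzle$distractor)) {
    locs <- which(g == d, arr.ind = TRUE)
    if (any(is_peer(puzzle$goal[1], puzzle$goal[2], locs[, 1], locs[, 2]))) {
      stop("target/distractor instance peers the goal cell")
    }
  }
  if (!is_forced(puzzle, puzzle$target)) stop("target is not forced")
  if (is_forced(puzzle, puzzle$distractor)) stop("distractor is forced")
  invisible(TRUE)
}

# --- generation ------------------------------------------------------------

# Generate a row-house puzzle by constructive placement; the column case is
# obtained by transposing. Returns NULL when a sampled configuration is
# infeasible (caller retries).
try_generate_row <- function(house_index, cell_index, target, distractor,
                             in_house) {
  r <- house_index
  gc_col <- cell_index
  band <- function(i) (i - 1L) %/% 3L # 0..2
  row_band <- band(r)
  goal_cb <- band(gc_col)
  bcb_cb <- sample(setdiff(0:2, goal_cb), 1L)
  bcb_cols <- (3L * bcb_cb + 1L):(3L * bcb_cb + 3L)
  other_cols <- setdiff(1:9, c(gc_col, bcb_cols))  # 5 columns
  inh_cols <- sample(other_cols, 3L)
  empty_cols <- setdiff(other_cols, inh_cols)      # e1, e2
  g <- matrix(0L, 9, 9)
  g[r, inh_cols] <- as.integer(sample(in_house))

  box_rows <- (3L * row_band + 1L):(3L * row_band + 3L)
  off_rows <- setdiff(box_rows, r)
  # bcb off-house cells: 2 rows x 3 cols
  bcb_cells <- expand.grid(row = off_rows, col = bcb_cols)
  pick <- sample(nrow(bcb_cells), 2L)
  t0 <- as.integer(bcb_cells[pick[1], ]); d0 <- as.integer(bcb_cells[pick[2], ])
  g[t0[1], t0[2]] <- target
  g[d0[1], d0[2]] <- distractor

  goal_box <- box_of(r, gc_col)
  placed_t <- list(t0)
  # one target instance on the perpendicular line (column) through each
  # non-box empty house cell
  for (ec in sample(empty_cols)) {
    used_rows <- vapply(placed_t, `[`, integer(1), 1L)
    used_boxes <- vapply(placed_t, function(p) box_of(p[1], p[2]), integer(1))
    cand <- setdiff(1:9, c(r, used_rows))
    cand <- cand[g[cand, ec] == 0L]
    cand <- cand[box_of(cand, ec) != goal_box]
    cand <- cand[!(box_of(cand, ec) %in% used_boxes)]
    if (length(cand) == 0) return(NULL)
    x <- cand[sample.int(length(cand), 1L)]
    g[x, ec] <- target
    placed_t <- c(placed_t, list(c(x, ec)))
  }

  # distractor covers exactly one of the two empty house cells
  cover_col <- sample(empty_cols, 1L)
  open_col <- setdiff(empty_cols, cover_col)
  cand <- setdiff(1:9, c(r, d0[1]))
  cand <- cand[g[cand, cover_col] == 0L]
  cand <- cand[box_of(cand, cover_col) != goal_box]
  cand <- cand[box_of(cand, cover_col) != box_of(d0[1], d0[2])]
  # must not also cover the open cell through a shared box
  cand <- cand[!(box_of(cand, cover_col) == box_of(r, open_col))]
  if (length(cand) == 0) return(NULL)
  x1 <- cand[sample.int(length(cand), 1L)]
  g[x1, cover_col] <- distractor
  d1 <- c(x1, cover_col)

  # last distractor instance: legal, peer of neither goal nor open cell
  cells <- which(g == 0L, arr.ind = TRUE)
  ok <- cells[, 1] != r &
    !is_peer(cells[, 1], cells[, 2], r, gc_col) &
    !is_peer(cells[, 1], cells[, 2], r, open_col) &
    !(cells[, 1] %in% c(d0[1], d1[1])) &
    !(cells[, 2] %in% c(d0[2], d1[2])) &
    !(box_of(cells[, 1], cells[, 2]) %in%
        c(box_of(d0[1], d0[2]), box_of(d1[1], d1[2])))
  cells <- cells[ok, , drop = FALSE]
  if (nrow(cells) == 0) return(NULL)
  k <- sample.int(nrow(cells), 1L)
  g[cells[k, 1], cells[k, 2]] <- distractor

  if (!grid_is_legal(g)) return(NULL)
  list(grid = g, bcb = box_of(r, bcb_cols[1]))
}

transpose_box <- function(b) 3L * (b %% 3L) + b %/% 3L

#' Generate a hidden-single puzzle
#'
#' Constructive placement with rejection sampling. The box-constraint box
#' is chosen uniformly from the two house-intersecting boxes not
#' containing the goal; its three house cells stay empty and single
#' target and distractor instances inside the box eliminate them. Three
#' of the remaining five non-goal house cells receive the in-house
#' digits. The two other target instances sit on the perpendicular lines
#' through the two remaining empty house cells; the distractor covers
#' exactly one of them, leaving at least one open cell so only the
#' target is forced. Infeasible draws are rejected and resampled.
#'
#' @param house_type `"row"` or `"column"`.
#' @param house_index,cell_index Indices in 1..9.
#' @param target,distractor Distinct digits in 1..9.
#' @param in_house Three digits disjoint from target and distractor.
#' @param seed Optional integer seed for reproducible generation.
#' @param max_tries Rejection-sampling bound.
#' @return An `hs_puzzle` satisfying [validate_puzzle()].
#' @export
#' @examples
#' p <- generate_puzzle("column", 7, 8, target = 1, distractor = 7,
#'                      in_house = c(2, 3, 5), seed = 42)
#' classify_response(p, 1)
generate_puzzle <- function(house_type = c("row", "column"), house_index,
                            cell_index, target, distractor, in_house,
                            seed = NULL, max_tries = 1000L) {
  house_type <- match.arg(house_type)
  target <- as.integer(target); distractor <- as.integer(distractor)
  in_house <- as.integer(in_house)
  stopifnot(target %in% 1:9, distractor %in% 1:9, target != distractor,
            length(in_house) == 3, all(in_house %in% 1:9))
  if (any(in_house %in% c(target, distractor)) || anyDuplicated(in_house)) {
    stop("in_house must be 3 distinct digits disjoint from target/distractor")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (i in seq_len(max_tries)) {
    res <- try_generate_row(as.integer(house_index), as.integer(cell_index),
                            target, distractor, in_house)
    if (!is.null(res)) {
      grid <- res$grid
      bcb <- res$bcb
      if (house_type == "column") {
        grid <- t(grid)
        bcb <- transpose_box(bcb)
      }
      pz <- new_puzzle(grid, house_type, house_index, cell_index, target,
                       distractor, in_house, bcb,
                       seed = if (is.null(seed)) NA_integer_ else seed)
      validate_puzzle(pz)
      return(pz)
    }
  }
  stop(sprintf(
    "puzzle generation failed after %d attempts (house %s %d, cell %d, target %d, distractor %d)",
    max_tries, house_type, house_index, cell_index, target, distractor))
}

#' Explanatory feedback for a practice-phase response
#'
#' Reconstructs the puzzle-specific explanation for each response type:
#' an in-house response points at the house cell already holding the
#' digit (the contradiction); an absent response shows the filled house
#' cells and the open cells where the digit could still go; a distractor
#' response shows the open cell(s) not seeing any distractor instance;
#' a target response gives, for each of the 8 non-goal house cells, the
#' reason it cannot hold the target (`filled`, `box_constrained`, or
#' `line_constrained`).
#'
#' @param puzzle An `hs_puzzle`.
#' @param response Response digit in 1..9.
#' @return A list of class `hs_feedback` with elements `category`,
#'   `contradiction_cell` (in-house only), `open_cells`, and
#'   `eliminated_cells` (data frame of cell + reason).
#' @export
compute_feedback <- function(puzzle, response) {
  response <- as.integer(response)
  if (is.na(response) || response < 1L || response > 9L) {
    stop("response must be a digit in 1..9")
  }
  category <- classify_response(puzzle, response)
  hs <- house_state(puzzle)
  non_goal <- which(!hs$is_goal)
  filled <- non_goal[hs$vals[non_goal] > 0L]
  empties <- non_goal[hs$vals[non_goal] == 0L]
  locs <- which(puzzle$grid == response, arr.ind = TRUE)
  sees_digit <- function(k) {
    nrow(locs) > 0 &&
      any(is_peer(hs$cells[k, 1], hs$cells[k, 2], locs[, 1], locs[, 2]))
  }
  out <- list(category = category, contradiction_cell = NULL,
              open_cells = NULL, eliminated_cells = NULL)
  if (category == "in_house") {
    k <- which(hs$vals == response)
    out$contradiction_cell <- hs$cells[k, , drop = TRUE]
  } else if (category %in% c("absent", "distractor")) {
    open <- empties[!vapply(empties, sees_digit, logical(1))]
    out$open_cells <- hs$cells[open, , drop = FALSE]
    out$eliminated_cells <- data.frame(
      row = hs$cells[filled, 1], col = hs$cells[filled, 2],
      reason = "filled", stringsAsFactors = FALSE
    )
  } else { # target: a reason for each of the 8 non-goal house cells
    reason <- character(length(non_goal))
    for (i in seq_along(non_goal)) {
      k <- non_goal[i]
      if (hs$vals[k] > 0L) {
        reason[i] <- "filled"
      } else {
        same_box <- any(box_of(locs[, 1], locs[, 2]) ==
                          box_of(hs$cells[k, 1], hs$cells[k, 2]))
        reason[i] <- if (same_box) "box_constrained" else "line_constrained"
      }
    }
    out$eliminated_cells <- data.frame(
      row = hs$cells[non_goal, 1], col = hs$cells[non_goal, 2],
      reason = reason, stringsAsFactors = FALSE
    )
  }
  structure(out, class = "hs_feedback")
}
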