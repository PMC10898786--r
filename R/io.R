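# Shared readers/writers for the pipeline's CSV and JSON dialects.

#' Read and write response tables
#'
#' Responses CSV dialect: header row with `participant_id`, `trial`,
#' `category`, `digit`, `correct`. Categories are validated against
#' [hs_categories()] and duplicate (participant, trial) keys are
#' rejected.
#'
#' @param path File path.
#' @param responses Data frame in the responses dialect.
#' @return `read_responses` returns the validated data frame;
#'   `write_responses` returns `path` invisibly.
#' @export
read_responses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "trial", "category")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("responses file missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(df)
  bad <- which(!df$category %in% hs_categories())
  if (length(bad) > 0) {
    stop(sprintf("invalid category '%s' in row %d", df$category[bad[1]], bad[1]))
  }
  key <- paste(df$participant_id, df$trial)
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, trial) key: ", key[anyDuplicated(key)])
  }
  if (!"correct" %in% names(df)) df$correct <- df$category == "target"
  df$correct <- as.logical(df$correct)
  df
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' Read and write aggregate parameter files
#'
#' Parameter JSON schema: `a` (length 4), `X` and `W` (4x4), plus the
#' fixed `strategy_order` and `category_order` for self-description.
#' Structural zeros are verified and rows renormalized (tolerance
#' [0.999, 1.001]) on load.
#'
#' @param path File path.
#' @param params An [hs_params] object.
#' @return `read_params` returns an [hs_params]; `write_params` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("a", "X", "W")) {
    if (is.null(obj[[f]])) stop("parameter file missing field: ", f)
  }
  hs_params(obj$a, as.matrix(obj$X), as.matrix(obj$W))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "hs_params"))
  jsonlite::write_json(
    list(a = unname(params$a),
         X = unname(params$X), W = unname(params$W),
         strategy_order = hs_strategies(),
         category_order = hs_categories()),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Write a puzzle batch as JSON
#'
#' One record per puzzle: 81-character grid string, feature fields, and
#' digit roles.
#'
#' @param puzzles List of `hs_puzzle` objects.
#' @param path Output path.
#' @export
write_puzzles <- function(puzzles, path) {
  recs <- lapply(puzzles, function(p) {
    list(grid = grid_to_string(p$grid), house_type = p$house_type,
         house_index = p$house_index, cell_index = p$cell_index,
         target = p$target, distractor = p$distractor,
         in_house = p$in_house, absent = p$absent,
         box_constraint_box = p$box_constraint_box,
         seed = if (is.na(p$seed)) NULL else p$seed)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI run records its command, arguments, seed, and outputs so a
#' rerun with the same manifest inputs reproduces the same outputs.
#'
#' @param command Subcommand name.
#' @param args Named list of parsed arguments.
#' @param outputs Character vector of written paths.
#' @param path Manifest path.
#' @export
write_manifest <- function(command, args, outputs, path) {
  jsonlite::write_json(
    list(command = command, args = args, outputs = outputs,
         package_version = as.character(utils::packageVersion("hiddensingle")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
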