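# Shared fixtures: all synthetic, built in code.

# a small batch of generated puzzles spanning both house types
make_puzzle_batch <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    td <- sample(1:9, 2)
    inh <- sample(setdiff(1:9, td), 3)
    generate_puzzle(sample(c("row", "column"), 1), sample(9, 1), sample(9, 1),
                    target = td[1], distractor = td[2], in_house = inh)
  })
}

# practice records data frame for the classifier
make_practice_records <- function(correct_by_participant) {
  do.call(rbind, lapply(names(correct_by_participant), function(id) {
    v <- correct_by_participant[[id]]
    data.frame(participant_id = id, trial = seq_along(v), correct = v,
               stringsAsFactors = FALSE)
  }))
}

# simulate practice correctness for n participants under params
simulate_practice_correct <- function(params, n, T_len = 25, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    resp <- sample_responses(params, sample_path(params, T_len))
    data.frame(participant_id = sprintf("p%03d", i), trial = resp$trial,
               correct = resp$correct, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# a minimal synthetic test-phase table with known effects
make_test_records <- function(n_participants, config, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(n_participants), function(i) {
    f <- assign_training_features()
    d <- build_test_design(f)
    r <- sample_test_records(config, d, solver = TRUE)
    cbind(participant_id = sprintf("p%03d", i), r, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
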