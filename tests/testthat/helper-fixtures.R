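# Small builders shared across test files. Everything is generated in code;
# no fixture files.

tiny_games <- function() {
  tibble::tibble(
    player_id = rep(c("a", "b"), c(3, 4)),
    format = "ODI", discipline = "batting",
    order = c(1, 2, 3, 2, 1, 3, 4),
    score = c(10, 0, 42, 7, 30, 12, 55)
  )
}

careers_of_lengths <- function(lengths, seed = 99) {
  purrr::map2_dfr(lengths, seq_along(lengths), function(len, i) {
    synthesize_career(len, "null_iid", seed = seed + i,
                      player_id = sprintf("p%02d", i))
  })
}

# A cohort whose three best scores are planted inside a window of `spread`
# consecutive games at a random location: explicit ground-truth co-location
# for the top-three clustering detector.
planted_cohort <- function(n_careers, career_length = 100, spread = 3,
                           seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_careers), function(i) {
      sc <- rgeom(career_length, 1 / 26)
      sc <- pmin(sc, 150) # keep planted values strictly on top
      start <- sample.int(career_length - spread + 1, 1)
      sc[start:(start + spread - 1)] <- c(200, 180, 190)
      tibble::tibble(
        player_id = sprintf("plant%03d", i), format = "synthetic",
        discipline = "batting", scores = list(as.integer(sc)),
        career_length = career_length
      )
    })
  })
}
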