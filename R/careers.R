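#' Build a career table from per-game records
#'
#' A *career table* is the package's central container: one row per
#' (player, format, discipline) career, with the ordered score sequence held
#' in a list-column. Scores are indexed by the rank of the game within the
#' career (calendar order), not by date.
#'
#' @param games A data frame with one row per player-game.
#' @param schema Named character vector mapping the required roles
#'   (`player_id`, `format`, `discipline`, `order`, `score`) to column names
#'   in `games`. Any role missing from `schema` keeps its default name.
#'
#' @return A tibble with columns `player_id`, `format`, `discipline`,
#'   `scores` (list of integer vectors ordered by the order index) and
#'   `career_length`.
#' @export
#' @examples
#' games <- tibble::tibble(
#'   player_id = "p1", format = "ODI", discipline = "batting",
#'   order = c(2, 1, 3), score = c(0, 10, 42)
#' )
#' career_table(games)
career_table <- function(games, schema = default_schema()) {
  schema <- utils::modifyList(as.list(default_schema()), as.list(schema))
  required <- c("player_id", "format", "discipline", "order", "score")
  missing_cols <- setdiff(unlist(schema[required]), names(games))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Input is missing required column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df <- tibble::tibble(
    player_id = as.character(games[[schema$player_id]]),
    format = as.character(games[[schema$format]]),
    discipline = as.character(games[[schema$discipline]]),
    order = as.numeric(games[[schema$order]]),
    score = games[[schema$score]],
    row = seq_len(nrow(games))
  )
  bad <- which(is.na(df$score) | df$score < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Negative or missing score in row(s): %s.",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  if (nrow(df) == 0) {
    warn("No game rows found; returning an empty career table.")
  }
  df |>
    dplyr::arrange(.data$player_id, .data$format, .data$discipline, .data$order) |>
    dplyr::group_by(.data$player_id, .data$format, .data$discipline) |>
    dplyr::summarise(
      scores = list(as.integer(.data$score)),
      career_length = dplyr::n(),
      .groups = "drop"
    )
}

#' Default column schema for career files
#'
#' @return Named character vector mapping roles to column names.
#' @export
default_schema <- function() {
  c(player_id = "player_id", format = "format", discipline = "discipline",
    order = "order", score = "score")
}

#' Read careers from a delimited text file
#'
#' @param path Path to a delimited file with a header row.
#' @param schema Column mapping, see [career_table()].
#' @param delim Field delimiter (default comma).
#' @return A career table, see [career_table()].
#' @export
load_careers <- function(path, schema = default_schema(), delim = ",") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  games <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE
  )
  career_table(games, schema = schema)
}

#' Write a career table to a delimited text file
#'
#' Inverse of [load_careers()]: emits one row per player-game using the
#' default schema, so a written file reloads to an identical career table.
#'
#' @param careers A career table.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_careers <- function(careers, path, delim = ",") {
  long <- careers |>
    dplyr::mutate(order = purrr::map(.data$scores, seq_along)) |>
    tidyr::unnest(c("scores", "order")) |>
    dplyr::transmute(
      player_id = .data$player_id, format = .data$format,
      discipline = .data$discipline, order = .data$order,
      score = .data$scores
    )
  readr::write_delim(long, path, delim = delim)
  invisible(path)
}

#' Keep only careers with at least a minimum number of games
#'
#' The analysis population is restricted to careers long enough for a stable
#' point-process fit; the default threshold of 30 games matches the filter
#' used throughout the pipeline.
#'
#' @param careers A career table.
#' @param min_games Minimum career length (inclusive).
#' @return The filtered career table.
#' @export
filter_min_games <- function(careers, min_games = 30) {
  stopifnot(min_games >= 1)
  kept <- dplyr::filter(careers, .data$career_length >= min_games)
  message(sprintf(
    "filter_min_games: retained %d of %d careers (min_games = %d).",
    nrow(kept), nrow(careers), min_games
  ))
  kept
}

#' Aggregate a match table into per-team performance series
#'
#' Team performance in a game is the sum of that game's individual scores.
#' Outcomes must be consistent within a (team, game) group and are carried
#' through; anything that is not a win or a loss maps to `"other"`.
#'
#' @param matches Data frame with columns `team`, `order` (game index),
#'   `score` (individual score) and `outcome`.
#' @return A tibble with one row per team: `team_id`, `performances`
#'   (list of numeric vectors) and `outcomes` (list of character vectors).
#' @export
team_performance_series <- function(matches) {
  stopifnot(all(c("team", "order", "score", "outcome") %in% names(matches)))
  norm_outcome <- function(x) {
    x <- tolower(as.character(x))
    x[!x %in% c("win", "loss")] <- "other"
    x
  }
  per_game <- matches |>
    dplyr::mutate(outcome = norm_outcome(.data$outcome)) |>
    dplyr::group_by(.data$team, .data$order) |>
    dplyr::summarise(
      performance = sum(.data$score),
      n_outcomes = dplyr::n_distinct(.data$outcome),
      outcome = dplyr::first(.data$outcome),
      .groups = "drop"
    )
  if (any(per_game$n_outcomes > 1)) {
    bad <- per_game[per_game$n_outcomes > 1, c("team", "order")]
    abort(sprintf(
      "Conflicting outcomes within team-game group(s): %s.",
      paste(sprintf("%s/%s", bad$team, bad$order), collapse = ", ")
    ))
  }
  per_game |>
    dplyr::arrange(.data$team, .data$order) |>
    dplyr::group_by(team_id = .data$team) |>
    dplyr::summarise(
      performances = list(.data$performance),
      outcomes = list(.data$outcome),
      .groups = "drop"
    )
}
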