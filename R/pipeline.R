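#' Default pipeline configuration
#'
#' The tunable constants of the full analysis in one place: the minimum
#' career length (30 games), the chronological split fraction (0.8), the
#' shuffle-control count (100), the streak null-ensemble size (1000), the
#' zero-score floor, the EM settings and the significance level.
#'
#' @param ... Named overrides of any default.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_games = 30, train_fraction = 0.8, n_controls = 100,
    n_streak_shuffles = 1000, s_min = 0.5, alpha = 0.05,
    correction = "holm", em = list(n_bins = 8, tol = 1e-6, max_iter = 500),
    seed = 1
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full hot-hand pipeline on a cohort
#'
#' End-to-end orchestration: filter careers by minimum length, evaluate
#' each against shuffle controls ([evaluate_career()]), summarise the
#' cohort ([cohort_summary()]), and — when team outcome series are supplied
#' — run the winning-streak analysis ([streak_significance()]) per team
#' with cohort-level binomial meta-probabilities. When `out_dir` is given,
#' per-career and per-streak CSVs and a JSON summary (embedding the full
#' configuration and seed for provenance) are written there.
#'
#' @param careers A career table, or a path readable by [load_careers()].
#'   `config` may likewise be a path to a YAML file of overrides for
#'   [pipeline_config()].
#' @param teams Optional tibble from [team_performance_series()] (needs an
#'   `outcomes` list-column).
#' @param config A [pipeline_config()] list.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list with `results` (per-career tibble), `summary_loglik`,
#'   `summary_branching`, optional `streaks` and `streak_summary`, and the
#'   `config` echo.
#' @export
run_hothand_pipeline <- function(careers, teams = NULL,
                                 config = pipeline_config(),
                                 out_dir = NULL) {
  if (is.character(careers)) careers <- load_careers(careers)
  if (is.character(config)) {
    rlang::check_installed("yaml")
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  kept <- filter_min_games(careers, config$min_games)
  bundle <- list(config = config)

  if (nrow(kept) == 0) {
    warn("No careers pass the minimum-games filter; returning empty results.")
    bundle$results <- tibble::tibble()
  } else {
    bundle$results <- evaluate_cohort(
      kept, seed = config$seed, train_fraction = config$train_fraction,
      n_controls = config$n_controls, s_min = config$s_min,
      em_args = config$em
    )
    bundle$summary_loglik <-
      cohort_summary(bundle$results, config$alpha, "loglik")
    bundle$summary_branching <-
      cohort_summary(bundle$results, config$alpha, "branching")
  }

  if (!is.null(teams)) {
    bundle$streaks <- purrr::map2_dfr(
      teams$outcomes, teams$team_id,
      function(oc, id) {
        sig <- streak_significance(
          oc, n_shuffles = config$n_streak_shuffles, alpha = config$alpha,
          headline = config$correction,
          seed = substream_seed(config$seed, paste("streak", id))
        )
        if (nrow(sig) > 0) sig$team_id <- id
        sig
      }
    )
    n_str <- nrow(bundle$streaks)
    if (n_str > 0) {
      k_extreme <- sum(bundle$streaks$label == "extreme")
      bundle$streak_summary <- tibble::tibble(
        n_streaks = n_str, k_extreme = k_extreme,
        p_meta_exact = binomial_meta(k_extreme, n_str, config$alpha, "exactly"),
        p_meta_more = binomial_meta(k_extreme, n_str, config$alpha, "more_than")
      )
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(bundle$results) && nrow(bundle$results) > 0) {
      readr::write_csv(bundle$results, file.path(out_dir, "career_results.csv"))
    }
    if (!is.null(bundle$streaks) && nrow(bundle$streaks) > 0) {
      readr::write_csv(bundle$streaks, file.path(out_dir, "streak_results.csv"))
    }
    summary_json <- list(
      config = config,
      summary_loglik = bundle$summary_loglik,
      summary_branching = bundle$summary_branching,
      streak_summary = bundle$streak_summary
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(bundle)
}
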