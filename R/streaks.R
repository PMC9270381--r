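#' Extract winning streaks from an outcome sequence
#'
#' A winning streak is a maximal run of consecutive wins; anything that is
#' not a win (loss, draw, tie, no-result) terminates it.
#'
#' @param outcomes Character vector over `"win"`, `"loss"`, `"other"`.
#' @return A tibble with columns `length` (streak length `n`) and `freq`
#'   (number of maximal streaks of exactly that length), sorted by length.
#'   Zero rows if there are no wins.
#' @export
#' @examples
#' extract_streaks(c("win", "win", "loss", "win", "win", "win", "loss"))
extract_streaks <- function(outcomes) {
  r <- rle(outcomes == "win")
  lens <- r$lengths[r$values]
  if (length(lens) == 0) {
    return(tibble::tibble(length = integer(0), freq = integer(0)))
  }
  tb <- table(lens)
  tibble::tibble(length = as.integer(names(tb)), freq = as.integer(tb)) |>
    dplyr::arrange(.data$length)
}

#' Null ensemble of streak patterns from outcome shuffles
#'
#' Generates `n_shuffles` uniformly random permutations of the outcome
#' sequence (win count preserved, order destroyed) and records the maximal
#' win-run lengths of each.
#'
#' @param outcomes Character outcome sequence.
#' @param n_shuffles Ensemble size (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `streak_ensemble`: a list of integer vectors,
#'   one per null trajectory, each holding that trajectory's maximal streak
#'   lengths.
#' @export
null_streak_ensemble <- function(outcomes, n_shuffles = 1000, seed = NULL) {
  stopifnot(n_shuffles >= 1)
  n <- length(outcomes)
  runs <- with_seed_if(seed, {
    lapply(seq_len(n_shuffles), function(k) {
      r <- rle(outcomes[sample.int(n)] == "win")
      as.integer(r$lengths[r$values])
    })
  })
  structure(runs, class = "streak_ensemble")
}

#' Permutation p-values for observed streaks
#'
#' For each observed (length `n`, frequency `f`) pair: `p_n` is the fraction
#' of null trajectories whose longest streak is at least `n`; `p_nf` is the
#' fraction containing at least `f` streaks of length at least `n`. Both
#' use the add-one Monte-Carlo correction `(count + 1) / (M + 1)` so no
#' p-value is exactly zero.
#'
#' @param observed Streak table from [extract_streaks()].
#' @param ensemble A [null_streak_ensemble()].
#' @return `observed` with columns `p_n` and `p_nf` appended.
#' @export
streak_pvalues <- function(observed, ensemble) {
  if (length(ensemble) == 0) abort("`ensemble` must be non-empty.")
  M <- length(ensemble)
  maxes <- vapply(ensemble, function(r) if (length(r)) max(r) else 0L, integer(1))
  observed$p_n <- vapply(observed$length, function(n) {
    (sum(maxes >= n) + 1) / (M + 1)
  }, numeric(1))
  observed$p_nf <- purrr::map2_dbl(observed$length, observed$freq, function(n, f) {
    hits <- sum(vapply(ensemble, function(r) sum(r >= n) >= f, logical(1)))
    (hits + 1) / (M + 1)
  })
  observed
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] accepting the five supported
#' method names.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @param method One of `"bonferroni"`, `"holm"`, `"hochberg"`,
#'   `"benjamini_hochberg"`, `"benjamini_yekutieli"`.
#' @return Adjusted p-values, clipped to 1.
#' @export
adjust_pvalues <- function(p, method = "holm") {
  lookup <- c(bonferroni = "bonferroni", holm = "holm", hochberg = "hochberg",
              benjamini_hochberg = "BH", benjamini_yekutieli = "BY")
  if (!method %in% names(lookup)) {
    abort(sprintf("Unknown correction method: %s.", method))
  }
  p.adjust(p, method = lookup[[method]])
}

#' Label streaks as probable or extreme after multiple-testing correction
#'
#' Applies all five correction methods to the `p_n` and `p_nf` families
#' (each family adjusted across the rows of `sig`) and labels a streak
#' `"extreme"` when, under the headline method, either adjusted p-value
#' falls below `alpha`; otherwise `"probable"`.
#'
#' @param sig Output of [streak_pvalues()].
#' @param alpha Significance level (default 0.05).
#' @param headline Correction method deciding the label (default
#'   `"holm"`).
#' @return `sig` with adjusted columns (`p_n_<method>`, `p_nf_<method>`)
#'   and a `label` column appended.
#' @export
flag_extreme <- function(sig, alpha = 0.05, headline = "holm") {
  methods <- c("bonferroni", "holm", "hochberg", "benjamini_hochberg",
               "benjamini_yekutieli")
  if (!headline %in% methods) abort("`headline` must be one of the five methods.")
  for (m in methods) {
    sig[[paste0("p_n_", m)]] <- adjust_pvalues(sig$p_n, m)
    sig[[paste0("p_nf_", m)]] <- adjust_pvalues(sig$p_nf, m)
  }
  sig$label <- ifelse(
    sig[[paste0("p_n_", headline)]] < alpha |
      sig[[paste0("p_nf_", headline)]] < alpha,
    "extreme", "probable"
  )
  sig
}

#' Full winning-streak significance analysis for one outcome sequence
#'
#' Convenience pipeline: extract streaks, build the shuffle-null ensemble,
#' compute permutation p-values, and label streaks after correction.
#'
#' @param outcomes Character outcome sequence.
#' @param n_shuffles Null ensemble size (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param headline Correction method for the label (default `"holm"`).
#' @param seed Optional integer seed.
#' @return A tibble: one row per observed (length, frequency) pair with raw
#'   and adjusted p-values and the `label`.
#' @export
streak_significance <- function(outcomes, n_shuffles = 1000, alpha = 0.05,
                                headline = "holm", seed = NULL) {
  observed <- extract_streaks(outcomes)
  if (nrow(observed) == 0) {
    return(dplyr::mutate(observed, p_n = numeric(0), p_nf = numeric(0),
                         label = character(0)))
  }
  ens <- null_streak_ensemble(outcomes, n_shuffles = n_shuffles, seed = seed)
  flag_extreme(streak_pvalues(observed, ens), alpha = alpha,
               headline = headline)
}
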