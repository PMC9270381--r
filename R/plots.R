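#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_hline geom_histogram geom_tile labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot the estimated excitation kernel of a Hawkes fit
#'
#' Bars show the histogram kernel phi over lag; the dashed line is the
#' background intensity mu for scale.
#'
#' @param object A `hawkes_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hawkes_fit <- function(object, ...) {
  df <- tidy.hawkes_fit(object)
  df <- df[df$term != "mu", ]
  ggplot(df, aes(x = (.data$lag_start + .data$lag_end) / 2,
                 y = .data$estimate,
                 width = .data$lag_end - .data$lag_start)) +
    geom_col(fill = "steelblue", alpha = 0.8) +
    geom_hline(yintercept = object$mu, linetype = "dashed") +
    labs(
      x = "lag (performance time)", y = expression(varphi(lag)),
      title = sprintf("Excitation kernel (n = %.2f, mu = %.2f)",
                      object$branching, object$mu)
    ) +
    theme_minimal()
}

#' Plot the real-vs-shuffled ratio of top-three co-location statistics
#'
#' One panel per difference kind; the horizontal line at 1 is the
#' no-clustering reference. A peak above 1 near 0 indicates that the best
#' performances cluster in career time.
#'
#' @param object A `delta_distributions` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.delta_distributions <- function(object, ...) {
  ggplot(object$ratio, aes(x = .data$bin_mid, y = .data$R)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_line(na.rm = TRUE) +
    geom_point(size = 0.8, na.rm = TRUE) +
    facet_wrap(~kind) +
    labs(x = expression(Delta * t), y = expression(R(Delta * t)),
         title = "Co-location of top-three performances vs shuffled nulls") +
    theme_minimal()
}

#' Plot a cohort's hot-hand evaluation results
#'
#' Histogram of the relative validation-score differences delta across
#' careers; mass to the right of 0 on the model-beats-control side
#' indicates predictive advantage of the self-exciting fit. Note delta
#' shares the sign of the (negative) control log-likelihood denominator.
#'
#' @param results Tibble from [evaluate_cohort()].
#' @return A ggplot object.
#' @export
plot_delta_hist <- function(results) {
  df <- results[is.finite(results$delta), ]
  ggplot(df, aes(x = .data$delta, fill = .data$model_beats_control)) +
    geom_histogram(bins = 30, colour = "white") +
    labs(x = expression(delta), y = "careers",
         fill = "model beats control",
         title = "Relative out-of-sample log-likelihood differences") +
    theme_minimal()
}

#' Plot observed streaks against the shuffle-null ensemble
#'
#' Tiles show the null joint frequency of (streak length, frequency)
#' patterns; points mark the observed streaks, coloured by label.
#'
#' @param sig Labelled streak table from [streak_significance()].
#' @param ensemble The matching [null_streak_ensemble()].
#' @return A ggplot object.
#' @export
plot_streak_null <- function(sig, ensemble) {
  null_df <- purrr::map_dfr(ensemble, function(r) {
    if (length(r) == 0) return(NULL)
    tb <- table(r)
    tibble::tibble(length = as.integer(names(tb)), freq = as.integer(tb))
  }) |>
    dplyr::count(.data$length, .data$freq, name = "n_null")
  ggplot(null_df, aes(x = .data$length, y = .data$freq)) +
    geom_tile(aes(fill = .data$n_null)) +
    geom_point(data = sig, aes(colour = .data$label), size = 3) +
    labs(x = "streak length n", y = "frequency f", fill = "null count",
         colour = NULL, title = "Winning streaks vs shuffle-null ensemble") +
    theme_minimal()
}
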