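#' Indices of the three best performances in a career
#'
#' Ranks are by score, ties broken by the earlier game index at each rank
#' (a deterministic, order-stable policy).
#'
#' @param scores Numeric score sequence (length at least 3).
#' @return A one-row tibble: `t1`, `t2`, `t3` (game indices of the best,
#'   second-best and third-best score) and `tau` (career length).
#' @export
#' @examples
#' top_three_indices(c(3, 50, 20, 70, 10, 60)) # t1 = 4, t2 = 6, t3 = 2
top_three_indices <- function(scores) {
  assert_scores(scores)
  tau <- length(scores)
  if (tau < 3) abort("At least 3 games are required to rank the top three.")
  ord <- order(-scores, seq_len(tau)) # earliest-first at equal scores
  tibble::tibble(t1 = ord[1], t2 = ord[2], t3 = ord[3], tau = tau)
}

#' Relative index differences of the top three performances
#'
#' For top-three indices t1 (best), t2, t3 in a career of length tau,
#' computes d12 = (t1 - t2) / tau, d13 = (t1 - t3) / tau and
#' d23 = (t2 - t3) / tau. The telescoping identity d12 + d23 = d13 holds
#' exactly. Values near 0 mean the best performances fell close together in
#' the career.
#'
#' @param idx A one-row tibble from [top_three_indices()] (or any data frame
#'   with columns `t1`, `t2`, `t3`, `tau`).
#' @return A tibble with columns `d12`, `d13`, `d23`, each in `[-1, 1]`.
#' @export
delta_stats <- function(idx) {
  tibble::tibble(
    d12 = (idx$t1 - idx$t2) / idx$tau,
    d13 = (idx$t1 - idx$t3) / idx$tau,
    d23 = (idx$t2 - idx$t3) / idx$tau
  )
}

#' Shuffle the order of a score sequence
#'
#' Uniformly random permutation of the games within one career: the score
#' multiset is preserved while all temporal structure is destroyed. This is
#' the null operation behind every shuffle control in the package.
#'
#' @param scores Numeric score sequence.
#' @param seed Optional integer seed.
#' @return Permuted score sequence.
#' @export
shuffle_career <- function(scores, seed = NULL) {
  if (length(scores) <= 1) return(scores)
  with_seed_if(seed, scores[sample.int(length(scores))])
}

#' Distributions of top-three co-location statistics versus shuffled nulls
#'
#' For every eligible career (length at least 3) computes the relative
#' index differences of the three best scores, then recomputes them on
#' `n_shuffles_per_career` shuffled copies. Returns the marginal histograms
#' P (real) and P' (shuffled) of each difference kind, their binwise ratio
#' R = P / P' (with additive smoothing `1 / total shuffled count`; bins with
#' no shuffled mass are `NA` rather than infinite), and the joint 2D
#' histograms Q(d12, d13) for real and shuffled careers. A ratio peak above
#' 1 near 0 is the signature of temporally clustered best performances.
#'
#' @param careers A career table (see [career_table()]).
#' @param n_shuffles_per_career Shuffled copies per career (default 10).
#' @param bin_width Histogram bin width on `[-1, 1]` (default 0.05).
#' @param seed Master seed for the shuffles.
#' @return An object of class `delta_distributions`: a list with tibbles
#'   `deltas` (per-career values), `marginals`, `ratio`, `joint`, and the
#'   configuration.
#' @export
delta_distributions <- function(careers, n_shuffles_per_career = 10,
                                bin_width = 0.05, seed = 1) {
  eligible <- dplyr::filter(careers, .data$career_length >= 3)
  if (nrow(eligible) == 0) abort("No careers of length >= 3 to analyse.")

  career_deltas <- function(scores) delta_stats(top_three_indices(scores))

  real <- purrr::map_dfr(eligible$scores, career_deltas)
  real$player_id <- eligible$player_id

  shuffled <- purrr::map2_dfr(
    eligible$scores, eligible$player_id,
    function(sc, id) {
      purrr::map_dfr(seq_len(n_shuffles_per_career), function(k) {
        career_deltas(shuffle_career(sc, seed = substream_seed(seed, paste(id, k))))
      })
    }
  )

  breaks <- seq(-1, 1, by = bin_width)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  hist_of <- function(x) {
    cnt <- tabulate(findInterval(x, breaks, left.open = TRUE,
                                 rightmost.closed = FALSE, all.inside = TRUE),
                    nbins = length(mids))
    tibble::tibble(bin_mid = mids, count = cnt, prob = cnt / sum(cnt))
  }

  kinds <- c("d12", "d13", "d23")
  marginals <- purrr::map_dfr(kinds, function(kind) {
    dplyr::bind_rows(
      dplyr::mutate(hist_of(real[[kind]]), kind = kind, source = "real"),
      dplyr::mutate(hist_of(shuffled[[kind]]), kind = kind, source = "shuffled")
    )
  })

  eps <- 1 / max(nrow(shuffled), 1)
  ratio <- purrr::map_dfr(kinds, function(kind) {
    p <- dplyr::filter(marginals, .data$kind == !!kind, .data$source == "real")
    q <- dplyr::filter(marginals, .data$kind == !!kind, .data$source == "shuffled")
    tibble::tibble(
      kind = kind, bin_mid = p$bin_mid,
      R = ifelse(q$count == 0, NA_real_, (p$prob + eps) / (q$prob + eps))
    )
  })

  joint_of <- function(df) {
    bx <- findInterval(df$d12, breaks, left.open = TRUE, all.inside = TRUE)
    by <- findInterval(df$d13, breaks, left.open = TRUE, all.inside = TRUE)
    cnt <- table(factor(bx, levels = seq_along(mids)),
                 factor(by, levels = seq_along(mids)))
    tibble::tibble(
      d12_mid = mids[as.integer(rep(seq_along(mids), times = length(mids)))],
      d13_mid = mids[as.integer(rep(seq_along(mids), each = length(mids)))],
      prob = as.numeric(cnt) / sum(cnt)
    )
  }
  joint <- dplyr::bind_rows(
    dplyr::mutate(joint_of(real), source = "real"),
    dplyr::mutate(joint_of(shuffled), source = "shuffled")
  )

  structure(list(
    deltas = real, deltas_shuffled = shuffled,
    marginals = marginals, ratio = ratio, joint = joint,
    config = list(n_shuffles_per_career = n_shuffles_per_career,
                  bin_width = bin_width, seed = seed,
                  n_careers = nrow(eligible))
  ), class = "delta_distributions")
}

#' @export
print.delta_distributions <- function(x, ...) {
  cat(sprintf(
    "<delta_distributions> %d careers, %d shuffles/career, bin width %g\n",
    x$config$n_careers, x$config$n_shuffles_per_career, x$config$bin_width
  ))
  r0 <- dplyr::filter(x$ratio, abs(.data$bin_mid) == min(abs(.data$bin_mid)))
  cat("Ratio R near 0 by kind:\n")
  print(stats::aggregate(R ~ kind, data = r0, FUN = mean))
  invisible(x)
}

# Quadrant-probe two-sample statistic: max over anchor points and the four
# half-open quadrants of |F_A - F_B|.
ks2d_statistic <- function(a, b) {
  anchors <- rbind(a, b)
  na <- nrow(a); nb <- nrow(b)
  stat <- 0
  for (i in seq_len(nrow(anchors))) {
    x0 <- anchors[i, 1]; y0 <- anchors[i, 2]
    ax <- a[, 1] <= x0; ay <- a[, 2] <= y0
    bx <- b[, 1] <= x0; by <- b[, 2] <= y0
    da <- c(sum(ax & ay), sum(ax & !ay), sum(!ax & ay), sum(!ax & !ay)) / na
    db <- c(sum(bx & by), sum(bx & !by), sum(!bx & by), sum(!bx & !by)) / nb
    stat <- max(stat, abs(da - db))
  }
  stat
}

#' Two-sample two-dimensional Kolmogorov-Smirnov test
#'
#' Peacock-style statistic: the maximum over data-anchored quadrant probes
#' of the absolute difference between the two empirical distribution
#' functions. The p-value is obtained by permuting pooled labels (exact in
#' distribution), or by exhaustive enumeration of all label assignments
#' when `exact = TRUE` and the split count is tractable.
#'
#' @param a,b Two-column matrices or data frames of 2D points (at least 5
#'   rows each).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @param exact If `TRUE`, enumerate all `choose(n, nA)` label splits
#'   instead of sampling (errors if more than 50000 splits).
#' @return A list with `statistic` (in `[0, 1]`) and `p.value` (in
#'   `(0, 1]`).
#' @export
ks2d_two_sample <- function(a, b, n_permutations = 999, seed = NULL,
                            exact = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 2 || ncol(b) != 2) abort("`a` and `b` must be 2-column.")
  if (nrow(a) < 5 || nrow(b) < 5) abort("Need at least 5 points per sample.")
  pool <- rbind(a, b)
  na <- nrow(a)
  if (nrow(unique(pool)) == 1) {
    return(list(statistic = 0, p.value = 1))
  }
  obs <- ks2d_statistic(a, b)
  n <- nrow(pool)
  if (exact) {
    n_splits <- choose(n, na)
    if (n_splits > 50000) abort("Too many splits for exhaustive enumeration.")
    splits <- combn(n, na)
    hits <- sum(apply(splits, 2, function(ix) {
      ks2d_statistic(pool[ix, , drop = FALSE], pool[-ix, , drop = FALSE]) >=
        obs - 1e-12
    }))
    return(list(statistic = obs, p.value = hits / n_splits))
  }
  hits <- with_seed_if(seed, {
    sum(vapply(seq_len(n_permutations), function(k) {
      ix <- sample.int(n, na)
      ks2d_statistic(pool[ix, , drop = FALSE], pool[-ix, , drop = FALSE]) >=
        obs - 1e-12
    }, logical(1)))
  })
  list(statistic = obs, p.value = (hits + 1) / (n_permutations + 1))
}
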