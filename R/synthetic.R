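#' Simulate a Hawkes process by thinning
#'
#' Ogata-style thinning with a piecewise-constant dominating intensity: the
#' bound at the current time is `mu` plus, for each past event within the
#' kernel support, the running maximum of the kernel over all later lags.
#' That bound is non-increasing until the next event, so acceptance by
#' `lambda / bound` is exact for any histogram kernel, monotone or not; it
#' is refreshed after every accepted event.
#'
#' @param mu Background intensity (events per unit time), `>= 0`.
#' @param kernel A [hawkes_kernel()] with branching ratio `< 1`, or `NULL`
#'   for a homogeneous Poisson process.
#' @param horizon Length of the simulation window `(0, horizon]`.
#' @param seed Optional integer seed for reproducibility.
#' @return Strictly increasing numeric vector of event times.
#' @export
simulate_hawkes <- function(mu, kernel = NULL, horizon, seed = NULL) {
  stopifnot(mu >= 0, horizon >= 0)
  if (!is.null(kernel)) {
    if (!inherits(kernel, "hawkes_kernel")) abort("`kernel` must be a hawkes_kernel.")
    if (branching_ratio(kernel) >= 1) {
      abort("Kernel integral (branching ratio) must be < 1: supercritical process.")
    }
  }
  if (horizon == 0) return(numeric(0))
  with_seed_if(seed, {
    if (is.null(kernel) || all(kernel$heights == 0)) {
      if (mu == 0) return(numeric(0))
      times <- cumsum(rexp(ceiling(mu * horizon + 5 * sqrt(mu * horizon) + 10), mu))
      while (length(times) > 0 && max(times) <= horizon) {
        times <- c(times, max(times) + cumsum(rexp(100, mu)))
      }
      return(times[times <= horizon])
    }
    support <- max(kernel$edges)
    # running suffix maximum of the kernel: bar_phi(u) = max_{v >= u} phi(v)
    sufmax <- rev(cummax(rev(kernel$heights)))
    bar_phi <- function(lag) {
      b <- findInterval(lag, kernel$edges, left.open = TRUE)
      out <- numeric(length(lag))
      ok <- b >= 1 & b <= length(sufmax)
      out[ok] <- sufmax[b[ok]]
      out[lag <= 0] <- sufmax[1]
      out
    }
    events <- numeric(0)
    recent <- numeric(0) # past events still within kernel support
    s <- 0
    repeat {
      bound <- mu + sum(bar_phi(s - recent))
      if (bound <= 0) break
      s <- s + rexp(1, bound)
      if (s > horizon) break
      recent <- recent[s - recent <= support]
      lam <- mu + sum(kernel_value(kernel, s - recent))
      if (runif(1) * bound <= lam) {
        events <- c(events, s)
        recent <- c(recent, s)
      }
    }
    events
  })
}

#' Exponential-shaped histogram kernel
#'
#' Convenience constructor: a histogram kernel whose heights follow an
#' exponential decay `exp(-lag / scale)` over `[0, n_scales * scale]`,
#' normalised so the kernel integrates exactly to `branching`.
#'
#' @param branching Target branching ratio in `[0, 1)`.
#' @param scale Decay scale of the kernel (same units as the time axis).
#' @param n_bins Number of histogram bins (default 20).
#' @param n_scales Support length in units of `scale` (default 5).
#' @return A [hawkes_kernel()].
#' @export
exp_decay_kernel <- function(branching, scale, n_bins = 20, n_scales = 5) {
  stopifnot(branching >= 0, branching < 1, scale > 0)
  edges <- seq(0, n_scales * scale, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- exp(-mids / scale)
  mass <- sum(h * diff(edges))
  hawkes_kernel(edges, if (mass > 0) h * branching / mass else h)
}

#' Synthesize one career with known ground truth
#'
#' Two modes. `"null_iid"` draws independent scores from a zero-inflated
#' geometric family — frequent ducks and a heavy right tail, the shape of
#' real batting scores — with no temporal structure. `"hot_hawkes"` inverts
#' the performance-time subordination: it simulates a self-exciting point
#' process on the H axis and converts each inter-event gap back to a score
#' via `S = round(1 / gap)` clamped to `[1, s_max]`, so the career carries
#' genuine self-excitation of known strength `branching`.
#'
#' Defaults encode a realistic batting career: mean score 25, zero inflation
#' 0.08, and in hot mode a background rate `mu = score_mean * (1 -
#' branching)` so the event rate on the H axis matches the score level, with
#' kernel memory spanning roughly 2.5 mean inter-event gaps.
#'
#' @param career_length Number of games.
#' @param mode `"null_iid"` or `"hot_hawkes"`.
#' @param score_mean Mean of the geometric score family.
#' @param zero_inflation Extra probability mass at score 0 (null mode).
#' @param mu Background H-axis rate (hot mode); default
#'   `score_mean * (1 - branching)`.
#' @param branching Self-excitation strength in `[0, 1)` (hot mode).
#' @param kernel_scale Decay scale of the excitation kernel on the H axis;
#'   default 2.5 mean gaps, i.e. `2.5 * (1 - branching) / mu`.
#' @param s_max Clamp for scores recovered from tiny gaps (default 500).
#' @param seed Optional integer seed.
#' @param player_id Identifier used in the returned career row.
#' @return A one-row career table with additional ground-truth columns
#'   `mode`, `true_mu`, `true_branching`.
#' @export
synthesize_career <- function(career_length,
                              mode = c("null_iid", "hot_hawkes"),
                              score_mean = 25, zero_inflation = 0.08,
                              mu = NULL, branching = 0.5,
                              kernel_scale = NULL, s_max = 500,
                              seed = NULL, player_id = "synthetic") {
  mode <- match.arg(mode)
  stopifnot(career_length >= 1, score_mean > 0,
            branching >= 0, branching < 1)
  scores <- with_seed_if(seed, {
    if (mode == "null_iid") {
      base <- rgeom(career_length, prob = 1 / (1 + score_mean))
      ifelse(runif(career_length) < zero_inflation, 0L, as.integer(base))
    } else {
      if (is.null(mu)) mu <- score_mean * (1 - branching)
      if (is.null(kernel_scale)) kernel_scale <- 2.5 * (1 - branching) / mu
      kern <- if (branching > 0) exp_decay_kernel(branching, kernel_scale) else NULL
      rate <- mu / (1 - branching)
      horizon <- career_length / rate * 1.4 + 10 / rate
      events <- simulate_hawkes(mu, kern, horizon)
      attempts <- 0L
      while (length(events) < career_length && attempts < 8L) {
        attempts <- attempts + 1L
        horizon <- horizon * 1.7
        events <- simulate_hawkes(mu, kern, horizon)
      }
      if (length(events) < career_length) {
        abort(paste(
          "Could not reach the requested career length within the simulation",
          "horizon; increase `mu` or decrease `career_length`."
        ))
      }
      gaps <- diff(c(0, events[seq_len(career_length)]))
      as.integer(pmin(pmax(round(1 / gaps), 1), s_max))
    }
  })
  if (mode == "null_iid" || is.null(mu)) mu <- NA_real_
  tibble::tibble(
    player_id = player_id, format = "synthetic", discipline = "batting",
    scores = list(scores), career_length = as.integer(career_length),
    mode = mode, true_mu = mu,
    true_branching = if (mode == "hot_hawkes") branching else 0
  )
}

#' Synthesize a cohort of careers
#'
#' Vectorised wrapper around [synthesize_career()]: one career per row, each
#' drawn from its own RNG substream derived from `seed` and the player id,
#' so cohorts are reproducible and order-independent.
#'
#' @param n_careers Number of careers.
#' @param career_length Games per career (recycled).
#' @param seed Master seed.
#' @param ... Passed to [synthesize_career()].
#' @return A career table with ground-truth columns.
#' @export
synthesize_cohort <- function(n_careers, career_length, seed = 1, ...) {
  lengths <- rep_len(career_length, n_careers)
  purrr::map2_dfr(seq_len(n_careers), lengths, function(i, len) {
    id <- sprintf("sim%04d", i)
    synthesize_career(len, seed = substream_seed(seed, id),
                      player_id = id, ...)
  })
}

#' Synthesize a win/loss sequence with optional persistence
#'
#' The first outcome is Bernoulli(`p_win`); each later outcome repeats the
#' previous one with probability `persistence` and is otherwise a fresh
#' Bernoulli(`p_win`) draw. `persistence = 0` gives i.i.d. outcomes — the
#' null model for streak analysis; positive persistence creates streaky
#' sequences with known structure.
#'
#' @param length Number of games.
#' @param p_win Base win probability.
#' @param persistence Probability of copying the previous outcome, `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Character vector of `"win"` / `"loss"`.
#' @export
synthesize_outcomes <- function(length, p_win = 0.5, persistence = 0,
                                seed = NULL) {
  stopifnot(length >= 1, p_win >= 0, p_win <= 1,
            persistence >= 0, persistence < 1)
  with_seed_if(seed, {
    out <- character(length)
    out[1] <- if (runif(1) < p_win) "win" else "loss"
    if (length > 1) {
      copy <- runif(length - 1) < persistence
      fresh <- ifelse(runif(length - 1) < p_win, "win", "loss")
      for (i in 2:length) {
        out[i] <- if (copy[i - 1]) out[i - 1] else fresh[i - 1]
      }
    }
    out
  })
}
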