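#' Subordinate a score sequence to "performance time"
#'
#' Maps an ordered score sequence S(1), ..., S(tau) onto the cumulative sums
#' H(t) = sum_{i <= t} 1 / max(S(i), s_min). Each game contributes an
#' increment inversely proportional to its score, so a run of high scores
#' becomes a tight cluster of points on the H axis — the representation on
#' which the self-exciting model operates.
#'
#' Zero scores make the raw increment infinite; they are floored at `s_min`.
#' The default `s_min = 0.5` gives a duck a gap of 2, strictly larger than
#' the gap of any positive integer score (at most 1), so the
#' worse-score-implies-longer-gap ordering is preserved. This floor is the
#' one policy choice in the transformation and is recorded on the result.
#'
#' @param scores Numeric vector of non-negative scores in career order.
#' @param s_min Positive floor applied to scores before inversion.
#' @return Numeric vector of strictly increasing time stamps, one per game,
#'   with attribute `s_min` recording the zero policy.
#' @export
#' @examples
#' to_performance_time(c(50, 100, 25)) # 0.02 0.03 0.07
to_performance_time <- function(scores, s_min = 0.5) {
  if (!is.numeric(s_min) || length(s_min) != 1 || s_min <= 0) {
    abort("`s_min` must be a single positive number.")
  }
  assert_scores(scores)
  stamps <- cumsum(1 / pmax(scores, s_min))
  attr(stamps, "s_min") <- s_min
  stamps
}

#' Invert performance time back to a score sequence
#'
#' Recovers S(t) = 1 / (H(t) - H(t-1)) from strictly increasing stamps (with
#' H(0) = 0). Exact inverse of [to_performance_time()] on all-positive
#' integer scores; slots floored at `s_min` come back as `s_min`.
#'
#' @param stamps Strictly increasing numeric vector of performance times.
#' @return Numeric score sequence.
#' @export
from_performance_time <- function(stamps) {
  if (length(stamps) < 1) abort("`stamps` must be non-empty.")
  gaps <- diff(c(0, as.numeric(stamps)))
  if (any(gaps <= 0)) abort("`stamps` must be strictly increasing.")
  1 / gaps
}
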