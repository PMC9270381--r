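w <- "win"; l <- "loss"

test_that("streak extraction finds maximal win runs", {
  st <- extract_streaks(c(w, w, l, w, w, w, l))
  expect_equal(st, tibble::tibble(length = 2:3, freq = c(1L, 1L)))
  expect_equal(nrow(extract_streaks(rep(l, 5))), 0)
  expect_equal(extract_streaks(rep(w, 4)),
               tibble::tibble(length = 4L, freq = 1L))
  # draws and no-results break streaks like losses
  st2 <- extract_streaks(c(w, "other", w, w))
  expect_equal(st2, tibble::tibble(length = 1:2, freq = c(1L, 1L)))
  # sum(n * f) equals the win count, on random sequences
  withr::with_seed(91, {
    for (rep in 1:20) {
      oc <- sample(c(w, l, "other"), 60, replace = TRUE)
      st <- extract_streaks(oc)
      expect_equal(sum(st$length * st$freq), sum(oc == w))
    }
  })
})

test_that("null ensembles permute outcomes and match exhaustive enumeration", {
  oc <- c(w, w, w, l, l)
  ens <- null_streak_ensemble(oc, n_shuffles = 2000, seed = 92)
  expect_length(ens, 2000)
  expect_true(all(vapply(ens, sum, numeric(1)) == 3)) # wins preserved
  # exhaustive oracle over all C(5,3) = 10 arrangements: the maximal streak
  # is 3 in 3 cases, 2 in 6 cases, 1 in 1 case
  maxes <- vapply(ens, max, numeric(1))
  expect_lt(abs(mean(maxes == 3) - 0.3), 4 * sqrt(0.3 * 0.7 / 2000))
  expect_lt(abs(mean(maxes == 2) - 0.6), 4 * sqrt(0.6 * 0.4 / 2000))
  expect_lt(abs(mean(maxes == 1) - 0.1), 4 * sqrt(0.1 * 0.9 / 2000))
  # all-win sequences are shuffle-invariant
  ens_w <- null_streak_ensemble(rep(w, 6), n_shuffles = 10, seed = 1)
  expect_true(all(vapply(ens_w, identical, logical(1), 6L)))
  expect_identical(null_streak_ensemble(oc, 50, seed = 9),
                   null_streak_ensemble(oc, 50, seed = 9))
})

test_that("streak p-values match the exhaustive oracle with add-one form", {
  oc <- c(w, w, w, l, l)
  obs <- extract_streaks(oc) # one streak of length 3
  ens <- null_streak_ensemble(oc, n_shuffles = 10000, seed = 93)
  pv <- streak_pvalues(obs, ens)
  # exhaustive p(max >= 3) = 3/10
  expect_lt(abs(pv$p_n - 0.3), 4 * sqrt(0.3 * 0.7 / 10000) + 1e-4)
  # a streak of length 1 is always matched when any win exists
  oc1 <- c(w, l, l)
  pv1 <- streak_pvalues(extract_streaks(oc1),
                        null_streak_ensemble(oc1, 500, seed = 94))
  expect_equal(pv1$p_n, 1)
  # p(n_f) <= p(n) for f >= 1 (set inclusion) on random sequences
  withr::with_seed(95, {
    for (rep in 1:10) {
      oc <- sample(c(w, l), 40, replace = TRUE)
      st <- extract_streaks(oc)
      if (nrow(st) == 0) next
      pv <- streak_pvalues(st, null_streak_ensemble(oc, 300))
      expect_true(all(pv$p_nf <= pv$p_n + 1e-12))
      expect_true(all(pv$p_n > 0 & pv$p_n <= 1))
    }
  })
})

test_that("multiple-testing adjustments match the standard formulas", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "benjamini_hochberg"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.2), "bonferroni"), c(0.02, 0.4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_error(adjust_pvalues(0.5, "fisher"), "Unknown correction")
  # adjusted >= raw and order invariance, all five methods
  withr::with_seed(96, {
    p <- runif(12)
    for (m in c("bonferroni", "holm", "hochberg", "benjamini_hochberg",
                "benjamini_yekutieli")) {
      adj <- adjust_pvalues(p, m)
      expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
      perm <- sample.int(12)
      expect_equal(adjust_pvalues(p[perm], m), adj[perm])
    }
  })
})

test_that("extreme labels follow the stated disjunction", {
  sig <- tibble::tibble(length = c(3L, 5L), freq = c(2L, 1L),
                        p_n = c(0.01, 0.50), p_nf = c(0.50, 0.50))
  lab <- flag_extreme(sig, alpha = 0.05, headline = "bonferroni")
  expect_equal(lab$label, c("extreme", "probable"))
  expect_true(all(c("p_n_holm", "p_nf_benjamini_yekutieli") %in% names(lab)))
  expect_error(flag_extreme(sig, headline = "nope"), "must be one of")
})

test_that("extreme rate under the i.i.d. null stays controlled", {
  # scaled-down version of the calibration experiment: per-team Holm family
  withr::with_seed(97, {
    labs <- purrr::map_dfr(1:20, function(i) {
      oc <- synthesize_outcomes(80, p_win = 0.5)
      streak_significance(oc, n_shuffles = 400)
    })
  })
  expect_lte(mean(labs$label == "extreme"), 0.10)
})
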