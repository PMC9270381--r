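test_that("top-three indices rank scores with earliest-first tie-breaking", {
  expect_equal(
    top_three_indices(c(3, 50, 20, 70, 10, 60))[, c("t1", "t2", "t3")],
    tibble::tibble(t1 = 4L, t2 = 6L, t3 = 2L)
  )
  expect_equal(
    unlist(top_three_indices(c(5, 9, 9, 9, 1))[, c("t1", "t2", "t3")],
           use.names = FALSE),
    c(2L, 3L, 4L)
  )
  expect_error(top_three_indices(c(7, 7)), "At least 3")
})

test_that("delta statistics satisfy the telescoping identity exactly", {
  d <- delta_stats(tibble::tibble(t1 = 4, t2 = 6, t3 = 2, tau = 6))
  expect_equal(unlist(d, use.names = FALSE), c(-1 / 3, 1 / 3, 2 / 3))
  d2 <- delta_stats(tibble::tibble(t1 = 10, t2 = 8, t3 = 12, tau = 20))
  expect_equal(unlist(d2, use.names = FALSE), c(0.10, -0.10, -0.20))
  # identity d12 + d23 = d13 on random careers, real and shuffled
  withr::with_seed(4, {
    for (rep in 1:25) {
      sc <- sample(0:200, 50, replace = TRUE)
      for (s in list(sc, shuffle_career(sc))) {
        d <- delta_stats(top_three_indices(s))
        expect_equal(d$d12 + d$d23, d$d13)
        expect_true(all(abs(unlist(d)) <= 1))
      }
    }
  })
})

test_that("career shuffling preserves the score multiset and is seeded", {
  sc <- c(5, 9, 0, 120, 9, 33)
  expect_equal(sort(shuffle_career(sc, seed = 3)), sort(sc))
  expect_identical(shuffle_career(sc, seed = 3), shuffle_career(sc, seed = 3))
  expect_identical(shuffle_career(42), 42)
})

test_that("delta distributions normalise and are flat under the i.i.d. null", {
  coh <- synthesize_cohort(600, 80, seed = 31, mode = "null_iid")
  dd <- delta_distributions(coh, n_shuffles_per_career = 10, seed = 32)
  # every histogram sums to 1
  sums <- dd$marginals |>
    dplyr::group_by(kind, source) |>
    dplyr::summarise(s = sum(prob), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  jt <- dd$joint |>
    dplyr::group_by(source) |>
    dplyr::summarise(s = sum(prob), .groups = "drop")
  expect_true(all(abs(jt$s - 1) < 1e-12))

  # binwise agreement with the shuffled null within Monte-Carlo error:
  # standardized residuals of real counts against shuffled proportions
  n_real <- nrow(dd$deltas)
  z_by_kind <- purrr::map(c("d12", "d13", "d23"), function(kind) {
    p <- dplyr::filter(dd$marginals, .data$kind == !!kind, source == "real")
    q <- dplyr::filter(dd$marginals, .data$kind == !!kind, source == "shuffled")
    keep <- q$count >= 50
    phat <- q$prob[keep]
    (p$count[keep] - n_real * phat) / sqrt(n_real * phat * (1 - phat))
  })
  z <- unlist(z_by_kind)
  expect_gt(length(z), 30)
  expect_gt(mean(abs(z) < 3), 0.9)
  expect_lt(abs(mean(z)), 0.5)
  # smoothed ratio stays near 1 where the null is well populated
  expect_true(all(is.na(dd$ratio$R) | dd$ratio$R >= 0))
})

test_that("planted co-location of the top three inflates the central ratio", {
  coh <- planted_cohort(150, career_length = 100, spread = 3, seed = 41)
  dd <- delta_distributions(coh, n_shuffles_per_career = 10, seed = 42)
  central <- dd$ratio |>
    dplyr::filter(abs(.data$bin_mid) < 0.06) |>
    dplyr::group_by(kind) |>
    dplyr::summarise(R = mean(R, na.rm = TRUE), .groups = "drop")
  # all three difference kinds concentrate at 0 far above the null
  expect_true(all(central$R > 1.5))
})

test_that("2D KS statistic and permutation p behave at the extremes", {
  withr::with_seed(51, {
    a <- matrix(runif(40), 20)
    expect_equal(ks2d_two_sample(a, a, n_permutations = 99, seed = 1)$statistic, 0)
    # disjoint quadrant supports
    lo <- matrix(runif(40, 0, 0.45), 20)
    hi <- matrix(runif(40, 0.55, 1), 20)
    r <- ks2d_two_sample(lo, hi, n_permutations = 999, seed = 2)
    expect_gte(r$statistic, 0.95)
    expect_lte(r$p.value, 0.01)
    # degenerate all-identical samples
    pt <- matrix(1, 6, 2)
    expect_equal(ks2d_two_sample(pt, pt), list(statistic = 0, p.value = 1))
    # bounds
    expect_true(r$statistic <= 1 && r$p.value > 0)
  })
})

test_that("permutation p matches exhaustive relabelling on 5-vs-5 sets", {
  withr::with_seed(52, {
    a <- matrix(rnorm(10), 5)
    b <- matrix(rnorm(10, mean = 0.8), 5)
  })
  exact <- ks2d_two_sample(a, b, exact = TRUE)
  mc <- ks2d_two_sample(a, b, n_permutations = 20000, seed = 53)
  expect_equal(mc$statistic, exact$statistic)
  # Monte-Carlo estimate within 4 binomial sigma of the exhaustive value
  tol <- 4 * sqrt(exact$p.value * (1 - exact$p.value) / 20000) + 1e-4
  expect_lt(abs(mc$p.value - exact$p.value), tol + 1 / 20000)
})
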