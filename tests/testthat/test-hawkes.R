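test_that("kernel constructor validates and integrates exactly", {
  k <- hawkes_kernel(c(0, 2, 4), c(0.1, 0.05))
  expect_equal(branching_ratio(k), 0.3)
  expect_equal(branching_ratio(hawkes_kernel(c(0, 5), 0)), 0)
  expect_error(hawkes_kernel(c(1, 2), 0.1), "start at 0")
  expect_error(hawkes_kernel(c(0, 1), c(-0.1)), "non-negative")
  expect_error(hawkes_kernel(c(0, 1, 2), 0.1), "one more element")
})

test_that("intensity adds kernel contributions from past events only", {
  m <- hawkes_model(1, hawkes_kernel(c(0, 2), 0.5))
  expect_equal(hawkes_intensity(m, history = 1, t = 2), 1.5)
  expect_equal(hawkes_intensity(m, history = 1, t = 4), 1.0)
  expect_equal(hawkes_intensity(m, history = numeric(0), t = 7), 1.0)
  expect_equal(hawkes_intensity(m, history = 1, t = 1), 1.0) # strictly before
  expect_error(hawkes_intensity(m, history = c(2, 1), t = 3), "sorted")
})

test_that("log-likelihood matches closed forms for the memoryless model", {
  m <- hawkes_model(2)
  expect_equal(hawkes_loglik(m, c(0.5, 1.0), c(0, 2)), 2 * log(2) - 4)
  expect_equal(hawkes_loglik(m, numeric(0), c(0, 7)), -14) # -mu*T
  expect_error(hawkes_loglik(m, c(3), c(0, 2)), "lie in")
  # zero intensity at an event is degenerate, not an error
  z <- hawkes_loglik(hawkes_model(0), 0.5, c(0, 1))
  expect_identical(as.numeric(z), -Inf)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("piecewise compensator agrees with breakpoint-aware quadrature", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      k <- hawkes_kernel(c(0, 0.5, 1.3, 2), runif(3, 0, 0.4))
      m <- hawkes_model(runif(1, 0.5, 2), k)
      hist <- sort(runif(4, 0, 3))
      ev <- sort(runif(5, 3, 6))
      a <- 3; b <- 6
      ll <- hawkes_loglik(m, ev, c(a, b), history = hist)
      # oracle: integrate the pointwise intensity exactly between all
      # breakpoints (event times + kernel edge offsets), midpoint rule is
      # exact for a piecewise-constant integrand
      brk <- sort(unique(pmin(pmax(
        c(a, b, ev, outer(c(hist, ev), k$edges, `+`)), a), b)))
      mids <- (brk[-1] + brk[-length(brk)]) / 2
      integral <- sum(hawkes_intensity(m, c(hist, ev), mids) * diff(brk))
      ll_oracle <- sum(log(hawkes_intensity(m, c(hist, ev), ev))) - integral
      expect_equal(ll, ll_oracle, tolerance = 1e-8)
    }
  })
})

test_that("EM trace is monotone and the fit beats the Poisson MLE", {
  for (seed in c(71, 72)) {
    ev <- simulate_hawkes(2, exp_decay_kernel(0.4, 0.5), 150, seed = seed)
    f <- hawkes_em(ev, horizon = 150)
    expect_true(all(diff(f$loglik_trace) >= -1e-9))
    n <- length(ev)
    ll_pois <- n * log(n / 150) - n
    expect_gte(f$loglik, ll_pois)
    expect_false(f$supercritical)
    # responsibilities implied by the fitted parameters normalise per event
    lam <- hawkes_intensity(f, ev, ev)
    contrib <- vapply(seq_along(ev), function(i) {
      past <- ev[ev < ev[i]]
      f$mu + sum(kernel_value(f$kernel, ev[i] - past))
    }, numeric(1))
    expect_equal(lam / contrib, rep(1, n))
  }
  expect_error(hawkes_em(1:5), "at least 10")
})

test_that("EM is deterministic and separates Poisson from Hawkes data", {
  ev <- simulate_hawkes(1, NULL, 800, seed = 73)
  f1 <- hawkes_em(ev, horizon = 800)
  f2 <- hawkes_em(ev, horizon = 800)
  expect_identical(glance(f1), glance(f2)) # no internal randomness
  expect_lt(f1$branching, 0.25)
  expect_lt(abs(f1$mu - 1), 0.25)

  evh <- simulate_hawkes(1, exp_decay_kernel(0.5, 0.5), 800, seed = 74)
  fh <- hawkes_em(evh, horizon = 800)
  expect_gt(fh$branching, f1$branching)
  expect_lt(abs(fh$branching - 0.5), 0.2)

  td <- tidy(fh)
  expect_equal(td$term[1], "mu")
  expect_equal(sum(td$mass, na.rm = TRUE), fh$branching)
})

test_that("time-rescaling residuals are Exp(1) under the true model", {
  # calibration: true memoryless model on its own simulations
  rej <- vapply(1:200, function(s) {
    ev <- simulate_hawkes(1, NULL, 300, seed = 8000 + s)
    residual_gof(hawkes_model(1), ev)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  # power: a grossly wrong model on clustered data is rejected
  k <- exp_decay_kernel(0.6, 0.5)
  rej_bad <- vapply(1:40, function(s) {
    ev <- simulate_hawkes(1, k, 120, seed = 8500 + s)
    residual_gof(hawkes_model(0.5), ev)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej_bad), 0.5)
  # rescaled gaps have unit mean under the true model
  ev <- simulate_hawkes(2, NULL, 500, seed = 8999)
  g <- residual_gof(hawkes_model(2), ev)$gaps
  expect_lt(abs(mean(g) - 1), 0.15)
})
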