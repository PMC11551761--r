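test_that("K = 1 MLE is the sample mean (closed form)", {
  f <- fit_mixture(dwell_set(c(1, 2, 3)), 1)
  expect_equal(f$lifetimes, 2)
  expect_equal(f$weights, 1)
  # with truncation the closed form is mean(t - t_min), reported as tau
  d <- dwell_set(c(1.5, 2.5, 3.5), t_min = 0.5)
  expect_equal(fit_mixture(d, 1)$lifetimes, 2)
  # agrees with direct numerical maximization of the truncated likelihood
  nll <- function(tau) -sum(log(dmixexp(d$durations_s, exp_mixture(tau, 1),
                                        t_min = 0.5)))
  tau_num <- optimize(nll, c(0.1, 20))$minimum
  expect_equal(fit_mixture(d, 1)$lifetimes, tau_num, tolerance = 1e-4)
})

test_that("likelihood is invariant to dwell ordering and K-nesting holds", {
  mix <- c_terminal_mixture()
  d <- sample_exponential_mixture(mix, 400, seed = 41)
  f2 <- fit_mixture(d, 2, seed = 42)
  d_perm <- dwell_set(rev(d$durations_s), t_min = d$t_min_s)
  f2p <- fit_mixture(d_perm, 2, seed = 42)
  expect_equal(f2$loglik, f2p$loglik, tolerance = 1e-6)
  f1 <- fit_mixture(d, 1)
  expect_gte(f2$loglik, f1$loglik)  # nested models
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
})

test_that("printed mixtures are recovered from 2000 dwells", {
  d_fl <- sample_exponential_mixture(full_length_mixture(), 2000, seed = 43)
  f_fl <- fit_mixture(d_fl, 3, seed = 44)
  expect_true(f_fl$converged)
  expect_equal(f_fl$lifetimes, c(0.08, 0.74, 11), tolerance = 0.2)
  d_ct <- sample_exponential_mixture(c_terminal_mixture(), 5000, seed = 45)
  f_ct <- fit_mixture(d_ct, 2, seed = 46)
  expect_equal(f_ct$lifetimes, c(0.25, 2), tolerance = 0.1)
  expect_equal(f_ct$weights, c(0.78, 0.22), tolerance = 0.1)
})

test_that("left-truncated fitting recovers the untruncated generator", {
  # single exponential, t_min = tau/2: censoring is severe (39% lost)
  tau <- 2
  d <- sample_exponential_mixture(exp_mixture(tau, 1), 1e4,
                                  t_min = tau / 2, seed = 47)
  f <- fit_mixture(d, 1)
  expect_equal(f$lifetimes, tau, tolerance = 0.1)
  # two components under truncation at one frame
  d2 <- sample_exponential_mixture(c_terminal_mixture(), 5000,
                                   t_min = 0.04, seed = 48)
  f2 <- fit_mixture(d2, 2, seed = 49)
  expect_equal(f2$lifetimes, c(0.25, 2), tolerance = 0.15)
})

test_that("BIC arithmetic is exact and penalizes useless components", {
  f <- fit_mixture(dwell_set(rexp(100, 1)), 1)
  f$loglik <- -250
  expect_equal(nicksearch:::bic_value(-250, 1, 100), log(100) + 500)
  expect_equal(nicksearch:::bic_value(-250, 1, 100), 504.6052, tolerance = 1e-4)
  expect_equal(nicksearch:::bic_value(-250, 2, 100), 504.6052 + 2 * log(100),
               tolerance = 1e-4)
  expect_equal(nicksearch:::bic_value(-250, 2, 100), 513.8155, tolerance = 1e-4)
  expect_error(bic(f, n = 0), "positive")
  # on single-exponential data an extra component usually cannot pay its
  # BIC penalty
  withr::with_seed(50, {
    worse <- replicate(10, {
      d <- sample_exponential_mixture(exp_mixture(2, 1), 500)
      fit_mixture(d, 2, seed = 1)$bic >= fit_mixture(d, 1)$bic - 2
    })
  })
  expect_gte(mean(worse), 0.8)
})

test_that("bootstrap is seeded, consistent, and shrinks like 1/sqrt(n)", {
  d <- sample_exponential_mixture(exp_mixture(3, 1), 400, seed = 51)
  b1 <- bootstrap_fit(d, 1, B = 200, seed = 52)
  b2 <- bootstrap_fit(d, 1, B = 200, seed = 52)
  expect_identical(b1$bootstrap, b2$bootstrap)
  # bootstrap mean close to the point estimate
  se <- sd(b1$bootstrap$lifetimes[, 1])
  expect_lt(abs(mean(b1$bootstrap$lifetimes[, 1]) - b1$lifetimes), 2 * se)
  # 4x the data roughly halves the bootstrap SE
  d4 <- sample_exponential_mixture(exp_mixture(3, 1), 1600, seed = 53)
  b4 <- bootstrap_fit(d4, 1, B = 200, seed = 54)
  ratio <- sd(b4$bootstrap$lifetimes[, 1]) / se
  expect_lt(abs(ratio - 0.5), 0.15)
  expect_error(bootstrap_fit(d, 1, B = 50), "at least 100")
})

test_that("the unimodality gate is calibrated", {
  withr::with_seed(55, {
    expect_true(unimodality_check(rnorm(500, 5, 0.3)))
    expect_false(unimodality_check(c(rnorm(250, 0), rnorm(250, 10))))
  })
  # weight samples piling at zero fail the floor rule regardless of shape
  withr::with_seed(56, {
    w <- abs(rnorm(500, 0.001, 0.0003))
  })
  expect_false(unimodality_check(w, weight_floor = 0.01))
  expect_error(unimodality_check(rnorm(50)), "at least 100")
})

test_that("select_model prefers the true order and applies the gate", {
  # single-exponential data: parsimony keeps K = 1
  d1 <- sample_exponential_mixture(exp_mixture(2, 1), 1000, seed = 57)
  s1 <- select_model(d1, K_max = 3, B = 150, seed = 58)
  expect_equal(s1$chosen_K, 1L)
  # chosen model's weights never sit below the floor in the bootstrap tail
  f <- s1$fit
  if (f$K > 1) {
    q5 <- apply(f$bootstrap$weights, 2, quantile, 0.05)
    expect_true(all(q5 > 0.01))
  }
  # two-component data at separation 8x: K = 2
  d2 <- sample_exponential_mixture(c_terminal_mixture(), 1000, seed = 59)
  s2 <- select_model(d2, K_max = 3, B = 150, seed = 60)
  expect_equal(s2$chosen_K, 2L)
})
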