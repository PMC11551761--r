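test_that("CVE reproduces hand-computed and degenerate cases", {
  # constant positions: no motion, no noise
  r0 <- cve_estimate(rep(5, 10), dt_s = 0.04)
  expect_equal(r0$D_hat, 0)
  expect_equal(r0$sigma2_hat, 0)
  # alternating positions: <dx^2> = 1, <dx_n dx_{n+1}> = -1
  r1 <- cve_estimate(c(0, 1, 0, 1, 0), dt_s = 1, blur_R = 0, min_steps = 4)
  expect_equal(r1$D_hat, -0.5)
  expect_equal(r1$sigma2_hat, 1)
  expect_error(cve_estimate(c(0, 1), dt_s = 1), "too few")
  expect_error(cve_estimate(1:10, dt_s = 1, frames = c(0:8, 10)),
               "non-uniform")
  expect_error(cve_estimate(1:10, dt_s = 1, blur_R = 0.4), "blur_R")
})

test_that("CVE is unbiased across D and noise levels", {
  withr::with_seed(21, {
    for (cond in list(c(D = 0.1, s = 0.3), c(D = 3.8, s = 0.1),
                      c(D = 10, s = 0))) {
      d_hat <- replicate(1000, {
        p <- simulate_diffusive_track(30, cond[["D"]], 0.04,
                                      sigma_loc = cond[["s"]])
        cve_estimate(p, 0.04, blur_R = 0)$D_hat
      })
      sem <- sd(d_hat) / sqrt(length(d_hat))
      expect_lt(abs(mean(d_hat) - cond[["D"]]), 3 * sem)
    }
  })
})

test_that("CVE agrees with the MSD-slope oracle on long noiseless tracks", {
  withr::with_seed(22, {
    p <- simulate_diffusive_track(1e4, 2.5, 0.04, sigma_loc = 0)
  })
  est <- cve_estimate(p, 0.04, blur_R = 0)$D_hat
  # independent oracle: linear fit of MSD over lags 1-5 through the origin
  lags <- 1:5
  msd <- vapply(lags, function(L) mean(diff(p, lag = L)^2), numeric(1))
  d_msd <- unname(coef(lm(msd ~ 0 + I(2 * 0.04 * lags)))[1])
  expect_equal(est, d_msd, tolerance = 0.05)
})

test_that("CVE rescales quadratically with the position units", {
  withr::with_seed(23, {
    p <- simulate_diffusive_track(500, 1.7, 0.04, sigma_loc = 0.1)
  })
  a <- cve_estimate(p, 0.04)$D_hat
  b <- cve_estimate(10 * p, 0.04)$D_hat
  expect_equal(b, 100 * a, tolerance = 1e-12)
})

test_that("population summaries follow mean +/- SEM", {
  s <- summarize_D(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(s$sem, 0.5774, tolerance = 1e-4)
  expect_equal(summarize_D(rep(4, 10))$sem, 0)
  expect_error(summarize_D(1), "at least 2")
})

test_that("Welch's t-test matches the hand-computed case", {
  r <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$dof, 4)
  expect_equal(r$p, 0.2878641, tolerance = 1e-6)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t_test(rep(1, 5), rep(2, 5)), "degenerate")
  # 10-fold separated populations are detected decisively
  withr::with_seed(24, {
    a <- rnorm(400, 3.8, 1.5)
    b <- rnorm(400, 0.38, 0.15)
  })
  expect_lt(welch_t_test(a, b)$p, 1e-6)
})
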