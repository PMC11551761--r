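test_that("noiseless two-level traces decode exactly", {
  states <- rep(c(0L, 1L, 0L, 1L, 0L), times = c(30, 10, 25, 5, 30))
  y <- square_trace(states) + rnorm(length(states), 0, 1e-3)
  id <- hmm_idealize(y)
  expect_identical(id$states, states)
  expect_equal(id$state_means, c(100, 400), tolerance = 1e-2)
  expect_true(all(abs(rowSums(id$transition_matrix) - 1) < 1e-9))
})

test_that("negating intensities swaps labels but preserves dwells", {
  states <- renewal_states(800, seed = 71)
  withr::with_seed(72, {
    y <- square_trace(states) + rnorm(800, 0, 40)
  })
  a <- hmm_idealize(y)
  b <- hmm_idealize(-y)
  expect_identical(a$states, 1L - b$states)
  da <- extract_dwells(a, 0.1)
  db <- extract_dwells(b, 0.1)
  expect_equal(sort(da$bound$durations_s), sort(db$unbound$durations_s))
})

test_that("frame-wise accuracy reaches 99% at SNR 3", {
  accs <- vapply(1:5, function(i) {
    states <- renewal_states(3000, seed = 73 + i)
    y <- withr::with_seed(80 + i, square_trace(states) + rnorm(3000, 0, 100))
    id <- hmm_idealize(y)
    mean(id$states == states)
  }, numeric(1))
  expect_gte(mean(accs), 0.99)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  states <- renewal_states(1000, seed = 74)
  y <- withr::with_seed(75, square_trace(states) + rnorm(1000, 0, 80))
  id <- hmm_idealize(y)
  expect_true(all(diff(id$loglik_trace) > -1e-6))
  expect_true(id$converged)
})

test_that("constant and unseparable segments are flagged degenerate", {
  idc <- hmm_idealize(rep(5, 100))
  expect_true(idc$degenerate)
  expect_true(all(idc$states == 0L))
  # pure noise with no two-level structure
  y <- withr::with_seed(76, rnorm(500, 100, 30))
  idn <- hmm_idealize(y)
  expect_true(idn$degenerate)
  expect_error(hmm_idealize(rnorm(10)), "too short")
})

test_that("dwell extraction does run-length arithmetic with censored edges", {
  d <- extract_dwells(c(0L, 0L, 1L, 1L, 1L, 0L), frame_s = 0.1)
  expect_equal(d$bound$durations_s, 0.3)
  expect_null(d$unbound)               # both unbound runs touch the edges
  expect_equal(d$censored_s, c(0.2, 0.1))
  expect_equal(d$total_s, 0.6)
  # alternating single frames
  alt <- extract_dwells(rep(c(1L, 0L), 10), frame_s = 0.1)
  expect_true(all(c(alt$bound$durations_s, alt$unbound$durations_s) == 0.1))
  # conservation holds for arbitrary idealizations
  states <- renewal_states(500, seed = 77)
  dd <- extract_dwells(states, frame_s = 0.1)
  total <- sum(dd$bound$durations_s, dd$unbound$durations_s, dd$censored_s)
  expect_equal(total, 50)
  # edges kept on request
  dk <- extract_dwells(c(0L, 0L, 1L, 1L, 1L, 0L), 0.1, drop_edges = FALSE)
  expect_equal(dk$unbound$durations_s, c(0.2, 0.1))
})

test_that("rastergrams stack traces ordered by first binding", {
  mk <- function(states) structure(list(states = states), class = "idealization")
  one <- rastergram(list(mk(c(0L, 1L, 0L))))
  expect_equal(unname(one$matrix[1, ]), c(0L, 1L, 0L))
  ids <- list(mk(c(0L, 0L, 1L)), mk(c(1L, 0L)), mk(c(0L, 1L, 0L, 0L)))
  r <- rastergram(ids, trace_ids = c("a", "b", "c"))
  expect_equal(r$order, c(2L, 3L, 1L))
  expect_equal(dim(r$matrix), c(3L, 4L))
  expect_true(is.na(r$matrix[1, 3]))  # right-padded with a sentinel
  # 80 traces give 80 rows; ties broken by trace id, stably
  many <- replicate(80, mk(c(0L, 1L)), simplify = FALSE)
  r80 <- rastergram(many)
  expect_equal(nrow(r80$matrix), 80L)
  expect_equal(r80$order, 1:80)
})
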