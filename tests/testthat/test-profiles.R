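make_profile_kymo <- function(rates, n_lines = 400, seed = 7) {
  withr::with_seed(seed, {
    g <- matrix(rpois(n_lines * length(rates), rep(rates, each = n_lines)),
                n_lines, length(rates))
  })
  kymograph(g, g * 0L, line_time_s = 0.04, pixel_size_um = 0.1,
            bead_edges_px = c(0, length(rates) - 1))
}

test_that("a single full-duration emitter normalizes to a peak of one", {
  px <- 0:199
  rates <- 40 * exp(-(px - 80)^2 / (2 * 1.5^2)) + 2
  km <- make_profile_kymo(rates)
  cal <- fit_calibration(c(2, 18), c(4850, 43650))  # 0.1 um/px map
  pr <- binding_density_profile(km, cal)
  expect_equal(max(pr$density), 1)
  peak_bp <- pr$positions_bp[which.max(pr$density)]
  expect_lt(abs(peak_bp - um_to_bp(cal, 8.0)), abs(um_to_bp(cal, 0.11)
                                                   - um_to_bp(cal, 0)))
  # strictly increasing grid
  expect_true(all(diff(pr$positions_bp) > 0))
})

test_that("peak heights track occupancy 2:1 within 10%", {
  px <- 0:199
  # emitter A on all lines, emitter B on half the lines
  rates_a <- 40 * exp(-(px - 60)^2 / (2 * 1.5^2))
  rates_b <- 40 * exp(-(px - 140)^2 / (2 * 1.5^2))
  withr::with_seed(8, {
    ga <- matrix(rpois(400 * 200, rep(rates_a + 2, each = 400)), 400, 200)
    gb <- matrix(rpois(400 * 200, rep(rates_b, each = 400)), 400, 200)
    gb[sample(400, 200), ] <- 0  # bound half the time
  })
  km <- kymograph(ga + gb, ga * 0L, 0.04, 0.1, c(0, 199))
  cal <- fit_calibration(c(2, 18), c(4850, 43650))
  pr <- binding_density_profile(km, cal)
  h_a <- max(pr$density[abs(pr$positions_bp - um_to_bp(cal, 6)) < 1000])
  h_b <- max(pr$density[abs(pr$positions_bp - um_to_bp(cal, 14)) < 1000])
  expect_equal(h_a / h_b, 2, tolerance = 0.1)
})

test_that("flat channels are rejected", {
  km <- kymograph(matrix(0L, 50, 60), matrix(0L, 50, 60), 0.04, 0.1,
                  c(0, 59))
  cal <- fit_calibration(c(1, 5), c(10000, 40000))
  expect_error(binding_density_profile(km, cal), "flat profile")
})

test_that("combining profiles is an identity for one input and linear", {
  mk <- function(shift = 0, peak = 20000) {
    grid <- seq(1000 + shift, 47000 + shift, by = 250)
    structure(list(positions_bp = grid,
                   density = exp(-(grid - peak)^2 / (2 * 800^2)),
                   n_kymographs = 1L),
              class = "density_profile")
  }
  p <- mk()
  c1 <- combine_profiles(list(p))
  expect_equal(stats::approx(c1$positions_bp, c1$density,
                             xout = p$positions_bp[10:170])$y,
               p$density[10:170] / max(p$density), tolerance = 1e-6)
  # two identical profiles: same shape as one
  c2 <- combine_profiles(list(p, p))
  expect_equal(c2$density, c1$density, tolerance = 1e-9)
  expect_equal(c2$n_kymographs, 2L)
  # shifted grids sharing a peak: combined peak at the shared position
  c3 <- combine_profiles(list(mk(0), mk(125)))
  expect_lt(abs(c3$positions_bp[which.max(c3$density)] - 20000), 300)
  # non-overlapping ranges are an error
  q <- mk(); q$positions_bp <- q$positions_bp + 1e6
  expect_error(combine_profiles(list(p, q)), "overlap")
})
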