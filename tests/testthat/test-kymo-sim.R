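test_that("an empty scene renders pure Poisson background", {
  sc <- kymo_scene(species = list(), duration_s = 40, background_rate = 2,
                   marker_photon_rate = 0, seed = 1)
  km <- simulate_kymograph(sc)$kymograph
  n <- length(km$green)
  expect_lt(abs(mean(km$green) - 2), 3 * sqrt(2 / n))
  expect_error(kymo_scene(duration_s = 0), "positive")
})

test_that("red-channel time average peaks at the two marker pixels", {
  sc <- kymo_scene(species = list(), duration_s = 40, seed = 2)
  km <- simulate_kymograph(sc)$kymograph
  prof <- colMeans(km$red)
  thr <- median(prof) + 4 * mad(prof)
  peaks <- which(prof > thr &
                   prof >= c(-Inf, prof[-length(prof)]) &
                   prof >= c(prof[-1], -Inf))
  # collapse adjacent indices into peak groups
  groups <- cumsum(c(1, diff(peaks) > 3))
  expect_equal(length(unique(groups)), 2L)
  expected_px <- (sc$bead_edges_um[1] +
                    c(33786, 44826) / 48500 * diff(sc$bead_edges_um)) /
    sc$pixel_size_um
  centres <- tapply(peaks, groups, function(g) g[which.max(prof[g])]) - 1
  expect_equal(sort(unname(centres)), sort(round(expected_px)),
               tolerance = 1, ignore_attr = TRUE)
})

test_that("a persistent static emitter dominates the profile at its nick", {
  sc <- static_scene(duration_s = 40, arrival_rate = 0.04, seed = 33)
  sim <- simulate_kymograph(sc)
  ev <- sim$truth[[1]]$events
  skip_if(nrow(ev) == 0)
  nick_bp <- sim$truth[[1]]$paths[[1]][1]
  expected_px <- round((sc$bead_edges_um[1] +
                          nick_bp / 48500 * diff(sc$bead_edges_um)) /
                         sc$pixel_size_um)
  prof <- colMeans(sim$kymograph$green)
  expect_lte(abs(which.max(prof) - 1 - expected_px), 1)
})

test_that("marker duty cycle modulates red excitation", {
  sc <- kymo_scene(species = list(), duration_s = 20, marker_duty = 0.5,
                   marker_period_lines = 20, seed = 3)
  km <- simulate_kymograph(sc)$kymograph
  m_px <- round((sc$bead_edges_um[1] + 33786 / 48500 * diff(sc$bead_edges_um)) /
                  sc$pixel_size_um) + 1
  line_means <- km$red[, m_px]
  on <- ((seq_along(line_means) - 1) %% 20) < 10
  expect_gt(mean(line_means[on]), 10 * max(mean(line_means[!on]), 0.5))
})

test_that("every ground-truth event is rendered and vice versa", {
  sc <- static_scene(duration_s = 30, arrival_rate = 0.1, seed = 44)
  sim <- simulate_kymograph(sc)
  km <- sim$kymograph
  truth <- sim$truth[[1]]
  n_lines <- nrow(km$green)
  for (i in seq_len(nrow(truth$events))) {
    l0 <- floor(truth$events$start_s[i] / sc$line_time_s)
    lines <- intersect(l0 + seq_along(truth$paths[[i]]) - 1L,
                       0:(n_lines - 1L))
    if (!length(lines)) next
    px <- round(nicksearch:::scene_bp_to_um(sc, truth$paths[[i]][1]) /
                  sc$pixel_size_um) + 1L
    # the emitter's pixel is far above background over its interval
    expect_gt(mean(km$green[lines + 1L, px]), 5 * sc$background_rate)
  }
  # identical seed -> bit-identical kymograph
  sim2 <- simulate_kymograph(sc)
  expect_identical(sim$kymograph$green, sim2$kymograph$green)
})
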