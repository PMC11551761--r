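test_that("an emitter-free kymograph yields no tracks", {
  withr::with_seed(1, {
    g <- matrix(rpois(500 * 120, 2), 500, 120)
  })
  expect_length(track_events(g), 0)
})

test_that("non-overlapping events are recovered with exact extents", {
  # 12 static emitters at distinct positions and disjoint or well-separated
  # line intervals, rendered noiselessly
  n_lines <- 400; n_px <- 200
  g <- matrix(0, n_lines, n_px)
  starts <- seq(10, 340, by = 30)
  pos <- 15 + (seq_along(starts) - 1) * 15
  px <- 0:(n_px - 1)
  for (i in seq_along(starts)) {
    lines <- starts[i]:(starts[i] + 19)
    g[lines + 1, ] <- g[lines + 1, ] +
      matrix(rep(50 * exp(-(px - pos[i])^2 / (2 * 1.5^2)), each = 20),
             nrow = 20)
  }
  trks <- track_events(g, peak_threshold = 5)
  expect_length(trks, 12)
  got <- lapply(trks, function(t) range(t$frames))
  want <- lapply(starts, function(s) c(s, s + 19))
  expect_setequal(lapply(got, paste, collapse = "-"),
                  lapply(want, paste, collapse = "-"))
})

test_that("static emitters are localized within 0.3 px RMS at SNR ~5", {
  rate <- function(centre) 25 * exp(-(0:149 - centre)^2 / (2 * 1.5^2)) + 1
  withr::with_seed(9, {
    g <- matrix(rpois(300 * 150, rep(rate(70.4), each = 300)), 300, 150)
  })
  trks <- track_events(g)
  expect_length(trks, 1)
  rms <- sqrt(mean((trks[[1]]$positions_px - 70.4)^2))
  expect_lt(rms, 0.3)
})

test_that("tracking recall and precision reach 0.95 on simulated scenes", {
  # moderate arrival rate keeps events mostly non-overlapping
  sp <- binding_kinetics(0.08, 0.5, 0, 0.5,
                         dwell = list(static = exp_mixture(8, 1),
                                      transient = exp_mixture(1, 1)),
                         photon_rate = 80)
  stats_all <- c(tp = 0, n_truth = 0, n_track = 0)
  for (seed in 1:3) {
    sc <- kymo_scene(species = list(sp), duration_s = 60, seed = seed)
    sim <- simulate_kymograph(sc)
    n_lines <- nrow(sim$kymograph$green)
    truth <- sim$truth[[1]]
    t_int <- cbind(floor(truth$events$start_s / sc$line_time_s),
                   pmin(floor(truth$events$end_s / sc$line_time_s),
                        n_lines - 1))
    # events at least min-length long are the detectable ground truth
    t_int <- t_int[t_int[, 2] - t_int[, 1] + 1 >= 3, , drop = FALSE]
    trks <- track_events(sim$kymograph)
    matched_truth <- rep(FALSE, nrow(t_int))
    matched_track <- rep(FALSE, length(trks))
    for (i in seq_len(nrow(t_int))) {
      for (j in seq_along(trks)) {
        if (matched_track[j]) next
        ov <- length(intersect(t_int[i, 1]:t_int[i, 2], trks[[j]]$frames))
        if (ov >= 0.5 * (t_int[i, 2] - t_int[i, 1] + 1)) {
          matched_truth[i] <- TRUE; matched_track[j] <- TRUE; break
        }
      }
    }
    stats_all <- stats_all + c(sum(matched_truth), nrow(t_int), length(trks))
  }
  recall <- stats_all[1] / stats_all[2]
  precision <- sum(stats_all[1]) / stats_all[3]
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("segment classification separates static from diffusive motion", {
  withr::with_seed(4, {
    # pure static with localization noise
    tr_s <- structure(list(id = 1, frames = 0:199,
                           positions_px = 50 + rnorm(200, 0, 0.3),
                           segments = NULL, excluded = FALSE, reason = NA),
                      class = "track")
    tr_s <- classify_segments(tr_s, localization_var_px2 = 0.09)
    expect_equal(nrow(tr_s$segments), 1L)
    expect_equal(tr_s$segments$label, "static")

    # pure diffusion: D = 3.8 kbp^2/s at 2.9 kbp/um, 0.1 um/px, 40 ms lines
    kbp_per_px <- 0.29
    sd_step <- sqrt(2 * 3.8 * 0.04) / kbp_per_px
    tr_d <- structure(list(id = 2, frames = 0:199,
                           positions_px = cumsum(c(70, rnorm(199, 0, sd_step))),
                           segments = NULL, excluded = FALSE, reason = NA),
                      class = "track")
    tr_d <- classify_segments(tr_d, localization_var_px2 = 0.09)
    expect_equal(nrow(tr_d$segments), 1L)
    expect_equal(tr_d$segments$label, "diffusive")

    # diffusive then static: boundary within 10 lines of the truth (line 200)
    pos <- c(cumsum(c(70, rnorm(199, 0, sd_step))))
    pos <- c(pos, rep(pos[200], 200) + rnorm(200, 0, 0.3))
    tr_m <- structure(list(id = 3, frames = 0:399, positions_px = pos,
                           segments = NULL, excluded = FALSE, reason = NA),
                      class = "track")
    tr_m <- classify_segments(tr_m, localization_var_px2 = 0.09)
    expect_equal(tr_m$segments$label, c("diffusive", "static"))
    expect_lte(abs(tr_m$segments$end[1] - 200), 10)
  })
})

test_that("segment labels are invariant under a position-axis mirror", {
  withr::with_seed(6, {
    pos <- c(cumsum(c(70, rnorm(149, 0, 1.2))), rep(30, 150) + rnorm(150, 0, 0.3))
  })
  mk <- function(p) structure(list(id = 1, frames = seq_along(p) - 1,
                                   positions_px = p, segments = NULL,
                                   excluded = FALSE, reason = NA),
                              class = "track")
  a <- classify_segments(mk(pos), localization_var_px2 = 0.09)
  b <- classify_segments(mk(200 - pos), localization_var_px2 = 0.09)
  expect_identical(a$segments, b$segments)
})

test_that("exclusion flags beads and collisions, monotonically", {
  mk <- function(id, frames, pos) {
    structure(list(id = id, frames = frames, positions_px = pos,
                   segments = NULL, excluded = FALSE, reason = NA),
              class = "track")
  }
  near_bead <- mk(1, 0:9, rep(11, 10))        # 1 px from left edge at 10
  mid_a <- mk(2, 0:9, rep(60, 10))
  mid_b <- mk(3, 0:9, rep(62, 10))            # 2 px from mid_a
  isolated <- mk(4, 20:29, rep(100, 10))
  out <- exclude_tracks(list(near_bead, mid_a, mid_b, isolated),
                        bead_edges_px = c(10, 170), bead_margin_px = 5,
                        collision_radius_px = 3)
  expect_equal(vapply(out, `[[`, character(1), "reason"),
               c("bead", "collision", "collision", NA))
  # monotone: growing either margin never unflags
  wider <- exclude_tracks(out, bead_edges_px = c(10, 170),
                          bead_margin_px = 10, collision_radius_px = 6)
  flagged_before <- vapply(out, `[[`, logical(1), "excluded")
  flagged_after <- vapply(wider, `[[`, logical(1), "excluded")
  expect_true(all(flagged_after[flagged_before]))
})

test_that("event frequency counts non-excluded tracks per minute", {
  mk <- function(excl) structure(list(id = 1, frames = 0:5,
                                      positions_px = rep(1, 6), segments = NULL,
                                      excluded = excl, reason = NA),
                                 class = "track")
  tracks <- c(replicate(220, mk(FALSE), simplify = FALSE),
              replicate(10, mk(TRUE), simplify = FALSE))
  expect_equal(event_frequency(tracks, 600), 22)
  expect_equal(event_frequency(list(), 60), 0)
  expect_error(event_frequency(list(), 0), "positive")
})
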