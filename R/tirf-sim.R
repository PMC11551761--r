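#' Simulate a two-colour TIRF colocalization trace
#'
#' Emulates the surface-tethered single-nick experiment: a protein channel
#' (Cy5) alternating between unbound and bound intensity levels, with bound
#' dwells drawn from an exponential mixture and unbound dwells exponential,
#' and a DNA-reporter channel (AF488) that is constant until it photobleaches
#' in a single step at an exponentially distributed time. Gaussian camera
#' noise is added per frame, with separate widths in the bound and unbound
#' states. Optional fluorophore blinking is a two-state on/off telegraph
#' within bound periods (off by default; the oxygen-scavenger/Trolox buffer
#' suppresses blinking in the experiment).
#'
#' @param bound_mixture [exp_mixture()] of bound-state dwell times (s).
#' @param unbound_tau_s mean unbound time (s), > 0.
#' @param duration_s trace length (s).
#' @param frame_s camera frame time (s); 0.100 in the experiment.
#' @param noise list with `bound_mean`, `unbound_mean`, `sd_bound`,
#'   `sd_unbound` (camera units). Signal-to-noise is
#'   `(bound_mean - unbound_mean) / sd`.
#' @param photobleach_rate AF488 single-step photobleach rate (1/s); 0
#'   disables bleaching.
#' @param blink optional list `list(k_off, k_on)` (1/s) for the bound-state
#'   dark-state telegraph; `NULL` disables blinking.
#' @param af488_levels pair of AF488 means (before, after bleach).
#' @param af488_sd AF488 Gaussian noise sd.
#' @param seed optional integer seed; identical seeds give identical traces.
#' @return list with `trace` (a `tirf_trace`: data frame `frame`, `time_s`,
#'   `af488`, `cy5`, plus `frame_s`, `trace_id`) and `truth` (data frame of
#'   bound/unbound intervals, per-frame state vector, bleach frame).
#' @export
simulate_tirf_trace <- function(bound_mixture,
                                unbound_tau_s,
                                duration_s = 600,
                                frame_s = 0.100,
                                noise = list(bound_mean = 600,
                                             unbound_mean = 300,
                                             sd_bound = 75,
                                             sd_unbound = 75),
                                photobleach_rate = 0,
                                blink = NULL,
                                af488_levels = c(1000, 100),
                                af488_sd = 40,
                                seed = NULL,
                                trace_id = "trace_1") {
  stopifnot(inherits(bound_mixture, "exp_mixture"))
  if (unbound_tau_s <= 0) stop("`unbound_tau_s` must be positive", call. = FALSE)
  if (frame_s <= 0) stop("`frame_s` must be positive", call. = FALSE)
  with_seed(seed, {
    n_frames <- max(1L, floor(duration_s / frame_s))
    # alternating renewal process, starting unbound
    t <- 0; bound <- FALSE
    starts <- numeric(0); ends <- numeric(0); states <- character(0)
    while (t < duration_s) {
      dwell <- if (bound) {
        sample_exponential_mixture(bound_mixture, 1)$durations_s
      } else {
        stats::rexp(1, 1 / unbound_tau_s)
      }
      starts <- c(starts, t); ends <- c(ends, min(t + dwell, duration_s))
      states <- c(states, if (bound) "bound" else "unbound")
      t <- t + dwell
      bound <- !bound
    }
    intervals <- data.frame(start_s = starts, end_s = ends, state = states,
                            stringsAsFactors = FALSE)
    frame_t <- (seq_len(n_frames) - 1L) * frame_s
    # state at each frame = state of the renewal interval containing it
    idx <- findInterval(frame_t, intervals$start_s)
    state <- as.integer(intervals$state[pmax(idx, 1L)] == "bound")
    emitting <- state
    if (!is.null(blink)) {
      # telegraph within bound frames: discrete-time approximation at frame_s
      p_off <- 1 - exp(-blink$k_off * frame_s)
      p_on <- 1 - exp(-blink$k_on * frame_s)
      dark <- FALSE
      for (j in seq_len(n_frames)) {
        if (state[j] == 1L) {
          dark <- if (dark) stats::runif(1) >= p_on else stats::runif(1) < p_off
          if (dark) emitting[j] <- 0L
        } else dark <- FALSE
      }
    }
    cy5_mean <- ifelse(emitting == 1L, noise$bound_mean, noise$unbound_mean)
    cy5_sd <- ifelse(emitting == 1L, noise$sd_bound, noise$sd_unbound)
    cy5 <- cy5_mean + stats::rnorm(n_frames, 0, cy5_sd)

    bleach_frame <- NA_integer_
    af_mean <- rep(af488_levels[1], n_frames)
    if (photobleach_rate > 0) {
      t_bleach <- stats::rexp(1, photobleach_rate)
      bleach_frame <- min(n_frames, max(1L, floor(t_bleach / frame_s) + 1L))
      if (bleach_frame <= n_frames) {
        af_mean[bleach_frame:n_frames] <- af488_levels[2]
      }
    }
    af488 <- af_mean + stats::rnorm(n_frames, 0, af488_sd)

    trace <- structure(
      list(data = data.frame(frame = seq_len(n_frames) - 1L,
                             time_s = frame_t, af488 = af488, cy5 = cy5),
           frame_s = frame_s, trace_id = trace_id),
      class = "tirf_trace"
    )
    list(trace = trace,
         truth = list(intervals = intervals, state = state,
                      emitting = emitting, bleach_frame = bleach_frame))
  })
}

#' @export
print.tirf_trace <- function(x, ...) {
  cat(sprintf("tirf_trace '%s': %d frames at %g ms\n", x$trace_id,
              nrow(x$data), 1000 * x$frame_s))
  invisible(x)
}
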