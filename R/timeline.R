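#' Binding kinetics of a fluorescent species on tethered DNA
#'
#' Describes how labelled ligase molecules arrive on the DNA and what they do
#' while bound. Arrivals over the whole DNA form a Poisson process; each
#' arrival draws one of three modes observed on kymographs: a static complex
#' parked at a nick, a 1D diffuser sliding along the duplex, or a transient
#' non-specific binder at a random position. Each mode has its own dwell-time
#' mixture; the diffusive mode additionally carries a diffusion coefficient
#' in kbp^2/s.
#'
#' @param arrival_rate events per second over the whole DNA.
#' @param p_static_at_nick,p_diffusive,p_transient mode probabilities; must
#'   sum to one (within 1e-9).
#' @param D_true diffusion coefficient of the diffusive mode (kbp^2/s).
#' @param dwell named list of [exp_mixture()]s for `static`, `diffusive` and
#'   `transient` dwells (only the modes with nonzero probability are needed).
#' @param capture_radius_bp if positive, a diffuser entering this distance of
#'   a nick converts to a static complex there for the rest of its dwell.
#'   Default 0 (off): diffusers can freely pass nick sites.
#' @param photon_rate photons per scan line emitted by one bound molecule
#'   (used by the kymograph renderer).
#' @return an object of class `binding_kinetics`.
#' @export
binding_kinetics <- function(arrival_rate,
                             p_static_at_nick,
                             p_diffusive,
                             p_transient,
                             D_true = 0,
                             dwell = list(),
                             capture_radius_bp = 0,
                             photon_rate = 60) {
  p <- c(p_static_at_nick, p_diffusive, p_transient)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("mode probabilities must be nonnegative and sum to 1", call. = FALSE)
  }
  if (D_true < 0) stop("`D_true` must be nonnegative", call. = FALSE)
  if (arrival_rate < 0) stop("`arrival_rate` must be nonnegative", call. = FALSE)
  needed <- c("static", "diffusive", "transient")[p > 0]
  for (mode in needed) {
    if (!inherits(dwell[[mode]], "exp_mixture")) {
      stop("`dwell$", mode, "` must be an exp_mixture (mode probability > 0)",
           call. = FALSE)
    }
  }
  structure(
    list(arrival_rate = arrival_rate,
         p_mode = c(static = p_static_at_nick, diffusive = p_diffusive,
                    transient = p_transient),
         D_true = D_true, dwell = dwell,
         capture_radius_bp = capture_radius_bp,
         photon_rate = photon_rate),
    class = "binding_kinetics"
  )
}

# Reflected Brownian path on [0, L] (bp), vectorized via the folding map:
# an unbounded walk folded into [0, 2L] and mirrored gives the reflected
# process exactly at the sampling times.
reflected_brownian <- function(x0, n_steps, D_bp2_s, dt_s, L) {
  if (n_steps == 0L) return(x0)
  steps <- stats::rnorm(n_steps, sd = sqrt(2 * D_bp2_s * dt_s))
  w <- x0 + cumsum(steps)
  folded <- w %% (2 * L)
  out <- ifelse(folded > L, 2 * L - folded, folded)
  c(x0, out)
}

#' Simulate ground-truth binding events on a DNA tether
#'
#' Event-level layer beneath the kymograph renderer: Poisson arrivals, a mode
#' per event, a dwell drawn from the mode's mixture, and per-event position
#' paths sampled at the scan line time. Diffusive paths are reflected
#' Brownian motion between the tether ends; with `capture_radius_bp > 0` a
#' diffuser freezes at the first nick it approaches within that radius.
#'
#' @param kinetics a [binding_kinetics()].
#' @param duration_s observation time (s), > 0.
#' @param dna_length_bp tether length in bp.
#' @param nick_positions_bp nick coordinates (bp), used by the static mode.
#' @param line_time_s sampling interval of position paths (s).
#' @param seed optional integer seed.
#' @return a `ground_truth` object: data frame `events` (columns `id`,
#'   `start_s`, `end_s`, `mode`) and list `paths` of per-event position
#'   vectors (bp) sampled at `line_time_s`.
#' @export
simulate_binding_timeline <- function(kinetics, duration_s,
                                      dna_length_bp = 48500,
                                      nick_positions_bp = default_nick_positions(),
                                      line_time_s = 0.040,
                                      seed = NULL) {
  stopifnot(inherits(kinetics, "binding_kinetics"))
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  with_seed(seed, {
    n_events <- stats::rpois(1, kinetics$arrival_rate * duration_s)
    modes <- character(0)
    if (n_events > 0) {
      modes <- sample(c("static", "diffusive", "transient"), n_events,
                      replace = TRUE, prob = kinetics$p_mode)
    }
    starts <- sort(stats::runif(n_events, 0, duration_s))
    events <- data.frame(id = seq_len(n_events), start_s = starts,
                         end_s = NA_real_, mode = modes,
                         stringsAsFactors = FALSE)
    paths <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      mode <- modes[i]
      dwell <- sample_exponential_mixture(kinetics$dwell[[mode]], 1)$durations_s
      end <- min(starts[i] + dwell, duration_s)
      n_samples <- max(1L, floor((end - starts[i]) / line_time_s) + 1L)
      if (mode == "static") {
        pos <- rep(sample(nick_positions_bp, 1), n_samples)
      } else if (mode == "transient") {
        pos <- rep(stats::runif(1, 0, dna_length_bp), n_samples)
      } else {
        x0 <- stats::runif(1, 0, dna_length_bp)
        pos <- reflected_brownian(x0, n_samples - 1L,
                                  kinetics$D_true * 1e6,  # kbp^2/s -> bp^2/s
                                  line_time_s, dna_length_bp)
        if (kinetics$capture_radius_bp > 0) {
          d <- vapply(pos, function(p) min(abs(p - nick_positions_bp)),
                      numeric(1))
          hit <- which(d <= kinetics$capture_radius_bp)[1]
          if (!is.na(hit) && hit < n_samples) {
            nick <- nick_positions_bp[which.min(abs(pos[hit] - nick_positions_bp))]
            pos[hit:n_samples] <- nick
            events$mode[i] <- "captured"
          }
        }
      }
      events$end_s[i] <- end
      paths[[i]] <- pos
    }
    structure(list(events = events, paths = paths,
                   dna_length_bp = dna_length_bp,
                   nick_positions_bp = nick_positions_bp,
                   line_time_s = line_time_s,
                   duration_s = duration_s),
              class = "ground_truth")
  })
}

#' Default nick-site layout
#'
#' Ten sites evenly spaced between 4 and 44 kbp on the 48.5 kbp tether. The
#' real substrate's site coordinates are configurable wherever nicks enter a
#' simulation; this even layout is the neutral default.
#' @return numeric vector of 10 positions (bp).
#' @export
default_nick_positions <- function() {
  seq(4000, 44000, length.out = 10)
}
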