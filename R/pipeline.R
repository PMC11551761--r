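#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown keys are
#' rejected, so a config file cannot silently misspell a parameter. The
#' config round-trips losslessly through [jsonlite::write_json()] /
#' [jsonlite::fromJSON()].
#'
#' @param ... overrides of the defaults (named).
#' @return a `run_config` (named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # kymograph simulation
    kymo = list(n_kymographs = 3L, duration_s = 120, line_time_s = 0.040,
                pixel_size_um = 0.1, psf_sigma_um = 0.15,
                background_rate = 2, photon_rate = 60,
                arrival_rate = 0.4, p_static = 0.25, p_diffusive = 0.35,
                p_transient = 0.40, D_true = 3.8,
                static_tau = 11, diffusive_tau = 0.74, transient_tau = 0.08),
    # kymograph analysis
    tracking = list(link_radius_px = 3, max_gap_lines = 2,
                    min_length_lines = 3, window_lines = 10,
                    static_threshold = 4, localization_var_px2 = 0.1,
                    bead_margin_px = 5, collision_radius_px = 3),
    diffusion = list(blur_R = 1 / 6, min_steps = 5),
    dwell = list(K_max = 4L, B = 500L, alpha = 0.05, weight_floor = 0.01,
                 restarts = 10L),
    # TIRF simulation + analysis
    tirf = list(n_traces = 50L, duration_s = 600, frame_s = 0.100,
                bound_lifetimes = c(0.9, 8), bound_weights = c(0.7, 0.3),
                unbound_tau = 42, snr = 4, photobleach_rate = 1 / 1200,
                min_spikes = 2L, step_improve = 0.30),
    paths = list(out_dir = NULL)
  )
  overrides <- list(...)
  merge_config(defaults, overrides)
}

merge_config <- function(defaults, overrides) {
  structure(merge_lists(defaults, overrides),
            class = c("run_config", "list"))
}

merge_lists <- function(defaults, overrides) {
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) {
      stop("unknown config key: `", key, "`", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      defaults[[key]] <- merge_lists(defaults[[key]], overrides[[key]])
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates the configured number of kymographs and TIRF traces, then runs
#' every analysis stage: marker detection and calibration, event tracking
#' with static/diffusive segmentation and exclusion flags, combined
#' nick-enrichment profile, covariance-based diffusion summary, dwell-time
#' mixture selection (BIC + bootstrap unimodality), TIRF trace QC, HMM
#' idealization and cumulative-frequency lifetime fits. Returns a report
#' with every number plus a reproducibility manifest (seed, config digest,
#' package version, per-stage filter counts). A given config and seed give
#' an identical report.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` (nested list); written as JSON to
#'   `paths$out_dir` when that is set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  kc <- config$kymo; tc <- config$tracking

  # --- kymograph arm -------------------------------------------------------
  species <- binding_kinetics(
    arrival_rate = kc$arrival_rate, p_static_at_nick = kc$p_static,
    p_diffusive = kc$p_diffusive, p_transient = kc$p_transient,
    D_true = kc$D_true,
    dwell = list(static = exp_mixture(kc$static_tau, 1),
                 diffusive = exp_mixture(kc$diffusive_tau, 1),
                 transient = exp_mixture(kc$transient_tau, 1)),
    photon_rate = kc$photon_rate
  )
  profiles <- list(); all_D <- numeric(0); all_dwells <- numeric(0)
  counts <- list(tracked = 0L, excluded_bead = 0L, excluded_collision = 0L,
                 censored_dwells = 0L, short_segments = 0L)
  n_lines_total <- 0
  for (i in seq_len(kc$n_kymographs)) {
    scene <- kymo_scene(duration_s = kc$duration_s,
                        line_time_s = kc$line_time_s,
                        pixel_size_um = kc$pixel_size_um,
                        psf_sigma_um = kc$psf_sigma_um,
                        background_rate = kc$background_rate,
                        species = list(species),
                        seed = substream_seed(seed, paste0("kymo", i)))
    sim <- simulate_kymograph(scene)
    km <- sim$kymograph
    n_lines_total <- n_lines_total + nrow(km$green)
    marker_um <- detect_markers(km)
    cal <- fit_calibration(marker_um, scene$marker_positions_bp)
    profiles[[i]] <- binding_density_profile(km, cal)
    tracks <- track_events(km, link_radius_px = tc$link_radius_px,
                           max_gap_lines = tc$max_gap_lines,
                           min_length_lines = tc$min_length_lines)
    tracks <- lapply(tracks, classify_segments,
                     window_lines = tc$window_lines,
                     static_threshold = tc$static_threshold,
                     localization_var_px2 = tc$localization_var_px2)
    tracks <- exclude_tracks(tracks, km$bead_edges_px,
                             bead_margin_px = tc$bead_margin_px,
                             collision_radius_px = tc$collision_radius_px)
    counts$tracked <- counts$tracked + length(tracks)
    reasons <- vapply(tracks, function(t)
      if (is.na(t$reason)) "" else t$reason, character(1))
    counts$excluded_bead <- counts$excluded_bead + sum(reasons == "bead")
    counts$excluded_collision <- counts$excluded_collision +
      sum(reasons == "collision")
    kbp_per_px <- abs(cal$slope_bp_per_um) * km$pixel_size_um / 1000
    n_lines <- nrow(km$green)
    for (tr in tracks) {
      if (tr$excluded) next
      # dwell: only events fully inside the observation window (uncensored)
      if (min(tr$frames) == 0 || max(tr$frames) >= n_lines - 1) {
        counts$censored_dwells <- counts$censored_dwells + 1L
        next
      }
      all_dwells <- c(all_dwells,
                      (diff(range(tr$frames)) + 1) * km$line_time_s)
      for (si in seq_len(nrow(tr$segments))) {
        if (tr$segments$label[si] != "diffusive") next
        idx <- (tr$segments$start[si] + 1L):tr$segments$end[si]
        if (length(idx) < config$diffusion$min_steps + 1) {
          counts$short_segments <- counts$short_segments + 1L
          next
        }
        pos_kbp <- tr$positions_px[idx] * kbp_per_px
        frames <- tr$frames[idx]
        if (length(unique(diff(frames))) > 1L) {
          pos_kbp <- stats::approx(frames, pos_kbp,
                                   xout = seq(min(frames), max(frames)))$y
        }
        est <- tryCatch(
          cve_estimate(pos_kbp, km$line_time_s,
                       blur_R = config$diffusion$blur_R,
                       min_steps = config$diffusion$min_steps),
          error = function(e) NULL
        )
        if (!is.null(est)) all_D <- c(all_D, est$D_hat)
      }
    }
  }
  observation_s <- n_lines_total * kc$line_time_s
  d_summary <- if (length(all_D) >= 2) summarize_D(all_D) else NULL
  dwell_sel <- NULL
  if (length(all_dwells) >= 12) {
    ds <- dwell_set(pmax(all_dwells, kc$line_time_s), t_min = kc$line_time_s)
    dwell_sel <- select_model(ds, K_max = min(config$dwell$K_max,
                                              (length(all_dwells) - 5) %/% 2),
                              B = config$dwell$B,
                              seed = substream_seed(seed, "dwell"),
                              alpha = config$dwell$alpha,
                              weight_floor = config$dwell$weight_floor,
                              restarts = config$dwell$restarts)
  }
  combined <- combine_profiles(profiles)

  # --- TIRF arm ------------------------------------------------------------
  tf <- config$tirf
  bound_mix <- exp_mixture(tf$bound_lifetimes, tf$bound_weights)
  sdn <- 300 / tf$snr
  traces <- lapply(seq_len(tf$n_traces), function(i) {
    simulate_tirf_trace(bound_mix, tf$unbound_tau,
                        duration_s = tf$duration_s, frame_s = tf$frame_s,
                        noise = list(bound_mean = 400, unbound_mean = 100,
                                     sd_bound = sdn, sd_unbound = sdn),
                        photobleach_rate = tf$photobleach_rate,
                        seed = substream_seed(seed, paste0("tirf", i)),
                        trace_id = sprintf("trace_%04d", i))$trace
  })
  sel <- select_traces(traces, min_spikes = tf$min_spikes,
                       improve = tf$step_improve)
  ideals <- lapply(sel$accepted, function(a) hmm_idealize(a$cy5))
  bound_d <- numeric(0); unbound_d <- numeric(0)
  for (id in ideals) {
    dw <- extract_dwells(id, tf$frame_s)
    if (!is.null(dw$bound)) bound_d <- c(bound_d, dw$bound$durations_s)
    if (!is.null(dw$unbound)) unbound_d <- c(unbound_d, dw$unbound$durations_s)
  }
  tirf_fits <- list()
  if (length(bound_d) >= 20) {
    tirf_fits$bound <- fit_cdf_lsq(
      dwell_set(bound_d, t_min = tf$frame_s, kind = "bound"))
  }
  if (length(unbound_d) >= 20) {
    tirf_fits$unbound <- fit_cdf_lsq(
      dwell_set(unbound_d, t_min = tf$frame_s, kind = "unbound"), K = 1)
  }

  report <- structure(list(
    manifest = list(seed = seed, config_digest = config_digest(config),
                    package_version =
                      as.character(utils::packageVersion("nicksearch")),
                    counts = counts,
                    tirf_accepted = sum(sel$qc$accepted),
                    tirf_total = nrow(sel$qc)),
    kymo = list(
      n_kymographs = kc$n_kymographs,
      event_frequency_per_min =
        length(all_dwells) * 60 / observation_s,
      diffusion = d_summary,
      dwell_selection = if (!is.null(dwell_sel)) list(
        chosen_K = dwell_sel$chosen_K,
        gate_failed = dwell_sel$gate_failed,
        lifetimes = lifetime_table(dwell_sel$fit)
      ),
      profile_peaks_bp = profile_peaks(combined),
      profile = combined
    ),
    tirf = list(
      qc = sel$qc,
      n_bound_dwells = length(bound_d),
      n_unbound_dwells = length(unbound_d),
      bound_fit = if (!is.null(tirf_fits$bound))
        lifetime_table(tirf_fits$bound),
      unbound_fit = if (!is.null(tirf_fits$unbound))
        lifetime_table(tirf_fits$unbound)
    )
  ), class = "pipeline_report")

  if (!is.null(config$paths$out_dir)) {
    dir.create(config$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
    rep_json <- report
    rep_json$kymo$profile <- NULL  # full curve goes to its own CSV
    jsonlite::write_json(
      rep_json, file.path(config$paths$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    write_profile_csv(combined,
                      file.path(config$paths$out_dir, "profile.csv"))
  }
  report
}

# (lifetime, percentage) rows in the layout of the standard lifetime figure
lifetime_table <- function(fit) {
  data.frame(lifetime_s = fit$lifetimes, percentage = 100 * fit$weights)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  cat(sprintf("  seed %s, config %s\n", x$manifest$seed,
              substr(x$manifest$config_digest, 1, 8)))
  cat(sprintf("  kymo: %d tracked events, %.1f events/min\n",
              x$manifest$counts$tracked, x$kymo$event_frequency_per_min))
  if (!is.null(x$kymo$diffusion)) {
    cat(sprintf("  D = %.3g +/- %.2g kbp^2/s (n = %d)\n",
                x$kymo$diffusion$mean, x$kymo$diffusion$sem,
                x$kymo$diffusion$n))
  }
  if (!is.null(x$kymo$dwell_selection)) {
    cat(sprintf("  dwell model: K = %d\n", x$kymo$dwell_selection$chosen_K))
  }
  cat(sprintf("  tirf: %d/%d traces accepted\n", x$manifest$tirf_accepted,
              x$manifest$tirf_total))
  invisible(x)
}
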