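#' Scene description for a synthetic kymograph
#'
#' Geometry and acquisition settings of a dual-trap confocal experiment: a
#' lambda-phage-length DNA held between two beads, nick sites and two red
#' marker fluorophores at known bp coordinates, and one or more labelled
#' protein species binding from solution. Basepair positions map to microns
#' through a single linear stretch factor (the DNA spans the bead gap);
#' downstream calibration never assumes this factor, it re-derives the map
#' from the detected markers.
#'
#' @param dna_length_bp tether length (bp).
#' @param nick_positions_bp strictly increasing nick coordinates (bp).
#' @param marker_positions_bp red marker coordinates (bp); default the two
#'   ATTO647N positions of the experimental substrate.
#' @param bead_edges_um inner bead-surface positions (um) in image
#'   coordinates; the DNA spans this gap.
#' @param species list of [binding_kinetics()] objects.
#' @param pixel_size_um confocal pixel size (um).
#' @param line_time_s scan line time (s); 0.040 in the experiment.
#' @param psf_sigma_um Gaussian point-spread sigma (um).
#' @param background_rate mean background photons per pixel per line.
#' @param marker_photon_rate photons per line per marker while excited.
#' @param marker_duty fraction of a `marker_period_lines` block during which
#'   the red markers are excited (intermittent excitation extends dye
#'   lifetime in the experiment; 1 = continuous).
#' @param marker_period_lines length of the marker excitation cycle (lines).
#' @param duration_s acquisition time (s), > 0.
#' @param seed integer seed for the scene's randomness.
#' @return an object of class `kymo_scene`.
#' @export
kymo_scene <- function(dna_length_bp = 48500,
                       nick_positions_bp = default_nick_positions(),
                       marker_positions_bp = c(33786, 44826),
                       bead_edges_um = c(1.5, 16.5),
                       species = list(),
                       pixel_size_um = 0.1,
                       line_time_s = 0.040,
                       psf_sigma_um = 0.15,
                       background_rate = 2,
                       marker_photon_rate = 120,
                       marker_duty = 1,
                       marker_period_lines = 20,
                       duration_s = 60,
                       seed = NULL) {
  if (line_time_s <= 0) stop("`line_time_s` must be positive", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  allpos <- c(nick_positions_bp, marker_positions_bp)
  if (any(allpos < 0 | allpos > dna_length_bp)) {
    stop("all bp positions must lie within [0, dna_length_bp]", call. = FALSE)
  }
  if (is.unsorted(nick_positions_bp, strictly = TRUE)) {
    stop("`nick_positions_bp` must be strictly increasing", call. = FALSE)
  }
  if (bead_edges_um[2] <= bead_edges_um[1]) {
    stop("`bead_edges_um` must be an increasing pair", call. = FALSE)
  }
  structure(as.list(environment()), class = "kymo_scene")
}

# bp -> um for a scene: the tether spans the bead gap linearly.
scene_bp_to_um <- function(scene, bp) {
  scene$bead_edges_um[1] +
    bp / scene$dna_length_bp * diff(scene$bead_edges_um)
}

#' Two-channel kymograph container
#'
#' @param green,red photon-count matrices, scan lines in rows and pixels in
#'   columns (line 0 at acquisition start, pixel 0 at the image's left edge;
#'   a pixel's centre sits at `pixel * pixel_size_um` um).
#' @param line_time_s scan line time (s).
#' @param pixel_size_um pixel size (um).
#' @param bead_edges_px inner bead-edge positions in (fractional) pixels.
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(green, red, line_time_s, pixel_size_um, bead_edges_px) {
  green <- as.matrix(green); red <- as.matrix(red)
  if (!all(dim(green) == dim(red))) {
    stop("`green` and `red` must have identical dimensions", call. = FALSE)
  }
  if (any(green < 0) || any(red < 0)) {
    stop("photon counts must be nonnegative", call. = FALSE)
  }
  if (line_time_s <= 0) stop("`line_time_s` must be positive", call. = FALSE)
  structure(list(green = green, red = red, line_time_s = line_time_s,
                 pixel_size_um = pixel_size_um,
                 bead_edges_px = bead_edges_px),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d lines x %d pixels, %g ms/line, %g um/px\n",
              nrow(x$green), ncol(x$green), 1000 * x$line_time_s,
              x$pixel_size_um))
  invisible(x)
}

# Add one emitter's expected photons to a rate matrix. `lines` are 1-based
# row indices, `pos_um` the emitter position per line; the PSF is integrated
# over each pixel.
add_emitter_rate <- function(rate, lines, pos_um, photons_per_line,
                             pixel_size_um, psf_sigma_um) {
  n_px <- ncol(rate)
  half_w <- ceiling(4 * psf_sigma_um / pixel_size_um)
  for (j in seq_along(lines)) {
    centre_px <- pos_um[j] / pixel_size_um
    px <- max(0L, floor(centre_px) - half_w):min(n_px - 1L, ceiling(centre_px) + half_w)
    if (!length(px)) next
    edges_lo <- (px - 0.5) * pixel_size_um
    edges_hi <- (px + 0.5) * pixel_size_um
    frac <- stats::pnorm(edges_hi, pos_um[j], psf_sigma_um) -
      stats::pnorm(edges_lo, pos_um[j], psf_sigma_um)
    rate[lines[j], px + 1L] <- rate[lines[j], px + 1L] + photons_per_line * frac
  }
  rate
}

#' Render a synthetic two-channel kymograph
#'
#' Simulates ground-truth binding timelines for every species in the scene,
#' renders each bound molecule as a 1D Gaussian point-spread function sampled
#' once per scan line with Poisson photon noise on top of a Poisson
#' background, and renders the red channel from the marker fluorophores
#' (optionally excited intermittently). The ground truth is returned with the
#' image, so tracking and diffusion estimates can be scored exactly.
#'
#' @param scene a [kymo_scene()].
#' @return a list with elements `kymograph` (a [kymograph()]) and `truth`
#'   (list of `ground_truth` objects, one per species).
#' @export
simulate_kymograph <- function(scene) {
  stopifnot(inherits(scene, "kymo_scene"))
  with_seed(scene$seed, {
    n_lines <- max(1L, floor(scene$duration_s / scene$line_time_s))
    span_um <- scene$bead_edges_um[2] + scene$bead_edges_um[1]
    n_px <- ceiling(span_um / scene$pixel_size_um) + 1L
    g_rate <- matrix(scene$background_rate, n_lines, n_px)
    r_rate <- matrix(scene$background_rate, n_lines, n_px)

    truths <- vector("list", length(scene$species))
    for (s in seq_along(scene$species)) {
      truth <- simulate_binding_timeline(
        scene$species[[s]], scene$duration_s,
        dna_length_bp = scene$dna_length_bp,
        nick_positions_bp = scene$nick_positions_bp,
        line_time_s = scene$line_time_s
      )
      truths[[s]] <- truth
      ev <- truth$events
      for (i in seq_len(nrow(ev))) {
        l0 <- floor(ev$start_s[i] / scene$line_time_s)
        lines <- l0 + seq_along(truth$paths[[i]]) - 1L
        keep <- lines < n_lines
        if (!any(keep)) next
        pos_um <- scene_bp_to_um(scene, truth$paths[[i]][keep])
        g_rate <- add_emitter_rate(g_rate, lines[keep] + 1L, pos_um,
                                   scene$species[[s]]$photon_rate,
                                   scene$pixel_size_um, scene$psf_sigma_um)
      }
    }

    # markers: deterministic duty cycle within each excitation period
    on_lines <- which((((seq_len(n_lines) - 1L) %% scene$marker_period_lines) /
                         scene$marker_period_lines) < scene$marker_duty)
    if (length(on_lines)) {
      for (m_bp in scene$marker_positions_bp) {
        m_um <- scene_bp_to_um(scene, m_bp)
        r_rate <- add_emitter_rate(r_rate, on_lines,
                                   rep(m_um, length(on_lines)),
                                   scene$marker_photon_rate,
                                   scene$pixel_size_um, scene$psf_sigma_um)
      }
    }

    green <- matrix(stats::rpois(length(g_rate), g_rate), n_lines, n_px)
    red <- matrix(stats::rpois(length(r_rate), r_rate), n_lines, n_px)
    km <- kymograph(green, red, scene$line_time_s, scene$pixel_size_um,
                    bead_edges_px = scene$bead_edges_um / scene$pixel_size_um)
    list(kymograph = km, truth = truths)
  })
}
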