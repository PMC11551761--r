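#' Binding-density profile of a kymograph
#'
#' Averages the green channel over time, subtracts the background (median of
#' the dimmest 20% of pixels), maps pixel coordinates to bp through the
#' marker calibration, and normalizes so the highest peak equals one. On
#' nick-containing substrates the profile's local maxima mark the enriched
#' binding sites.
#'
#' @param kymo a [kymograph()].
#' @param cal a [fit_calibration()] object.
#' @param background_quantile fraction of dimmest pixels defining the
#'   background estimate.
#' @return a `density_profile`: `positions_bp` (ascending grid), `density`
#'   (max 1), `n_kymographs = 1`.
#' @export
binding_density_profile <- function(kymo, cal, background_quantile = 0.2) {
  stopifnot(inherits(kymo, "kymograph"), inherits(cal, "calibration"))
  avg <- colMeans(kymo$green)
  if (all(avg == 0)) {
    stop("flat profile: green channel is all zero", call. = FALSE)
  }
  bg <- stats::median(avg[avg <= stats::quantile(avg, background_quantile)])
  dens <- pmax(avg - bg, 0)
  if (max(dens) == 0) {
    stop("flat profile: no signal above background", call. = FALSE)
  }
  px <- seq_along(avg) - 1
  bp <- um_to_bp(cal, px * kymo$pixel_size_um)
  if (bp[1] > bp[length(bp)]) { bp <- rev(bp); dens <- rev(dens) }
  structure(list(positions_bp = bp, density = dens / max(dens),
                 n_kymographs = 1L),
            class = "density_profile")
}

#' Combine binding-density profiles from several kymographs
#'
#' Interpolates each profile onto a common bp grid (the overlap of all
#' profiles, at the finest input spacing), sums them, and renormalizes the
#' sum to a maximum of one.
#'
#' @param profiles list of `density_profile`s (>= 1).
#' @return a combined `density_profile` with `n_kymographs` equal to the
#'   total count.
#' @export
combine_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  lapply(profiles, function(p) stopifnot(inherits(p, "density_profile")))
  lo <- max(vapply(profiles, function(p) min(p$positions_bp), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$positions_bp), numeric(1)))
  if (lo >= hi) {
    stop("profiles do not overlap in bp range", call. = FALSE)
  }
  step <- min(vapply(profiles, function(p) stats::median(diff(p$positions_bp)),
                     numeric(1)))
  grid <- seq(lo, hi, by = step)
  total <- rep(0, length(grid))
  for (p in profiles) {
    total <- total + stats::approx(p$positions_bp, p$density, xout = grid)$y
  }
  structure(list(positions_bp = grid, density = total / max(total),
                 n_kymographs = sum(vapply(profiles, function(p)
                   p$n_kymographs, integer(1)))),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d points, %.1f-%.1f kbp, %d kymograph(s)\n",
              length(x$density), min(x$positions_bp) / 1000,
              max(x$positions_bp) / 1000, x$n_kymographs))
  invisible(x)
}

#' Local maxima of a density profile
#'
#' Convenience for scoring nick enrichment: positions (bp) of profile peaks
#' above `min_height`, with non-maximum suppression over `min_sep_bp`.
#'
#' @param profile a `density_profile`.
#' @param min_height minimum normalized density of a reported peak.
#' @param min_sep_bp minimum separation between reported peaks (bp).
#' @return numeric vector of peak positions (bp).
#' @export
profile_peaks <- function(profile, min_height = 0.1, min_sep_bp = 1500) {
  stopifnot(inherits(profile, "density_profile"))
  step <- stats::median(diff(profile$positions_bp))
  idx <- local_maxima(profile$density, min_height,
                      min_sep = max(1L, round(min_sep_bp / step)))
  profile$positions_bp[idx]
}
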