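#' Detect marker fluorophores on the red kymograph channel
#'
#' Averages the red channel over time, finds persistent intensity columns as
#' local maxima above a robust threshold, and refines each to sub-pixel
#' precision with a Gaussian fit to the averaged profile around the maximum.
#'
#' @param red photon-count matrix (lines x pixels) or a [kymograph()] (its
#'   red channel is used).
#' @param pixel_size_um pixel size (um); taken from the kymograph when one is
#'   passed.
#' @param expected_n number of markers expected (2 for the standard
#'   substrate).
#' @param threshold intensity threshold on the time-averaged profile;
#'   default `median + 4 * MAD` of the profile.
#' @param window_px half-width of the fit window around each maximum.
#' @return numeric vector of `expected_n` marker positions (um), ascending.
#' @export
detect_markers <- function(red, pixel_size_um = NULL, expected_n = 2,
                           threshold = NULL, window_px = 4) {
  if (inherits(red, "kymograph")) {
    pixel_size_um <- red$pixel_size_um
    red <- red$red
  }
  if (is.null(pixel_size_um)) {
    stop("`pixel_size_um` is required when `red` is a plain matrix",
         call. = FALSE)
  }
  profile <- colMeans(red)
  if (is.null(threshold)) {
    threshold <- stats::median(profile) + 4 * stats::mad(profile)
  }
  peaks <- local_maxima(profile, threshold, min_sep = 2L * window_px)
  if (length(peaks) < expected_n) {
    stop(sprintf("marker detection failed: found %d peak(s), expected %d",
                 length(peaks), expected_n), call. = FALSE)
  }
  # keep the expected_n brightest persistent columns
  peaks <- peaks[order(profile[peaks], decreasing = TRUE)][seq_len(expected_n)]
  pos_px <- vapply(peaks, function(p) {
    gaussian_refine(profile, p, window_px)
  }, numeric(1))
  sort(pos_px) * pixel_size_um
}

# Local maxima of a profile above `threshold`, separated by >= min_sep px.
local_maxima <- function(profile, threshold, min_sep = 3L) {
  n <- length(profile)
  idx <- which(profile > threshold)
  idx <- idx[idx > 1 & idx < n]
  idx <- idx[profile[idx] >= profile[idx - 1] & profile[idx] >= profile[idx + 1]]
  if (!length(idx)) return(integer(0))
  # greedy suppression, brightest first
  keep <- integer(0)
  for (i in idx[order(profile[idx], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# Sub-pixel refinement by a Gaussian least-squares fit (amplitude, centre,
# width, offset) over a window around `peak` (1-based index). Falls back to
# the three-point parabolic-log estimate if the fit fails. Returns a 0-based
# pixel coordinate.
gaussian_refine <- function(profile, peak, window_px = 4) {
  n <- length(profile)
  lo <- max(1L, peak - window_px); hi <- min(n, peak + window_px)
  x <- (lo:hi) - 1  # 0-based pixel coordinates
  y <- profile[lo:hi]
  fallback <- function() {
    if (peak <= 1L || peak >= n) return(peak - 1)
    yc <- pmax(profile[(peak - 1):(peak + 1)], 1e-12)
    ly <- log(yc)
    denom <- ly[1] - 2 * ly[2] + ly[3]
    if (denom >= 0) return(peak - 1)
    (peak - 1) + 0.5 * (ly[1] - ly[3]) / denom
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * s^2)) + b,
      start = list(a = max(y) - min(y), mu = peak - 1, s = 1.5, b = min(y)),
      lower = c(0, lo - 1, 0.3, 0),
      upper = c(Inf, hi - 1, window_px, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fallback())
  stats::coef(fit)[["mu"]]
}

#' Two-point micron-to-basepair calibration from marker positions
#'
#' The two red markers sit at known bp coordinates on the substrate; their
#' detected um positions define an exact linear map between image coordinates
#' and position along the DNA, used to place binding events in bp.
#'
#' @param marker_um detected marker positions (um), length 2, distinct.
#' @param marker_bp known marker coordinates (bp), length 2; default the
#'   substrate's ATTO647N positions.
#' @return an object of class `calibration` with fields `slope_bp_per_um`,
#'   `intercept_bp`, `marker_um`, `marker_bp`.
#' @examples
#' cal <- fit_calibration(c(10, 14), c(33786, 44826))
#' um_to_bp(cal, 12)  # 39306 bp
#' @export
fit_calibration <- function(marker_um, marker_bp = c(33786, 44826)) {
  stopifnot(length(marker_um) == 2, length(marker_bp) == 2)
  ou <- order(marker_um); ob <- order(marker_bp)
  marker_um <- marker_um[ou]; marker_bp <- marker_bp[ob]
  if (abs(diff(marker_um)) < 1e-12) {
    stop("degenerate calibration: coincident marker positions", call. = FALSE)
  }
  slope <- diff(marker_bp) / diff(marker_um)
  intercept <- marker_bp[1] - slope * marker_um[1]
  structure(list(slope_bp_per_um = slope, intercept_bp = intercept,
                 marker_um = marker_um, marker_bp = marker_bp),
            class = "calibration")
}

#' Convert between image (um) and DNA (bp) coordinates
#' @param cal a [fit_calibration()] object.
#' @param um,bp coordinates to convert.
#' @return converted coordinates.
#' @export
um_to_bp <- function(cal, um) {
  stopifnot(inherits(cal, "calibration"))
  cal$slope_bp_per_um * um + cal$intercept_bp
}

#' @rdname um_to_bp
#' @export
bp_to_um <- function(cal, bp) {
  stopifnot(inherits(cal, "calibration"))
  (bp - cal$intercept_bp) / cal$slope_bp_per_um
}
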