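#' Extensible worm-like chain extension
#'
#' High-force (Odijk) approximation for the extension of double-stranded DNA
#' under tension: entropic shortening from thermal bending plus enthalpic
#' backbone stretching,
#' \deqn{x(F) = L_c \left(1 - \tfrac{1}{2}\sqrt{kT/(F L_p)} + F/K\right).}
#' Defaults are standard lambda-DNA values at 25 C.
#'
#' @param force_pN applied force (pN), strictly positive (scalar or vector).
#' @param contour_um contour length \eqn{L_c} (um).
#' @param persistence_nm persistence length \eqn{L_p} (nm).
#' @param stretch_modulus_pN enthalpic stretch modulus \eqn{K} (pN).
#' @param kT_pN_nm thermal energy (pN nm).
#' @return extension (um), same length as `force_pN`; strictly increasing
#'   in force.
#' @examples
#' ewlc_extension(10)  # ~15.9 um for lambda DNA
#' @export
ewlc_extension <- function(force_pN, contour_um = 16.5, persistence_nm = 50,
                           stretch_modulus_pN = 1200, kT_pN_nm = 4.114) {
  if (any(force_pN <= 0)) {
    stop("`force_pN` must be strictly positive", call. = FALSE)
  }
  contour_um * (1 - 0.5 * sqrt(kT_pN_nm / (force_pN * persistence_nm)) +
                  force_pN / stretch_modulus_pN)
}

# Invert ewlc_extension numerically: force (pN) at a given extension (um).
ewlc_force_at <- function(extension_um, contour_um = 16.5,
                          persistence_nm = 50, stretch_modulus_pN = 1200,
                          kT_pN_nm = 4.114, interval = c(1e-4, 500)) {
  vapply(extension_um, function(x) {
    f <- function(F) ewlc_extension(F, contour_um, persistence_nm,
                                    stretch_modulus_pN, kT_pN_nm) - x
    lo <- f(interval[1]); hi <- f(interval[2])
    if (lo > 0) return(interval[1])
    if (hi < 0) return(interval[2])
    stats::uniroot(f, interval, tol = 1e-9)$root
  }, numeric(1))
}

#' Verify that a force-distance curve matches a single dsDNA tether
#'
#' Fits the extensible worm-like chain curve to a measured force-distance
#' table with the contour length free (persistence length, stretch modulus
#' and kT fixed) and accepts the tether when the RMS force residual is below
#' `rms_threshold_pN` and the fitted contour length is within 10% of the
#' nominal value. A doubled tether shares the force between two molecules and
#' fails both checks.
#'
#' @param force_pN,distance_um measured curve; at least 10 points with force
#'   in (1, 30) pN are required.
#' @param nominal_contour_um expected contour length (um).
#' @param persistence_nm,stretch_modulus_pN,kT_pN_nm fixed model parameters.
#' @param rms_threshold_pN acceptance threshold on the RMS force residual.
#' @return logical scalar with attributes `contour_um_fit` and `rms_pN`.
#' @export
check_single_tether <- function(force_pN, distance_um,
                                nominal_contour_um = 16.5,
                                persistence_nm = 50,
                                stretch_modulus_pN = 1200,
                                kT_pN_nm = 4.114,
                                rms_threshold_pN = 0.5) {
  keep <- force_pN > 1 & force_pN < 30
  if (sum(keep) < 10) {
    stop("need at least 10 points with force in (1, 30) pN, got ",
         sum(keep), call. = FALSE)
  }
  f <- force_pN[keep]; d <- distance_um[keep]
  rms_at <- function(Lc) {
    pred <- ewlc_force_at(d, contour_um = Lc, persistence_nm = persistence_nm,
                          stretch_modulus_pN = stretch_modulus_pN,
                          kT_pN_nm = kT_pN_nm)
    sqrt(mean((pred - f)^2))
  }
  opt <- stats::optimize(rms_at, nominal_contour_um * c(0.4, 1.6))
  ok <- opt$objective < rms_threshold_pN &&
    abs(opt$minimum - nominal_contour_um) <= 0.1 * nominal_contour_um
  structure(ok, contour_um_fit = opt$minimum, rms_pN = opt$objective)
}
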