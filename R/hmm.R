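#' Idealize a protein-channel intensity segment with a two-state HMM
#'
#' Trains a two-state hidden Markov model with Gaussian emissions on the
#' Cy5 intensity series by expectation-maximization (scaled
#' forward-backward), then decodes the most probable state path by Viterbi
#' dynamic programming. State 1 is always the higher-mean (bound) state.
#' Initialization uses the 20th/80th intensity percentiles as state means;
#' the EM log-likelihood is non-decreasing by construction and training
#' stops when the per-iteration gain falls below `tol`.
#'
#' @param cy5 numeric intensity series (>= 20 frames).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param min_separation_sd minimum separation of the two fitted state means
#'   in units of their pooled emission sd; when the fitted states are closer
#'   than this the trace carries no resolvable two-level signal (e.g. no
#'   binding event in the window) and the EM has merely split the noise, so
#'   the result is returned as a flagged single-state (all-unbound)
#'   idealization rather than a spurious fast-flickering path.
#' @return an `idealization`: `states` (integer 0/1 per frame),
#'   `state_means`, `state_vars`, `transition_matrix` (rows sum to 1),
#'   `loglik`, `loglik_trace`, `converged`, `degenerate`.
#' @export
hmm_idealize <- function(cy5, tol = 1e-6, max_iter = 500,
                         min_separation_sd = 3) {
  cy5 <- as.numeric(cy5)
  n <- length(cy5)
  if (n < 20) stop("segment too short for idealization (< 20 frames)",
                   call. = FALSE)
  if (stats::sd(cy5) < 1e-12) {
    # constant segment: single-state result, flagged
    return(structure(
      list(states = rep(0L, n), state_means = c(cy5[1], cy5[1]),
           state_vars = c(0, 0),
           transition_matrix = matrix(c(1, 0, 1, 0), 2, byrow = TRUE),
           loglik = NA_real_, loglik_trace = numeric(0),
           converged = TRUE, degenerate = TRUE),
      class = "idealization"
    ))
  }
  q <- stats::quantile(cy5, c(0.2, 0.8), names = FALSE)
  if (diff(q) < 1e-9) q <- q + c(-1, 1) * stats::sd(cy5) / 2
  v0 <- rep(max(stats::var(cy5) / 4, 1e-8), 2)
  em <- .hmm2_em(cy5, q, v0,
                 matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE),
                 c(0.5, 0.5), as.integer(max_iter), tol)
  # order states so that state 1 has the higher emission mean
  ord <- order(em$means)  # ord[1] -> state 0, ord[2] -> state 1
  means <- em$means[ord]; vars <- em$vars[ord]
  trans <- em$trans[ord, ord, drop = FALSE]
  init <- em$init[ord]
  pooled_sd <- sqrt(mean(vars))
  if (diff(means) < min_separation_sd * pooled_sd) {
    return(structure(
      list(states = rep(0L, n), state_means = means, state_vars = vars,
           transition_matrix = trans, loglik = em$loglik,
           loglik_trace = em$loglik_trace, converged = em$converged,
           degenerate = TRUE),
      class = "idealization"
    ))
  }
  path <- .hmm2_viterbi(cy5, means, vars, trans, init)
  structure(
    list(states = as.integer(path), state_means = means, state_vars = vars,
         transition_matrix = trans, loglik = em$loglik,
         loglik_trace = em$loglik_trace, converged = em$converged,
         degenerate = FALSE),
    class = "idealization"
  )
}

#' @export
print.idealization <- function(x, ...) {
  cat(sprintf(
    "idealization: %d frames, %.1f%% bound, means %.1f/%.1f, loglik %.2f\n",
    length(x$states), 100 * mean(x$states), x$state_means[1],
    x$state_means[2], x$loglik))
  invisible(x)
}

#' Extract bound and unbound dwell times from an idealized trace
#'
#' Run-length encodes the state path and multiplies by the frame time. The
#' first and last runs touch the observation window's edges and are censored
#' (their true duration is unknown); they are excluded by default and
#' reported in the `censored_s` attribute. All runs together always account
#' for the full segment duration.
#'
#' @param ideal an [hmm_idealize()] result (or integer 0/1 vector).
#' @param frame_s frame time (s).
#' @param drop_edges exclude the edge-censored first/last runs.
#' @return list `bound` and `unbound` ([dwell_set()]s or `NULL` when empty),
#'   `censored_s` (durations of dropped runs), `total_s`.
#' @export
extract_dwells <- function(ideal, frame_s, drop_edges = TRUE) {
  states <- if (inherits(ideal, "idealization")) ideal$states else
    as.integer(ideal)
  r <- rle(states)
  dur <- r$lengths * frame_s
  keep <- rep(TRUE, length(dur))
  if (drop_edges && length(dur) > 0) {
    keep[1] <- FALSE
    keep[length(dur)] <- FALSE
  }
  bound_d <- dur[keep & r$values == 1L]
  unbound_d <- dur[keep & r$values == 0L]
  mk <- function(d, kind) {
    if (!length(d)) return(NULL)
    dwell_set(d, t_min = frame_s, kind = kind)
  }
  list(bound = mk(bound_d, "bound"), unbound = mk(unbound_d, "unbound"),
       censored_s = dur[!keep], total_s = sum(dur))
}
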