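#' Maximum-likelihood fit of an exponential-mixture dwell model
#'
#' Fits a K-component exponential mixture to a dwell set by
#' expectation-maximization, with the left-truncation threshold of the dwell
#' set handled exactly: conditioned on `t >= t_min`, the shifted dwells
#' `t - t_min` again follow an exponential mixture with the same lifetimes
#' and re-tilted weights \eqn{\tilde a_k \propto a_k e^{-t_{min}/\tau_k}}, so
#' the EM runs on the shifted data and the weights are un-tilted afterwards.
#' Initialization uses log-spaced lifetimes between the smallest and largest
#' dwell with equal weights; `restarts - 1` additional jittered starts guard
#' against local maxima and the best log-likelihood wins.
#'
#' @param dwells a [dwell_set()].
#' @param K number of components (1-4); requires `n >= 2K + 5`.
#' @param restarts number of EM starts.
#' @param seed optional integer seed (jitter and any ties are then
#'   reproducible).
#' @param tol EM stops when the log-likelihood gain drops below this.
#' @param max_iter maximum EM iterations per start.
#' @param init optional [exp_mixture()] used as the (single) starting point,
#'   e.g. the point estimate when refitting bootstrap resamples.
#' @return an `exp_mixture_fit`: `K`, `lifetimes` (ascending), `weights`,
#'   `loglik`, `bic`, `n`, `t_min_s`, `converged`.
#' @export
fit_mixture <- function(dwells, K, restarts = 10, seed = NULL, tol = 1e-8,
                        max_iter = 2000, init = NULL) {
  stopifnot(inherits(dwells, "dwell_set"))
  if (K < 1 || K > 4) stop("K must be between 1 and 4", call. = FALSE)
  n <- length(dwells$durations_s)
  # K = 1 has a closed form valid for any n; mixtures need headroom
  n_min <- if (K == 1) 1L else 2L * K + 5L
  if (n < n_min) {
    stop(sprintf("K = %d needs at least %d dwells, got %d", K, n_min, n),
         call. = FALSE)
  }
  s <- dwells$durations_s - dwells$t_min_s
  s <- pmax(s, 1e-12)  # dwells exactly at the detection limit

  if (K == 1) {
    tau <- mean(s)  # closed-form MLE of a (shifted) exponential
    ll <- sum(stats::dexp(s, 1 / tau, log = TRUE))
    return(new_fit(1L, tau, 1, ll, n, dwells$t_min_s, TRUE))
  }

  with_seed(seed, {
    # log-spaced between inner quantiles: anchoring the fastest start at the
    # sample minimum invites the classic single-point degeneracy (tau -> the
    # smallest dwell with weight 1/n), a spurious likelihood spike
    q <- stats::quantile(s, c(0.10, 0.90), names = FALSE)
    base_tau <- exp(seq(log(max(q[1], 1e-6)), log(max(q[2], 2e-6)),
                        length.out = K))
    starts <- vector("list", restarts)
    if (!is.null(init)) {
      stopifnot(inherits(init, "exp_mixture"), init$K == K)
      # tilt the supplied weights into shifted-data space
      w <- init$weights * exp(-dwells$t_min_s / init$lifetimes)
      starts <- list(list(tau = init$lifetimes, w = w / sum(w)))
    } else {
      starts[[1]] <- list(tau = base_tau, w = rep(1 / K, K))
      for (r in seq_len(restarts - 1)) {
        starts[[r + 1]] <- list(
          tau = base_tau * exp(stats::rnorm(K, 0, 0.6)),
          w = {
            w <- stats::rexp(K); w / sum(w)
          }
        )
      }
    }
    best <- NULL
    for (st in starts) {
      fit <- em_exp_mixture(s, st$tau, st$w, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    # un-tilt weights back to the untruncated parameterization
    a <- best$w * exp(dwells$t_min_s / best$tau)
    a <- a / sum(a)
    ord <- order(best$tau)
    new_fit(as.integer(K), best$tau[ord], a[ord], best$loglik, n,
            dwells$t_min_s, best$converged)
  })
}

# EM for an untruncated exponential mixture on nonnegative data
# (compiled; see src/expmix_em.cpp).
em_exp_mixture <- function(s, tau, w, tol, max_iter) {
  .expmix_em(s, tau, w, tol, as.integer(max_iter))
}

new_fit <- function(K, lifetimes, weights, loglik, n, t_min_s, converged,
                    method = "mle") {
  structure(
    list(K = K, lifetimes = lifetimes, weights = weights, loglik = loglik,
         bic = bic_value(loglik, K, n), n = n, t_min_s = t_min_s,
         converged = converged, method = method,
         bootstrap = NULL, unimodal = NULL),
    class = "exp_mixture_fit"
  )
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  cat(sprintf("exp_mixture_fit (%s): K = %d, n = %d, loglik = %.3f, BIC = %.3f%s\n",
              x$method, x$K, x$n, x$loglik, x$bic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  for (k in seq_len(x$K)) {
    cat(sprintf("  tau = %8.4g s   weight = %5.1f%%\n",
                x$lifetimes[k], 100 * x$weights[k]))
  }
  invisible(x)
}

bic_value <- function(loglik, K, n) {
  (2 * K - 1) * log(n) - 2 * loglik
}

#' Bayesian information criterion of a mixture fit
#'
#' `BIC = p ln(n) - 2 loglik` with `p = 2K - 1` free parameters (K lifetimes
#' and K - 1 independent weights).
#'
#' @param fit an `exp_mixture_fit` (must have converged).
#' @param n sample size; defaults to the fit's own.
#' @return the BIC value (lower is better).
#' @export
bic <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "exp_mixture_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  bic_value(fit$loglik, fit$K, n)
}

#' Bootstrap uncertainty of mixture parameters
#'
#' Nonparametric bootstrap: B resamples of the dwell set (with replacement,
#' same n), each refit by EM initialized at the point estimate. Components
#' are matched across resamples by sorting lifetimes ascending. Resamples
#' whose refit does not converge are dropped and counted; more than 20%
#' drops sets a warning flag.
#'
#' @param dwells a [dwell_set()].
#' @param K number of components.
#' @param B number of resamples (>= 100).
#' @param seed optional integer seed.
#' @param fit optional precomputed point estimate (refit otherwise).
#' @return the point-estimate fit with `bootstrap`: list of `lifetimes` and
#'   `weights` matrices (rows = resamples), `n_dropped`, `warn_drops`.
#' @export
bootstrap_fit <- function(dwells, K, B = 500, seed = NULL, fit = NULL) {
  stopifnot(inherits(dwells, "dwell_set"))
  if (B < 100) stop("`B` must be at least 100", call. = FALSE)
  if (is.null(fit)) fit <- fit_mixture(dwells, K, seed = seed)
  point <- exp_mixture(fit$lifetimes, fit$weights)
  n <- length(dwells$durations_s)
  with_seed(if (is.null(seed)) NULL else substream_seed(seed, "bootstrap"), {
    taus <- matrix(NA_real_, B, K)
    ws <- matrix(NA_real_, B, K)
    dropped <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      ds <- dwell_set(dwells$durations_s[idx], t_min = dwells$t_min_s,
                      kind = dwells$kind)
      fb <- tryCatch(
        fit_mixture(ds, K, restarts = 1, init = point),
        error = function(e) NULL
      )
      if (is.null(fb) || !fb$converged) { dropped <- dropped + 1L; next }
      taus[b, ] <- fb$lifetimes
      ws[b, ] <- fb$weights
    }
    ok <- !is.na(taus[, 1])
    fit$bootstrap <- list(lifetimes = taus[ok, , drop = FALSE],
                          weights = ws[ok, , drop = FALSE],
                          n_dropped = dropped,
                          warn_drops = dropped > 0.2 * B)
    fit
  })
}

#' Unimodality gate for a bootstrap parameter distribution
#'
#' Operationalizes the visual check that the bootstrap distribution of each
#' fitted parameter has a single mode: Hartigan's dip test must fail to
#' reject unimodality at level `alpha`, and (for weight parameters) the
#' lower 5% quantile must exceed `weight_floor`, guarding against components
#' collapsing to zero weight in part of the resamples.
#'
#' @param samples numeric vector of bootstrap draws (>= 100).
#' @param alpha dip-test significance level.
#' @param weight_floor if non-`NULL`, `samples` are weights and their 5%
#'   quantile must exceed this floor.
#' @return logical scalar.
#' @export
unimodality_check <- function(samples, alpha = 0.05, weight_floor = NULL) {
  if (length(samples) < 100) {
    stop("need at least 100 bootstrap samples", call. = FALSE)
  }
  if (!is.null(weight_floor) &&
      stats::quantile(samples, 0.05, names = FALSE) <= weight_floor) {
    return(FALSE)
  }
  dip_test(samples)$p.value >= alpha
}

#' Select the mixture order by BIC gated on bootstrap unimodality
#'
#' Fits K = 1..`K_max` (where the dwell count allows), bootstraps each fit,
#' and among the converged fits whose every parameter passes the
#' unimodality gate returns the K with the lowest BIC; gated models within
#' `bic_margin` of each other resolve to the smaller K (parsimony). If no
#' model passes the gate the lowest-BIC converged model is returned with
#' `gate_failed = TRUE`.
#'
#' @param dwells a [dwell_set()].
#' @param K_max largest order screened.
#' @param B bootstrap resamples per order.
#' @param seed optional integer seed.
#' @param alpha dip-test level.
#' @param weight_floor weight-collapse floor.
#' @param bic_margin BIC difference treated as a tie.
#' @param restarts EM restarts for each point fit.
#' @return list `chosen_K`, `fit` (the chosen fit), `fits` (all orders),
#'   `gate` (per-order logical), `gate_failed`.
#' @export
select_model <- function(dwells, K_max = 4, B = 500, seed = NULL,
                         alpha = 0.05, weight_floor = 0.01, bic_margin = 2,
                         restarts = 10) {
  stopifnot(inherits(dwells, "dwell_set"))
  n <- length(dwells$durations_s)
  Ks <- seq_len(K_max)[2 * seq_len(K_max) + 5 <= n]
  if (!length(Ks)) stop("dwell set too small for any model", call. = FALSE)
  fits <- list(); gate <- logical(0)
  for (K in Ks) {
    f <- tryCatch(
      fit_mixture(dwells, K, restarts = restarts,
                  seed = if (is.null(seed)) NULL
                  else substream_seed(seed, paste0("fit", K))),
      error = function(e) NULL
    )
    if (is.null(f) || !f$converged) {
      fits[[as.character(K)]] <- f
      gate <- c(gate, FALSE)
      next
    }
    f <- bootstrap_fit(dwells, K, B = B,
                       seed = if (is.null(seed)) NULL
                       else substream_seed(seed, paste0("boot", K)),
                       fit = f)
    ok <- TRUE
    uni <- list()
    for (k in seq_len(K)) {
      u_tau <- unimodality_check(f$bootstrap$lifetimes[, k], alpha)
      u_w <- if (K > 1) {
        unimodality_check(f$bootstrap$weights[, k], alpha, weight_floor)
      } else TRUE
      uni[[k]] <- c(lifetime = u_tau, weight = u_w)
      ok <- ok && u_tau && u_w
    }
    f$unimodal <- uni
    fits[[as.character(K)]] <- f
    gate <- c(gate, ok)
  }
  conv <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  if (!any(conv)) stop("no converged model", call. = FALSE)
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic, numeric(1))
  pool <- if (any(gate & conv)) which(gate & conv) else which(conv)
  gate_failed <- !any(gate & conv)
  # parsimony tie-break: among pooled models within bic_margin of the best,
  # prefer the smallest K
  best_bic <- min(bics[pool])
  tied <- pool[bics[pool] <= best_bic + bic_margin]
  chosen <- tied[which.min(Ks[tied])]
  list(chosen_K = Ks[chosen], fit = fits[[chosen]], fits = fits,
       gate = stats::setNames(gate, Ks), gate_failed = gate_failed)
}
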