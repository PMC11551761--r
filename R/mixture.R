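#' Exponential-mixture dwell-time model
#'
#' Dwell times of single-molecule binding events are modelled throughout the
#' package as a finite mixture of exponentials with density
#' \deqn{f(t) = \sum_k a_k (1/\tau_k) e^{-t/\tau_k},}
#' where the lifetimes \eqn{\tau_k} are in seconds and the weights \eqn{a_k}
#' sum to one. Between one and four components are supported, matching the
#' model orders screened during dwell-time model selection.
#'
#' @param lifetimes numeric vector of component lifetimes \eqn{\tau_k} (s),
#'   all strictly positive.
#' @param weights numeric vector of component weights \eqn{a_k}; must sum to
#'   one (within 1e-9) and have the same length as `lifetimes`.
#' @return an object of class `exp_mixture`.
#' @examples
#' full_length <- exp_mixture(c(0.08, 0.74, 11), c(0.58, 0.27, 0.15))
#' mixture_mean(full_length)
#' @export
exp_mixture <- function(lifetimes, weights) {
  lifetimes <- as.numeric(lifetimes)
  weights <- as.numeric(weights)
  if (length(lifetimes) != length(weights)) {
    stop("`lifetimes` and `weights` must have the same length", call. = FALSE)
  }
  K <- length(lifetimes)
  if (K < 1L || K > 4L) {
    stop("between 1 and 4 mixture components are supported, got ", K,
         call. = FALSE)
  }
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0)) {
    stop("all lifetimes must be finite and strictly positive", call. = FALSE)
  }
  if (any(weights < 0)) {
    stop("mixture weights must be nonnegative", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("mixture weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  }
  ord <- order(lifetimes)
  structure(
    list(lifetimes = lifetimes[ord], weights = weights[ord], K = K),
    class = "exp_mixture"
  )
}

#' @export
print.exp_mixture <- function(x, ...) {
  cat(sprintf("Exponential mixture, K = %d\n", x$K))
  for (k in seq_len(x$K)) {
    cat(sprintf("  tau = %8.4g s   weight = %5.1f%%\n",
                x$lifetimes[k], 100 * x$weights[k]))
  }
  invisible(x)
}

#' Mean of an exponential mixture
#' @param mix an [exp_mixture()].
#' @return the mean dwell time \eqn{\sum_k a_k \tau_k} in seconds.
#' @export
mixture_mean <- function(mix) {
  stopifnot(inherits(mix, "exp_mixture"))
  sum(mix$weights * mix$lifetimes)
}

#' Density and distribution function of a (left-truncated) exponential mixture
#'
#' With a detection dead time `t_min` the observable dwells follow the
#' mixture conditioned on \eqn{t \ge t_{min}}; the truncated density is the
#' raw mixture density divided by the mixture survival at `t_min`.
#'
#' @param t numeric vector of dwell times (s).
#' @param mix an [exp_mixture()].
#' @param t_min left-truncation threshold (s), default 0.
#' @return `dmixexp` the density, `pmixexp` the distribution function; both
#'   are zero below `t_min`.
#' @export
dmixexp <- function(t, mix, t_min = 0) {
  stopifnot(inherits(mix, "exp_mixture"), t_min >= 0)
  S <- sum(mix$weights * exp(-t_min / mix$lifetimes))
  d <- vapply(t, function(ti) {
    if (ti < t_min) return(0)
    sum(mix$weights * exp(-ti / mix$lifetimes) / mix$lifetimes) / S
  }, numeric(1))
  d
}

#' @rdname dmixexp
#' @export
pmixexp <- function(t, mix, t_min = 0) {
  stopifnot(inherits(mix, "exp_mixture"), t_min >= 0)
  S <- sum(mix$weights * exp(-t_min / mix$lifetimes))
  vapply(t, function(ti) {
    if (ti <= t_min) return(0)
    sum(mix$weights * (exp(-t_min / mix$lifetimes) -
                         exp(-ti / mix$lifetimes))) / S
  }, numeric(1))
}

#' Draw dwell times from a (left-truncated) exponential mixture
#'
#' Sampling uses the memorylessness of the exponential: a component is drawn
#' with probability proportional to \eqn{a_k e^{-t_{min}/\tau_k}} (its share
#' of the mass above the threshold) and the dwell is `t_min` plus a fresh
#' exponential with that component's lifetime. This is exact for the
#' truncated mixture density.
#'
#' @param mix an [exp_mixture()].
#' @param n number of dwells to draw.
#' @param t_min left-truncation threshold (s).
#' @param seed optional integer seed; identical seeds give identical samples.
#' @return a [dwell_set()] with `n` durations, all `>= t_min`.
#' @export
sample_exponential_mixture <- function(mix, n, t_min = 0, seed = NULL) {
  stopifnot(inherits(mix, "exp_mixture"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (t_min < 0) stop("`t_min` must be nonnegative", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    p <- mix$weights * exp(-t_min / mix$lifetimes)
    p <- p / sum(p)
    comp <- sample.int(mix$K, n, replace = TRUE, prob = p)
    durations <- t_min + stats::rexp(n, rate = 1 / mix$lifetimes[comp])
    dwell_set(durations, t_min = t_min)
  })
}

#' A set of dwell times with its truncation threshold
#'
#' @param durations_s numeric vector of dwell times (s), all `>= t_min`.
#' @param t_min left-truncation threshold (s): dwells shorter than this are
#'   unobservable at the instrument's frame time.
#' @param kind `"bound"` or `"unbound"`.
#' @return an object of class `dwell_set`.
#' @export
dwell_set <- function(durations_s, t_min = 0, kind = c("bound", "unbound")) {
  kind <- match.arg(kind)
  durations_s <- as.numeric(durations_s)
  if (length(durations_s) == 0L) {
    stop("a dwell set must contain at least one duration", call. = FALSE)
  }
  if (any(!is.finite(durations_s))) {
    stop("dwell durations must be finite", call. = FALSE)
  }
  if (any(durations_s < t_min)) {
    stop("all durations must be >= t_min", call. = FALSE)
  }
  structure(
    list(durations_s = durations_s, t_min_s = t_min, kind = kind),
    class = "dwell_set"
  )
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf("%d %s dwells, t_min = %g s, mean = %.3g s\n",
              length(x$durations_s), x$kind, x$t_min_s,
              mean(x$durations_s)))
  invisible(x)
}
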