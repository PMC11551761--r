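#' Detect a single photobleach step in the DNA-reporter channel
#'
#' Finds the best single change point by least-squares step fitting
#' (two constant segments). The trace qualifies as a single-step bleach
#' when (i) the two-segment fit reduces the residual sum of squares of the
#' flat fit by at least `improve`, (ii) splitting either segment again
#' (binary segmentation to three segments) does not reduce the two-segment
#' residual by `improve` as well, and (iii) the post-step level sits at the
#' background, defined as the mean of the final 10% of the trace.
#'
#' @param af488 reporter intensity series (>= 50 frames).
#' @param improve required fractional residual-variance reduction.
#' @param background_tol allowed post-step offset from background, as a
#'   fraction of the step height.
#' @return list `step_index` (1-based frame of the first post-step frame)
#'   and `is_single_step`.
#' @export
detect_photobleach_step <- function(af488, improve = 0.30,
                                    background_tol = 0.25) {
  y <- as.numeric(af488)
  n <- length(y)
  if (n < 50) stop("trace too short for step detection (< 50 frames)",
                   call. = FALSE)
  bs <- best_split(y)
  sse0 <- sum((y - mean(y))^2)
  if (sse0 < 1e-12) {
    return(list(step_index = NA_integer_, is_single_step = FALSE))
  }
  two_ok <- (sse0 - bs$sse) / sse0 >= improve
  # binary segmentation: best additional split within either segment
  left <- y[seq_len(bs$k - 1L)]
  right <- y[bs$k:n]
  sse3 <- bs$sse
  for (seg in list(left, right)) {
    if (length(seg) >= 4) {
      s <- best_split(seg)
      cand <- bs$sse - (sum((seg - mean(seg))^2) - s$sse)
      sse3 <- min(sse3, cand)
    }
  }
  three_not_better <- bs$sse < 1e-12 ||
    (bs$sse - sse3) / bs$sse < improve
  pre <- mean(y[seq_len(bs$k - 1L)])
  post <- mean(y[bs$k:n])
  bg <- mean(y[max(1L, floor(0.9 * n)):n])
  step_h <- pre - post
  at_bg <- step_h > 0 && abs(post - bg) <= background_tol * step_h
  list(step_index = bs$k,
       is_single_step = isTRUE(two_ok && three_not_better && at_bg))
}

# Best single change point k (first index of the right segment) minimizing
# the two-segment residual sum of squares; O(n) via cumulative sums.
best_split <- function(y) {
  n <- length(y)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  k <- 2:n
  nl <- k - 1; nr <- n - nl
  sl <- cs[nl]; sr <- cs[n] - sl
  ssel <- cs2[nl] - sl^2 / nl
  sser <- (cs2[n] - cs2[nl]) - sr^2 / nr
  sse <- ssel + sser
  i <- which.min(sse)
  list(k = k[i], sse = sse[i])
}

#' Count protein-channel intensity spikes
#'
#' Counts contiguous excursions of the Cy5 series above the background whose
#' peak exceeds twice the background mean; repeated spikes are the signature
#' of genuine reversible binding at the DNA spot rather than a surface
#' artefact.
#'
#' @param cy5 intensity series.
#' @param background_mean background level (> 0).
#' @param rise_factor multiple of background that opens an excursion.
#' @return number of qualifying spikes.
#' @export
count_spikes <- function(cy5, background_mean, rise_factor = 1.5) {
  if (background_mean <= 0) stop("`background_mean` must be positive",
                                 call. = FALSE)
  above <- cy5 > rise_factor * background_mean
  if (!any(above)) return(0L)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  sum(vapply(runs, function(i) {
    max(cy5[starts[i]:ends[i]]) > 2 * background_mean
  }, logical(1)))
}

#' Select genuine TIRF traces for idealization
#'
#' Applies the trace-quality criteria of the colocalization experiment: the
#' DNA reporter (AF488) must photobleach in a single step, proving a single
#' surface-tethered DNA, and the protein channel (Cy5) must show at least
#' `min_spikes` intensity spikes above twice background, proving repeated
#' binding at that spot. Only the pre-photobleach portion of the Cy5 series
#' is retained for downstream idealization (after the reporter is gone the
#' spot can no longer be attributed to the DNA).
#'
#' @param traces list of `tirf_trace` objects (see [simulate_tirf_trace()]).
#' @param min_spikes minimum number of Cy5 spikes.
#' @param improve step-fit threshold passed to [detect_photobleach_step()].
#' @param min_window_s minimum pre-bleach duration (s); spots whose reporter
#'   bleaches almost immediately carry too little observation time to
#'   constrain dwell times of tens of seconds and are discarded.
#' @return list `accepted` (list of `list(trace_id, cy5, frame_s)` with cy5
#'   cut at the bleach step) and `qc` (data frame, one row per input trace).
#' @export
select_traces <- function(traces, min_spikes = 2, improve = 0.30,
                          min_window_s = 120) {
  qc <- data.frame(trace_id = character(0), is_single_step = logical(0),
                   n_spikes = integer(0), window_s = numeric(0),
                   accepted = logical(0), stringsAsFactors = FALSE)
  accepted <- list()
  for (tr in traces) {
    stopifnot(inherits(tr, "tirf_trace"))
    step <- detect_photobleach_step(tr$data$af488, improve = improve)
    window <- if (!is.na(step$step_index)) {
      seq_len(max(step$step_index - 1L, 0L))
    } else seq_len(nrow(tr$data))
    cy5 <- tr$data$cy5[window]
    bg <- stats::median(cy5)
    nsp <- if (length(cy5)) count_spikes(cy5, max(bg, 1e-9)) else 0L
    window_s <- length(cy5) * tr$frame_s
    ok <- isTRUE(step$is_single_step) && nsp >= min_spikes &&
      window_s >= min_window_s
    qc <- rbind(qc, data.frame(trace_id = tr$trace_id,
                               is_single_step = isTRUE(step$is_single_step),
                               n_spikes = nsp, window_s = window_s,
                               accepted = ok,
                               stringsAsFactors = FALSE))
    if (ok) {
      accepted[[length(accepted) + 1L]] <-
        list(trace_id = tr$trace_id, cy5 = cy5, frame_s = tr$frame_s)
    }
  }
  list(accepted = accepted, qc = qc)
}

#' Rastergram of idealized traces
#'
#' Stacks the binary state paths of many idealized traces into one matrix
#' (one row per trace, bound = 1), right-padded with `NA` to the longest
#' trace and ordered by the time of first binding (ties broken by trace
#' id), reproducing the standard summary display of TIRF dwell structure.
#'
#' @param idealizations list of [hmm_idealize()] results.
#' @param trace_ids optional character ids (default sequential).
#' @return list `matrix` (traces x frames, entries 0/1/NA) and `order`
#'   (original indices in display order).
#' @export
rastergram <- function(idealizations, trace_ids = NULL) {
  stopifnot(length(idealizations) >= 1)
  if (is.null(trace_ids)) trace_ids <- sprintf("trace_%04d",
                                               seq_along(idealizations))
  first_bound <- vapply(idealizations, function(id) {
    w <- which(id$states == 1L)
    if (length(w)) w[1] else Inf
  }, numeric(1))
  ord <- order(first_bound, trace_ids)
  lens <- vapply(idealizations, function(id) length(id$states), integer(1))
  m <- matrix(NA_integer_, length(idealizations), max(lens))
  for (r in seq_along(ord)) {
    st <- idealizations[[ord[r]]]$states
    m[r, seq_along(st)] <- st
  }
  rownames(m) <- trace_ids[ord]
  list(matrix = m, order = ord)
}
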