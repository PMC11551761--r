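#' Track binding events on the green kymograph channel
#'
#' Per scan line, intensity peaks above a robust threshold are refined to
#' sub-pixel position with a local Gaussian fit, then linked across lines by
#' greedy nearest-neighbour association within `link_radius_px`, tolerating
#' detection gaps of up to `max_gap_lines` lines. Tracks with fewer than
#' `min_length_lines` detections are discarded. Defaults are matched to the
#' 40 ms line time: a 3-line minimum keeps events at the fastest resolvable
#' lifetime (~2 lines at 0.08 s) out of the noise floor while a 2-line gap
#' bridges single missed detections.
#'
#' @param green photon-count matrix (lines x pixels) or a [kymograph()].
#' @param peak_threshold absolute intensity threshold per line; default
#'   `median + 4 * MAD` over the whole channel.
#' @param link_radius_px maximum frame-to-frame displacement for linking.
#' @param max_gap_lines maximum number of consecutive missed lines bridged.
#' @param min_length_lines minimum number of detections per kept track.
#' @param window_px Gaussian-refinement half window.
#' @return list of `track` objects: `frames` (0-based line indices, strictly
#'   increasing), `positions_px` (0-based sub-pixel coordinates),
#'   `segments` (filled by [classify_segments()]), `excluded`/`reason`
#'   (filled by [exclude_tracks()]).
#' @export
track_events <- function(green, peak_threshold = NULL, link_radius_px = 3,
                         max_gap_lines = 2, min_length_lines = 3,
                         window_px = 3, min_sep_px = 4) {
  if (inherits(green, "kymograph")) green <- green$green
  if (is.null(peak_threshold)) {
    peak_threshold <- stats::median(green) + 4 * stats::mad(green)
  }
  n_lines <- nrow(green)

  active <- list()   # each: list(frames, pos, last_line, last_pos)
  done <- list()
  for (line in seq_len(n_lines)) {
    prof <- green[line, ]
    # peaks closer than one PSF footprint are duplicates (Poisson ties)
    peaks <- local_maxima(prof, peak_threshold, min_sep = min_sep_px)
    det <- vapply(peaks, function(p) gaussian_refine(prof, p, window_px),
                  numeric(1))
    if (length(det) > 1) {
      # refinement can pull two threshold crossings onto one emitter:
      # keep the brighter of any pair closer than the PSF footprint
      keep <- logical(0); kept_pos <- numeric(0)
      for (o in order(prof[peaks], decreasing = TRUE)) {
        if (!length(kept_pos) || all(abs(kept_pos - det[o]) >= min_sep_px)) {
          keep <- c(keep, o); kept_pos <- c(kept_pos, det[o])
        }
      }
      det <- sort(det[keep])
    }
    # greedy global-nearest-neighbour assignment of detections to tracks
    if (length(active) && length(det)) {
      last_pos <- vapply(active, `[[`, numeric(1), "last_pos")
      dmat <- abs(outer(last_pos, det, "-"))
      repeat {
        if (!length(dmat) || min(dmat) > link_radius_px) break
        idx <- arrayInd(which.min(dmat), dim(dmat))
        ti <- idx[1]; di <- idx[2]
        active[[ti]]$frames <- c(active[[ti]]$frames, line - 1L)
        active[[ti]]$pos <- c(active[[ti]]$pos, det[di])
        active[[ti]]$last_line <- line
        active[[ti]]$last_pos <- det[di]
        dmat[ti, ] <- Inf; dmat[, di] <- Inf
        det[di] <- NA_real_
      }
      det <- det[!is.na(det)]
    }
    for (d in det) {
      active[[length(active) + 1L]] <- list(frames = line - 1L, pos = d,
                                            last_line = line, last_pos = d)
    }
    # retire tracks whose gap exceeds the limit
    if (length(active)) {
      gap_over <- vapply(active, function(a) line - a$last_line > max_gap_lines,
                         logical(1))
      done <- c(done, active[gap_over])
      active <- active[!gap_over]
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$frames) >= min_length_lines, done)
  lapply(seq_along(done), function(i) {
    a <- done[[i]]
    structure(list(id = i, frames = a$frames, positions_px = a$pos,
                   segments = NULL, excluded = FALSE, reason = NA_character_),
              class = "track")
  })
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track %s: lines %d-%d (%d detections)%s\n",
              x$id, min(x$frames), max(x$frames), length(x$frames),
              if (isTRUE(x$excluded)) paste0(" [excluded: ", x$reason, "]")
              else ""))
  invisible(x)
}

#' Split a track into static and diffusive segments
#'
#' Computes the rolling variance of frame-to-frame displacements over a
#' window and labels a window static when that variance is below
#' `static_threshold` times the localization variance (pure localization
#' noise gives a displacement variance of twice the localization variance,
#' so the default factor 4 sits a factor two above the noise floor).
#' Contiguous runs of equal labels merge into half-open `[start, end)`
#' segments in track-index space; tracks shorter than the window get a
#' single segment labelled by their global displacement variance.
#'
#' @param track a `track` from [track_events()].
#' @param window_lines rolling window length (lines).
#' @param static_threshold multiple of the localization variance below which
#'   a window is static.
#' @param localization_var_px2 localization variance (pixels squared), e.g.
#'   the CVE's `sigma2_hat` converted to pixels.
#' @param min_segment_lines segments shorter than this are absorbed into
#'   their longer neighbour; the rolling variance occasionally flips a few
#'   windows inside a homogeneous stretch and a mode switch shorter than
#'   one window cannot be resolved anyway.
#' @return the track with `segments`: data frame `start`, `end`, `label`.
#' @export
classify_segments <- function(track, window_lines = 10, static_threshold = 4,
                              localization_var_px2 = 0.1,
                              min_segment_lines = window_lines) {
  stopifnot(inherits(track, "track"))
  pos <- track$positions_px
  n <- length(pos)
  thresh <- static_threshold * localization_var_px2
  dx <- diff(pos)
  if (n < window_lines || length(dx) < 2) {
    lab <- if (stats::var(dx) < thresh) "static" else "diffusive"
    track$segments <- data.frame(start = 0L, end = n, label = lab,
                                 stringsAsFactors = FALSE)
    return(track)
  }
  w <- max(2L, window_lines - 1L)  # window in displacement space
  nv <- length(dx) - w + 1L
  roll_var <- vapply(seq_len(nv), function(i) stats::var(dx[i:(i + w - 1L)]),
                     numeric(1))
  # per-position label: a position is static if the windows covering it are
  # predominantly below threshold
  votes_static <- integer(n); votes_total <- integer(n)
  for (i in seq_len(nv)) {
    cover <- i:(i + w)  # positions spanned by displacements i..i+w-1
    votes_total[cover] <- votes_total[cover] + 1L
    if (roll_var[i] < thresh) votes_static[cover] <- votes_static[cover] + 1L
  }
  lab <- ifelse(votes_static * 2L >= votes_total, "static", "diffusive")
  # absorb sub-resolution runs into their neighbours, shortest first: a
  # single mislabelled window can flip at most one window-span of positions
  repeat {
    r <- rle(lab)
    if (length(r$lengths) == 1L || min(r$lengths) > min_segment_lines) break
    i <- which.min(r$lengths)
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    neighbours <- c(if (i > 1L) r$lengths[i - 1L] else -1L,
                    if (i < length(r$lengths)) r$lengths[i + 1L] else -1L)
    take <- if (which.max(neighbours) == 1L) i - 1L else i + 1L
    lab[starts[i]:ends[i]] <- r$values[take]
  }
  # track ends are covered by fewer windows, so a chance cluster of
  # mislabelled windows can fabricate a short boundary segment; demand
  # two window-spans of evidence before a segment may touch an edge
  repeat {
    r <- rle(lab)
    k <- length(r$lengths)
    if (k == 1L) break
    if (r$lengths[1] < 2L * min_segment_lines) {
      lab[seq_len(r$lengths[1])] <- r$values[2]
    } else if (r$lengths[k] < 2L * min_segment_lines) {
      lab[(n - r$lengths[k] + 1L):n] <- r$values[k - 1L]
    } else break
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  track$segments <- data.frame(start = starts, end = ends, label = r$values,
                               stringsAsFactors = FALSE)
  track
}

#' Flag tracks near beads or colliding with other tracks
#'
#' Events diffusing into a bead or hindered by a neighbouring protein bias
#' diffusion and lifetime estimates; such tracks are flagged (never deleted)
#' so downstream summaries can drop them while the exclusion report keeps
#' the full census. Flags are monotone in both margins: enlarging
#' `bead_margin_px` or `collision_radius_px` can only add flags.
#'
#' @param tracks list of `track`s.
#' @param bead_edges_px inner bead-edge pixel coordinates (pair).
#' @param bead_margin_px distance to a bead edge below which a track is
#'   flagged `"bead"`.
#' @param collision_radius_px distance to another track (at any shared line)
#'   below which both are flagged `"collision"`.
#' @return the list of tracks with `excluded`/`reason` set.
#' @export
exclude_tracks <- function(tracks, bead_edges_px, bead_margin_px = 5,
                           collision_radius_px = 3) {
  flags <- rep(NA_character_, length(tracks))
  for (i in seq_along(tracks)) {
    p <- tracks[[i]]$positions_px
    if (any(p <= bead_edges_px[1] + bead_margin_px |
              p >= bead_edges_px[2] - bead_margin_px)) {
      flags[i] <- "bead"
    }
  }
  if (length(tracks) > 1) {
    for (i in seq_along(tracks)) {
      for (j in seq_along(tracks)) {
        if (j <= i) next
        fi <- tracks[[i]]$frames; fj <- tracks[[j]]$frames
        shared <- intersect(fi, fj)
        if (!length(shared)) next
        pi_ <- tracks[[i]]$positions_px[match(shared, fi)]
        pj_ <- tracks[[j]]$positions_px[match(shared, fj)]
        if (any(abs(pi_ - pj_) <= collision_radius_px)) {
          flags[i] <- if (is.na(flags[i])) "collision" else flags[i]
          flags[j] <- if (is.na(flags[j])) "collision" else flags[j]
        }
      }
    }
  }
  for (i in seq_along(tracks)) {
    tracks[[i]]$excluded <- !is.na(flags[i])
    tracks[[i]]$reason <- flags[i]
  }
  tracks
}

#' Binding-event frequency
#'
#' @param tracks list of `track`s (excluded tracks are not counted).
#' @param observation_s observation time (s), > 0.
#' @return events per minute.
#' @export
event_frequency <- function(tracks, observation_s) {
  if (observation_s <= 0) stop("`observation_s` must be positive", call. = FALSE)
  n <- sum(!vapply(tracks, function(t) isTRUE(t$excluded), logical(1)))
  n * 60 / observation_s
}
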