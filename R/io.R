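#' Read and write kymographs as TIFF plus JSON sidecar
#'
#' The image is stored as a two-page 32-bit float TIFF (page 1 green, page 2
#' red), normalized to `[0, 1]` by a single intensity scale recorded in a
#' JSON sidecar together with the scan metadata (line time, pixel size, bead
#' edges) and, optionally, the simulation ground truth. Writer and reader
#' are exact inverses for integer photon counts.
#'
#' @param kymo a [kymograph()].
#' @param tiff_path output TIFF path.
#' @param json_path sidecar path; default `tiff_path` with `.json`.
#' @param truth optional ground truth (stored in the sidecar).
#' @return `write_kymograph` the paths invisibly; `read_kymograph` a list
#'   with `kymograph` and `truth` (or `NULL`).
#' @export
write_kymograph <- function(kymo, tiff_path, json_path = NULL, truth = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  if (is.null(json_path)) json_path <- sub("\\.tiff?$", ".json", tiff_path)
  scale <- max(kymo$green, kymo$red, 1)
  tiff::writeTIFF(list(kymo$green / scale, kymo$red / scale), tiff_path,
                  bits.per.sample = 32L)
  meta <- list(intensity_scale = scale, line_time_s = kymo$line_time_s,
               pixel_size_um = kymo$pixel_size_um,
               bead_edges_px = kymo$bead_edges_px,
               n_lines = nrow(kymo$green), n_pixels = ncol(kymo$green))
  if (!is.null(truth)) meta$truth <- serialize_truth(truth)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tiff = tiff_path, json = json_path))
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(tiff_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.tiff?$", ".json", tiff_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (length(pages) != 2) {
    stop("kymograph TIFF must have exactly 2 pages (green, red), found ",
         length(pages), call. = FALSE)
  }
  if (!all(dim(pages[[1]]) == dim(pages[[2]]))) {
    stop("kymograph channels have mismatched shapes", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(json_path, simplifyVector = FALSE)
  for (field in c("intensity_scale", "line_time_s", "pixel_size_um",
                  "bead_edges_px")) {
    if (is.null(meta[[field]])) {
      stop("kymograph sidecar is missing field `", field, "`", call. = FALSE)
    }
  }
  km <- kymograph(round(pages[[1]] * as.numeric(meta$intensity_scale)),
                  round(pages[[2]] * as.numeric(meta$intensity_scale)),
                  as.numeric(meta$line_time_s),
                  as.numeric(meta$pixel_size_um),
                  as.numeric(unlist(meta$bead_edges_px)))
  truth <- if (!is.null(meta$truth)) deserialize_truth(meta$truth) else NULL
  list(kymograph = km, truth = truth)
}

serialize_truth <- function(truth) {
  if (inherits(truth, "ground_truth")) truth <- list(truth)
  lapply(truth, function(tr) {
    list(events = tr$events, paths = tr$paths,
         dna_length_bp = tr$dna_length_bp,
         nick_positions_bp = tr$nick_positions_bp,
         line_time_s = tr$line_time_s, duration_s = tr$duration_s)
  })
}

deserialize_truth <- function(x) {
  # x is a plain list of per-species records (simplifyVector = FALSE)
  lapply(x, function(tr) {
    events <- do.call(rbind, lapply(tr$events, function(row) {
      data.frame(id = as.integer(row$id), start_s = as.numeric(row$start_s),
                 end_s = as.numeric(row$end_s), mode = as.character(row$mode),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(events)) {
      events <- data.frame(id = integer(0), start_s = numeric(0),
                           end_s = numeric(0), mode = character(0),
                           stringsAsFactors = FALSE)
    }
    structure(list(events = events,
                   paths = lapply(tr$paths, function(p) as.numeric(unlist(p))),
                   dna_length_bp = as.numeric(tr$dna_length_bp),
                   nick_positions_bp = as.numeric(unlist(tr$nick_positions_bp)),
                   line_time_s = as.numeric(tr$line_time_s),
                   duration_s = as.numeric(tr$duration_s)),
              class = "ground_truth")
  })
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", what,
                 paste0("`", missing, "`", collapse = ", ")), call. = FALSE)
  }
}

#' Read and write TIRF traces as CSV
#'
#' Schema: columns `frame` (0-based), `af488`, `cy5`; the frame time and
#' trace id travel in a commented header line.
#'
#' @param trace a `tirf_trace`.
#' @param path CSV path.
#' @return `read_trace_csv` a `tirf_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tirf_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_s=%.17g trace_id=%s", trace$frame_s,
                     trace$trace_id), con)
  utils::write.csv(trace$data[, c("frame", "af488", "cy5")], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1)
  frame_s <- 0.1; trace_id <- basename(path)
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("frame_s=([0-9.eE+-]+) trace_id=(\\S+)",
                                    header))[[1]]
    if (length(m) == 3) { frame_s <- as.numeric(m[2]); trace_id <- m[3] }
  }
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, c("frame", "af488", "cy5"), "trace CSV")
  structure(list(data = data.frame(frame = df$frame,
                                   time_s = df$frame * frame_s,
                                   af488 = df$af488, cy5 = df$cy5),
                 frame_s = frame_s, trace_id = trace_id),
            class = "tirf_trace")
}

#' Read and write tracked binding events as CSV
#'
#' Long format, one row per detection: `track_id`, `frame`, `position_px`,
#' `segment_label` (empty until classified), `excluded`, `reason`.
#'
#' @param tracks list of `track`s.
#' @param path CSV path.
#' @return `read_tracks_csv` a list of `track`s.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    lab <- rep(NA_character_, length(tr$frames))
    if (!is.null(tr$segments)) {
      for (i in seq_len(nrow(tr$segments))) {
        idx <- (tr$segments$start[i] + 1L):tr$segments$end[i]
        lab[idx] <- tr$segments$label[i]
      }
    }
    data.frame(track_id = tr$id, frame = tr$frames,
               position_px = tr$positions_px, segment_label = lab,
               excluded = isTRUE(tr$excluded),
               reason = if (is.null(tr$reason)) NA_character_ else tr$reason,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("track_id", "frame", "position_px"), "tracks CSV")
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    seg <- NULL
    if ("segment_label" %in% names(d) && !all(is.na(d$segment_label))) {
      r <- rle(d$segment_label)
      ends <- cumsum(r$lengths)
      seg <- data.frame(start = c(0L, ends[-length(ends)]), end = ends,
                        label = r$values, stringsAsFactors = FALSE)
    }
    structure(list(id = d$track_id[1], frames = d$frame,
                   positions_px = d$position_px, segments = seg,
                   excluded = isTRUE(d$excluded[1]),
                   reason = if ("reason" %in% names(d)) d$reason[1]
                   else NA_character_),
              class = "track")
  })
}

#' Read and write dwell sets as CSV
#'
#' Schema: columns `duration_s`, `kind`, `t_min_s`.
#' @param dwells a [dwell_set()].
#' @param path CSV path.
#' @return `read_dwells_csv` a [dwell_set()].
#' @export
write_dwells_csv <- function(dwells, path) {
  stopifnot(inherits(dwells, "dwell_set"))
  utils::write.csv(data.frame(duration_s = dwells$durations_s,
                              kind = dwells$kind,
                              t_min_s = dwells$t_min_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dwells_csv
#' @export
read_dwells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("duration_s", "kind", "t_min_s"), "dwells CSV")
  dwell_set(df$duration_s, t_min = df$t_min_s[1], kind = df$kind[1])
}

#' Read and write binding-density profiles as CSV
#'
#' Schema: columns `position_bp`, `density`; `n_kymographs` in a commented
#' header line.
#' @param profile a `density_profile`.
#' @param path CSV path.
#' @return `read_profile_csv` a `density_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_kymographs=%d", profile$n_kymographs), con)
  utils::write.csv(data.frame(position_bp = profile$positions_bp,
                              density = profile$density),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  header <- readLines(path, n = 1)
  nk <- 1L
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("n_kymographs=([0-9]+)", header))[[1]]
    if (length(m) == 2) nk <- as.integer(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, c("position_bp", "density"), "profile CSV")
  structure(list(positions_bp = df$position_bp, density = df$density,
                 n_kymographs = nk),
            class = "density_profile")
}

#' Write a rastergram as a CSV matrix
#'
#' One row per trace in display order; padding frames beyond a trace's end
#' are written as `NA`.
#' @param raster a [rastergram()] result.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_rastergram_csv <- function(raster, path) {
  utils::write.csv(as.data.frame(raster$matrix), path, row.names = TRUE)
  invisible(path)
}

#' Write a mixture-fit report as JSON
#'
#' Serializes the fitted lifetimes/weights (the lifetime-percentage table of
#' the standard figure layout), log-likelihood, BIC, and when present the
#' bootstrap 95% intervals and unimodality-gate decisions.
#'
#' @param fit an `exp_mixture_fit`.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "exp_mixture_fit"))
  out <- list(
    method = fit$method, K = fit$K, n = fit$n, t_min_s = fit$t_min_s,
    loglik = fit$loglik, bic = fit$bic, converged = fit$converged,
    components = lapply(seq_len(fit$K), function(k) {
      comp <- list(lifetime_s = fit$lifetimes[k],
                   percentage = 100 * fit$weights[k])
      if (!is.null(fit$bootstrap)) {
        comp$lifetime_ci95 <-
          unname(stats::quantile(fit$bootstrap$lifetimes[, k],
                                 c(0.025, 0.975)))
        comp$weight_ci95 <-
          unname(stats::quantile(fit$bootstrap$weights[, k], c(0.025, 0.975)))
      }
      if (!is.null(fit$unimodal)) comp$unimodal <- as.list(fit$unimodal[[k]])
      comp
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
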