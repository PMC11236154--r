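# CASA-style kinematics: straight-line (VSL), curvilinear (VCL) and
# average-path (VAP) velocities, and motile fractions.

#' Summarize one track into CASA velocity parameters
#'
#' Definitions follow standard CASA conventions:
#' * VSL: net displacement (first to last point) over elapsed time;
#' * VCL: sum of frame-to-frame displacements over elapsed time;
#' * VAP: path length of the centered moving-average trajectory (window
#'   shrinking at the edges) over elapsed time.
#' Smoothing is a contraction and the triangle inequality bounds the chord,
#' so VCL >= VAP >= VSL holds for every track.
#'
#' @param track a [make_track()] object or data.frame with `t_seconds`,
#'   `x_um`, `y_um` (uniform, strictly increasing times; >= 2 frames).
#' @param smoothing_window odd window width (frames) for the VAP average
#'   path (default 5).
#' @param motility_threshold VCL cutoff in um/s for calling a track motile
#'   (default 25; a documented stand-in for instrument-internal criteria).
#' @return List: `VSL`, `VCL`, `VAP` (um/s) and `motile`.
#' @export
summarize_track <- function(track, smoothing_window = 5L,
                            motility_threshold = 25) {
  if (!is.data.frame(track) ||
      !all(c("t_seconds", "x_um", "y_um") %in% names(track)))
    stop_param("track", "must have columns t_seconds, x_um, y_um")
  if (nrow(track) < 2L)
    stop_param("track", "needs at least 2 frames")
  if (any(diff(track$t_seconds) <= 0))
    stop_param("track", "times must be strictly increasing")
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L)
    stop_param("smoothing_window", "must be an odd integer >= 1")

  xy <- cbind(track$x_um, track$y_um)
  elapsed <- track$t_seconds[nrow(xy)] - track$t_seconds[1L]
  vsl <- sqrt(sum((xy[nrow(xy), ] - xy[1L, ])^2)) / elapsed
  vcl <- path_length(xy) / elapsed
  vap <- path_length(moving_average_path(xy, w)) / elapsed
  list(VSL = vsl, VCL = vcl, VAP = vap,
       motile = vcl >= motility_threshold)
}

path_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

# Centered moving average with window shrinking at the track ends
# (half-width reduced so the window always fits).
moving_average_path <- function(xy, w) {
  if (w <= 1L) return(xy)
  h <- w %/% 2L
  n <- nrow(xy)
  out <- xy
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    out[i, ] <- colMeans(xy[(i - hh):(i + hh), , drop = FALSE])
  }
  out
}

#' Fraction of motile tracks
#'
#' @param summaries list of [summarize_track()] results, or a logical
#'   vector of motile flags.
#' @return Fraction in [0, 1].
#' @export
motile_fraction <- function(summaries) {
  flags <- if (is.logical(summaries)) summaries else
    vapply(summaries, function(s) isTRUE(s$motile), logical(1))
  if (length(flags) < 1L)
    stop_param("summaries", "needs at least one track")
  mean(flags)
}

#' Write / read track tables
#'
#' Dialect: CSV with header `track_id,frame,t_seconds,x_um,y_um`.
#'
#' @param path CSV file.
#' @param tracks named list of track data.frames.
#' @export
write_tracks <- function(path, tracks) {
  if (is.data.frame(tracks)) tracks <- list(track_1 = tracks)
  if (is.null(names(tracks)))
    names(tracks) <- sprintf("track_%d", seq_along(tracks))
  df <- do.call(rbind, lapply(names(tracks), function(id)
    data.frame(track_id = id, tracks[[id]][c("frame", "t_seconds",
                                             "x_um", "y_um")])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("track_id", "frame", "t_seconds", "x_um", "y_um")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("track CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$track_id), function(g)
    g[order(g$frame), c("frame", "t_seconds", "x_um", "y_um")])
  out[unique(df$track_id)]
}
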