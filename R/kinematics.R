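#' Curvilinear velocity (VCL) of one sperm track
#'
#' VCL is the time-averaged speed of the sperm head along its actual
#' point-to-point path: the sum of Euclidean distances between successive
#' tracked positions divided by the elapsed time. Elapsed time is computed
#' from frame numbers (`(last - first) / fps`), so tracks with dropped
#' frames are timed correctly.
#'
#' @param track A data frame with columns `frame`, `x_um`, `y_um` (one
#'   track; positions in micrometres, frames strictly increasing).
#' @param fps Recording speed in frames per second.
#' @return Speed in micrometres per second (non-negative scalar).
#' @examples
#' tr <- tibble::tibble(frame = 0:2, x_um = c(0, 1, 2), y_um = 0)
#' vcl(tr, fps = 60) # 60: 2 um covered in 2/60 s
#' @seealso [vap()], [track_velocities()]
#' @export
vcl <- function(track, fps = 60) {
  pts <- check_track(track, fps)
  path_length(pts$x_um, pts$y_um) / elapsed_time(pts$frame, fps)
}

#' Average-path velocity (VAP) of one sperm track
#'
#' VAP is the time-averaged speed along the *average path*: the raw
#' positions are smoothed with a centred moving average of `window` points
#' and the length of the smoothed path is divided by its elapsed time. Near
#' the track ends the window shrinks symmetrically (half-width
#' `min(h, i - 1, n - i)`), so the smoothed track keeps its first and last
#' points and no positions are fabricated. With that edge rule every
#' smoothed step is a convex-weighted mixture of raw steps, which guarantees
#' `vap(track, w) <= vcl(track)` for every window.
#'
#' @inheritParams vcl
#' @param window Odd integer, the moving-average span in points
#'   (default 5, a common CASA choice at 60 fps). `window = 1` leaves the
#'   track unsmoothed, so `vap()` equals [vcl()].
#' @return Speed in micrometres per second.
#' @export
vap <- function(track, fps = 60, window = 5) {
  pts <- check_track(track, fps)
  n <- nrow(pts)
  if (window < 1 || window %% 2 == 0) {
    stop("`window` must be a positive odd integer, got ", window, call. = FALSE)
  }
  if (window > n) {
    stop("`window` (", window, ") exceeds track length (", n, ")", call. = FALSE)
  }
  sm <- smooth_path(pts$x_um, pts$y_um, window)
  path_length(sm$x, sm$y) / elapsed_time(pts$frame, fps)
}

# centred moving average with symmetrically shrinking half-width at the edges
smooth_path <- function(x, y, window) {
  n <- length(x)
  h <- (window - 1L) / 2L
  idx <- seq_len(n)
  hw <- pmin(h, idx - 1L, n - idx)
  cx <- c(0, cumsum(x))
  cy <- c(0, cumsum(y))
  w <- 2L * hw + 1L
  lo <- idx - hw
  hi <- idx + hw
  list(x = (cx[hi + 1L] - cx[lo]) / w, y = (cy[hi + 1L] - cy[lo]) / w)
}

path_length <- function(x, y) {
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

elapsed_time <- function(frame, fps) {
  (frame[length(frame)] - frame[1L]) / fps
}

check_track <- function(track, fps) {
  stopifnot(is.data.frame(track))
  need <- c("frame", "x_um", "y_um")
  miss <- setdiff(need, names(track))
  if (length(miss)) {
    stop("track is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(track) < 2L) {
    stop("degenerate track: need at least 2 points, got ", nrow(track), call. = FALSE)
  }
  if (any(diff(track$frame) <= 0)) {
    stop("track frames must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  track[, need]
}

#' Per-track kinematics for a set of tracked sperm heads
#'
#' Computes VCL and VAP for every track in a long-format trajectory table,
#' dropping tracks shorter than `min_frames` points (short fragments carry
#' little kinematic information and are filtered by CASA software in the
#' same spirit).
#'
#' @param tracks Data frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um`; additional id columns (e.g. `male_id`, `subsample`) are carried
#'   through.
#' @inheritParams vap
#' @param min_frames Minimum points for a track to enter summaries
#'   (default 30).
#' @return A tibble with one row per retained track: the carried id
#'   columns, `n_frames`, `vcl`, `vap`.
#' @export
track_velocities <- function(tracks, fps = 60, window = 5, min_frames = 30) {
  stopifnot(is.data.frame(tracks), "track_id" %in% names(tracks))
  ids <- setdiff(names(tracks), c("frame", "x_um", "y_um"))
  tracks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::filter(dplyr::n() >= min_frames) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      vcl = vcl(dplyr::pick(dplyr::everything()), fps = fps),
      vap = vap(dplyr::pick(dplyr::everything()), fps = fps, window = window),
      .groups = "drop"
    )
}

#' Summarise one subsample of tracked sperm
#'
#' Unweighted mean VCL and VAP over the tracks of a single activation
#' subsample, with the number of tracks retained.
#'
#' @inheritParams track_velocities
#' @return One-row tibble: `mean_vcl`, `mean_vap`, `n_tracks`.
#' @export
summarize_subsample <- function(tracks, fps = 60, window = 5, min_frames = 30) {
  tv <- track_velocities(tracks, fps = fps, window = window, min_frames = min_frames)
  if (nrow(tv) == 0L) {
    stop("no track passes the minimum-length filter (min_frames = ",
         min_frames, ")", call. = FALSE)
  }
  tibble::tibble(
    mean_vcl = mean(tv$vcl),
    mean_vap = mean(tv$vap),
    n_tracks = nrow(tv)
  )
}

#' Male-level sperm velocity traits
#'
#' Sperm parameters are measured on several activation subsamples per male
#' (three in the study design) and the male-level trait is the *mean of
#' subsample means* — not the pooled mean over tracks, which would weight
#' subsamples by how many cells happened to be tracked.
#'
#' @param tracks Data frame with columns `male_id`, `subsample`,
#'   `track_id`, `frame`, `x_um`, `y_um` for one or more males.
#' @inheritParams track_velocities
#' @return A tibble with one row per male: `male_id`, `vcl_mean`,
#'   `vap_mean` (means of subsample means, um/s), `n_subsamples`,
#'   `n_tracks` (total retained).
#' @export
summarize_male <- function(tracks, fps = 60, window = 5, min_frames = 30) {
  stopifnot(all(c("male_id", "subsample") %in% names(tracks)))
  tv <- track_velocities(tracks, fps = fps, window = window, min_frames = min_frames)
  tv |>
    dplyr::group_by(.data$male_id, .data$subsample) |>
    dplyr::summarise(
      mean_vcl = mean(.data$vcl), mean_vap = mean(.data$vap),
      n_tracks = dplyr::n(), .groups = "drop_last"
    ) |>
    dplyr::summarise(
      vcl_mean = mean(.data$mean_vcl),
      vap_mean = mean(.data$mean_vap),
      n_subsamples = dplyr::n(),
      n_tracks = sum(.data$n_tracks),
      .groups = "drop"
    )
}
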