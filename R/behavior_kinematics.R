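## Swim-test kinematics from frame-level trajectories: between-frame
## speeds, pause segmentation, activity fraction, active and
## fastest-window speeds, vertical position index and total distance.
##
## The pause rule: a pause is a maximal run of at least `min_frames`
## consecutive between-frame speed measurements none of which exceeds
## `threshold` (strictly greater than; a measurement equal to the
## threshold stays inside a pause run). At the default 10 fps, 20 frames
## span 2 s. Speeds across flagged tracking gaps are undefined (NA) and
## terminate any pause run; distance across a gap is excluded.

#' Between-frame speeds
#'
#' Euclidean displacement between consecutive frames times the frame
#' rate. Intervals spanning a flagged tracking gap are `NA`.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @return Numeric vector of length `n_frames - 1`, in cm/s.
#' @export
frame_speeds <- function(traj) {
  n <- length(traj$frames)
  if (n < 2L) stop("at least 2 frames required")
  sp <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2) * traj$fps
  sp[traj$gap_after] <- NA_real_
  sp
}

#' Detect pauses in swimming
#'
#' Maximal runs of at least `min_frames` consecutive speeds not exceeding
#' `threshold` (strict "greater than" breaks a run; `NA` speeds, from
#' tracking gaps, also break runs).
#'
#' @param speeds between-frame speeds from [frame_speeds()].
#' @param min_frames minimum run length in frames (default 20).
#' @param threshold speed threshold in cm/s (default 1.5).
#' @return data.frame with `start_frame`, `end_frame` (1-based inclusive
#'   interval indices) and `n_frames`; zero rows when no pause qualifies.
#' @export
detect_pauses <- function(speeds, min_frames = 20, threshold = 1.5) {
  slow <- !is.na(speeds) & speeds <= threshold
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  data.frame(start_frame = starts[keep], end_frame = ends[keep],
             n_frames = r$lengths[keep])
}

.pause_mask <- function(n, pauses) {
  mask <- logical(n)
  for (i in seq_len(nrow(pauses)))
    mask[pauses$start_frame[i]:pauses$end_frame[i]] <- TRUE
  mask
}

#' Percentage of time actively swimming
#'
#' 100 times the fraction of between-frame intervals not inside any
#' detected pause.
#'
#' @param traj a [trajectory()].
#' @param pauses output of [detect_pauses()]; computed from `traj` with
#'   defaults when omitted.
#' @inheritParams detect_pauses
#' @return Percent in \[0, 100\].
#' @export
percent_time_active <- function(traj, pauses = NULL, min_frames = 20,
                                threshold = 1.5) {
  speeds <- frame_speeds(traj)
  if (is.null(pauses)) pauses <- detect_pauses(speeds, min_frames, threshold)
  100 * sum(!.pause_mask(length(speeds), pauses)) / length(speeds)
}

#' Mean speed during active swimming
#'
#' Mean of between-frame speeds outside detected pauses (gap intervals
#' excluded).
#'
#' @inheritParams percent_time_active
#' @return Speed in cm/s.
#' @export
active_speed <- function(traj, pauses = NULL, min_frames = 20,
                         threshold = 1.5) {
  speeds <- frame_speeds(traj)
  if (is.null(pauses)) pauses <- detect_pauses(speeds, min_frames, threshold)
  act <- speeds[!.pause_mask(length(speeds), pauses)]
  act <- act[!is.na(act)]
  if (length(act) == 0L) stop("no active frames")
  mean(act)
}

#' Fastest-window speed
#'
#' Default mode: the maximum over all contiguous runs of `window`
#' between-frame speeds of the run mean (e.g. the fastest 100 consecutive
#' frames, 10 s at 10 fps; 50- and 30-frame windows are common
#' alternates). Mode `"top-n-seconds"` instead averages the `n_top`
#' highest non-overlapping 1-s-bin mean speeds.
#'
#' @param speeds between-frame speeds from [frame_speeds()].
#' @param window window length in frames (default 100).
#' @param mode `"window"` or `"top-n-seconds"`.
#' @param n_top number of 1-s bins averaged in top-n-seconds mode
#'   (default 30).
#' @param fps frames per second (needed for top-n-seconds binning).
#' @return Speed in cm/s.
#' @export
fastest_window_speed <- function(speeds, window = 100,
                                 mode = c("window", "top-n-seconds"),
                                 n_top = 30, fps = 10) {
  mode <- match.arg(mode)
  if (mode == "top-n-seconds") {
    per_bin <- as.integer(round(fps))
    n_bins <- length(speeds) %/% per_bin
    if (n_bins < 1L) stop("record shorter than one 1-s bin")
    bins <- vapply(seq_len(n_bins), function(b)
      mean(speeds[((b - 1L) * per_bin + 1L):(b * per_bin)]), numeric(1L))
    bins <- bins[!is.na(bins)]
    return(mean(sort(bins, decreasing = TRUE)[seq_len(min(n_top, length(bins)))]))
  }
  if (length(speeds) < window) stop("record shorter than the window")
  cs <- cumsum(c(0, ifelse(is.na(speeds), NA, speeds)))
  means <- (cs[(window + 1L):length(cs)] - cs[seq_len(length(cs) - window)]) /
    window
  means <- means[!is.na(means)]
  if (length(means) == 0L) stop("no gap-free window available")
  max(means)
}

#' Vertical position index
#'
#' Mean over frames of 100 times the height above the tank bottom divided
#' by the tank depth: 0 is the bottom of the tank, 100 the top.
#'
#' @param traj a [trajectory()] whose `y_cm` is height above the bottom
#'   (image-coordinate input is flipped at read time, see
#'   [read_trajectory()]).
#' @param tolerance_cm allowed calibration slack outside \[0, depth\]
#'   before an error is raised (default 0.1 cm); values inside the slack
#'   are clamped.
#' @return Index in \[0, 100\].
#' @export
vertical_position_index <- function(traj, tolerance_cm = 0.1) {
  depth <- traj$tank$depth_cm
  if (any(traj$y_cm < -tolerance_cm | traj$y_cm > depth + tolerance_cm))
    stop("y positions outside the tank depth beyond tolerance; ",
         "check px_per_cm / y_origin calibration")
  y <- pmin(pmax(traj$y_cm, 0), depth)
  mean(100 * y / depth)
}

#' Total distance swum
#'
#' Sum of between-frame Euclidean displacements, pauses included;
#' displacement across flagged tracking gaps is excluded.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @return Distance in cm.
#' @export
total_distance <- function(traj) {
  sp <- frame_speeds(traj)
  sum(sp[!is.na(sp)]) / traj$fps
}

#' Full kinematics summary for one fish
#'
#' Computes the five swim-test summary statistics.
#'
#' @param traj a [trajectory()].
#' @param pause_min_frames,pause_speed_threshold pause rule parameters.
#' @param fastest_window_frames fastest-window length.
#' @return list with `total_distance_cm`, `percent_time_active`,
#'   `active_speed_cm_s`, `fastest_speed_cm_s`,
#'   `vertical_position_index`, and the parameters used.
#' @export
kinematics_summary <- function(traj, pause_min_frames = 20,
                               pause_speed_threshold = 1.5,
                               fastest_window_frames = 100) {
  speeds <- frame_speeds(traj)
  pauses <- detect_pauses(speeds, pause_min_frames, pause_speed_threshold)
  list(total_distance_cm = total_distance(traj),
       percent_time_active = percent_time_active(traj, pauses),
       active_speed_cm_s = active_speed(traj, pauses),
       fastest_speed_cm_s = fastest_window_speed(speeds,
                                                 fastest_window_frames),
       vertical_position_index = vertical_position_index(traj),
       parameters = list(pause_min_frames = pause_min_frames,
                         pause_speed_threshold = pause_speed_threshold,
                         fastest_window_frames = fastest_window_frames))
}
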