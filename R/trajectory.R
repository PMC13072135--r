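#' 3D swim trajectory
#'
#' Container for the tracked position of one fish over a trial: a uniformly
#' sampled time series of 3D coordinates (cm) inside a [tank_geometry()].
#' All behavioral measures ([extract_profile()] and friends) consume this
#' type. Positions are for a single designated body point; multi-keypoint
#' pose files must be reduced to one point before construction (see
#' [read_trajectory_csv()]).
#'
#' @param times Numeric vector of frame times in seconds; strictly
#'   increasing and uniformly spaced (relative tolerance 1e-6).
#' @param x,y,z Coordinates in cm, one value per frame, all inside the tank.
#' @param geometry A [tank_geometry()].
#' @param fish_id Identifier attached to derived metrics.
#'
#' @return An object of class `trajectory3d` with fields `times` (s),
#'   `positions` (n x 3 matrix, cm), `geometry`, `fish_id`.
#' @seealso [make_scripted_trajectory()], [simulate_trajectory()]
#' @export
trajectory3d <- function(times, x, y, z, geometry = tank_geometry(),
                         fish_id = "fish") {
  stopifnot(inherits(geometry, "tank_geometry"))
  n <- length(times)
  if (n < 2L)
    stop("a trajectory needs at least 2 frames", call. = FALSE)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("times, x, y, z must have equal length", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(x)) ||
      !all(is.finite(y)) || !all(is.finite(z)))
    stop("trajectory contains non-finite values", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if ((max(dt) - min(dt)) > 1e-6 * mean(dt))
    stop("frame interval must be uniform (relative tolerance 1e-6)",
         call. = FALSE)
  ext <- geometry_extents(geometry)
  pos <- cbind(x = x, y = y, z = z)
  inside <- pos >= 0 & sweep(pos, 2, ext, "<=")
  if (!all(inside))
    stop(sprintf("%d position(s) fall outside the tank geometry",
                 sum(!inside)), call. = FALSE)
  structure(
    list(times = as.numeric(times), positions = unname(pos),
         geometry = geometry, fish_id = as.character(fish_id)),
    class = "trajectory3d"
  )
}

#' @export
print.trajectory3d <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf(
    "<trajectory3d> fish '%s': %d frames over %.1f s (dt = %.4g s)\n",
    x$fish_id, n, x$times[n] - x$times[1], frame_interval(x)))
  invisible(x)
}

frame_interval <- function(traj) {
  (traj$times[length(traj$times)] - traj$times[1]) /
    (length(traj$times) - 1)
}

n_frames <- function(traj) nrow(traj$positions)

#' Build a trajectory that visits given waypoints, one per frame
#'
#' Fixture builder: the resulting trajectory passes through exactly the
#' supplied points in order, so path length, per-step speeds and the set of
#' visited voxels are known by construction.
#'
#' @param waypoints Numeric matrix (n x 3) or data frame of x, y, z in cm;
#'   every point must lie inside the tank.
#' @param frame_interval Time between consecutive waypoints, s.
#' @param geometry A [tank_geometry()].
#' @param fish_id Identifier.
#' @return A [trajectory3d()].
#' @examples
#' g <- tank_geometry()
#' wp <- rbind(c(1, 1, 1), c(2, 1, 1), c(2, 2, 1))
#' make_scripted_trajectory(wp, frame_interval = 1, geometry = g)
#' @export
make_scripted_trajectory <- function(waypoints, frame_interval = 1,
                                     geometry = tank_geometry(),
                                     fish_id = "scripted") {
  wp <- as.matrix(waypoints)
  if (ncol(wp) != 3L)
    stop("waypoints must have three columns (x, y, z)", call. = FALSE)
  check_finite_scalar(frame_interval, "frame_interval", 0, strict_min = TRUE)
  times <- (seq_len(nrow(wp)) - 1L) * frame_interval
  trajectory3d(times, wp[, 1], wp[, 2], wp[, 3], geometry, fish_id)
}

#' Read / write a trajectory CSV
#'
#' The on-disk dialect is a plain CSV with columns `time_s, x_cm, y_cm,
#' z_cm`. A 5-keypoint pose file with columns `time_s, point_name, x_cm,
#' y_cm, z_cm` is accepted when `body_point` names the keypoint to keep.
#'
#' @param path File path.
#' @param geometry A [tank_geometry()].
#' @param fish_id Identifier; defaults to the file name without extension.
#' @param body_point Keypoint name used to reduce a pose-format file.
#' @return A [trajectory3d()].
#' @export
read_trajectory_csv <- function(path, geometry = tank_geometry(),
                                fish_id = NULL, body_point = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("point_name" %in% names(df)) {
    if (is.null(body_point))
      stop("pose-format file: supply 'body_point' to select a keypoint",
           call. = FALSE)
    df <- df[df$point_name == body_point, , drop = FALSE]
    if (nrow(df) == 0L)
      stop(sprintf("body point '%s' not present in %s", body_point, path),
           call. = FALSE)
  }
  need <- c("time_s", "x_cm", "y_cm", "z_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.null(fish_id))
    fish_id <- sub("\\.[^.]*$", "", basename(path))
  trajectory3d(df$time_s, df$x_cm, df$y_cm, df$z_cm, geometry, fish_id)
}

#' @rdname read_trajectory_csv
#' @param traj A [trajectory3d()] to write.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory3d"))
  df <- data.frame(time_s = traj$times,
                   x_cm = traj$positions[, 1],
                   y_cm = traj$positions[, 2],
                   z_cm = traj$positions[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
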