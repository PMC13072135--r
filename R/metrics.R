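#' Per-step swim speeds
#'
#' Raw frame-to-frame speeds: the Euclidean displacement between
#' consecutive frames divided by the frame interval, converted to mm/s.
#' No smoothing is applied — smoothing would shift the immobility break
#' that [detect_immobility_threshold()] looks for.
#'
#' @param traj A [trajectory3d()].
#' @return An object of class `velocity_series`: list with `speeds`
#'   (mm/s, length `n_frames - 1`) and `frame_interval` (s).
#' @export
compute_velocity <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  d <- diff(traj$positions)
  step_cm <- sqrt(rowSums(d^2))
  structure(
    list(speeds = step_cm * 10 / frame_interval(traj),
         frame_interval = frame_interval(traj)),
    class = "velocity_series"
  )
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %d steps, median %.2f mm/s\n",
              length(x$speeds), median(x$speeds)))
  invisible(x)
}

as_velocity_series <- function(speeds, frame_interval = 1 / 30) {
  stopifnot(is.numeric(speeds), all(speeds >= 0))
  structure(list(speeds = as.numeric(speeds),
                 frame_interval = frame_interval),
            class = "velocity_series")
}

#' Total path length
#'
#' Sum of inter-frame Euclidean displacements, in cm.
#'
#' @param traj A [trajectory3d()].
#' @return Path length, cm.
#' @export
distance_traveled <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  sum(sqrt(rowSums(diff(traj$positions)^2)))
}

#' Mean height above the tank floor
#'
#' Time-average of the vertical coordinate. High values indicate a fish
#' swimming near the surface — the classic bold phenotype in the novel
#' tank; bottom-dwelling reads as anxiety-like.
#'
#' @param traj A [trajectory3d()].
#' @return Mean height, cm.
#' @export
mean_bottom_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  mean(traj$positions[, 3])
}

#' Mean distance from the tank's central axis
#'
#' Time-average horizontal distance from the tank's central vertical axis
#' (thigmotaxis convention: wall-hugging gives large values). Set
#' `use_3d = TRUE` for distance from the 3D tank center instead.
#'
#' @param traj A [trajectory3d()].
#' @param use_3d Measure from the 3D center rather than the vertical axis.
#' @return Mean center distance, cm.
#' @export
mean_center_distance <- function(traj, use_3d = FALSE) {
  stopifnot(inherits(traj, "trajectory3d"))
  ext <- geometry_extents(traj$geometry)
  dx <- traj$positions[, 1] - ext[1] / 2
  dy <- traj$positions[, 2] - ext[2] / 2
  if (use_3d) {
    dz <- traj$positions[, 3] - ext[3] / 2
    mean(sqrt(dx^2 + dy^2 + dz^2))
  } else {
    mean(sqrt(dx^2 + dy^2))
  }
}

# voxel index (1-based) of each frame under the geometry's grid;
# half-open cells with the far boundary folded into the last cell
voxel_ids <- function(traj) {
  g <- traj$geometry
  ext <- geometry_extents(g)
  k <- g$grid_divisions
  idx <- sapply(1:3, function(ax) {
    i <- floor(traj$positions[, ax] / (ext[ax] / k))
    pmin(i, k - 1)
  })
  idx[, 1] + k * idx[, 2] + k * k * idx[, 3] + 1
}

#' Percentage of the tank explored
#'
#' The tank is partitioned into `grid_divisions^3` axis-aligned voxels
#' (1000 by default); the statistic is the percentage of voxels the fish
#' visited at least once. Cells are half-open per axis, with the far tank
#' wall folded into the last cell so boundary positions are countable.
#'
#' @param traj A [trajectory3d()].
#' @return Percent of voxels visited, in \[100/n_voxels, 100\].
#' @export
percent_explored <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  k <- traj$geometry$grid_divisions
  100 * length(unique(voxel_ids(traj))) / k^3
}

#' Data-driven immobility threshold
#'
#' Looks for the break between the immobile and swimming modes of the
#' speed distribution: the deepest valley of a kernel-smoothed histogram
#' of log10(speed) between its two dominant modes. When no two-mode
#' structure exists (unimodal, near-constant or all-zero speeds), the
#' conventional default of 1.5 mm/s is returned and the result carries
#' `attr(, "defaulted") = TRUE` plus a warning.
#'
#' @param vel A `velocity_series` from [compute_velocity()].
#' @param default Fallback threshold, mm/s.
#' @return Threshold in mm/s with attribute `defaulted`.
#' @export
detect_immobility_threshold <- function(vel, default = 1.5) {
  stopifnot(inherits(vel, "velocity_series"))
  pos <- vel$speeds[vel$speeds > 0]
  fallback <- function(msg) {
    warning(paste0(msg, "; using default ", default, " mm/s"),
            call. = FALSE)
    structure(default, defaulted = TRUE)
  }
  if (length(pos) < 10 || diff(range(pos)) == 0)
    return(fallback("no usable speed distribution"))
  lx <- log10(pos)
  den <- density(lx, n = 512)
  y <- den$y
  # interior local maxima of the smoothed density, ignoring tail wiggles
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  is_max <- is_max[y[is_max] >= 0.1 * max(y)]
  if (length(is_max) < 2)
    return(fallback("speed distribution is not bimodal"))
  # two dominant modes = the two highest substantive peaks
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  # a real break must dip well below both modes
  if (y[valley] > 0.75 * min(y[top2]))
    return(fallback("speed distribution is not bimodal"))
  structure(10^den$x[valley], defaulted = FALSE)
}

#' Percentage of time immobile
#'
#' Share of inter-frame steps with speed strictly below the threshold.
#'
#' @param vel A `velocity_series`.
#' @param threshold Immobility cut-off, mm/s (default 1.5).
#' @return Percent of steps immobile, in \[0, 100\].
#' @export
percent_immobile <- function(vel, threshold = 1.5) {
  stopifnot(inherits(vel, "velocity_series"))
  100 * mean(vel$speeds < threshold)
}

#' Maximum velocity (median of the top 5%)
#'
#' A robust maximum: the median of the `ceiling(0.05 * n)` largest speed
#' measurements (midpoint of the two central values when that subset has
#' even size). Requires at least 20 speed samples so the top 5% subset is
#' non-empty by construction.
#'
#' @param vel A `velocity_series`.
#' @return Maximum velocity, mm/s.
#' @export
max_velocity <- function(vel) {
  stopifnot(inherits(vel, "velocity_series"))
  n <- length(vel$speeds)
  if (n < 20)
    stop(sprintf(
      "max_velocity needs >= 20 speed samples (got %d)", n), call. = FALSE)
  k <- ceiling(0.05 * n)
  top <- sort(vel$speeds, decreasing = TRUE)[seq_len(k)]
  median(top)
}

#' Extract the six-measure behavior profile
#'
#' Computes all behavioral measures of one trajectory: mean bottom
#' distance (cm), mean center distance (cm), distance traveled (cm),
#' percent explored (%), percent immobile (%), and maximum velocity
#' (mm/s). Pure function of its inputs.
#'
#' @param traj A [trajectory3d()].
#' @param immobility_threshold Cut-off for [percent_immobile()], mm/s.
#' @param center_3d Use the 3D-center convention for center distance.
#' @return One-row data frame of class `behavior_profile`:
#'   `fish_id, bottom_distance, center_distance, distance_traveled,
#'   percent_explored, percent_immobile, max_velocity`. `max_velocity` is
#'   NA (with a warning) for trajectories with fewer than 21 frames.
#' @export
extract_profile <- function(traj, immobility_threshold = 1.5,
                            center_3d = FALSE) {
  stopifnot(inherits(traj, "trajectory3d"))
  vel <- compute_velocity(traj)
  maxv <- if (length(vel$speeds) >= 20) max_velocity(vel) else {
    warning("too few frames for max_velocity; reporting NA",
            call. = FALSE)
    NA_real_
  }
  out <- data.frame(
    fish_id = traj$fish_id,
    bottom_distance = mean_bottom_distance(traj),
    center_distance = mean_center_distance(traj, use_3d = center_3d),
    distance_traveled = distance_traveled(traj),
    percent_explored = percent_explored(traj),
    percent_immobile = percent_immobile(vel, immobility_threshold),
    max_velocity = maxv,
    stringsAsFactors = FALSE
  )
  class(out) <- c("behavior_profile", "data.frame")
  out
}

#' Behavior metrics for a whole cohort
#'
#' Applies [extract_profile()] to every trajectory in a cohort.
#'
#' @param trajectories A named list of [trajectory3d()] (for example
#'   `cohort$trajectories`).
#' @param immobility_threshold Cut-off in mm/s.
#' @return Data frame, one row per fish.
#' @export
behavior_metrics_table <- function(trajectories,
                                   immobility_threshold = 1.5) {
  out <- do.call(rbind, lapply(trajectories, extract_profile,
                               immobility_threshold = immobility_threshold))
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
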