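#' Tank geometry
#'
#' Describes the novel-tank arena: an axis-aligned box with an exploration
#' grid overlaid on it. The default is the standard 15 x 15 x 15 cm acrylic
#' novel tank divided 10-fold per axis, i.e. 1000 voxels.
#'
#' @param width_x,depth_y,height_z Tank extents in cm; all must be positive.
#' @param grid_divisions Number of grid divisions per axis used by
#'   [percent_explored()]; the voxel count is `grid_divisions^3`.
#'
#' @return An object of class `tank_geometry`.
#' @examples
#' tank_geometry()
#' tank_geometry(15.2, 8.9, 6.0)  # respirometry chamber footprint
#' @export
tank_geometry <- function(width_x = 15, depth_y = 15, height_z = 15,
                          grid_divisions = 10L) {
  check_finite_scalar(width_x, "width_x", 0, strict_min = TRUE)
  check_finite_scalar(depth_y, "depth_y", 0, strict_min = TRUE)
  check_finite_scalar(height_z, "height_z", 0, strict_min = TRUE)
  check_finite_scalar(grid_divisions, "grid_divisions", 1)
  structure(
    list(width_x = width_x, depth_y = depth_y, height_z = height_z,
         grid_divisions = as.integer(grid_divisions)),
    class = "tank_geometry"
  )
}

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf("<tank_geometry> %g x %g x %g cm, %d^3 = %d voxels\n",
              x$width_x, x$depth_y, x$height_z,
              x$grid_divisions, x$grid_divisions^3L))
  invisible(x)
}

geometry_extents <- function(geometry) {
  c(geometry$width_x, geometry$depth_y, geometry$height_z)
}
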