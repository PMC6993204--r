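#' Tissue geometry
#'
#' Geometry of the artificial-tissue fixture: the tissue surface frame (with
#' its z axis normal to the tissue face), the planar outline of the tissue,
#' and the needle entrance / exit points. The exit points are data inputs
#' (extracted upstream, e.g. from calibrated camera images).
#'
#' @param origin Origin of the surface frame in world coordinates, m.
#' @param axes 3 x 3 rotation matrix whose columns are the surface frame's
#'   x, y, z axes expressed in world coordinates; the third column must be
#'   the outward tissue normal.
#' @param contour k x 2 matrix of the tissue outline in surface-frame (x, y)
#'   coordinates, m; a simple (non-self-intersecting) polygon.
#' @param entrance_point Actual needle entrance point, world 3-vector, m.
#' @param desired_exit Desired exit point, world 3-vector, m.
#' @param actual_exit Actual exit point, world 3-vector, m, or `NULL` when
#'   unavailable (open-setup trials).
#' @param marker_radius Radius of the exit-point marker, m. Default 0.002.
#' @return An object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(origin = c(0, 0, 0), axes = diag(3),
                            contour = default_contour(),
                            entrance_point, desired_exit, actual_exit = NULL,
                            marker_radius = 0.002) {
  origin <- as_vec3(origin, "origin")
  axes <- as.matrix(axes)
  if (any(abs(crossprod(axes) - diag(3)) > 1e-8))
    stop("`axes` must be orthonormal", call. = FALSE)
  contour <- as.matrix(contour)
  if (ncol(contour) != 2 || nrow(contour) < 3)
    stop("`contour` must be a k x 2 polygon with k >= 3", call. = FALSE)
  geom <- structure(list(origin = origin, axes = unname(axes),
                         contour = unname(contour),
                         entrance_point = as_vec3(entrance_point, "entrance_point"),
                         desired_exit = as_vec3(desired_exit, "desired_exit"),
                         actual_exit = if (is.null(actual_exit)) NULL
                                       else as_vec3(actual_exit, "actual_exit"),
                         marker_radius = marker_radius),
                    class = "tissue_geometry")
  for (p in c("entrance_point", "desired_exit")) {
    xy <- surface_coords(matrix(geom[[p]], 1), geom)[, 1:2, drop = FALSE]
    if (!point_in_contour(xy, geom))
      stop(sprintf("`%s` lies outside the tissue contour", p), call. = FALSE)
  }
  geom
}

# 80 mm square tissue outline centered on the frame origin.
default_contour <- function(half_side = 0.04) {
  rbind(c(-half_side, -half_side), c(half_side, -half_side),
        c(half_side, half_side), c(-half_side, half_side))
}

# World points (n x 3) -> surface-frame coordinates (n x 3): columns are
# in-plane x, y and height above the tissue face.
surface_coords <- function(points, geom) {
  points <- matrix(points, ncol = 3)
  sweep(points, 2, geom$origin) %*% geom$axes
}

surface_to_world <- function(points, geom) {
  points <- matrix(points, ncol = 3)
  sweep(points %*% t(geom$axes), 2, geom$origin, "+")
}

# TRUE for each row of `xy` (surface-frame in-plane coordinates) that falls
# inside the tissue contour.
point_in_contour <- function(xy, geom) {
  xy <- matrix(xy, ncol = 2)
  mgcv::in.out(rbind(geom$contour, geom$contour[1, ]), xy)
}

# Euclidean distance between actual entrance and exit points (d_ie), the
# normalizer of the total normalized force. NULL when no actual exit exists.
entrance_exit_distance <- function(geom) {
  if (is.null(geom$actual_exit)) return(NULL)
  sqrt(sum((geom$entrance_point - geom$actual_exit)^2))
}

# Rigidly transform a geometry (used by invariance tests and the synthetic
# generator): world' = R %*% world + shift.
transform_geometry <- function(geom, rotation = diag(3), shift = c(0, 0, 0)) {
  g <- geom
  g$origin <- as.numeric(rotation %*% geom$origin + shift)
  g$axes <- rotation %*% geom$axes
  g$entrance_point <- as.numeric(rotation %*% geom$entrance_point + shift)
  g$desired_exit <- as.numeric(rotation %*% geom$desired_exit + shift)
  if (!is.null(geom$actual_exit))
    g$actual_exit <- as.numeric(rotation %*% geom$actual_exit + shift)
  g
}
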