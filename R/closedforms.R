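# Closed-form divergence/curl/shear for the canonical surface configurations.
#
# All cases share the translation-only component algebra: with
# tu = x v_z - f v_x, tv = y v_z - f v_y and a depth surface Z(x, y),
#   du/dx = v_z/Z - tu Zx/Z^2        du/dy = -tu Zy/Z^2
#   dv/dx = -tv Zx/Z^2               dv/dy = v_z/Z - tv Zy/Z^2
# so the components are linear in (Zx, Zy, 1/Z). Fixating eye-rotation terms
# are an order of magnitude smaller in the behavioural regimes and are left
# out of the closed forms (they are present in the rendered fields that the
# finite-difference oracle uses for smooth regions away from fixation).

components_from_depth <- function(cam, x, y, Z, Zx, Zy, v) {
  f <- cam$f
  tu <- x * v[3] - f * v[1]
  tv <- y * v[3] - f * v[2]
  list(div = 2 * v[3] / Z - (tu * Zx + tv * Zy) / Z^2,
       curl = (-tv * Zx + tu * Zy) / Z^2,
       shear1 = (-tu * Zx + tv * Zy) / Z^2,
       shear2 = -(tv * Zx + tu * Zy) / Z^2)
}

#' Components for translation toward a tilted plane
#'
#' A plane whose normal is tilted by `alpha` away from the gaze direction
#' (within the xz-plane for `tilt_axis = "x"`, the canonical
#' fixation-at-centre configuration; within the yz-plane for
#' `tilt_axis = "y"`), at distance `d`
#' along the normal, under pure translation `v`. For `alpha = 0` and forward
#' motion this reduces to `div = 2 v_z / d` with zero curl and shear; for
#' `alpha > 0` divergence and Type I shear are affine in the declination
#' while curl and Type II shear are independent of it.
#'
#' @param alpha tilt angle (rad), `|alpha| < pi/2`.
#' @param d plane distance along its normal (m), `> 0`.
#' @param v translational velocity (m/s).
#' @param x,y evaluation image coordinates (image-plane units; vectors
#'   recycle).
#' @param cam a [camera_model()].
#' @param tilt_axis `"x"` or `"y"`: the image axis along which the plane is
#'   tilted.
#' @return list of vectors `div`, `curl`, `shear1`, `shear2` (1/s).
#' @export
components_translation_plane <- function(alpha, d, v, x, y = 0,
                                         cam = camera_model(),
                                         tilt_axis = c("x", "y")) {
  tilt_axis <- match.arg(tilt_axis)
  if (abs(alpha) >= pi / 2)
    stop("tangential configuration: use components_parallel_plane()")
  stopifnot(d > 0)
  f <- cam$f
  n <- if (tilt_axis == "x") c(sin(alpha), 0, cos(alpha))
       else c(0, sin(alpha), cos(alpha))
  denom <- n[1] * x + n[2] * y + n[3] * f
  Z <- d * f / denom
  Zx <- -n[1] * Z^2 / (d * f)
  Zy <- -n[2] * Z^2 / (d * f)
  components_from_depth(cam, x, y, Z, Zx, Zy, v)
}

#' Components for tangential fixation of a gaze-parallel plane
#'
#' A plane parallel to the gaze direction passing at lateral offset `x_off`
#' (image-plane units) from the line of sight, evaluated at a fixed off-axis
#' image point. Every component is exactly proportional to `1 / x_off` (the
#' hyperbola law), diverging as the fixation becomes tangential
#' (`x_off -> 0`), and curl and Type II shear are identical for all inputs.
#'
#' @param x_off lateral image-plane offset(s) of the plane from gaze;
#'   `x_off = 0` is the tangential singularity.
#' @param v translational velocity (m/s).
#' @param cam a [camera_model()].
#' @param at length-2 evaluation image point `(x0, y0)`; the default sits
#'   about a degree off-axis so that no component vanishes by symmetry.
#' @return as [components_translation_plane()]; if any `x_off` is zero the
#'   value is a `"tangential_singularity"` object, not a number.
#' @export
components_parallel_plane <- function(x_off, v, cam = camera_model(),
                                      at = c(0.02, 0.015) * cam$f) {
  if (any(x_off == 0)) {
    return(structure(list(message = "singular (tangential fixation)"),
                     class = "tangential_singularity"))
  }
  f <- cam$f
  x0 <- at[1]; y0 <- at[2]
  Z <- x_off * f / x0          # plane X = x_off (image units) seen at x0
  Zx <- -Z / x0
  components_from_depth(cam, x0, y0, Z, Zx, 0, v)
}

#' Components for tangential fixation of a cylindrical (curved) edge
#'
#' A smoothly curved surface, modelled as a vertical circular cylinder of
#' radius `R` whose near surface reaches the camera (silhouette edge at
#' `(X, Z) = (R, d)`). Under the small-angle parallel-projection
#' approximation the visible depth is `Z(x) = d - sqrt(R^2 - x^2)`, so in
#' the tangential configuration `d = R` the depth itself vanishes as
#' `x -> 0` while the depth slope diverges at the silhouette `x -> R`: all
#' four components approach +/- infinity at both ends of `(0, R)`, with a
#' magnitude minimum in between.
#'
#' @param R post radius (m).
#' @param v translational velocity (m/s).
#' @param x evaluation coordinate(s) in `(0, R)` (image-plane units under
#'   the parallel-projection identification `x = X`).
#' @param d axial distance of the silhouette edge (m), `>= R`; default the
#'   tangential case `d = R`.
#' @param y evaluation y coordinate.
#' @param cam a [camera_model()].
#' @return as [components_translation_plane()].
#' @export
components_cylinder <- function(R, v, x, d = R, y = 0, cam = camera_model()) {
  stopifnot(R > 0, d >= R)
  if (any(x <= 0 | x >= R)) stop("x must lie strictly inside (0, R)")
  s <- sqrt(R^2 - x^2)
  Z <- d - s
  Zx <- x / s
  components_from_depth(cam, x, y, Z, Zx, 0, v)
}

#' Apical edge geometry
#'
#' An object's outer vertical edge: a 3D line from `P0` (on the ground)
#' rising by `h`, with the ground plane `d_g` below the camera behind it.
#' The camera is rotated by `yaw` then `pitch` (zero roll). The depth jump
#' at the edge is approximated by projecting the edge line onto the ground
#' (a "shadow" cast from the camera's nodal point), rotating both lines into
#' camera coordinates, and reading the depth difference between
#' corresponding points; the x-partial of depth at the edge is that
#' difference over the image-coordinate separation, and the y-partial is
#' taken as zero.
#'
#' @param P0 length-3 start of the edge line (world frame, on the ground:
#'   `P0[2] = -d_g`).
#' @param h edge height (m).
#' @param d_g camera height above ground (m).
#' @param yaw,pitch camera rotation (rad).
#' @return object of class `apical_edge`.
#' @export
apical_edge <- function(P0, h, d_g, yaw = 0, pitch = 0) {
  P0 <- as.numeric(P0)
  stopifnot(length(P0) == 3, h > 0, d_g > 0)
  if (abs(P0[2] + d_g) > 1e-9)
    stop("edge line must start on the ground plane (P0[2] = -d_g)")
  structure(list(P0 = P0, h = h, d_g = d_g,
                 pose = camera_pose(yaw = yaw, pitch = pitch)),
            class = "apical_edge")
}

# edge/shadow geometry sampled at parameter lambda in (0, 1]; the shadow is
# cast from the camera's nodal point, so each shadow point lies on the same
# visual ray as its edge point: the pair measures the depth jump across the
# edge at one image location
edge_geometry <- function(edge, lambda, cam) {
  f <- cam$f
  E <- outer(rep(1, length(lambda)), edge$P0) +
    outer(lambda, c(0, edge$h, 0))               # edge points, world frame
  ey <- E[, 2]
  if (any(ey >= 0))
    stop("edge points at or above the camera have no ground shadow")
  s <- -edge$d_g / ey
  S <- E * s                                      # shadow points on ground
  Rt <- t(edge$pose$R)
  Ec <- E %*% t(Rt); Sc <- S %*% t(Rt)            # camera coordinates
  list(x = f * Ec[, 1] / Ec[, 3], y = f * Ec[, 2] / Ec[, 3],
       Z = Ec[, 3], Zs = Sc[, 3])
}

#' Components at an apical edge
#'
#' Evaluates the closed-form components on the projected edge line of an
#' [apical_edge()]. Either supply the line parameter `lambda` directly or an
#' image point `(x, y)` that must fall on the projected edge line (within
#' `tol_px` pixels perpendicular distance, else a domain error).
#'
#' At the edge itself the depth derivative is undefined; it is approximated
#' by the depth jump between the edge point and the background ("shadow")
#' point on its visual ray, divided by the across-edge sampling offset `dx`
#' (image-plane units, signed toward the background side, default one
#' pixel). The y-partial of depth is taken as zero along the vertical edge.
#' Consequently pure sideward motion excites only divergence and Type I
#' shear, pure vertical motion only curl and Type II shear, and forward
#' motion all four; the depth-jump contribution to every component scales
#' as `1/dx`, diverging as the sampling approaches the discontinuity.
#'
#' @param edge an [apical_edge()].
#' @param v translational velocity (m/s).
#' @param cam a [camera_model()].
#' @param lambda edge-line parameter(s) in (0, 1].
#' @param x,y image point (used when `lambda` is missing).
#' @param dx across-edge sampling offset(s), image-plane units (nonzero).
#' @param tol_px tolerance (pixels) for accepting `(x, y)` as on the line.
#' @return as [components_translation_plane()], plus the image coordinates
#'   `x`, `y` of the evaluated points and `lambda`.
#' @export
components_apical_edge <- function(edge, v, cam = camera_model(),
                                   lambda = NULL, x = NULL, y = NULL,
                                   dx = 1 / cam$px_per_unit,
                                   tol_px = 0.5) {
  stopifnot(inherits(edge, "apical_edge"))
  if (is.null(lambda)) {
    stopifnot(!is.null(x), !is.null(y))
    # invert the projected line for lambda, then check perpendicular distance
    A <- world_to_camera(edge$pose, edge$P0)
    B <- world_to_camera(edge$pose, c(0, edge$h, 0))
    lam <- (cam$f * A[2] - y * A[3]) / (y * B[3] - cam$f * B[2])
    g <- edge_geometry(edge, pmin(pmax(lam, 1e-6), 1), cam)
    dpx <- sqrt(((g$x - x) * cam$px_per_unit)^2 +
                  ((g$y - y) * cam$px_per_unit_y)^2)
    if (any(dpx > tol_px))
      stop("point is not on the projected edge line (off by ",
           signif(max(dpx), 3), " px)")
    lambda <- pmin(pmax(lam, 1e-6), 1)
  }
  stopifnot(all(lambda > 0 & lambda <= 1), all(dx != 0))
  g <- edge_geometry(edge, lambda, cam)
  Zx <- (g$Zs - g$Z) / dx
  out <- components_from_depth(cam, g$x, g$y, g$Z, Zx, 0, v)
  out$x <- g$x; out$y <- g$y; out$lambda <- lambda
  out
}
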