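#' Instantaneous image flow for a passive observer
#'
#' The classical instantaneous motion-field model: for a pinhole camera with
#' focal length `f` translating with `v` and rotating with `omega`, the image
#' velocity at image location `(x, y)` of a scene point at depth `Z` is the
#' sum of a depth-dependent translational term and a depth-free rotational
#' term:
#' \deqn{u = (x v_z - f v_x)/Z + \omega_x x y/f - \omega_y (f + x^2/f) + \omega_z y}
#' \deqn{v = (y v_z - f v_y)/Z + \omega_x (f + y^2/f) - \omega_y x y/f - \omega_z x}
#' Coordinates are analytic image-plane coordinates (origin at the principal
#' point, y up); the sign convention is pinned by a trajectory
#' finite-difference oracle in the test suite, which is convention-free.
#'
#' @param cam a [camera_model()].
#' @param x,y image-plane coordinates (vectors or matrices, same shape).
#' @param Z scene depth(s) in metres, `> 0` (same shape as `x` or scalar).
#' @param v translational velocity (m/s).
#' @param omega rotational velocity (rad/s).
#' @param parts if `TRUE` return translational and rotational terms
#'   separately (they superimpose linearly).
#' @return list with components `u`, `v` (image-plane units/s); with
#'   `parts = TRUE` also `trans` and `rot` sublists.
#' @export
flow_passive <- function(cam, x, y, Z, v, omega = c(0, 0, 0), parts = FALSE) {
  if (any(Z <= 0, na.rm = TRUE)) stop("depth must be positive")
  f <- cam$f
  tu <- (x * v[3] - f * v[1]) / Z
  tv <- (y * v[3] - f * v[2]) / Z
  ru <- omega[1] * x * y / f - omega[2] * (f + x^2 / f) + omega[3] * y
  rv <- omega[1] * (f + y^2 / f) - omega[2] * x * y / f - omega[3] * x
  out <- list(u = tu + ru, v = tv + rv)
  if (parts) {
    out$trans <- list(u = tu, v = tv)
    out$rot <- list(u = ru + 0 * x, v = rv + 0 * x)
  }
  out
}

#' Instantaneous image flow for a fixating observer
#'
#' Image flow for an observer translating with `v` while performing the
#' compensatory zero-roll eye rotation that keeps a scene point fixated
#' (stationary on the image plane). The rotation is not free: it is derived
#' from `v` and the fixation point by [fixation_rates()], so the flow is the
#' passive model evaluated at those rates. The flow vanishes at the image
#' projection of the fixated point (the centre of motion), and as
#' `Z_F -> Inf` it converges to the pure translational flow.
#'
#' @inheritParams flow_passive
#' @param fix a [fixation_spec()].
#' @return as [flow_passive()].
#' @export
flow_fixating <- function(cam, x, y, Z, v, fix, parts = FALSE) {
  omega <- fixation_rates(cam, v, fix)
  flow_passive(cam, x, y, Z, v, omega, parts = parts)
}

#' Dense flow field container
#'
#' Holds dense grids of image velocities in analytic image-plane convention
#' (y up, image-plane units/s) together with the camera that defines the
#' raster, an optional validity mask, and (optionally) the separately stored
#' translational and rotational layers. Masked entries (rays that hit no
#' surface) are `NA`, never silently zero.
#'
#' @param u,v numeric matrices (height x width) of image velocities.
#' @param cam a [camera_model()].
#' @param mask logical matrix, `TRUE` where the flow is defined.
#' @param trans,rot optional lists with `u`, `v` layers.
#' @return object of class `flow_field`.
#' @export
flow_field <- function(u, v, cam, mask = NULL, trans = NULL, rot = NULL) {
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)))
  if (is.null(mask)) mask <- !is.na(u) & !is.na(v)
  stopifnot(all(dim(mask) == dim(u)))
  structure(list(u = u, v = v, cam = cam, mask = mask,
                 trans = trans, rot = rot,
                 convention = list(y_axis = "up", units = "image-plane units/s")),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %dx%d px, %d masked, |flow| max %.3g units/s\n",
              ncol(x$u), nrow(x$u), sum(!x$mask),
              suppressWarnings(max(sqrt(x$u^2 + x$v^2), na.rm = TRUE))))
  invisible(x)
}

#' Pixel-raster view of a flow field
#'
#' Converts a [flow_field()] from the analytic convention (image-plane
#' units/s, y up) to the raster convention used by pixel-based flow formats
#' (pixels/s, y down): `u` is scaled, `v` is scaled and sign-flipped.
#'
#' @param field a [flow_field()].
#' @return list of matrices `u`, `v` in pixels/s, y-down.
#' @export
flow_pixels <- function(field) {
  cam <- field$cam
  list(u = field$u * cam$px_per_unit, v = -field$v * cam$px_per_unit_y)
}

#' Render a dense flow field from a depth map
#'
#' Evaluates the passive or fixating flow model at every pixel of the camera
#' raster using the per-pixel depths of `depth`. The translational and
#' rotational layers are stored separately and superimpose linearly (their
#' sum is exactly the rendered field).
#'
#' @param cam a [camera_model()].
#' @param depth a [depth_map()] whose grid matches the camera raster.
#' @param motion a [self_motion()].
#' @return a [flow_field()].
#' @export
render_flow <- function(cam, depth, motion) {
  stopifnot(inherits(depth, "depth_map"))
  if (!all(dim(depth$Z) == c(cam$height, cam$width)))
    stop("depth grid does not match the camera raster")
  g <- camera_grid(cam)
  Z <- depth$Z
  Z[!depth$mask] <- NA_real_
  omega <- if (motion$mode == "fixating")
    fixation_rates(cam, motion$v, motion$fixation) else motion$omega
  Zsafe <- ifelse(is.na(Z), 1, Z)  # placeholder; masked below
  fl <- flow_passive(cam, g$x, g$y, Zsafe, motion$v, omega, parts = TRUE)
  for (nm in c("u", "v")) {
    fl$trans[[nm]][is.na(Z)] <- NA_real_
    fl[[nm]] <- fl$trans[[nm]] + fl$rot[[nm]]
  }
  flow_field(fl$u, fl$v, cam, mask = !is.na(Z), trans = fl$trans, rot = fl$rot)
}

#' Focus of expansion (or contraction) of a translational flow
#'
#' For translation with `v_z != 0` the translational flow field radiates from
#' the image point `(f v_x/v_z, f v_y/v_z)`: the focus of expansion (FOE) for
#' forward motion (`v_z > 0`) and focus of contraction (FOC) for backward
#' motion. Lateral translation (`v_z = 0`) has no such singular point.
#'
#' @param v translational velocity (m/s).
#' @param cam a [camera_model()].
#' @return list with `x`, `y` (image-plane coords) and `type` ("FOE"/"FOC"),
#'   or `NULL` (invisibly printed as undefined) when `v_z = 0`.
#' @export
find_foe <- function(v, cam) {
  if (v[3] == 0) return(NULL)
  list(x = cam$f * v[1] / v[3], y = cam$f * v[2] / v[3],
       type = if (v[3] > 0) "FOE" else "FOC")
}

#' Centre of motion of a rendered flow field
#'
#' Locates, with sub-pixel precision, the stationary point of the full flow:
#' the pixel of minimal flow magnitude, refined by a local linear fit
#' `u ~ a + b x + c y`, `v ~ ...` on a neighbourhood and solved for the
#' common zero. For fixating motion the centre of motion coincides with the
#' projection of the fixated point; for translation-plus-rotation it is
#' displaced from the FOE.
#'
#' @param field a [flow_field()].
#' @param halfwin half-width (pixels) of the refinement neighbourhood.
#' @return list with `x`, `y` (image-plane), `col`, `row` (pixels), or
#'   `NULL` when no zero crossing is present in either component.
#' @export
find_com <- function(field, halfwin = 3L) {
  u <- field$u; v <- field$v
  ok <- field$mask
  if (!any(ok)) return(NULL)
  rng_u <- range(u[ok]); rng_v <- range(v[ok])
  if (rng_u[1] > 0 || rng_u[2] < 0 || rng_v[1] > 0 || rng_v[2] < 0)
    return(NULL)  # no sign change: no stationary point inside the field
  mag <- ifelse(ok, u^2 + v^2, Inf)
  idx <- arrayInd(which.min(mag), dim(mag))
  r0 <- idx[1]; c0 <- idx[2]
  rows <- max(1, r0 - halfwin):min(nrow(u), r0 + halfwin)
  cols <- max(1, c0 - halfwin):min(ncol(u), c0 + halfwin)
  g <- camera_grid(field$cam)
  sel <- ok[rows, cols]
  # a depth discontinuity through the window would corrupt the linear fit:
  # keep only the slow half of the window (the COM side)
  magw <- sqrt(mag[rows, cols])
  sel <- sel & magw <= stats::quantile(magw[sel], 0.5)
  if (sum(sel) >= 6) {
    X <- cbind(1, as.vector(g$x[rows, cols])[sel], as.vector(g$y[rows, cols])[sel])
    bu <- qr.solve(X, as.vector(u[rows, cols])[sel])
    bv <- qr.solve(X, as.vector(v[rows, cols])[sel])
    A <- rbind(bu[2:3], bv[2:3])
    if (abs(det(A)) > 1e-12 * (sum(A^2) + 1e-300)) {
      p <- solve(A, -c(bu[1], bv[1]))
      px <- plane_to_pixel(field$cam, p[1], p[2])
      # accept the refinement only if it stays near the grid minimum
      if (abs(px$col - c0) <= 2 * halfwin && abs(px$row - r0) <= 2 * halfwin)
        return(list(x = p[1], y = p[2], col = px$col, row = px$row))
    }
  }
  xy <- pixel_to_plane(field$cam, c0, r0)
  list(x = xy$x, y = xy$y, col = c0, row = r0)
}
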