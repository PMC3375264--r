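#' Flow Jacobian field
#'
#' Per-pixel spatial partial derivatives of the image flow, in 1/s (the
#' Jacobian is unit-free in the sense that flow and coordinates share the
#' same length unit). `provenance` records how the partials were obtained:
#' `"analytic"` (exact symbolic evaluation), `"finite-difference"` (central
#' differences of a rendered field) or `"operator-bank"`.
#'
#' @param dudx,dudy,dvdx,dvdy numeric matrices.
#' @param provenance character tag.
#' @param mask logical matrix where the partials are valid.
#' @param cam optional [camera_model()].
#' @return object of class `jacobian_field`.
#' @export
jacobian_field <- function(dudx, dudy, dvdx, dvdy,
                           provenance = c("analytic", "finite-difference",
                                          "operator-bank"),
                           mask = NULL, cam = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(dudx), all(dim(dudy) == dim(dudx)),
            all(dim(dvdx) == dim(dudx)), all(dim(dvdy) == dim(dudx)))
  if (is.null(mask))
    mask <- is.finite(dudx) & is.finite(dudy) & is.finite(dvdx) & is.finite(dvdy)
  structure(list(dudx = dudx, dudy = dudy, dvdx = dvdx, dvdy = dvdy,
                 provenance = provenance, mask = mask, cam = cam),
            class = "jacobian_field")
}

#' Analytic flow Jacobian from a depth map
#'
#' Exact per-pixel evaluation of the four flow partials for translational
#' plus (derived or free) rotational motion over a depth map with analytic
#' depth partials:
#' \deqn{\partial_x u = v_z/Z - (x v_z - f v_x) Z_x/Z^2 + \omega_x y/f - 2\omega_y x/f}
#' and correspondingly for the other three entries. For a fixating observer
#' the rates come from [fixation_rates()]; no partial derivatives of the
#' fixation depth `Z_F` occur, since `Z_F` does not vary with image position.
#' Pixels without analytic depth partials (or flagged as discontinuities)
#' are masked; if the depth map carries no partials at all the function
#' falls back to central differences of the rendered flow and tags the
#' result accordingly.
#'
#' @param cam a [camera_model()].
#' @param depth a [depth_map()] with analytic partials.
#' @param motion a [self_motion()].
#' @return a [jacobian_field()].
#' @export
jacobian_analytic <- function(cam, depth, motion) {
  stopifnot(inherits(depth, "depth_map"))
  if (is.null(depth$dZdx) || is.null(depth$dZdy)) {
    return(jacobian_fd(render_flow(cam, depth, motion)))
  }
  g <- camera_grid(cam)
  f <- cam$f
  v <- motion$v
  omega <- if (motion$mode == "fixating")
    fixation_rates(cam, v, motion$fixation) else motion$omega
  Z <- depth$Z; Zx <- depth$dZdx; Zy <- depth$dZdy
  x <- g$x; y <- g$y
  tu <- x * v[3] - f * v[1]
  tv <- y * v[3] - f * v[2]
  dudx <- v[3] / Z - tu * Zx / Z^2 + omega[1] * y / f - 2 * omega[2] * x / f
  dudy <- -tu * Zy / Z^2 + omega[1] * x / f + omega[3]
  dvdx <- -tv * Zx / Z^2 - omega[2] * y / f - omega[3]
  dvdy <- v[3] / Z - tv * Zy / Z^2 + 2 * omega[1] * y / f - omega[2] * x / f
  mask <- depth$mask & !depth$disc & is.finite(Zx) & is.finite(Zy)
  for (m in list(dudx, dudy, dvdx, dvdy)) mask <- mask & is.finite(m)
  jacobian_field(dudx, dudy, dvdx, dvdy, "analytic", mask = mask, cam = cam)
}

#' Finite-difference flow Jacobian of a rendered field
#'
#' Central differences of the flow grids with respect to the analytic
#' image-plane coordinates (y up). Border pixels and pixels adjacent to
#' masked entries are masked.
#'
#' @param field a [flow_field()].
#' @return a [jacobian_field()] tagged `"finite-difference"`.
#' @export
jacobian_fd <- function(field) {
  cam <- field$cam
  hx <- 1 / cam$px_per_unit     # pixel pitch, image-plane units
  hy <- 1 / cam$px_per_unit_y
  u <- field$u; v <- field$v
  u[!field$mask] <- NA_real_; v[!field$mask] <- NA_real_
  nr <- nrow(u); nc <- ncol(u)
  cd <- function(m, along) {
    out <- matrix(NA_real_, nr, nc)
    if (along == "x") {
      out[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / (2 * hx)
    } else {
      # row index grows downward while analytic y grows upward
      out[2:(nr - 1), ] <- (m[1:(nr - 2), ] - m[3:nr, ]) / (2 * hy)
    }
    out
  }
  jacobian_field(cd(u, "x"), cd(u, "y"), cd(v, "x"), cd(v, "y"),
                 "finite-difference", cam = cam)
}

#' Divergence / curl / shear component field
#'
#' The four linear invariants of the local flow Jacobian:
#' `div = du/dx + dv/dy` (isotropic expansion), `curl = dv/dx - du/dy`
#' (positive = counterclockwise), `shear_I = du/dx - dv/dy` (deformation
#' along the coordinate axes) and `shear_II = du/dy + dv/dx` (deformation
#' along axes rotated 45 degrees counterclockwise). The map Jacobian ->
#' components is a linear bijection; [recompose()] inverts it exactly.
#'
#' @param J a [jacobian_field()] (or a list with the four partials).
#' @return object of class `component_field` with matrices `div`, `curl`,
#'   `shear1`, `shear2`, plus `provenance` and `mask`.
#' @export
decompose <- function(J) {
  structure(list(div = J$dudx + J$dvdy,
                 curl = J$dvdx - J$dudy,
                 shear1 = J$dudx - J$dvdy,
                 shear2 = J$dudy + J$dvdx,
                 provenance = if (!is.null(J$provenance)) J$provenance else "analytic",
                 mask = J$mask, cam = J$cam),
            class = "component_field")
}

#' @rdname decompose
#' @param comp a `component_field`.
#' @return `recompose()`: a [jacobian_field()] with
#'   `decompose(recompose(comp))` identical to `comp`.
#' @export
recompose <- function(comp) {
  jacobian_field(dudx = (comp$div + comp$shear1) / 2,
                 dudy = (comp$shear2 - comp$curl) / 2,
                 dvdx = (comp$shear2 + comp$curl) / 2,
                 dvdy = (comp$div - comp$shear1) / 2,
                 provenance = if (!is.null(comp$provenance)) comp$provenance else "analytic",
                 mask = comp$mask, cam = comp$cam)
}

component_names <- c("div", "curl", "shear1", "shear2")
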