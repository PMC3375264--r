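#' Fixation specification
#'
#' The 3D point, in camera coordinates (metres, camera at the origin, looking
#' down +Z, y up), that a gaze-stabilizing observer keeps stationary on the
#' image. Roll rotation is identically zero for such an observer; the
#' compensatory rotation uses yaw and pitch only.
#'
#' @param point numeric length-3, `(X_F, Y_F, Z_F)` with `Z_F > 0`.
#' @return object of class `fixation_spec`.
#' @export
fixation_spec <- function(point) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3, is.finite(point))
  if (point[3] <= 0) stop("fixation point must lie in front of the camera (Z_F > 0)")
  structure(list(point = point), class = "fixation_spec")
}

#' Self-motion state
#'
#' Instantaneous rigid self-motion of the observer: translational velocity
#' `v` (m/s) and either a free rotational velocity `omega` (rad/s, passive
#' mode) or a fixation constraint (fixating mode). In fixating mode the
#' rotational velocity is not free: it is the unique zero-roll (yaw + pitch)
#' rotation that keeps the fixated point stationary on the image plane, as
#' computed by [fixation_rates()].
#'
#' @param v numeric length-3 translational velocity (m/s), camera frame.
#' @param omega numeric length-3 rotational velocity (rad/s); ignored in
#'   fixating mode.
#' @param fixation a [fixation_spec()] (switches the state to fixating mode).
#' @return object of class `self_motion`.
#' @export
self_motion <- function(v = c(0, 0, 0), omega = c(0, 0, 0), fixation = NULL) {
  v <- as.numeric(v); stopifnot(length(v) == 3, is.finite(v))
  if (is.null(fixation)) {
    omega <- as.numeric(omega); stopifnot(length(omega) == 3, is.finite(omega))
    structure(list(v = v, omega = omega, mode = "passive", fixation = NULL),
              class = "self_motion")
  } else {
    stopifnot(inherits(fixation, "fixation_spec"))
    structure(list(v = v, omega = NULL, mode = "fixating", fixation = fixation),
              class = "self_motion")
  }
}

#' @export
print.self_motion <- function(x, ...) {
  cat(sprintf("<self_motion> %s, v = (%.3g, %.3g, %.3g) m/s", x$mode,
              x$v[1], x$v[2], x$v[3]))
  if (x$mode == "passive") {
    cat(sprintf(", omega = (%.3g, %.3g, %.3g) rad/s\n",
                x$omega[1], x$omega[2], x$omega[3]))
  } else {
    p <- x$fixation$point
    cat(sprintf(", fixating (%.3g, %.3g, %.3g) m\n", p[1], p[2], p[3]))
  }
  invisible(x)
}

#' Gaze-stabilizing rotation rates for a fixating observer
#'
#' Solves for the zero-roll rotational velocity `(omega_x, omega_y, 0)` that
#' makes the image flow vanish at the projection of the fixated point. The
#' fixated point is a scene point at depth `Z_F`; requiring both flow
#' components of the passive model to be zero there gives a 2x2 linear system
#' in `(omega_x, omega_y)` whose determinant `f^2 + x_F^2 + y_F^2` is always
#' positive, so the rates are unique.
#'
#' For a fixation point on the optical axis this reduces to
#' `omega_x = v_y / Z_F`, `omega_y = -v_x / Z_F`.
#'
#' @param cam a [camera_model()].
#' @param v translational velocity (m/s), camera frame.
#' @param fix a [fixation_spec()].
#' @return numeric length-3 rotational velocity (rad/s), third entry 0.
#' @export
fixation_rates <- function(cam, v, fix) {
  stopifnot(inherits(fix, "fixation_spec"))
  f <- cam$f
  P <- fix$point
  ZF <- P[3]
  xF <- f * P[1] / ZF
  yF <- f * P[2] / ZF
  # translational flow at the fixation point (omega must cancel it)
  tu <- (xF * v[3] - f * v[1]) / ZF
  tv <- (yF * v[3] - f * v[2]) / ZF
  # rotational flow coefficients, roll = 0:
  #   u_rot =  wx*xF*yF/f      - wy*(f + xF^2/f)
  #   v_rot =  wx*(f + yF^2/f) - wy*xF*yF/f
  A <- matrix(c(xF * yF / f,      -(f + xF^2 / f),
                f + yF^2 / f,     -xF * yF / f), 2, 2, byrow = TRUE)
  w <- solve(A, -c(tu, tv))
  c(w[1], w[2], 0)
}
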