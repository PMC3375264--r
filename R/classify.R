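#' Classify a component response curve
#'
#' Assigns one of the qualitative response-curve classes to samples
#' `(x, value)` of a flow-derivative component as a function of the
#' declination `x`:
#' * `"0"`  — absent: `max |value| <= ztol * scale`;
#' * `"-"`  — constant nonzero;
#' * `"/"`  — affine in `x` with nonzero slope;
#' * `"∩"` — hyperbolic: a reciprocal-polynomial curve
#'   `a + c1/x + c2/x^2 + c3/x^3` with nonzero reciprocal part (singular in
#'   the tangential limit; the wider family covers the steeper-than-`1/x`
#'   divergence of curved-edge responses).
#'
#' Each parametric model is fitted by least squares; a model is accepted
#' when its residual RMS relative to the sample spread is below `tol`, and
#' nested models are preferred (constant before affine/hyperbolic). When no
#' model reaches `tol` (e.g. curved-edge responses, which diverge like a
#' square-root reciprocal), the best-fitting of affine and hyperbolic wins
#' if its residual beats the runner-up by `margin`; otherwise the result is
#' `"ambiguous"`.
#'
#' @param x sample declinations (>= 4 distinct values, `x > 0`).
#' @param value component samples at `x`.
#' @param scale reference field scale for the zero test (e.g. the largest
#'   component magnitude of the configuration under study).
#' @param tol relative residual below which a model is an exact fit.
#' @param ztol zero threshold relative to `scale`.
#' @param margin residual ratio required to break ties between inexact fits.
#' @param div_ratio growth factor from the large-`x` to the small-`x` end of
#'   the window required as evidence of divergence before `"∩"` is
#'   considered (hyperbolic means singular in the tangential limit, not
#'   merely reciprocal-shaped).
#' @return a single character: `"0"`, `"-"`, `"/"`, `"∩"` or `"ambiguous"`.
#' @export
classify_curve <- function(x, value, scale = 1, tol = 1e-6, ztol = 1e-9,
                           margin = 0.5, div_ratio = 3) {
  stopifnot(length(x) == length(value), length(unique(x)) >= 4, all(x > 0),
            all(is.finite(x)), all(is.finite(value)))
  if (max(abs(value)) <= ztol * scale) return("0")
  o <- order(x)
  xo <- x[o]; vo <- value[o]
  k <- max(1L, length(x) %/% 6)
  end_ratio <- mean(abs(vo[seq_len(k)])) /
    max(mean(abs(vo[seq(length(vo) - k + 1, length(vo))])), 1e-300)
  hyper_ok <- is.finite(end_ratio) && end_ratio >= div_ratio
  amp <- max(abs(value))
  relrms <- function(fit) sqrt(mean((value - fit)^2)) / amp
  r_const <- relrms(mean(value))
  b_aff <- stats::lm.fit(cbind(1, x), value)$coefficients
  r_aff <- relrms(b_aff[1] + b_aff[2] * x)
  Xh <- cbind(1, 1 / x, 1 / x^2, 1 / x^3)
  fit_hyp <- stats::lm.fit(Xh, value)
  r_hyp <- relrms(drop(Xh %*% fit_hyp$coefficients))
  if (r_const <= tol) return("-")
  if (hyper_ok && r_hyp <= tol) return("∩")
  if (r_aff <= tol) return("/")
  # inexact regime: require a clear margin between the two candidates
  if (hyper_ok && r_hyp <= margin * r_aff) return("∩")
  if (r_aff <= margin * r_hyp || !hyper_ok && r_aff <= tol * 50) return("/")
  "ambiguous"
}

# ---- printed signature tables ---------------------------------------------

# sensor-by-scenario response classes (div, curl, shear1, shear2)
.table_sensor <- list(
  pinhole = list(
    tilted_plane   = c("/", "-", "/", "-"),
    parallel_plane = c("∩", "∩", "∩", "∩"),
    parallel_circle = c("∩", "∩", "∩", "∩")
  ),
  monopole_periphery = list(
    tilted_plane   = c("-", "0", "-", "0"),
    parallel_plane = c("∩", "0", "∩", "0"),
    parallel_circle = c("∩", "0", "∩", "0")
  ),
  monopole_fovea = list(
    tilted_plane   = c("/", "/", "-", "-"),
    parallel_plane = c("∩", "∩", "∩", "∩"),
    parallel_circle = c("∩", "∩", "∩", "∩")
  )
)

# strategy-by-motion-axis classes; the strategy table collapses constant
# and linear responses into "/" (finite, non-hyperbolic)
.table_strategy <- list(
  `target-approach` = list(
    nx = list(vx = c("/", "0", "/", "0"),
              vy = c("0", "/", "0", "/"),
              vz = c("/", "/", "/", "/")),
    ny = list(vx = c("0", "/", "0", "/"),
              vy = c("/", "0", "/", "0"),
              vz = c("/", "/", "/", "/"))
  ),
  `obstacle-avoidance` = list(
    tangential = list(vx = c("∩", "0", "∩", "0"),
                      vy = c("0", "∩", "0", "∩"),
                      vz = c("∩", "∩", "∩", "∩")),
    apical = list(vx = c("∩", "0", "∩", "0"),
                  vy = c("0", "∩", "0", "∩"),
                  vz = c("∩", "∩", "∩", "∩"))
  )
)

#' Qualitative response-class tables
#'
#' `response_table()` returns the sensor-by-scenario classification of the
#' four components as a function of declination (rows: tilted plane,
#' gaze-parallel plane, gaze-parallel circle; sensors: pinhole raster,
#' monopole periphery, monopole fovea). `predict_signature()` returns the
#' strategy table row for a gaze strategy, surface case and motion axis; in
#' the strategy table constant and linear responses are both printed `"/"`
#' (finite), opposed to the hyperbolic `"∩"` of tangential/apical fixation.
#'
#' @param sensor `"pinhole"`, `"monopole_periphery"` or `"monopole_fovea"`.
#' @return named list of length-4 character vectors
#'   `(div, curl, shear1, shear2)`.
#' @export
response_table <- function(sensor = c("pinhole", "monopole_periphery",
                                      "monopole_fovea")) {
  .table_sensor[[match.arg(sensor)]]
}

#' @rdname response_table
#' @param strategy `"target-approach"` or `"obstacle-avoidance"`.
#' @param surface for approach: `"nx"` (normal tilted within xz) or `"ny"`
#'   (within yz); for avoidance: `"tangential"` or `"apical"`.
#' @param v_axis `"vx"`, `"vy"` or `"vz"`.
#' @export
predict_signature <- function(strategy = c("target-approach",
                                           "obstacle-avoidance"),
                              surface, v_axis = c("vx", "vy", "vz")) {
  strategy <- match.arg(strategy)
  v_axis <- match.arg(v_axis)
  rows <- .table_strategy[[strategy]]
  if (!surface %in% names(rows))
    stop("surface must be one of: ", paste(names(rows), collapse = ", "))
  rows[[surface]][[v_axis]]
}

#' Coarsen fine response classes to the strategy-table alphabet
#'
#' The strategy table distinguishes only finite (`"/"`), hyperbolic (`"∩"`)
#' and absent (`"0"`) responses; constant curves are finite.
#'
#' @param cls character vector of classes from [classify_curve()].
#' @return character vector over `{"/", "∩", "0"}`.
#' @export
coarse_class <- function(cls) {
  out <- cls
  out[cls == "-"] <- "/"
  out
}
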