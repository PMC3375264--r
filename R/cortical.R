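#' Schwartz-type monopole mapping to cortical coordinates
#'
#' Retino-cortical coordinate transform `w = k log(z + a)`, where `z` is the
#' complex retinal position in angular units (radians of visual angle, small
#' angle: `z = (x + i y) / f`) and `a > 0` regularizes the fovea. The
#' magnification `k / |z + a|` is strictly decreasing in eccentricity, the
#' map is smooth and invertible, and the exact centre is handled through the
#' `a`-shifted logarithm rather than a pole.
#'
#' @param a_deg foveal regularization parameter, degrees of visual angle.
#' @param k magnification scale (cortical units).
#' @return object of class `monopole_map`.
#' @export
monopole_map <- function(a_deg = 0.5, k = 1) {
  stopifnot(a_deg > 0, k > 0)
  structure(list(a = a_deg * pi / 180, k = k, a_deg = a_deg),
            class = "monopole_map")
}

#' @export
print.monopole_map <- function(x, ...) {
  cat(sprintf("<monopole_map> a = %.3g deg, k = %.3g\n", x$a_deg, x$k))
  invisible(x)
}

map_z <- function(cam, x, y) complex(real = x / cam$f, imaginary = y / cam$f)

#' Retina <-> cortex coordinate transform
#'
#' @param map a [monopole_map()].
#' @param cam a [camera_model()] fixing the angular scale.
#' @param x,y retinal image-plane coordinates.
#' @return `to_cortex`: list of cortical coordinates `xc`, `yc`.
#' @export
to_cortex <- function(map, cam, x, y) {
  w <- map$k * log(map_z(cam, x, y) + map$a)
  list(xc = Re(w), yc = Im(w))
}

#' @rdname to_cortex
#' @param xc,yc cortical coordinates.
#' @return `from_cortex`: list of retinal coordinates `x`, `y`.
#' @export
from_cortex <- function(map, cam, xc, yc) {
  z <- exp(complex(real = xc, imaginary = yc) / map$k) - map$a
  list(x = Re(z) * cam$f, y = Im(z) * cam$f)
}

#' Local cortical magnification
#' @param map a [monopole_map()].
#' @param ecc_deg eccentricity in degrees.
#' @return magnification (cortical units per radian of visual angle).
#' @export
cortical_magnification <- function(map, ecc_deg) {
  map$k / (ecc_deg * pi / 180 + map$a)
}

# complex map derivatives at retinal position
map_deriv <- function(map, cam, x, y) {
  z <- map_z(cam, x, y)
  list(F1 = map$k / (z + map$a) / cam$f,        # dw/d(x,y-units)
       F2 = -map$k / (z + map$a)^2 / cam$f^2)
}

#' Cortical flow-derivative components at retinal positions
#'
#' Transforms a retinal flow through the monopole map (cortical velocity
#' `V = w'(z) U`, complex form) and differentiates it, returning the four
#' components of the resulting Jacobian. Two derivative conventions are
#' supported, corresponding to the natural metric of each region of the
#' visual field:
#' * `frame = "cortical"` — derivatives per unit cortical distance
#'   (`dV/dw`); the foveal convention.
#' * `frame = "retinal"` — derivatives of the cortical velocity per unit
#'   retinal distance (equivalently, magnification-normalized cortical
#'   derivatives); the periphery convention, where the map compresses
#'   retinal space without bound.
#'
#' The retinal flow is supplied as a function `flow_fn(x, y)` returning
#' `list(u, v)` (closed-form surface flows; see
#' [components_translation_plane()] and friends for the generating models).
#' Retinal flow partials are taken by central differences with step `h`;
#' the map derivatives are analytic.
#'
#' @param map a [monopole_map()].
#' @param cam a [camera_model()].
#' @param flow_fn function of `(x, y)` returning `list(u, v)`.
#' @param x,y retinal evaluation positions (vectors).
#' @param frame `"cortical"` or `"retinal"` (see Details).
#' @param h finite-difference step (image-plane units); default adaptive.
#' @return list of vectors `div`, `curl`, `shear1`, `shear2`.
#' @export
cortical_components_at <- function(map, cam, flow_fn, x, y,
                                   frame = c("cortical", "retinal"),
                                   h = NULL) {
  frame <- match.arg(frame)
  if (is.null(h)) h <- pmax(1e-7 * cam$f, 1e-5 * abs(x))
  Vc <- function(xx, yy) {
    U <- flow_fn(xx, yy)
    md <- map_deriv(map, cam, xx, yy)
    md$F1 * complex(real = U$u, imaginary = U$v)
  }
  C1 <- (Vc(x + h, y) - Vc(x - h, y)) / (2 * h)   # dV/dx (complex)
  C2 <- (Vc(x, y + h) - Vc(x, y - h)) / (2 * h)   # dV/dy
  if (frame == "cortical") {
    # chain to cortical coordinates: [C1 C2] %*% Jmap^{-1}; for the
    # conformal map, Jmap is the scaled rotation of F1 = dw/dz
    F1 <- map_deriv(map, cam, x, y)$F1
    A <- Re(F1); B <- Im(F1)
    det <- A^2 + B^2
    D1 <- (C1 * A + C2 * B) / det
    D2 <- (C2 * A - C1 * B) / det
    C1 <- D1; C2 <- D2
  }
  list(div = Re(C1) + Im(C2), curl = Im(C1) - Re(C2),
       shear1 = Re(C1) - Im(C2), shear2 = Re(C2) + Im(C1))
}

#' Cortical components of a rendered flow field
#'
#' Grid version of [cortical_components_at()] for a dense [flow_field()]:
#' pixels within the region's eccentricity band are transformed and
#' differentiated (the fovea uses the cortical frame, the periphery the
#' magnification-normalized retinal frame). Pixels outside the band, masked
#' pixels, and band borders are `NA`.
#'
#' @param map a [monopole_map()].
#' @param field a [flow_field()].
#' @param region `"fovea"` or `"periphery"`.
#' @param band eccentricity band in degrees (defaults: fovea `[0, 2 a]`,
#'   periphery `[10, 90]` intersected with the raster).
#' @return a `component_field` (provenance `"analytic"`), masked outside
#'   the band.
#' @export
cortical_components <- function(map, field, region = c("fovea", "periphery"),
                                band = NULL) {
  region <- match.arg(region)
  cam <- field$cam
  if (is.null(band))
    band <- if (region == "fovea") c(0, 2 * map$a_deg) else c(10, 90)
  g <- camera_grid(cam)
  ecc <- atan(sqrt(g$x^2 + g$y^2) / cam$f) * 180 / pi
  insel <- ecc >= band[1] & ecc <= band[2] & field$mask
  if (!any(insel)) stop("empty region: no pixels in the eccentricity band")
  md <- map_deriv(map, cam, g$x, g$y)
  nr <- cam$height; nc <- cam$width
  V <- matrix(md$F1 * complex(real = field$u, imaginary = field$v), nr, nc)
  V[!field$mask] <- NA_complex_
  hx <- 1 / cam$px_per_unit; hy <- 1 / cam$px_per_unit_y
  C1 <- C2 <- matrix(NA_complex_, nr, nc)
  C1[, 2:(nc - 1)] <- (V[, 3:nc] - V[, 1:(nc - 2)]) / (2 * hx)
  C2[2:(nr - 1), ] <- (V[1:(nr - 2), ] - V[3:nr, ]) / (2 * hy)  # y up
  if (region == "fovea") {
    A <- Re(md$F1); B <- Im(md$F1); det <- A^2 + B^2
    D1 <- (C1 * A + C2 * B) / det
    D2 <- (C2 * A - C1 * B) / det
    C1 <- D1; C2 <- D2
  }
  mask <- insel & is.finite(Re(C1)) & is.finite(Re(C2))
  out <- list(div = Re(C1) + Im(C2), curl = Im(C1) - Re(C2),
              shear1 = Re(C1) - Im(C2), shear2 = Re(C2) + Im(C1))
  for (nm in names(out)) out[[nm]][!mask] <- NA_real_
  structure(c(out, list(provenance = "analytic", mask = mask, cam = cam)),
            class = "component_field")
}

# ---- sensor-row classification --------------------------------------------

# retinal closed-form translational flow functions for the three scenarios
flow_fn_tilted <- function(alpha, d, v, cam) {
  n <- c(sin(alpha), 0, cos(alpha)); f <- cam$f
  function(x, y) {
    Z <- d * f / (n[1] * x + n[3] * f)
    list(u = (x * v[3] - f * v[1]) / Z, v = (y * v[3] - f * v[2]) / Z)
  }
}
flow_fn_parallel <- function(x_off, v, cam) {
  f <- cam$f
  function(x, y) {
    Z <- x_off * f / x
    list(u = (x * v[3] - f * v[1]) / Z, v = (y * v[3] - f * v[2]) / Z)
  }
}
# local silhouette of a cylinder of radius Rc whose tangent point sits at
# retinal coordinate x_s: depth rises from the surface as delta = x - x_s
flow_fn_circle <- function(x_s, Rc, d, v, cam) {
  f <- cam$f
  function(x, y) {
    dl <- x - x_s
    Z <- d - sqrt(pmax(dl * (2 * Rc - dl), 1e-300))
    list(u = (x * v[3] - f * v[1]) / Z, v = (y * v[3] - f * v[2]) / Z)
  }
}

# trend of an amplitude sequence across doubled eccentricities
limit_trend <- function(amp, decay = 0.6, grow = 1.7) {
  r <- abs(amp)
  if (max(r) == 0) return("0")
  rat <- r[-1] / pmax(r[-length(r)], 1e-300)
  tail_rat <- rat[length(rat)]
  if (tail_rat < decay) "0" else if (tail_rat > grow) "/" else "-"
}

#' Qualitative response classes measured for a sensor/scenario pair
#'
#' Recomputes, from the model, the response-curve class of each flow
#' component for one row of the sensor classification table: the pinhole
#' rows from the closed-form component expressions, and the monopole rows
#' from the numerically transformed cortical flow, using the limit
#' conventions of [cortical_components_at()] (fovea: cortical frame at
#' eccentricities around `fovea_deg`; periphery: retinal frame, classified
#' by the trend across doubled eccentricities starting at `periph_deg`).
#' For the tangential scenarios (parallel plane/circle) the declination is
#' the tangential offset and a component is `"0"` when its amplitude decays
#' with eccentricity doubling, `"∩"` otherwise.
#'
#' @param sensor `"pinhole"`, `"monopole_fovea"` or `"monopole_periphery"`.
#' @param scenario `"tilted_plane"`, `"parallel_plane"` or
#'   `"parallel_circle"`.
#' @param v translational velocity (default generic, all axes nonzero).
#' @param cam a [camera_model()].
#' @param map a [monopole_map()].
#' @param alpha,d tilted-plane parameters.
#' @param fovea_deg,periph_deg probe eccentricities (degrees).
#' @return length-4 character vector of classes (div, curl, shear I, II).
#' @export
sensor_row_classes <- function(sensor, scenario, v = c(0.3, 0.2, 1),
                               cam = camera_model(), map = monopole_map(),
                               alpha = 0.3, d = 2,
                               fovea_deg = 0.1, periph_deg = 20) {
  sensor <- match.arg(sensor, c("pinhole", "monopole_fovea",
                                "monopole_periphery"))
  scenario <- match.arg(scenario, c("tilted_plane", "parallel_plane",
                                    "parallel_circle"))
  f <- cam$f
  nm <- c("div", "curl", "shear1", "shear2")
  if (sensor == "pinhole") {
    if (scenario == "tilted_plane") {
      xs <- seq(0.05, 0.5, length.out = 12) * f
      cc <- components_translation_plane(alpha, d, v, xs, y = 0, cam)
    } else if (scenario == "parallel_plane") {
      xs <- seq(0.05, 0.5, length.out = 12) * f
      cc <- components_parallel_plane(xs, v, cam)
    } else {
      R <- 0.05 * f
      xs <- seq(0.05, 0.5, length.out = 12) * R
      cc <- components_cylinder(R, v, xs, cam = cam)
    }
    sc <- max(vapply(cc[nm], function(z) max(abs(z)), 0))
    return(vapply(nm, function(n)
      classify_curve(xs, cc[[n]], scale = sc, tol = 1e-6), ""))
  }
  region <- if (sensor == "monopole_fovea") "fovea" else "periphery"
  frame <- if (region == "fovea") "cortical" else "retinal"
  e0 <- (if (region == "fovea") fovea_deg else periph_deg) * pi / 180
  eccs <- e0 * c(1, 2, 4, 8)   # doubling probes for the limit trend
  if (scenario == "tilted_plane") {
    # declination is eccentricity itself: classify the curve over the
    # region window; periphery additionally uses the doubling trend
    if (region == "fovea") {
      xs <- seq(0.5, 1.5, length.out = 12) * e0 * f
      cc <- cortical_components_at(map, cam, flow_fn_tilted(alpha, d, v, cam),
                                   xs, 0 * xs, frame = frame)
      sc <- max(vapply(cc[nm], function(z) max(abs(z)), 0))
      return(vapply(nm, function(n) {
        z <- cc[[n]]
        if (max(abs(z)) <= 1e-9 * sc) return("0")
        if (diff(range(z)) < 0.02 * max(abs(z))) return("-")
        classify_curve(xs, z, scale = sc, tol = 0.02, margin = 0.6)
      }, ""))
    }
    cc <- cortical_components_at(map, cam, flow_fn_tilted(alpha, d, v, cam),
                                 eccs * f, 0 * eccs, frame = frame)
    return(vapply(nm, function(n) limit_trend(cc[[n]]), ""))
  }
  # tangential scenarios: hyperbolic in the tangential offset unless the
  # amplitude dies away with eccentricity (periphery limit)
  amp_at <- function(e) {
    x0 <- e * f; y0 <- 0.05 * x0
    if (scenario == "parallel_plane") {
      offs <- c(0.05, 0.1) * f
      A <- vapply(offs, function(xo)
        unlist(cortical_components_at(map, cam, flow_fn_parallel(xo, v, cam),
                                      x0, y0, frame = frame)[nm]),
        numeric(4))
      rowMeans(abs(A))
    } else {
      Rc <- 2 * e * f; dls <- c(0.02, 0.05) * Rc
      A <- vapply(dls, function(dl)
        unlist(cortical_components_at(
          map, cam, flow_fn_circle(x0 - 0.01 * Rc, Rc, d, v, cam),
          x0 - 0.01 * Rc + dl, y0, frame = frame,
          h = 1e-4 * dl)[nm]),
        numeric(4))
      rowMeans(abs(A))
    }
  }
  if (region == "fovea") {
    amps <- amp_at(e0)
    sc <- max(amps)
    return(vapply(seq_along(nm), function(i)
      if (amps[i] <= 1e-9 * sc) "0" else "∩", ""))
  }
  A <- vapply(eccs, amp_at, numeric(4))
  vapply(seq_len(4), function(i) {
    tr <- limit_trend(A[i, ])
    if (tr == "0") "0" else "∩"
  }, "")
}
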