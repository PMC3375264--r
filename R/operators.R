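#' Antagonistic center-surround derivative operator bank
#'
#' Builds the biologically inspired derivative operators: each partial
#' derivative is estimated as the difference between correlations with two
#' juxtaposed elliptical Gaussian subfields. For the x-derivative pair the
#' positive (center) subfield has standard deviation 1 px along x and 2 px
#' along y on a 9 x 5 px support (rows x cols), the negative (surround)
#' subfield 3 px along x and 2 px along y on 9 x 13 px; the center
#' correlation is shifted one pixel left and the surround correlation two
#' pixels right, putting the positive lobe left of the negative lobe. The
#' y-derivative pair is the same circuit rotated 90 degrees. Each subfield
#' is normalized to unit sum before subtraction, so the response to a
#' constant field is exactly zero and the response to a unit ramp is a
#' single measurable gain (3, the distance between the effective lobe
#' centres), reported in the bank.
#'
#' @param center_size,surround_size supports as `c(rows, cols)`.
#' @param center_sigma,surround_sigma standard deviations as `c(sd_x, sd_y)`
#'   in pixels.
#' @param center_shift,surround_shift sampling offsets (pixels along the
#'   derivative axis; positive samples further along the axis).
#' @return object of class `operator_bank` with the kernels, shifts and the
#'   measured ramp `gain`.
#' @export
build_bank <- function(center_size = c(9, 5), surround_size = c(9, 13),
                       center_sigma = c(1, 2), surround_sigma = c(3, 2),
                       center_shift = 1L, surround_shift = -2L) {
  if (any(c(center_size, surround_size) < 3))
    stop("kernel support below 3 px")
  gk <- function(size, sigma) {
    r <- outer(seq_len(size[1]) - (size[1] + 1) / 2,
               rep(1, size[2]))
    c_ <- outer(rep(1, size[1]),
                seq_len(size[2]) - (size[2] + 1) / 2)
    k <- exp(-0.5 * ((c_ / sigma[1])^2 + (r / sigma[2])^2))
    k / sum(k)
  }
  bank <- structure(list(
    center = gk(center_size, center_sigma),
    surround = gk(surround_size, surround_sigma),
    center_shift = as.integer(center_shift),
    surround_shift = as.integer(surround_shift),
    gain = NA_real_), class = "operator_bank")
  # measure the gain on an exact ramp
  ramp <- matrix(rep(seq_len(41), each = 41), 41, 41)
  resp <- operator_response(bank, ramp, axis = "col")
  bank$gain <- resp[21, 21]
  bank
}

#' @export
print.operator_bank <- function(x, ...) {
  cat(sprintf("<operator_bank> center %dx%d, surround %dx%d, gain %.4g\n",
              nrow(x$center), ncol(x$center), nrow(x$surround),
              ncol(x$surround), x$gain))
  invisible(x)
}

# correlation of a matrix with a kernel sampled at an extra offset along
# the derivative axis; outside-reach pixels are NA
corr2_shift <- function(m, kernel, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(kernel); kc <- ncol(kernel)
  cr <- (kr + 1) / 2; cc <- (kc + 1) / 2
  out <- matrix(0, nr, nc)
  na <- matrix(FALSE, nr, nc)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    w <- kernel[i, j]
    if (w == 0) next
    oi <- i - cr + dr; oj <- j - cc + dc
    rs <- seq_len(nr) + oi; cs <- seq_len(nc) + oj
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] + w * m[rs[ok_r], cs[ok_c]]
    na[!ok_r, ] <- TRUE; na[, !ok_c] <- TRUE
  }
  out[na] <- NA_real_
  out
}

#' Raw operator response along one raster axis
#'
#' Correlates a matrix with the bank's center and surround subfields
#' (shifted as configured) and returns their difference: an estimate of
#' `gain` times the derivative along the chosen raster axis. Pixels within
#' kernel reach of the border are `NA` (no padding).
#'
#' @param bank an [build_bank()] operator bank.
#' @param m numeric matrix.
#' @param axis `"col"` (x pair) or `"row"` (the 90-degree rotated pair).
#' @return matrix of responses.
#' @export
operator_response <- function(bank, m, axis = c("col", "row")) {
  axis <- match.arg(axis)
  if (axis == "col") {
    corr2_shift(m, bank$center, 0L, bank$center_shift) -
      corr2_shift(m, bank$surround, 0L, bank$surround_shift)
  } else {
    corr2_shift(m, t(bank$center), bank$center_shift, 0L) -
      corr2_shift(m, t(bank$surround), bank$surround_shift, 0L)
  }
}

#' Apply the operator bank to a flow field
#'
#' Estimates the four flow partials by correlating the pixel-raster view of
#' the flow with the operator bank, divides by the bank gain, converts back
#' to the analytic (y-up) convention, and wires the partials into
#' divergence, curl and shear maps. Pixels within kernel reach of the
#' border or of masked entries are undefined (masked), not padded.
#'
#' @param bank an [build_bank()] operator bank.
#' @param field a [flow_field()] larger than the kernel support.
#' @return list with `jacobian` (a [jacobian_field()] tagged
#'   `"operator-bank"`), `components` (a `component_field`) and `gain`.
#' @export
apply_bank <- function(bank, field) {
  px <- flow_pixels(field)
  if (nrow(px$u) < nrow(bank$surround) + 4 ||
      ncol(px$u) < ncol(bank$surround) + 4)
    stop("field smaller than operator support")
  u <- px$u; v <- px$v
  u[!field$mask] <- NA_real_; v[!field$mask] <- NA_real_
  g <- bank$gain
  dudx <- operator_response(bank, u, "col") / g
  dudy_px <- operator_response(bank, u, "row") / g
  dvdx_px <- operator_response(bank, v, "col") / g
  dvdy_px <- operator_response(bank, v, "row") / g
  # raster view is (px/s, y down): v and the row axis both flip sign
  J <- jacobian_field(dudx = dudx, dudy = -dudy_px,
                      dvdx = -dvdx_px, dvdy = dvdy_px,
                      provenance = "operator-bank", cam = field$cam)
  list(jacobian = J, components = decompose(J), gain = g)
}
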