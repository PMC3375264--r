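#' Circular histogram of flow directions
#'
#' Histograms the per-pixel flow direction `atan2(v, u)` over a circular
#' foveal region (or its left/right half), in equal angular bins. Directions
#' use the analytic convention (y up, angles counterclockwise from the
#' +x axis, degrees in [0, 360)). Pixels with undefined or (numerically)
#' zero flow are excluded.
#'
#' @param field a [flow_field()].
#' @param region `"full"`, `"left-half"` or `"right-half"` of the circular
#'   fovea centred on the image centre.
#' @param bins number of angular bins (default 36, i.e. 10 degree bins).
#' @param radius_px fovea radius in pixels (default: half the smaller image
#'   dimension).
#' @param min_speed speed threshold (image-plane units/s) below which a
#'   pixel is treated as stationary.
#' @return object of class `direction_histogram`: list with bin `centers`
#'   (deg), normalized `density` (sums to 1), raw `counts` and `n`.
#' @export
direction_histograms <- function(field, region = c("full", "left-half",
                                                   "right-half"),
                                 bins = 36L, radius_px = NULL,
                                 min_speed = 1e-12) {
  region <- match.arg(region)
  cam <- field$cam
  if (is.null(radius_px)) radius_px <- min(cam$width, cam$height) / 2
  col <- matrix(seq_len(cam$width), cam$height, cam$width, byrow = TRUE)
  row <- matrix(seq_len(cam$height), cam$height, cam$width)
  cc <- (cam$width + 1) / 2; rc <- (cam$height + 1) / 2
  sel <- (col - cc)^2 + (row - rc)^2 <= radius_px^2
  if (region == "left-half") sel <- sel & col < cc
  if (region == "right-half") sel <- sel & col > cc
  sel <- sel & field$mask & sqrt(field$u^2 + field$v^2) > min_speed
  if (!any(sel)) stop("empty region: no defined, moving pixels")
  ang <- (atan2(field$v[sel], field$u[sel]) * 180 / pi) %% 360
  width <- 360 / bins
  idx <- floor(ang / width) %% bins
  counts <- tabulate(idx + 1L, nbins = bins)
  structure(list(centers = (seq_len(bins) - 0.5) * width,
                 density = counts / sum(counts), counts = counts,
                 n = sum(counts), region = region, bin_width = width),
            class = "direction_histogram")
}

#' @export
print.direction_histogram <- function(x, ...) {
  cat(sprintf("<direction_histogram> %s, %d px, %d bins, mode at %.0f deg\n",
              x$region, x$n, length(x$counts),
              x$centers[which.max(x$counts)]))
  invisible(x)
}

#' Dominant modes of a circular direction histogram
#'
#' Extracts the two dominant modes: the global peak bin, and the strongest
#' bin at least `min_sep` degrees (circular) away from it. Each mode is
#' refined below the bin width by the circular mean of the peak bin and its
#' immediate neighbours, weighted by their counts. Returns the modes and
#' their circular separation.
#'
#' @param hist a [direction_histograms()] result.
#' @param min_sep minimal circular separation (deg) between the two modes.
#' @param refine logical; refine modes below the bin width.
#' @return list with `modes` (deg), `separation` (deg, in [0, 180]) and the
#'   modes' `density` values.
#' @export
histogram_modes <- function(hist, min_sep = 60, refine = TRUE) {
  ctr <- hist$centers
  nb <- length(ctr)
  i1 <- which.max(hist$counts)
  dsep <- circular_distance(ctr, ctr[i1])
  cand <- which(dsep >= min_sep)
  if (!length(cand)) stop("no second mode at the requested separation")
  i2 <- cand[which.max(hist$counts[cand])]
  locate <- function(i) {
    if (!refine) return(ctr[i])
    nbh <- ((i + c(-2, -1, 0, 1, 2) - 1) %% nb) + 1
    w <- hist$counts[nbh]
    th <- ctr[nbh] * pi / 180
    (atan2(sum(w * sin(th)), sum(w * cos(th))) * 180 / pi) %% 360
  }
  m1 <- locate(i1); m2 <- locate(i2)
  list(modes = c(m1, m2),
       separation = circular_distance(m1, m2),
       density = hist$density[c(i1, i2)])
}

#' Circular distance between angles
#' @param a,b angles in degrees.
#' @return elementwise circular distance in [0, 180] degrees.
#' @export
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Angular support of a direction histogram
#'
#' The total angular extent (deg) of bins whose density exceeds `thresh`
#' times the maximum bin density; used to characterise broad (about 180
#' degree) versus narrow unimodal distributions.
#'
#' @param hist a [direction_histograms()] result.
#' @param thresh relative density threshold.
#' @return support in degrees.
#' @export
histogram_support <- function(hist, thresh = 0.05) {
  sum(hist$density > thresh * max(hist$density)) * hist$bin_width
}
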