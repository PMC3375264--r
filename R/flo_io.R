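#' Middlebury .flo input/output
#'
#' Reads and writes dense flow fields in the Middlebury `.flo` format:
#' little-endian, a float32 magic (the bytes "PIEH"), int32 width and
#' height, then row-major interleaved float32 (u, v) pairs in the pixel
#' raster convention (y down). [write_flo()] stores the pixel-raster view
#' of a [flow_field()]; [read_flo()] wraps the file in a [flow_field()]
#' with a nominal pixel-unit camera (focal length `f_px`, one image-plane
#' unit per pixel), converting back to the analytic y-up convention.
#' Non-finite entries mark missing flow and become masked pixels.
#'
#' @param field a [flow_field()].
#' @param path file path.
#' @return `read_flo`: a [flow_field()].
#' @export
write_flo <- function(field, path) {
  px <- flow_pixels(field)
  u <- px$u; v <- px$v
  u[!field$mask] <- NA_real_; v[!field$mask] <- NA_real_
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(202021.25, con, size = 4, endian = "little")
  writeBin(c(ncol(u), nrow(u)), con, size = 4, endian = "little")
  inter <- rbind(as.vector(t(u)), as.vector(t(v)))  # u,v interleaved, row-major
  writeBin(as.vector(inter), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_flo
#' @param f_px nominal focal length (pixels) attached to the camera of the
#'   returned field.
#' @export
read_flo <- function(path, f_px = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", 1, size = 4, endian = "little")
  if (!isTRUE(abs(magic - 202021.25) < 1e-3))
    stop("not a .flo file (bad magic)")
  wh <- readBin(con, "integer", 2, size = 4, endian = "little")
  if (any(wh <= 0) || any(wh > 1e5)) stop("implausible .flo dimensions")
  n <- 2 * wh[1] * wh[2]
  dat <- readBin(con, "numeric", n, size = 4, endian = "little")
  if (length(dat) != n) stop("truncated .flo file")
  u_px <- matrix(dat[seq(1, n, 2)], wh[2], wh[1], byrow = TRUE)
  v_px <- matrix(dat[seq(2, n, 2)], wh[2], wh[1], byrow = TRUE)
  if (is.null(f_px)) f_px <- max(wh)
  cam <- camera_model(f_px = f_px, width = wh[1], height = wh[2],
                      sensor_w = wh[1])  # 1 image-plane unit = 1 pixel
  flow_field(u_px, -v_px, cam)
}

#' Load an externally computed flow field
#'
#' Ingests precomputed dense optical flow (e.g. estimated from a passive
#' video sequence by a variational method) for derivative analysis and
#' segmentation; this package never estimates flow from images.
#'
#' @param path path to a Middlebury `.flo` file.
#' @param f_px nominal focal length in pixels (optional).
#' @return a [flow_field()] in pixel units.
#' @export
load_external_flow <- function(path, f_px = NULL) read_flo(path, f_px = f_px)
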