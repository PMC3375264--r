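#' Pinhole camera model
#'
#' Defines the imaging geometry used throughout the package: a pinhole camera
#' with the principal point at the exact image centre, focal length `f`
#' expressed in image-plane (sensor) units, and a pixel raster of
#' `width` x `height` pixels covering a sensor of `sensor_w` x `sensor_h`
#' image-plane units. Analytic image coordinates (x, y) have the origin at
#' the principal point and y pointing up; pixel rasters have y pointing down.
#' Pixel centres sit at half-integer offsets, so the conversion
#' pixel <-> image-plane coordinates is exact and invertible.
#'
#' The default parameters reproduce the foveal sensor used in the behavioural
#' scenarios: a 1 cm x 1 cm sensor, 240 x 240 pixels, and a focal length of
#' 2748.45 pixels, which subtends a 5 degree by 5 degree field of view.
#'
#' @param f_px focal length in pixels (> 0).
#' @param width,height raster size in pixels.
#' @param sensor_w,sensor_h sensor size in image-plane units (metres of
#'   sensor; the default 0.01 corresponds to the 1 cm display).
#' @return an object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' cam$fov_deg  # ~5 degrees
#' @export
camera_model <- function(f_px = 2748.45, width = 240L, height = width,
                         sensor_w = 0.01, sensor_h = sensor_w * height / width) {
  stopifnot(f_px > 0, width >= 1, height >= 1, sensor_w > 0, sensor_h > 0)
  px_per_unit <- width / sensor_w   # pixels per image-plane unit (x)
  px_per_unit_y <- height / sensor_h
  f <- f_px / px_per_unit           # focal length in image-plane units
  structure(list(
    f = f, f_px = f_px,
    width = as.integer(width), height = as.integer(height),
    sensor_w = sensor_w, sensor_h = sensor_h,
    px_per_unit = px_per_unit, px_per_unit_y = px_per_unit_y,
    fov_deg = 2 * atan(sensor_w / 2 / f) * 180 / pi
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %dx%d px, f = %.2f px (%.4g units), fov %.2f deg\n",
              x$width, x$height, x$f_px, x$f, x$fov_deg))
  invisible(x)
}

#' Pixel <-> image-plane coordinate conversion
#'
#' Pixel indices are 1-based with (row 1, col 1) the top-left pixel; pixel
#' centres are at half-integer offsets from the raster corner. Image-plane
#' coordinates are metric, centred on the principal point, y up.
#'
#' @param cam a [camera_model()].
#' @param col,row pixel column/row indices (may be fractional).
#' @return `pixel_to_plane`: list with vectors `x`, `y` (image-plane units).
#' @export
pixel_to_plane <- function(cam, col, row) {
  list(x = (col - 0.5 - cam$width / 2) / cam$px_per_unit,
       y = -(row - 0.5 - cam$height / 2) / cam$px_per_unit_y)
}

#' @rdname pixel_to_plane
#' @param x,y image-plane coordinates.
#' @return `plane_to_pixel`: list with vectors `col`, `row`.
#' @export
plane_to_pixel <- function(cam, x, y) {
  list(col = x * cam$px_per_unit + cam$width / 2 + 0.5,
       row = -y * cam$px_per_unit_y + cam$height / 2 + 0.5)
}

#' Image-plane coordinate grids for a camera raster
#'
#' @param cam a [camera_model()].
#' @return list of matrices `x`, `y` (height x width, row 1 = top) giving the
#'   analytic image-plane coordinates of every pixel centre.
#' @export
camera_grid <- function(cam) {
  cr <- pixel_to_plane(cam, col = seq_len(cam$width), row = seq_len(cam$height))
  list(x = matrix(cr$x, cam$height, cam$width, byrow = TRUE),
       y = matrix(cr$y, cam$height, cam$width, byrow = FALSE))
}
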