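#' Calibrated grayscale micrograph
#'
#' A micrograph is the unit of all measurement in the package: a 2-D
#' grayscale intensity matrix together with a physical calibration in
#' nanometres per pixel. Intensities are stored exactly as read (integer
#' grey levels for 8/16-bit data); no rescaling is applied.
#'
#' The coordinate convention used throughout the package is 0-based
#' `(x, y)` with `x` indexing columns and `y` indexing rows, and half-open
#' windows (see [window()]). Matrix element `image[r, c]` is the pixel at
#' `x = c - 1`, `y = r - 1`.
#'
#' @param image numeric matrix of intensities (rows = y, columns = x).
#' @param nm_per_pixel positive scalar calibration in nm per pixel.
#' @param id identifier string carried into measurement tables.
#' @return An object of class `micrograph`.
#' @examples
#' mg <- micrograph(matrix(128, 64, 64), nm_per_pixel = 0.5)
#' dim(mg$image)
#' @export
micrograph <- function(image, nm_per_pixel, id = "micrograph") {
  abort_if(!is.matrix(image) || !is.numeric(image),
           "`image` must be a numeric matrix")
  abort_if(nrow(image) < 2 || ncol(image) < 2,
           "`image` must have at least 2 rows and 2 columns")
  abort_if(!is.numeric(nm_per_pixel) || length(nm_per_pixel) != 1 ||
             !is.finite(nm_per_pixel) || nm_per_pixel <= 0,
           "`nm_per_pixel` must be a positive finite scalar")
  structure(
    list(image = image, nm_per_pixel = as.numeric(nm_per_pixel),
         id = as.character(id)),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph '%s': %d x %d px, %.4g nm/px, grey range [%s, %s]>\n",
              x$id, nrow(x$image), ncol(x$image), x$nm_per_pixel,
              format(min(x$image)), format(max(x$image))))
  invisible(x)
}

#' Read a micrograph from a TIFF or PNG file
#'
#' Intensities are preserved without rescaling: 8-bit files yield integer
#' grey levels 0-255, 16-bit files 0-65535. RGB or multi-channel images are
#' rejected; measurements are only defined on single-channel data.
#'
#' @param path file path; format is chosen by extension (`.tif`, `.tiff`,
#'   `.png`).
#' @param nm_per_pixel calibration in nm per pixel. The calibration is not
#'   read from image metadata; magnification bookkeeping is the caller's
#'   responsibility.
#' @param id identifier; defaults to the file name.
#' @return A [micrograph()].
#' @seealso [write_micrograph()]
#' @export
read_micrograph <- function(path, nm_per_pixel, id = basename(path)) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = ,
    "tiff" = tiff::readTIFF(path, as.is = TRUE),
    "png" = {
      x <- png::readPNG(path)
      abort_if(length(dim(x)) != 2,
               "image is not 2-D single-channel grayscale")
      # readPNG always rescales to [0, 1]; undo assuming 8-bit unless the
      # quantisation clearly requires 16.
      v <- round(x * 255)
      if (max(abs(v - x * 255)) > 1e-6) v <- round(x * 65535)
      matrix(as.integer(v), nrow(v), ncol(v))
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  abort_if(length(dim(img)) != 2,
           "image is not 2-D single-channel grayscale")
  micrograph(img, nm_per_pixel, id = id)
}

#' Write a micrograph to a TIFF or PNG file
#'
#' Grey levels are written losslessly at the stated bit depth, so
#' `read_micrograph(write_micrograph(x))` reproduces the intensity grid
#' exactly for integer-valued images.
#'
#' @param mg a [micrograph()].
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @param bits bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(mg, path, bits = 8L) {
  stopifnot(inherits(mg, "micrograph"))
  abort_if(!bits %in% c(8L, 16L), "`bits` must be 8 or 16")
  maxval <- 2^bits - 1
  img <- mg$image
  abort_if(min(img) < 0 || max(img) > maxval,
           sprintf("intensities outside [0, %d]; rescale before writing", maxval))
  scaled <- img / maxval
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "tif" = ,
    "tiff" = tiff::writeTIFF(scaled, path, bits.per.sample = bits),
    "png" = png::writePNG(scaled, path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Rectangular evaluation window
#'
#' Windows are half-open pixel-coordinate rectangles
#' `[x0, x1) x [y0, y1)` in the package's 0-based convention: the pixel
#' column `x1` lies outside the window, so the window covers exactly
#' `(x1 - x0) * (y1 - y0)` pixels.
#'
#' @param x0,y0,x1,y1 integer pixel coordinates, `x1 > x0`, `y1 > y0`.
#' @return An object of class `window`.
#' @export
window <- function(x0, y0, x1, y1) {
  abort_if(x1 <= x0 || y1 <= y0, "window must satisfy x1 > x0 and y1 > y0")
  abort_if(x0 < 0 || y0 < 0, "window coordinates must be non-negative")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "window")
}

#' @export
print.window <- function(x, ...) {
  cat(sprintf("<window [%d,%d) x [%d,%d), %d px>\n",
              x$x0, x$x1, x$y0, x$y1,
              (x$x1 - x$x0) * (x$y1 - x$y0)))
  invisible(x)
}

window_area_px <- function(w) (w$x1 - w$x0) * (w$y1 - w$y0)

#' Central square evaluation window of a micrograph
#'
#' Returns the centred `side_px` x `side_px` window used to restrict
#' annotation and evaluation away from image borders (by default the
#' central 820 x 820 pixel window). When the remainder is odd the window
#' is shifted toward the origin (floor division).
#'
#' @param mg a [micrograph()] (or an integer vector `c(nrow, ncol)`).
#' @param side_px window side length in pixels; must not exceed either
#'   image dimension.
#' @return A [window()].
#' @examples
#' central_window(c(1024L, 1024L), 820)   # [102, 922) on both axes
#' @export
central_window <- function(mg, side_px = 820L) {
  dims <- if (inherits(mg, "micrograph")) dim(mg$image) else as.integer(mg)
  abort_if(length(dims) != 2, "need image dimensions c(nrow, ncol)")
  side_px <- as.integer(side_px)
  abort_if(side_px <= 0, "`side_px` must be positive")
  abort_if(side_px > min(dims), "`side_px` exceeds the image dimensions")
  oy <- (dims[1] - side_px) %/% 2L
  ox <- (dims[2] - side_px) %/% 2L
  window(ox, oy, ox + side_px, oy + side_px)
}
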