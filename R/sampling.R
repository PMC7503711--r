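#' Scanning band with forbidden and acceptance lines
#'
#' A pair of horizontal lines used as an unbiased counting rule during
#' scanning: events touching the forbidden line are excluded, events
#' touching the acceptance line (or lying entirely between the lines)
#' are counted. Rows are 0-based pixel coordinates.
#'
#' @param acceptance_y,forbidden_y distinct row coordinates.
#' @return An object of class `band`.
#' @export
band <- function(acceptance_y, forbidden_y) {
  abort_if(acceptance_y == forbidden_y,
           "acceptance and forbidden lines must differ")
  structure(list(acceptance_y = as.integer(acceptance_y),
                 forbidden_y = as.integer(forbidden_y),
                 orientation = "horizontal"),
            class = "band")
}

#' Filter instances by area inside an evaluation window
#'
#' Keeps instances that have at least `min_area_frac` of their pixel area
#' inside the window (>= comparison, so a mask exactly half inside is
#' kept). With `min_area_frac = 0` everything passes; with `1` only
#' fully contained instances pass. Predictions and ground truth should be
#' filtered by the same rule before evaluation.
#'
#' @param instances an [instance_set()].
#' @param window a [window()] (half-open, 0-based).
#' @param min_area_frac minimum contained-area fraction (default 0.5).
#' @return A filtered [instance_set()] (scores subset accordingly).
#' @export
window_filter <- function(instances, window, min_area_frac = 0.5) {
  stopifnot(inherits(instances, "instance_set"), inherits(window, "window"))
  nr <- instances$dim[1]
  keep <- vapply(instances$masks, function(idx) {
    x <- idx_cols(idx, nr) - 1L
    y <- idx_rows(idx, nr) - 1L
    inside <- x >= window$x0 & x < window$x1 & y >= window$y0 & y < window$y1
    mean(inside) >= min_area_frac
  }, TRUE)
  instance_subset(instances, keep)
}

#' Unbiased selection of instances with a scanning band
#'
#' Implements the forbidden/acceptance-line counting rule: an instance is
#' kept when it lies entirely strictly between the two lines or touches
#' the acceptance line; any instance touching the forbidden line is
#' dropped, even if it also touches the acceptance line (forbidden beats
#' acceptance, the standard unbiased counting-frame convention).
#' "Touching" a line means the mask intersects that 1-px-thick row.
#'
#' @param instances an [instance_set()].
#' @param band a [band()].
#' @return A filtered [instance_set()].
#' @export
band_select <- function(instances, band) {
  stopifnot(inherits(instances, "instance_set"), inherits(band, "band"))
  nr <- instances$dim[1]
  lo <- min(band$acceptance_y, band$forbidden_y)
  hi <- max(band$acceptance_y, band$forbidden_y)
  keep <- vapply(instances$masks, function(idx) {
    y <- idx_rows(idx, nr) - 1L
    if (any(y == band$forbidden_y)) return(FALSE)
    if (any(y == band$acceptance_y)) return(TRUE)
    all(y > lo & y < hi)
  }, TRUE)
  instance_subset(instances, keep)
}

#' Systematic uniform random sampling of fields
#'
#' Lays a non-overlapping grid of `field_shape` fields over the image
#' with a single uniformly random phase offset, then selects every
#' `round(1/fraction)`-th field in raster order starting from a uniformly
#' random start — the classical systematic uniform random (SUR) sampling
#' design, which gives every field the same inclusion probability.
#' Deterministic for a given `seed`.
#'
#' @param image_shape image dimensions `c(nrow, ncol)`.
#' @param field_shape field dimensions `c(nrow, ncol)`; must fit in the
#'   image.
#' @param fraction target sampled fraction of fields in (0, 1].
#' @param seed integer seed.
#' @return list of [window()] objects for the selected fields.
#' @export
sur_sample_positions <- function(image_shape, field_shape, fraction = 1,
                                 seed = 1L) {
  image_shape <- as.integer(image_shape); field_shape <- as.integer(field_shape)
  abort_if(any(field_shape > image_shape), "field larger than image")
  abort_if(fraction <= 0 || fraction > 1, "`fraction` must be in (0, 1]")
  with_seed(seed, {
    oy <- sample.int(field_shape[1], 1L) - 1L
    ox <- sample.int(field_shape[2], 1L) - 1L
    ys <- seq.int(oy, image_shape[1] - field_shape[1], by = field_shape[1])
    xs <- seq.int(ox, image_shape[2] - field_shape[2], by = field_shape[2])
    grid <- expand.grid(y = ys, x = xs)   # raster order: down columns
    n <- nrow(grid)
    period <- max(1L, as.integer(round(1 / fraction)))
    start <- sample.int(period, 1L)
    sel <- seq.int(start, n, by = period)
    purrr::map(sel, function(k) {
      window(grid$x[k], grid$y[k],
             grid$x[k] + field_shape[2], grid$y[k] + field_shape[1])
    })
  })
}
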