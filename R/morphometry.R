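#' Oblate-spheroid shape prior for orientation correction
#'
#' Low-density lipoprotein particles are flattened (oblate) spheroids; in
#' thin embedding films they adsorb en face, so a projected image reports
#' the particle's major-axis diameter rather than an orientation-averaged
#' one. The reference shape used for correction is the literature LDL
#' discoid: major axis 21.4 nm, minor axis 12.1 nm, giving an aspect ratio
#' `r = ref_minor / ref_major` of about 0.565 (axis ratio 1.77).
#'
#' @param ref_major,ref_minor reference axes in nm.
#' @return An object of class `spheroid_model` with fields `ref_major`,
#'   `ref_minor` and `aspect`.
#' @export
spheroid_model <- function(ref_major = 21.4, ref_minor = 12.1) {
  abort_if(ref_major <= 0 || ref_minor <= 0, "axes must be positive")
  abort_if(ref_minor > ref_major, "`ref_minor` must not exceed `ref_major`")
  structure(list(ref_major = ref_major, ref_minor = ref_minor,
                 aspect = ref_minor / ref_major),
            class = "spheroid_model")
}

#' Spheroid-equivalent diameter of an en-face measured particle
#'
#' Corrects an en-face (maximal) diameter to the mean axis length of the
#' corresponding oblate spheroid, for comparison against methods that are
#' sensitive to rotationally averaged diameters. The measured diameter `d`
#' is taken as the spheroid's two equal major axes and the third axis as
#' `d * aspect`, so the correction is the arithmetic mean of the three
#' axis lengths:
#' \deqn{d_{eq} = d \cdot (2 + r) / 3, \quad r = ref\_minor / ref\_major.}
#' With the default LDL reference shape the factor is
#' `(2 + 12.1/21.4) / 3 = 0.8551`. The correction is linear in `d` and is
#' the identity for a sphere (`r = 1`).
#'
#' @param measured_major measured en-face diameter(s) in nm; vectorised.
#' @param model a [spheroid_model()].
#' @return numeric vector of corrected diameters in nm.
#' @examples
#' spheroid_equivalent_diameter(24.00)   # 20.52 nm
#' @export
spheroid_equivalent_diameter <- function(measured_major,
                                         model = spheroid_model()) {
  stopifnot(inherits(model, "spheroid_model"))
  abort_if(any(!is.finite(measured_major)) || any(measured_major <= 0),
           "`measured_major` must be positive")
  measured_major * (2 + model$aspect) / 3
}

calliper_from_idx <- function(idx, nr, nm_per_pixel) {
  cols <- idx_cols(idx, nr)
  (max(cols) - min(cols) + 1L) * nm_per_pixel
}

as_mask_idx <- function(mask) {
  abort_if(!is.matrix(mask), "`mask` must be a matrix")
  idx <- which(mask != 0)
  abort_if(length(idx) == 0, "empty mask")
  list(idx = idx, nr = nrow(mask))
}

#' Horizontal calliper diameter of a particle mask
#'
#' The horizontal extent of the mask — the number of pixel columns it
#' spans, inclusive of both end pixels — converted to nm. Because
#' particles land with arbitrary in-plane orientation, a fixed horizontal
#' measurement direction is a random direction with respect to each
#' particle, which is what makes pooled calliper distributions unbiased.
#'
#' @param mask logical or 0/1 matrix (non-empty).
#' @param nm_per_pixel calibration in nm per pixel.
#' @return calliper diameter in nm.
#' @export
horizontal_calliper <- function(mask, nm_per_pixel) {
  m <- as_mask_idx(mask)
  calliper_from_idx(m$idx, m$nr, nm_per_pixel)
}

axes_from_idx <- function(idx, nr, nm_per_pixel) {
  r <- idx_rows(idx, nr); c <- idx_cols(idx, nr)
  cr <- mean(r); cc <- mean(c)
  n <- length(idx)
  vrr <- sum((r - cr)^2) / n
  vcc <- sum((c - cc)^2) / n
  vrc <- sum((r - cr) * (c - cc)) / n
  ev <- eigen(matrix(c(vrr, vrc, vrc, vcc), 2, 2), symmetric = TRUE)$values
  abort_if(ev[2] <= 1e-9, "degenerate (collinear) mask")
  # A solid ellipse with semi-axes (a, b) has coordinate variances
  # (a^2/4, b^2/4) along its principal directions, so full axis = 4*sqrt(ev).
  major <- 4 * sqrt(ev[1]) * nm_per_pixel
  minor <- 4 * sqrt(ev[2]) * nm_per_pixel
  c(major = major, minor = minor, ratio = major / minor)
}

#' Second-moment-equivalent ellipse axes of a mask
#'
#' Fits the ellipse with the same second central moments as the mask
#' pixels and returns its full axis lengths in nm plus the major/minor
#' ratio. Requires at least 5 pixels; collinear masks are rejected.
#'
#' @inheritParams horizontal_calliper
#' @return named numeric vector `c(major, minor, ratio)`.
#' @export
fit_axes <- function(mask, nm_per_pixel) {
  m <- as_mask_idx(mask)
  abort_if(length(m$idx) < 5, "mask must contain at least 5 pixels")
  axes_from_idx(m$idx, m$nr, nm_per_pixel)
}

#' Linear size of a particle from its mask area
#'
#' The square root of the pixel area, a scale-free linear size measure
#' used for annotation statistics and Bland-Altman size agreement.
#'
#' @param area_px2 area(s) in pixels^2, non-negative; vectorised.
#' @return numeric vector, sqrt(area) in pixels.
#' @export
linear_size_from_area <- function(area_px2) {
  abort_if(any(area_px2 < 0), "area must be non-negative")
  sqrt(area_px2)
}

#' Measure every particle in an instance set
#'
#' One row per instance: pixel area and its square-root linear size,
#' horizontal calliper diameter, moment-equivalent axes with their ratio,
#' and the centroid in 0-based (x, y) pixel coordinates. Instances with
#' fewer than 5 pixels get `NA` axes.
#'
#' @param instances an [instance_set()].
#' @param nm_per_pixel calibration in nm per pixel, or a [micrograph()]
#'   from which to take it.
#' @return A tibble with columns `id`, `area_px2`, `linear_size_px`,
#'   `calliper_nm`, `major_nm`, `minor_nm`, `ratio`, `centroid_x`,
#'   `centroid_y`.
#' @export
measure_particles <- function(instances, nm_per_pixel) {
  stopifnot(inherits(instances, "instance_set"))
  if (inherits(nm_per_pixel, "micrograph")) {
    nm_per_pixel <- nm_per_pixel$nm_per_pixel
  }
  nr <- instances$dim[1]
  rows <- purrr::map(seq_along(instances$masks), function(k) {
    idx <- instances$masks[[k]]
    ax <- if (length(idx) >= 5) {
      tryCatch(axes_from_idx(idx, nr, nm_per_pixel),
               error = function(e) c(major = NA_real_, minor = NA_real_,
                                     ratio = NA_real_))
    } else c(major = NA_real_, minor = NA_real_, ratio = NA_real_)
    tibble::tibble(
      id = k,
      area_px2 = length(idx),
      linear_size_px = sqrt(length(idx)),
      calliper_nm = calliper_from_idx(idx, nr, nm_per_pixel),
      major_nm = unname(ax["major"]),
      minor_nm = unname(ax["minor"]),
      ratio = unname(ax["ratio"]),
      centroid_x = mean(idx_cols(idx, nr)) - 1,
      centroid_y = mean(idx_rows(idx, nr)) - 1
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarise a particle size distribution
#'
#' Mean, sample standard deviation (n - 1 denominator; 0 when n = 1),
#' coefficient of variation in percent, and a binned relative-frequency
#' histogram. Bins are half-open `[lower, lower + bin_width)` nm and are
#' labelled by their lower limit; relative frequencies are percentages of
#' the total and sum to 100.
#'
#' @param values particle sizes in nm (n >= 1).
#' @param bin_width histogram bin width in nm (default 2).
#' @return An object of class `size_summary`: list with `n`, `mean`, `sd`,
#'   `cv_percent` and `histogram` (tibble `bin_lower`, `count`,
#'   `rel_freq_pct`).
#' @export
summarize_sizes <- function(values, bin_width = 2) {
  abort_if(length(values) < 1, "need at least one value")
  abort_if(any(!is.finite(values)), "values must be finite")
  m <- mean(values)
  s <- if (length(values) == 1) 0 else stats::sd(values)
  lowers <- floor(values / bin_width) * bin_width
  tab <- table(lowers)
  hist <- tibble::tibble(
    bin_lower = as.numeric(names(tab)),
    count = as.integer(tab),
    rel_freq_pct = 100 * as.integer(tab) / length(values)
  )
  structure(list(n = length(values), mean = m, sd = s,
                 cv_percent = if (m == 0) NA_real_ else 100 * s / m,
                 bin_width = bin_width, histogram = hist),
            class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf(
    "<size_summary: n=%d, mean=%.2f nm, SD=%.3f nm, CV=%.2f%%, %d bins of %g nm>\n",
    x$n, x$mean, x$sd, x$cv_percent, nrow(x$histogram), x$bin_width))
  invisible(x)
}

#' Intensity profile along a line segment
#'
#' Samples the image by nearest pixel at 1-px steps from `p0` to `p1`
#' (plus the exact endpoint when the length is not an integer). Used to
#' inspect the grey-level transition through a particle edge.
#'
#' @param mg a [micrograph()].
#' @param p0,p1 endpoints as `c(x, y)` in 0-based pixel coordinates,
#'   inside the image.
#' @return A tibble with `position_nm` (distance from `p0`) and
#'   `intensity`.
#' @export
edge_profile <- function(mg, p0, p1) {
  stopifnot(inherits(mg, "micrograph"))
  dims <- dim(mg$image)
  chk <- function(p) {
    abort_if(p[1] < 0 || p[2] < 0 || p[1] > dims[2] - 1 || p[2] > dims[1] - 1,
             "profile endpoint outside the image")
  }
  chk(p0); chk(p1)
  len <- sqrt(sum((p1 - p0)^2))
  d <- seq(0, len, by = 1)
  if (length(d) == 0 || d[length(d)] < len) d <- c(d, len)
  t <- if (len == 0) 0 else d / len
  xs <- round(p0[1] + t * (p1[1] - p0[1]))
  ys <- round(p0[2] + t * (p1[2] - p0[2]))
  tibble::tibble(
    position_nm = d * mg$nm_per_pixel,
    intensity = mg$image[cbind(ys + 1, xs + 1)]
  )
}

#' Grey-level contrast range of an edge profile
#'
#' Contrast is expressed as the range (max minus min) of grey values
#' along a profile running from background through the particle edge.
#'
#' @param profile a tibble from [edge_profile()] or a numeric vector of
#'   intensities.
#' @return numeric contrast range in intensity units.
#' @export
contrast_range <- function(profile) {
  v <- if (is.data.frame(profile)) profile$intensity else profile
  abort_if(length(v) == 0, "empty profile")
  max(v) - min(v)
}

#' Linear trend of mean particle size across SEC fractions
#'
#' Ordinary least squares fit of mean particle size against gel
#' filtration fraction index, summarising how particle size decreases
#' across successive size-exclusion chromatography fractions.
#'
#' @param data data frame with the predictor in the first column and mean
#'   size (nm) in the second, or given via `x`/`y`.
#' @param x,y optional column names (tidy-select style strings) when
#'   `data` has other columns; defaults to the first two columns.
#' @return An object of class `sec_trend`: list with `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying `lm` fit. `r_squared` is `NaN`
#'   when the response is constant.
#' @export
sec_trend_fit <- function(data, x = NULL, y = NULL) {
  df <- as.data.frame(data)
  xs <- if (is.null(x)) df[[1]] else df[[x]]
  ys <- if (is.null(y)) df[[2]] else df[[y]]
  abort_if(length(unique(xs)) < 2, "need at least 2 distinct x values")
  fit <- stats::lm(ys ~ xs)
  r2 <- if (stats::var(ys) == 0) NaN else
    1 - sum(stats::resid(fit)^2) / sum((ys - mean(ys))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(xs), fit = fit,
                 data = tibble::tibble(x = xs, y = ys)),
            class = "sec_trend")
}

#' @export
print.sec_trend <- function(x, ...) {
  cat(sprintf("<sec_trend: y = %.4gx + %.4g, R^2 = %.4g, n = %d>\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
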