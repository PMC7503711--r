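#' Parameters for the baseline particle segmenter
#'
#' Controls for [segment_particles()], the classical rim-contrast
#' instance segmenter. Defaults target dark-rimmed lipoprotein particles
#' of 14-80 nm on a bright background.
#'
#' @param expected_diameter_range particle diameter search range in nm.
#' @param detection_threshold minimum normalised radial-symmetry vote for
#'   a seed (in \[0, 1\]; 1 is the vote mass of an ideal full circle).
#' @param min_area_px2 minimum instance area in pixels^2.
#' @param split_touching split foreground components that contain several
#'   seeds (marker-based nearest-seed splitting)?
#' @param smooth_sigma Gaussian presmoothing in pixels.
#' @param edge_quantile gradient-magnitude quantile above which pixels
#'   vote.
#' @param min_gradient absolute gradient floor (grey levels per pixel);
#'   keeps featureless images from voting.
#' @param fg_threshold_frac foreground threshold position as a fraction
#'   of the way from the background grey level (median) toward the dark
#'   rim level (0.002 quantile). 0.42 places the mask contour at the
#'   outer rim transition without an outward blur bias.
#' @param watershed_tolerance depth tolerance (in distance-map units) for
#'   splitting merged foreground blobs; small single particles stay whole
#'   while touching pairs split at the neck.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(expected_diameter_range = c(14, 80),
                       detection_threshold = 0.8,
                       min_area_px2 = 80,
                       split_touching = TRUE,
                       smooth_sigma = 1.5,
                       edge_quantile = 0.92,
                       min_gradient = 8,
                       fg_threshold_frac = 0.42,
                       watershed_tolerance = 4) {
  abort_if(expected_diameter_range[1] >= expected_diameter_range[2],
           "diameter range must satisfy min < max")
  abort_if(!is.finite(detection_threshold), "threshold must be finite")
  structure(list(expected_diameter_range = expected_diameter_range,
                 detection_threshold = detection_threshold,
                 min_area_px2 = min_area_px2,
                 split_touching = split_touching,
                 smooth_sigma = smooth_sigma,
                 edge_quantile = edge_quantile,
                 min_gradient = min_gradient,
                 fg_threshold_frac = fg_threshold_frac,
                 watershed_tolerance = watershed_tolerance),
            class = "seg_params")
}

# Central-difference gradients (rotation-symmetric, no kernel phase).
grad_x <- function(im) {
  g <- matrix(0, nrow(im), ncol(im))
  g[, 2:(ncol(im) - 1)] <- (im[, 3:ncol(im)] - im[, 1:(ncol(im) - 2)]) / 2
  g
}
grad_y <- function(im) {
  g <- matrix(0, nrow(im), ncol(im))
  g[2:(nrow(im) - 1), ] <- (im[3:nrow(im), ] - im[1:(nrow(im) - 2), ]) / 2
  g
}

#' Segment dark-rimmed particles in a micrograph
#'
#' Classical instance segmentation for positively contrasted (dark rim on
#' bright background) spheroidal particles:
#' smoothing, then gradient-based radial-symmetry voting over the
#' expected radius range (each strong edge pixel votes down its intensity
#' gradient, so rim pixels vote toward their particle centre), peak
#' detection on the smoothed vote map with non-maximum suppression, a
#' rim-bounded foreground (thresholded between background and rim grey
#' level, holes filled), distance-map watershed splitting of merged
#' foreground blobs, and marker-based nearest-seed splitting of regions
#' that still contain several seeds; regions without a seed are
#' discarded. Each instance carries a confidence score: its seed's vote mass
#' normalised by the mass an ideal full circle of the minimum radius
#' would cast.
#'
#' The detector is deterministic, and every emitted mask's
#' area-equivalent diameter lies within `expected_diameter_range` (hard
#' filter). It stands in for a trained instance-segmentation model where
#' none is available; the evaluation suite ([evaluate_segmentation()])
#' accepts any model's masks.
#'
#' @param mg a [micrograph()].
#' @param params a [seg_params()].
#' @return A scored [instance_set()] with `source = "prediction"`
#'   (possibly empty).
#' @export
segment_particles <- function(mg, params = seg_params()) {
  stopifnot(inherits(mg, "micrograph"))
  p <- params
  nmpp <- mg$nm_per_pixel
  dims <- dim(mg$image)
  nr <- dims[1]
  im <- EBImage::imageData(EBImage::gblur(mg$image, p$smooth_sigma))

  gx <- grad_x(im); gy <- grad_y(im)
  mag <- sqrt(gx^2 + gy^2)
  thr <- max(stats::quantile(mag, p$edge_quantile), p$min_gradient)
  edge <- which(mag > thr)
  empty <- instance_set(list(), dim = dims, scores = numeric(0),
                        source = "prediction")
  if (length(edge) == 0) return(empty)

  r_min <- p$expected_diameter_range[1] / (2 * nmpp)
  r_max <- p$expected_diameter_range[2] / (2 * nmpp)
  radii <- seq(r_min, r_max, by = max(1.5, (r_max - r_min) / 30))

  er <- idx_rows(edge, nr); ec <- idx_cols(edge, nr)
  ux <- gx[edge] / mag[edge]; uy <- gy[edge] / mag[edge]
  acc <- matrix(0, dims[1], dims[2])
  for (r in radii) {
    # vote against the gradient: rims are darker than their surroundings,
    # so -grad points from the rim toward the particle interior
    vr <- round(er - r * uy); vc <- round(ec - r * ux)
    keep <- vr >= 1 & vr <= dims[1] & vc >= 1 & vc <= dims[2]
    votes <- tabulate(rc_to_idx(vr[keep], vc[keep], nr), nbins = prod(dims))
    acc <- acc + votes
  }
  acc <- EBImage::imageData(EBImage::gblur(acc, 2))

  # vote mass of an ideal circle at the minimum radius, concentrated by
  # the accumulator blur: perimeter * (radius steps landing within the
  # blur kernel) / (kernel area effective). Calibrated constant 0.16.
  vote_scale <- 0.16 * 2 * pi * r_min
  # local maxima with non-maximum suppression at 1.8 * r_min (duplicate
  # vote peaks inside one ellipse sit on its evolute, up to ~0.8 r apart)
  w <- 2L * as.integer(floor(r_min / 2)) + 1L
  mx <- EBImage::imageData(
    EBImage::dilate(acc, EBImage::makeBrush(w, shape = "disc")))
  peaks <- which(acc >= mx - 1e-9 & acc / vote_scale >= p$detection_threshold)
  if (length(peaks) == 0) return(empty)
  ord <- order(-acc[peaks], peaks)
  peaks <- peaks[ord]
  pr <- idx_rows(peaks, nr); pc <- idx_cols(peaks, nr)
  keep <- rep(TRUE, length(peaks))
  for (i in seq_along(peaks)) {
    if (!keep[i]) next
    if (i < length(peaks)) {
      later <- seq.int(i + 1L, length(peaks))
      nms_r <- 1.8 * r_min
      close <- later[(pr[later] - pr[i])^2 + (pc[later] - pc[i])^2 < nms_r^2]
      keep[close] <- FALSE
    }
  }
  peaks <- peaks[keep]; pr <- pr[keep]; pc <- pc[keep]
  scores <- pmin(1, acc[peaks] / vote_scale)

  # rim-bounded foreground: threshold part-way from background (median)
  # toward the rim grey level (low quantile), holes filled so the mask is
  # the full particle. A 1-px erosion then removes the outward bleed that
  # 2-D blur causes at the high-curvature extremities of each ellipse,
  # keeping calliper measurements on the emitted masks unbiased.
  bg <- stats::median(im)
  dark <- stats::quantile(im, 0.002)
  fg <- im < bg - p$fg_threshold_frac * (bg - dark)
  fg <- EBImage::imageData(EBImage::fillHull(fg)) > 0
  fg <- EBImage::imageData(
    EBImage::erode(fg, EBImage::makeBrush(3, shape = "box"))) > 0
  # shape-based splitting of merged blobs before seed assignment
  lab <- if (p$split_touching) {
    EBImage::imageData(EBImage::watershed(EBImage::distmap(fg),
                                          tolerance = p$watershed_tolerance,
                                          ext = 1))
  } else {
    EBImage::imageData(EBImage::bwlabel(fg))
  }

  seed_comp <- lab[peaks]
  in_fg <- seed_comp > 0
  peaks <- peaks[in_fg]; pr <- pr[in_fg]; pc <- pc[in_fg]
  scores <- scores[in_fg]; seed_comp <- seed_comp[in_fg]
  if (length(peaks) == 0) return(empty)

  masks <- vector("list", length(peaks))
  for (comp in unique(seed_comp)) {
    s <- which(seed_comp == comp)
    cidx <- which(lab == comp)
    if (length(s) == 1L || !p$split_touching) {
      # single seed: the region is the mask
      masks[[s[1]]] <- cidx
    } else {
      # nearest-seed (marker-based) splitting; ties go to the stronger seed
      rr <- idx_rows(cidx, nr); cc <- idx_cols(cidx, nr)
      d2 <- vapply(s, function(k) (rr - pr[k])^2 + (cc - pc[k])^2,
                   numeric(length(cidx)))
      assign <- max.col(-d2, ties.method = "first")
      for (k in seq_along(s)) masks[[s[k]]] <- cidx[assign == k]
    }
  }
  ok <- !vapply(masks, is.null, TRUE) & vapply(masks, length, 1L) > 0
  masks <- masks[ok]; scores <- scores[ok]
  # hard filters: area and area-equivalent diameter within expectations
  areas <- vapply(masks, length, 1L)
  deq <- 2 * sqrt(areas / pi) * nmpp
  ok <- areas >= p$min_area_px2 &
    deq >= p$expected_diameter_range[1] & deq <= p$expected_diameter_range[2]
  instance_set(masks[ok], dim = dims, scores = scores[ok],
               source = "prediction")
}

#' Detect antibody blobs outside particle masks
#'
#' Antibody densities are the darkest compact structures in a labelled
#' scene. Candidates are pixels darker than 60% of the way from the
#' background (median grey) to the darkest grey level, excluding pixels
#' inside the supplied particle masks; connected candidates are kept
#' when compact (area at least 40% of their bounding circle) and when
#' their area-equivalent diameter falls within `size_range` (a 1.5 nm
#' margin absorbs rim occlusion and blur losses).
#'
#' @param mg a [micrograph()].
#' @param particle_masks an [instance_set()] of particle masks.
#' @param size_range blob diameter range in nm (default `c(7, 22)`).
#' @return An [instance_set()] of blob masks (`source = "prediction"`).
#' @export
detect_blobs <- function(mg, particle_masks, size_range = c(7, 22)) {
  stopifnot(inherits(mg, "micrograph"))
  dims <- dim(mg$image)
  nmpp <- mg$nm_per_pixel
  im <- EBImage::imageData(EBImage::gblur(mg$image, 1))
  bg <- stats::median(im)
  dark <- stats::quantile(im, 0.001)
  cand <- im < bg - 0.6 * (bg - dark)
  if (length(particle_masks$masks) > 0) {
    abort_if(!identical(particle_masks$dim, dims), "mask grid differs")
    cand[unlist(particle_masks$masks)] <- FALSE
  }
  lab <- EBImage::imageData(EBImage::bwlabel(cand))
  nlab <- max(lab)
  if (nlab == 0) {
    return(instance_set(list(), dim = dims, source = "prediction"))
  }
  nr <- dims[1]
  masks <- lapply(seq_len(nlab), function(l) which(lab == l))
  keep <- vapply(masks, function(idx) {
    area <- length(idx)
    deq <- 2 * sqrt(area / pi) * nmpp
    if (deq < size_range[1] - 1.5 || deq > size_range[2] + 1.5) return(FALSE)
    b <- mask_bbox(idx, nr)
    ext <- max(b["rmax"] - b["rmin"], b["cmax"] - b["cmin"]) + 1
    area / (pi / 4 * ext^2) >= 0.4
  }, TRUE)
  instance_set(masks[keep], dim = dims, source = "prediction")
}
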