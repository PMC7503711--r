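#' Parameters for a synthetic lipoprotein micrograph
#'
#' Describes a bright-background positive-contrast scene of dark-rimmed
#' spheroidal particles, as produced by mixed-metal methylcellulose (MC)
#' embedding: each particle projects as an ellipse whose rim is darkest,
#' whose interior is slightly darker than the background, and whose
#' projected axis ratio depends on the film thickness (thin films let
#' flattened particles lie en face, giving mean major/minor ratios near
#' 1.29; thick films allow tilted orientations, near 1.42). Sub-14-nm
#' clutter mimics plasma proteins, antibody labelling adds very dark
#' 7-22 nm blobs at particle peripheries, and a fraction of particles is
#' laid down in touching chains (aggregates).
#'
#' The drawn particle size is the *calliper* diameter the scene will
#' present horizontally — the quantity all reported size distributions
#' are built from — truncated at 14 nm, the lower limit of distinct
#' particles in these preparations.
#'
#' @param n_particles number of particles (>= 0).
#' @param size_mean,size_sd calliper size distribution in nm (normal,
#'   truncated at `size_min`).
#' @param size_min truncation floor in nm (default 14).
#' @param film_mode `"thin"` or `"thick"` MC film.
#' @param clutter_density expected sub-14-nm clutter blobs per square
#'   micron.
#' @param labelled_fraction fraction of particles carrying antibody
#'   blobs, in \[0, 1\].
#' @param blobs_per_labelled mean blob count per labelled particle
#'   (>= 1; counts are 1 plus a Poisson remainder).
#' @param blob_size_mean,blob_size_sd,blob_size_range blob diameter
#'   distribution in nm (normal truncated to the range).
#' @param aggregate_fraction fraction of particles placed in touching
#'   chains of 2-4 particles, in \[0, 1\].
#' @param noise_sd additive Gaussian intensity noise (8-bit grey levels).
#' @param blur_sigma Gaussian blur in pixels applied before noise.
#' @param img_shape image dimensions `c(nrow, ncol)` in pixels.
#' @param nm_per_pixel calibration (default 0.5 nm/px).
#' @param rim_width_px width of the dark rim in pixels.
#' @param min_gap_px minimum gap between non-aggregated particles.
#' @param seed integer seed; identical parameters give bit-identical
#'   scenes.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(n_particles = 200L,
                         size_mean = 23.7, size_sd = 2.5, size_min = 14,
                         film_mode = c("thin", "thick"),
                         clutter_density = 100,
                         labelled_fraction = 0,
                         blobs_per_labelled = 1,
                         blob_size_mean = 13.37, blob_size_sd = 3.55,
                         blob_size_range = c(7, 22),
                         aggregate_fraction = 0.1,
                         noise_sd = 6, blur_sigma = 1.2,
                         img_shape = c(1400L, 1400L),
                         nm_per_pixel = 0.6,
                         rim_width_px = 3, min_gap_px = 4,
                         seed = 1L) {
  film_mode <- match.arg(film_mode)
  abort_if(n_particles < 0, "`n_particles` must be >= 0")
  abort_if(size_mean <= size_min, "`size_mean` must exceed `size_min`")
  abort_if(labelled_fraction < 0 || labelled_fraction > 1 ||
             aggregate_fraction < 0 || aggregate_fraction > 1,
           "fractions must lie in [0, 1]")
  abort_if(blobs_per_labelled < 1, "`blobs_per_labelled` must be >= 1")
  abort_if(blob_size_range[1] < 7 - 1e-9 || blob_size_range[2] > 22 + 1e-9 ||
             blob_size_range[1] >= blob_size_range[2],
           "`blob_size_range` must lie within (7, 22) nm")
  structure(
    list(n_particles = as.integer(n_particles), size_mean = size_mean,
         size_sd = size_sd, size_min = size_min, film_mode = film_mode,
         clutter_density = clutter_density,
         labelled_fraction = labelled_fraction,
         blobs_per_labelled = blobs_per_labelled,
         blob_size_mean = blob_size_mean, blob_size_sd = blob_size_sd,
         blob_size_range = blob_size_range,
         aggregate_fraction = aggregate_fraction,
         noise_sd = noise_sd, blur_sigma = blur_sigma,
         img_shape = as.integer(img_shape), nm_per_pixel = nm_per_pixel,
         rim_width_px = rim_width_px, min_gap_px = min_gap_px,
         seed = as.integer(seed)),
    class = "scene_params")
}

# Grey levels by film mode. Thin films give stronger edge contrast
# (darker rims against a brighter background) than thick films.
scene_levels <- function(film_mode) {
  if (film_mode == "thin") {
    list(bg = 200, interior = 150, rim = 60, clutter = 180, blob = 25)
  } else {
    list(bg = 190, interior = 165, rim = 110, clutter = 175, blob = 25)
  }
}

# Projected major/minor axis-ratio law by film mode (truncated normal on
# the ratio). Thin films hold particles near en face (narrow, mean 1.29);
# thick films allow tilt (wide, mean 1.42).
draw_axis_ratios <- function(n, film_mode) {
  if (n == 0) return(numeric(0))
  if (film_mode == "thin") rnorm_trunc(n, 1.29, 0.08, lower = 1, upper = 2)
  else rnorm_trunc(n, 1.42, 0.15, lower = 1, upper = 2.2)
}

# Pixels (linear indices) of the ellipse with centre (cx, cy) in 1-based
# continuous pixel coordinates, semi-axes (a, b) in px, orientation theta;
# also returns the normalised radius of each pixel for rim banding.
ellipse_pixels <- function(cx, cy, a, b, theta, dims) {
  nr <- dims[1]; nc <- dims[2]
  half_w <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  half_h <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  cols <- max(1L, floor(cx - half_w)):min(nc, ceiling(cx + half_w))
  rows <- max(1L, floor(cy - half_h)):min(nr, ceiling(cy + half_h))
  dx <- rep(cols - cx, each = length(rows))
  dy <- rep(rows - cy, times = length(cols))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  rho <- sqrt(u^2 + v^2)
  keep <- rho <= 1
  idx <- rc_to_idx(rep(rows, times = length(cols))[keep],
                   rep(cols, each = length(rows))[keep], nr)
  list(idx = idx, rho = rho[keep])
}

disc_pixels <- function(cx, cy, r, dims) {
  nr <- dims[1]; nc <- dims[2]
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  dx <- rep(cols - cx, each = length(rows))
  dy <- rep(rows - cy, times = length(cols))
  keep <- dx^2 + dy^2 <= r^2
  rc_to_idx(rep(rows, times = length(cols))[keep],
            rep(cols, each = length(rows))[keep], nr)
}

# Split k particles into chain sizes of 2-4.
draw_chain_sizes <- function(k) {
  sizes <- integer(0)
  while (k > 0) {
    s <- if (k == 1) 1L else
      sample(2:4, 1, prob = c(0.6, 0.25, 0.15))
    s <- min(s, k)
    if (s == 1 && length(sizes) > 0) {
      sizes[length(sizes)] <- sizes[length(sizes)] + 1L
      k <- 0
    } else {
      sizes <- c(sizes, s)
      k <- k - s
    }
  }
  sizes[sizes >= 2]
}

#' Simulate a calibrated micrograph with full ground truth
#'
#' Renders the scene described by a [scene_params()] object and returns
#' both the micrograph and a complete `scene_truth`: per-particle true
#' calliper diameter, projected axes, centre, orientation, labelling and
#' aggregate membership, plus instance masks for particles and antibody
#' blobs and a clutter mask. Identical parameters (including the seed)
#' produce bit-identical output.
#'
#' Each particle's ellipse is scaled so that its analytic horizontal
#' extent equals the drawn calliper diameter, so downstream calliper
#' measurement recovers the generating size distribution without an
#' orientation bias; particle centres are continuous, which makes the
#' pixel-grid quantisation of the extent unbiased as well.
#'
#' @param params a [scene_params()].
#' @return list with elements `micrograph` (a [micrograph()]) and
#'   `truth` (a `scene_truth`).
#' @export
simulate_micrograph <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  dims <- p$img_shape
  lv <- scene_levels(p$film_mode)
  nmpp <- p$nm_per_pixel
  with_seed(p$seed, {
    n <- p$n_particles
    sizes_nm <- if (n > 0)
      rnorm_trunc(n, p$size_mean, p$size_sd, lower = p$size_min) else numeric(0)
    ratios <- draw_axis_ratios(n, p$film_mode)
    thetas <- stats::runif(n, 0, pi)
    c_px <- sizes_nm / nmpp
    s_px <- c_px / (2 * sqrt(cos(thetas)^2 + sin(thetas)^2 / ratios^2))
    a_px <- s_px
    b_px <- s_px / ratios

    # chain membership: the last `k` particles form aggregates
    n_agg <- round(p$aggregate_fraction * n)
    chain_sizes <- if (n_agg >= 2) draw_chain_sizes(n_agg) else integer(0)
    n_agg <- sum(chain_sizes)
    aggregate_id <- rep(NA_integer_, n)
    if (n_agg > 0) {
      ids <- rep(seq_along(chain_sizes), chain_sizes)
      aggregate_id[seq.int(n - n_agg + 1L, n)] <- ids
    }

    cx <- numeric(n); cy <- numeric(n)
    placed <- logical(n)
    margin <- a_px + p$rim_width_px + 3
    place_one <- function(i, prev = NA_integer_) {
      for (try in seq_len(3000L)) {
        if (is.na(prev)) {
          x <- stats::runif(1, margin[i] + 1, dims[2] - margin[i])
          y <- stats::runif(1, margin[i] + 1, dims[1] - margin[i])
        } else {
          # chain continuation: touch the previous member
          phi <- stats::runif(1, 0, 2 * pi)
          d <- 0.92 * (sqrt(a_px[prev] * b_px[prev]) + sqrt(a_px[i] * b_px[i]))
          x <- cx[prev] + d * cos(phi)
          y <- cy[prev] + d * sin(phi)
          if (x < margin[i] + 1 || x > dims[2] - margin[i] ||
              y < margin[i] + 1 || y > dims[1] - margin[i]) next
        }
        others <- which(placed)
        others <- others[is.na(aggregate_id[others]) |
                           is.na(aggregate_id[i]) |
                           aggregate_id[others] != aggregate_id[i]]
        if (length(others) > 0) {
          dmin <- a_px[i] + a_px[others] + p$min_gap_px
          if (any((cx[others] - x)^2 + (cy[others] - y)^2 < dmin^2)) next
        }
        cx[i] <<- x; cy[i] <<- y; placed[i] <<- TRUE
        return(TRUE)
      }
      FALSE
    }
    if (n > 0) {
      ord <- c(which(is.na(aggregate_id)), which(!is.na(aggregate_id)))
      prev_in_chain <- NA_integer_; prev_chain <- NA_integer_
      for (i in ord) {
        prev <- if (!is.na(aggregate_id[i]) &&
                      identical(aggregate_id[i], prev_chain)) prev_in_chain
                else NA_integer_
        ok <- place_one(i, prev)
        abort_if(!ok, "could not place all particles; reduce density")
        if (!is.na(aggregate_id[i])) {
          prev_in_chain <- i; prev_chain <- aggregate_id[i]
        }
      }
    }

    # rasterise particle masks and paint
    canvas <- matrix(lv$bg, dims[1], dims[2])
    masks <- vector("list", n)
    rims <- vector("list", n)
    for (i in seq_len(n)) {
      ep <- ellipse_pixels(cx[i], cy[i], a_px[i], b_px[i], thetas[i], dims)
      masks[[i]] <- sort(ep$idx)
      rim_frac <- p$rim_width_px / sqrt(a_px[i] * b_px[i])
      rims[[i]] <- ep$idx[ep$rho > 1 - rim_frac]
    }
    # clutter: faint sub-14-nm discs
    area_um2 <- prod(dims) * (nmpp / 1000)^2
    n_clutter <- stats::rpois(1, p$clutter_density * area_um2)
    clutter_idx <- integer(0)
    if (n_clutter > 0) {
      for (k in seq_len(n_clutter)) {
        d_nm <- stats::runif(1, 5, 13)
        r <- d_nm / (2 * nmpp)
        clutter_idx <- c(clutter_idx,
                         disc_pixels(stats::runif(1, 1, dims[2]),
                                     stats::runif(1, 1, dims[1]), r, dims))
      }
      clutter_idx <- sort(unique(clutter_idx))
    }
    # antibody blobs on a labelled subset
    n_lab <- round(p$labelled_fraction * n)
    labelled_ids <- if (n_lab > 0) sort(sample.int(n, n_lab)) else integer(0)
    blob_masks <- list(); blob_parent <- integer(0)
    n_blobs <- integer(n)
    for (i in labelled_ids) {
      k <- 1L + stats::rpois(1, max(0, p$blobs_per_labelled - 1))
      n_blobs[i] <- k
      for (bj in seq_len(k)) {
        d_nm <- rnorm_trunc(1, p$blob_size_mean, p$blob_size_sd,
                            lower = p$blob_size_range[1],
                            upper = p$blob_size_range[2])
        br <- d_nm / (2 * nmpp)
        for (try in seq_len(30L)) {
          t <- stats::runif(1, 0, 2 * pi)
          # boundary point and outward normal of the particle ellipse
          bx <- a_px[i] * cos(t); by <- b_px[i] * sin(t)
          nx <- cos(t) / a_px[i]; ny <- sin(t) / b_px[i]
          nn <- sqrt(nx^2 + ny^2); nx <- nx / nn; ny <- ny / nn
          rot <- function(x, y) c(x * cos(thetas[i]) - y * sin(thetas[i]),
                                  x * sin(thetas[i]) + y * cos(thetas[i]))
          bp <- rot(bx, by); nv <- rot(nx, ny)
          bcx <- cx[i] + bp[1] + nv[1] * (br - 1)
          bcy <- cy[i] + bp[2] + nv[2] * (br - 1)
          if (bcx < br + 2 || bcx > dims[2] - br - 1 ||
              bcy < br + 2 || bcy > dims[1] - br - 1) next
          others <- setdiff(seq_len(n), i)
          if (length(others) > 0 &&
              any(sqrt((cx[others] - bcx)^2 + (cy[others] - bcy)^2) <
                    a_px[others] + br + 2.5)) next
          break
        }
        bm <- disc_pixels(bcx, bcy, br, dims)
        blob_masks[[length(blob_masks) + 1L]] <- sort(bm)
        blob_parent <- c(blob_parent, i)
      }
    }

    if (length(clutter_idx) > 0) {
      canvas[clutter_idx] <- pmin(canvas[clutter_idx], lv$clutter)
    }
    for (i in seq_len(n)) {
      canvas[masks[[i]]] <- pmin(canvas[masks[[i]]], lv$interior)
    }
    for (i in seq_len(n)) {
      canvas[rims[[i]]] <- pmin(canvas[rims[[i]]], lv$rim)
    }
    for (bm in blob_masks) canvas[bm] <- pmin(canvas[bm], lv$blob)

    if (p$blur_sigma > 0) {
      canvas <- EBImage::imageData(EBImage::gblur(canvas, p$blur_sigma))
    }
    if (p$noise_sd > 0) {
      canvas <- canvas + stats::rnorm(length(canvas), 0, p$noise_sd)
    }
    canvas <- matrix(pmin(pmax(round(canvas), 0), 255), dims[1], dims[2])

    particles <- tibble::tibble(
      id = seq_len(n),
      true_diameter_nm = sizes_nm,
      major_nm = 2 * a_px * nmpp,
      minor_nm = 2 * b_px * nmpp,
      orientation = thetas,
      center_x = cx - 1,
      center_y = cy - 1,
      labelled = n_blobs >= 1L,
      n_blobs = n_blobs,
      aggregate_id = aggregate_id
    )
    truth <- structure(
      list(particles = particles,
           masks = instance_set(masks, dim = dims, source = "simulation"),
           blobs = instance_set(blob_masks, dim = dims, source = "simulation"),
           blob_parent = blob_parent,
           clutter_idx = clutter_idx,
           dim = dims, nm_per_pixel = nmpp, params = p),
      class = "scene_truth")
    list(micrograph = micrograph(canvas, nmpp,
                                 id = sprintf("sim-seed%d", p$seed)),
         truth = truth)
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth: %d particles (%d labelled, %d blobs), %d x %d px>\n",
    nrow(x$particles), sum(x$particles$labelled), length(x$blobs$masks),
    x$dim[1], x$dim[2]))
  invisible(x)
}

#' Extract ground-truth particle masks as an instance set
#'
#' @param truth a `scene_truth` from [simulate_micrograph()].
#' @return An [instance_set()] with `source = "simulation"`, in particle
#'   order.
#' @export
truth_to_instances <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  truth$masks
}
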