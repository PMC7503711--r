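# Internal sparse-mask geometry: bounding boxes, boundaries, distances,
# dilation and IoU. Masks are sorted linear index vectors; `nr` is the
# number of image rows.

mask_bbox <- function(idx, nr) {
  r <- idx_rows(idx, nr)
  c <- idx_cols(idx, nr)
  c(rmin = min(r), rmax = max(r), cmin = min(c), cmax = max(c))
}

bboxes_within <- function(b1, b2, gap) {
  # TRUE when the two bounding boxes come within `gap` pixels (Chebyshev).
  !(b1["rmin"] > b2["rmax"] + gap || b2["rmin"] > b1["rmax"] + gap ||
      b1["cmin"] > b2["cmax"] + gap || b2["cmin"] > b1["cmax"] + gap)
}

# Boundary pixels: mask pixels with a 4-neighbour outside the mask (or on
# the image border). Distances between disjoint masks are attained on
# boundaries, so this cuts pairwise work considerably.
mask_boundary <- function(idx, dims) {
  nr <- dims[1]; nc <- dims[2]
  r <- idx_rows(idx, nr); c <- idx_cols(idx, nr)
  inside <- matrix(FALSE, nr, nc)
  inside[idx] <- TRUE
  on_edge <- r == 1L | r == nr | c == 1L | c == nc
  has_bg <- on_edge
  ok <- !on_edge
  if (any(ok)) {
    ri <- r[ok]; ci <- c[ok]
    nb <- !(inside[rc_to_idx(ri - 1L, ci, nr)] &
              inside[rc_to_idx(ri + 1L, ci, nr)] &
              inside[rc_to_idx(ri, ci - 1L, nr)] &
              inside[rc_to_idx(ri, ci + 1L, nr)])
    has_bg[ok] <- nb
  }
  idx[has_bg]
}

# Minimum pixel-centre distance between two masks. metric "euclidean" or
# "chebyshev"; overlapping masks have distance 0.
mask_min_dist <- function(idx_a, idx_b, dims, metric = "euclidean") {
  if (length(intersect(idx_a, idx_b)) > 0) return(0)
  nr <- dims[1]
  ba <- mask_boundary(idx_a, dims)
  bb <- mask_boundary(idx_b, dims)
  ra <- idx_rows(ba, nr); ca <- idx_cols(ba, nr)
  rb <- idx_rows(bb, nr); cb <- idx_cols(bb, nr)
  dr <- abs(outer(ra, rb, "-"))
  dc <- abs(outer(ca, cb, "-"))
  if (metric == "chebyshev") min(pmax(dr, dc)) else min(sqrt(dr^2 + dc^2))
}

# Chebyshev (square structuring element) dilation of an index mask by
# `r` pixels, clipped to the image. r = 0 returns the mask unchanged.
mask_dilate_idx <- function(idx, dims, r) {
  if (r <= 0) return(idx)
  nr <- dims[1]; nc <- dims[2]
  rows <- idx_rows(idx, nr); cols <- idx_cols(idx, nr)
  off <- seq.int(-r, r)
  out <- integer(0)
  for (dr in off) {
    rr <- rows + dr
    keep_r <- rr >= 1L & rr <= nr
    for (dc in off) {
      cc <- cols + dc
      keep <- keep_r & cc >= 1L & cc <= nc
      out <- c(out, rc_to_idx(rr[keep], cc[keep], nr))
    }
  }
  sort(unique(out))
}

# Pairwise IoU between two instance sets (bounding-box prefiltered).
iou_matrix <- function(pred, truth) {
  np <- length(pred$masks); nt <- length(truth$masks)
  out <- matrix(0, np, nt)
  if (np == 0 || nt == 0) return(out)
  nr <- pred$dim[1]
  bp <- lapply(pred$masks, mask_bbox, nr = nr)
  bt <- lapply(truth$masks, mask_bbox, nr = nr)
  for (i in seq_len(np)) {
    ai <- length(pred$masks[[i]])
    for (j in seq_len(nt)) {
      if (!bboxes_within(bp[[i]], bt[[j]], 0L)) next
      inter <- length(intersect(pred$masks[[i]], truth$masks[[j]]))
      if (inter > 0) {
        out[i, j] <- inter / (ai + length(truth$masks[[j]]) - inter)
      }
    }
  }
  out
}
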