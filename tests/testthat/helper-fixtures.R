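# Fixture builders and independent oracles used across the suite.
# Oracles deliberately avoid the package's own geometry helpers: they
# work on dense logical matrices with EBImage morphology and brute-force
# enumeration.

# Solid ellipse mask (1-based centre coordinates, semi-axes in px).
ellipse_mask <- function(nr, nc, cy, cx, a, b = a, theta = 0) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dx <- c - cx; dy <- r - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u^2 + v^2 <= 1
}

disc_mask <- function(nr, nc, cy, cx, radius) {
  ellipse_mask(nr, nc, cy, cx, radius, radius)
}

# Random non-degenerate disc layout as an instance set.
random_disc_set <- function(n, nr = 60, nc = 60, r_range = c(3, 6),
                            scores = FALSE) {
  masks <- replicate(n, {
    r <- stats::runif(1, r_range[1], r_range[2])
    disc_mask(nr, nc, stats::runif(1, r + 2, nr - r - 1),
              stats::runif(1, r + 2, nc - r - 1), r)
  }, simplify = FALSE)
  instance_set(masks, scores = if (scores) stats::runif(n) else NULL,
               source = if (scores) "prediction" else "annotation")
}

# --- oracles -------------------------------------------------------------

# Pairwise "touch after dilation" via EBImage morphology on dense masks.
dilated_overlap_oracle <- function(iset, dilate_px) {
  n <- length(iset$masks)
  if (n < 2) return(0L)
  br <- EBImage::makeBrush(2L * dilate_px + 1L, shape = "box")
  dense <- lapply(seq_len(n), function(i) {
    m <- instance_mask(iset, i)
    if (dilate_px > 0) EBImage::imageData(EBImage::dilate(m, br)) > 0 else m
  })
  count <- 0L
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (any(dense[[i]] & dense[[j]])) count <- count + 1L
  }
  count
}

# Aggregate census oracle: pairwise Chebyshev-gap touch tests on dense
# masks, components via igraph.
census_oracle <- function(iset, gap = 1) {
  n <- length(iset$masks)
  if (n == 0) return(integer(0))
  br <- EBImage::makeBrush(2L * gap + 1L, shape = "box")
  dense <- lapply(seq_len(n), function(i) instance_mask(iset, i))
  dil <- lapply(dense, function(m)
    EBImage::imageData(EBImage::dilate(m, br)) > 0)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && any(dil[[i]] & dense[[j]])) adj[i, j] <- adj[j, i] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  sort(as.integer(table(igraph::components(g)$membership)))
}

# Optimal-assignment matching oracle: exhaustive search over injective
# prediction -> truth maps, maximising the number of pairs with
# IoU >= threshold. Feasible for <= 5 instances a side.
optimal_match_count <- function(pred, truth, threshold) {
  np <- length(pred$masks); nt <- length(truth$masks)
  if (np == 0 || nt == 0) return(0L)
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    a <- pred$masks[[i]]; b <- truth$masks[[j]]
    inter <- length(intersect(a, b))
    iou[i, j] <- inter / (length(a) + length(b) - inter)
  }
  ok <- iou >= threshold
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    recurse(i + 1L, used, count)  # leave prediction i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nt), 0L)
  best
}

# Tie-corrected Kruskal-Wallis H from first principles.
kw_h_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
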