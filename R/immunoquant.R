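#' Attach antibody blob densities to particles
#'
#' Heavily stained antibody "blobs" sit at particle peripheries. A blob
#' is attached to a particle when the two masks touch or lie within
#' `max_gap_px` (minimum Euclidean pixel-centre distance); each blob is
#' assigned to its nearest qualifying particle (ties go to the
#' lower-indexed particle). Blobs farther than `max_gap_px` from every
#' particle are reported as unbound.
#'
#' @param particles,blobs [instance_set()] objects on the same grid.
#' @param max_gap_px maximum gap in pixels (default 2).
#' @return A tibble of class `label_counts` with one row per particle:
#'   `particle_id`, `n_densities`, `positive` (`n_densities >= 1`).
#'   Attributes: `unbound` (indices of unassigned blobs) and
#'   `assignment` (per-blob particle id, `NA` for unbound).
#' @export
attach_densities <- function(particles, blobs, max_gap_px = 2) {
  stopifnot(inherits(particles, "instance_set"), inherits(blobs, "instance_set"))
  abort_if(!identical(particles$dim, blobs$dim),
           "particle and blob masks must share one grid")
  np <- length(particles$masks)
  nr <- particles$dim[1]
  pb <- lapply(particles$masks, mask_bbox, nr = nr)
  assignment <- rep(NA_integer_, length(blobs$masks))
  for (b in seq_along(blobs$masks)) {
    bb <- mask_bbox(blobs$masks[[b]], nr)
    best <- NA_integer_; best_d <- Inf
    for (p in seq_len(np)) {
      if (!bboxes_within(pb[[p]], bb, ceiling(max_gap_px) + 1L)) next
      d <- mask_min_dist(blobs$masks[[b]], particles$masks[[p]],
                         particles$dim, metric = "euclidean")
      if (d <= max_gap_px && d < best_d) {
        best <- p; best_d <- d
      }
    }
    assignment[b] <- best
  }
  counts <- tabulate(assignment[!is.na(assignment)], nbins = np)
  out <- tibble::tibble(particle_id = seq_len(np),
                        n_densities = counts,
                        positive = counts >= 1L)
  attr(out, "unbound") <- which(is.na(assignment))
  attr(out, "assignment") <- assignment
  class(out) <- c("label_counts", class(out))
  out
}

#' Percentage of labelled particles
#'
#' @param counts a `label_counts` tibble from [attach_densities()], or any
#'   data frame with a logical `positive` column.
#' @return percent of particles with at least one attached density.
#' @export
labelling_fraction <- function(counts) {
  abort_if(nrow(counts) == 0, "no particles")
  100 * mean(counts$positive)
}

#' Labelled fraction versus antibody concentration, with plateau detection
#'
#' Binding saturates when the labelled fraction stabilises with
#' increasing antibody concentration. Scanning from the highest
#' concentration downward, the plateau is the longest suffix of points
#' whose pairwise differences all stay within `tol` percentage points;
#' the plateau estimate is the mean labelled fraction over that suffix.
#' A suffix of fewer than 2 points means no stabilisation was reached.
#'
#' @param concentrations antibody concentrations (any monotone units);
#'   at least 3.
#' @param fractions labelled fractions in percent, aligned with
#'   `concentrations`.
#' @param tol plateau tolerance in percentage points (default 2).
#' @return A tibble of class `saturation_curve` (`concentration`,
#'   `fraction`, `in_plateau`) with attributes `plateau` (mean percent,
#'   `NA` if none), `plateau_n` and `has_plateau`.
#' @export
saturation_curve <- function(concentrations, fractions, tol = 2) {
  abort_if(length(concentrations) < 3, "need at least 3 concentrations")
  abort_if(length(concentrations) != length(fractions),
           "inputs must be aligned")
  ord <- order(concentrations)
  conc <- concentrations[ord]; frac <- fractions[ord]
  n <- length(frac)
  start <- n
  for (k in seq.int(n - 1L, 1L)) {
    cand <- frac[k:n]
    if (max(cand) - min(cand) <= tol) start <- k else break
  }
  in_plateau <- seq_len(n) >= start & (n - start + 1L) >= 2L
  has <- any(in_plateau)
  out <- tibble::tibble(concentration = conc, fraction = frac,
                        in_plateau = in_plateau)
  attr(out, "plateau") <- if (has) mean(frac[in_plateau]) else NA_real_
  attr(out, "plateau_n") <- sum(in_plateau)
  attr(out, "has_plateau") <- has
  class(out) <- c("saturation_curve", class(out))
  out
}

#' Percent antibody-positive particles per size bin
#'
#' Bins particle sizes into half-open `[lower, lower + bin_width)` nm
#' bins and reports the percent positive in each occupied bin together
#' with the bin count (empty bins are simply absent; a bin's percent is
#' undefined without members).
#'
#' @param sizes particle sizes in nm.
#' @param positives logical vector aligned with `sizes`.
#' @param bin_width bin width in nm (default 2).
#' @return tibble with `bin_lower`, `n`, `n_positive`, `pct_positive`.
#' @export
positive_fraction_by_bin <- function(sizes, positives, bin_width = 2) {
  abort_if(length(sizes) != length(positives), "inputs must be aligned")
  tibble::tibble(bin_lower = floor(sizes / bin_width) * bin_width,
                 positive = as.logical(positives)) |>
    dplyr::group_by(.data$bin_lower) |>
    dplyr::summarise(n = dplyr::n(),
                     n_positive = sum(.data$positive),
                     pct_positive = 100 * mean(.data$positive),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin_lower)
}

# Minimal union-find used to group touching masks into aggregates.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

#' Census of particle aggregates
#'
#' Groups particles into events: connected components of the "touching"
#' relation, where two masks touch when their minimum Chebyshev distance
#' is at most `touch_gap_px` (so at the default of 1, 8-neighbouring
#' pixels count as touching and overlapping masks always do). Each event
#' — a single particle or an aggregate — is categorised by its number of
#' component particles, collapsed to \{1, 2, 3, >=4\}.
#'
#' @param instances an [instance_set()].
#' @param touch_gap_px touching tolerance in pixels (default 1).
#' @return An object of class `aggregate_census`: list with `counts`
#'   (named vector over categories `1`, `2`, `3`, `>=4`), `sizes` (the
#'   full vector of component sizes) and `n_events`.
#' @export
aggregate_census <- function(instances, touch_gap_px = 1) {
  stopifnot(inherits(instances, "instance_set"))
  n <- length(instances$masks)
  parent <- uf_new(max(n, 1L))
  if (n > 1) {
    nr <- instances$dim[1]
    bb <- lapply(instances$masks, mask_bbox, nr = nr)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (!bboxes_within(bb[[i]], bb[[j]], touch_gap_px)) next
        d <- mask_min_dist(instances$masks[[i]], instances$masks[[j]],
                           instances$dim, metric = "chebyshev")
        if (d <= touch_gap_px) parent <- uf_union(parent, i, j)
      }
    }
  }
  roots <- if (n == 0) integer(0) else
    vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  sizes <- as.integer(table(roots))
  census_from_sizes(sizes)
}

#' Build an aggregate census from recorded component sizes
#'
#' @param sizes integer vector, one entry per event giving its number of
#'   component particles.
#' @return An `aggregate_census`.
#' @export
census_from_sizes <- function(sizes) {
  sizes <- as.integer(sizes)
  abort_if(any(sizes < 1), "component sizes must be >= 1")
  counts <- c(`1` = sum(sizes == 1L), `2` = sum(sizes == 2L),
              `3` = sum(sizes == 3L), `>=4` = sum(sizes >= 4L))
  structure(list(counts = counts, sizes = sizes,
                 n_events = length(sizes)),
            class = "aggregate_census")
}

#' @export
print.aggregate_census <- function(x, ...) {
  cat(sprintf("<aggregate_census: %d events | 1:%d 2:%d 3:%d >=4:%d>\n",
              x$n_events, x$counts[1], x$counts[2], x$counts[3], x$counts[4]))
  invisible(x)
}

#' Chi-square comparison of two aggregate censuses
#'
#' Pearson chi-square on the 2 x 4 contingency table of event counts by
#' category \{1, 2, 3, >=4\}, expected counts from the marginals (df = 3
#' when all four categories have nonzero expectation). Categories with
#' zero expected count are pooled before testing — `>=4` merges into `3`
#' first, then `3` into `2` — with the degrees of freedom reduced
#' accordingly.
#'
#' @param a,b `aggregate_census` objects with at least one event each.
#' @return A list of class `census_chisq`: `statistic`, `df`, `p_value`,
#'   and the (possibly pooled) `table`.
#' @export
chi_square_census <- function(a, b) {
  stopifnot(inherits(a, "aggregate_census"), inherits(b, "aggregate_census"))
  abort_if(a$n_events == 0 || b$n_events == 0,
           "both censuses need at least one event")
  tab <- rbind(a = a$counts, b = b$counts)
  repeat {
    zero <- which(colSums(tab) == 0)
    if (length(zero) == 0 || ncol(tab) <= 1) break
    # pool the highest zero-expectation category into its left neighbour
    k <- max(zero)
    k <- if (k == 1) 2L else k
    tab[, k - 1L] <- tab[, k - 1L] + tab[, k]
    tab <- tab[, -k, drop = FALSE]
  }
  if (ncol(tab) == 1) {
    return(structure(list(statistic = 0, df = 0L, p_value = NA_real_,
                          table = tab),
                     class = "census_chisq"))
  }
  suppressWarnings(res <- stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 table = tab),
            class = "census_chisq")
}

#' @export
print.census_chisq <- function(x, ...) {
  cat(sprintf("<census_chisq: chi^2 = %.4g, df = %d, p = %.3g>\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

census_small_share <- function(census, weighting) {
  if (weighting == "particle") {
    w <- census$sizes
    # when only category counts are known, >=4 events contribute 4 particles
    sum(w[w <= 3L]) / sum(w)
  } else {
    sum(census$counts[c("1", "2", "3")]) / census$n_events
  }
}

#' Redistribution of particles into larger aggregates
#'
#' Quantifies antibody-induced aggregation as the decrease, in
#' percentage points, of the share of particles found as singles or in
#' the smallest aggregates (2 and 3 particles) between two censuses.
#' Shares are particle-weighted: a category-k event contributes k
#' particles (events of `>=4` use their recorded component sizes). The
#' event-weighted share is also computed and returned as an attribute,
#' since the choice of weighting is an interpretation.
#'
#' @param before,after `aggregate_census` objects.
#' @return numeric percentage points (particle-weighted), with attribute
#'   `event_weighted`.
#' @export
redistribution_percent <- function(before, after) {
  stopifnot(inherits(before, "aggregate_census"),
            inherits(after, "aggregate_census"))
  abort_if(before$n_events == 0 || after$n_events == 0, "empty census")
  out <- 100 * (census_small_share(before, "particle") -
                  census_small_share(after, "particle"))
  attr(out, "event_weighted") <-
    100 * (census_small_share(before, "event") -
             census_small_share(after, "event"))
  out
}

#' Compare particle size distributions between groups
#'
#' Kruskal-Wallis rank test (tie-corrected H) across all groups plus
#' pairwise two-sample Kolmogorov-Smirnov statistics.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list with `kruskal` (tibble: `H`, `df`, `p_value`) and
#'   `pairwise_ks` (tibble: `group1`, `group2`, `D`, `p_value`).
#' @export
compare_size_distributions <- function(groups) {
  abort_if(length(groups) < 2, "need at least 2 groups")
  abort_if(any(vapply(groups, length, 1L) < 2), "each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  ks <- purrr::map_dfr(pairs, function(p) {
    suppressWarnings(r <- stats::ks.test(groups[[p[1]]], groups[[p[2]]]))
    tibble::tibble(group1 = p[1], group2 = p[2],
                   D = unname(r$statistic), p_value = r$p.value)
  })
  list(kruskal = tibble::tibble(H = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p_value = kw$p.value),
       pairwise_ks = ks)
}
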