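#' Match predicted instances to ground truth at an IoU threshold
#'
#' One-to-one greedy matching: candidate (prediction, truth) pairs with
#' IoU at or above the threshold are visited in descending IoU order
#' (ties broken by higher prediction score, then lower prediction index,
#' then lower truth index) and accepted when both members are still
#' unmatched.
#'
#' @param pred,truth [instance_set()] objects on the same grid.
#' @param iou_threshold minimum IoU for a valid pair (default 0.5).
#' @return A list of class `match_result`: `pairs` (tibble `pred_id`,
#'   `truth_id`, `iou`), `unmatched_pred`, `unmatched_truth`, `n_pred`,
#'   `n_truth`.
#' @export
match_instances <- function(pred, truth, iou_threshold = 0.5) {
  stopifnot(inherits(pred, "instance_set"), inherits(truth, "instance_set"))
  abort_if(!identical(pred$dim, truth$dim), "mask grids differ")
  iou <- iou_matrix(pred, truth)
  cand <- which(iou >= iou_threshold, arr.ind = TRUE)
  scores <- pred$scores %||% rep(0, length(pred$masks))
  pairs <- tibble::tibble(pred_id = integer(0), truth_id = integer(0),
                          iou = numeric(0))
  if (nrow(cand) > 0) {
    ord <- order(-iou[cand], -scores[cand[, 1]], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    used_p <- logical(length(pred$masks))
    used_t <- logical(length(truth$masks))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE; keep[k] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    pairs <- tibble::tibble(pred_id = as.integer(cand[, 1]),
                            truth_id = as.integer(cand[, 2]),
                            iou = iou[cand])
  }
  structure(list(pairs = pairs,
                 unmatched_pred = setdiff(seq_along(pred$masks), pairs$pred_id),
                 unmatched_truth = setdiff(seq_along(truth$masks), pairs$truth_id),
                 n_pred = length(pred$masks),
                 n_truth = length(truth$masks)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d/%d truths matched, %d/%d predictions used>\n",
              nrow(x$pairs), x$n_truth, nrow(x$pairs), x$n_pred))
  invisible(x)
}

#' Detection rate and false detections per 100
#'
#' `detection_rate` is the percentage of ground-truth particles matched
#' by a prediction; `false_per_100` is the number of unmatched
#' predictions per 100 detections (predictions). Either statistic is
#' `NaN` when its denominator is zero.
#'
#' @param match a `match_result` from [match_instances()].
#' @return tibble with `detection_rate`, `false_per_100`, `n_truth`,
#'   `n_pred`, `n_matched`.
#' @export
detection_stats <- function(match) {
  stopifnot(inherits(match, "match_result"))
  n_matched <- nrow(match$pairs)
  tibble::tibble(
    detection_rate = if (match$n_truth == 0) NaN else
      100 * n_matched / match$n_truth,
    false_per_100 = if (match$n_pred == 0) NaN else
      100 * length(match$unmatched_pred) / match$n_pred,
    n_truth = match$n_truth, n_pred = match$n_pred, n_matched = n_matched)
}

# Average precision by all-point interpolation: area under the precision
# envelope of the PR curve traced by sweeping predictions in descending
# score order with greedy best-IoU matching (COCO convention).
ap_at_threshold <- function(pred, truth, iou, threshold) {
  nt <- ncol(iou)
  np <- nrow(iou)
  if (np == 0) return(0)
  ord <- order(-(pred$scores), seq_len(np))
  used_t <- logical(nt)
  tp <- logical(np)
  for (r in seq_len(np)) {
    i <- ord[r]
    cand <- which(!used_t & iou[i, ] >= threshold)
    if (length(cand) > 0) {
      j <- cand[which.max(iou[i, cand])]
      used_t[j] <- TRUE
      tp[r] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_len(np)
  recall <- cum_tp / nt
  # precision envelope (non-increasing from the right)
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Mean average precision over IoU 0.50-0.95
#'
#' COCO-style mAP: for each IoU threshold in `0.50, 0.55, ..., 0.95` an
#' average precision is computed by sweeping scored predictions in
#' descending confidence with greedy matching, interpolating the
#' precision-recall curve by its envelope (all-point interpolation); the
#' reported value aggregates the ten APs. The default aggregate is the
#' mean; `aggregate = "median"` is available since "median average
#' precision" is also in circulation for this metric.
#'
#' @param pred a scored [instance_set()].
#' @param truth an [instance_set()]; must be non-empty.
#' @param thresholds IoU thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return mAP in \[0, 1\], with attribute `ap_by_threshold`.
#' @export
mean_ap <- function(pred, truth, thresholds = seq(0.5, 0.95, by = 0.05),
                    aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(pred, "instance_set"), inherits(truth, "instance_set"))
  abort_if(length(truth$masks) == 0, "mAP undefined without ground truth")
  if (length(pred$masks) == 0) {
    out <- 0
    attr(out, "ap_by_threshold") <- stats::setNames(rep(0, length(thresholds)),
                                                    thresholds)
    return(out)
  }
  abort_if(is.null(pred$scores), "predictions must carry scores")
  iou <- iou_matrix(pred, truth)
  aps <- vapply(thresholds, function(t) ap_at_threshold(pred, truth, iou, t),
                1.0)
  out <- if (aggregate == "mean") mean(aps) else stats::median(aps)
  attr(out, "ap_by_threshold") <- stats::setNames(aps, thresholds)
  out
}

#' Bland-Altman agreement between two size series
#'
#' Differences are `a - b`; bias is their mean and the limits of
#' agreement are `bias +/- 1.96 * SD` of the differences (sample SD).
#'
#' @param sizes_a,sizes_b paired numeric vectors (n >= 2).
#' @return A list of class `bland_altman`: `bias`, `lower`, `upper`,
#'   `sd_diff`, and `points` (tibble `mean`, `difference`).
#' @export
bland_altman <- function(sizes_a, sizes_b) {
  abort_if(length(sizes_a) != length(sizes_b), "series must be paired")
  abort_if(length(sizes_a) < 2, "need at least 2 pairs")
  d <- sizes_a - sizes_b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 lower = bias - 1.96 * s, upper = bias + 1.96 * s,
                 points = tibble::tibble(mean = (sizes_a + sizes_b) / 2,
                                         difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman: bias %.4g, limits [%.4g, %.4g], n = %d>\n",
              x$bias, x$lower, x$upper, nrow(x$points)))
  invisible(x)
}

#' Count touching or overlapping particle pairs
#'
#' A simple aggregation measure: the number of unordered instance pairs
#' whose masks intersect after each mask is dilated by `dilate_px`
#' pixels (square 8-connected structuring element). With `dilate_px = 0`
#' only genuinely intersecting masks count; the count is monotone
#' non-decreasing in `dilate_px`.
#'
#' @param instances an [instance_set()].
#' @param dilate_px dilation radius in pixels (default 1).
#' @return integer pair count.
#' @export
overlapping_pairs <- function(instances, dilate_px = 1) {
  stopifnot(inherits(instances, "instance_set"))
  n <- length(instances$masks)
  if (n < 2) return(0L)
  nr <- instances$dim[1]
  dil <- lapply(instances$masks, mask_dilate_idx, dims = instances$dim,
                r = dilate_px)
  bb <- lapply(dil, mask_bbox, nr = nr)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (!bboxes_within(bb[[i]], bb[[j]], 0L)) next
      if (length(intersect(dil[[i]], dil[[j]])) > 0) count <- count + 1L
    }
  }
  count
}

#' Full segmentation evaluation report
#'
#' Applies the central-window 50%-area rule to predictions and ground
#' truth alike, then reports detection rate, false detections per 100,
#' mAP over IoU 0.50-0.95, overlapping-pair counts for both sets (after
#' 1-px dilation), and Bland-Altman agreement of matched particle sizes
#' (sqrt-area linear size, in pixels).
#'
#' @param pred scored predicted [instance_set()].
#' @param truth ground-truth [instance_set()].
#' @param window optional [window()]; `NULL` evaluates the full frame.
#' @param min_area_frac window containment rule (default 0.5).
#' @param iou_threshold matching threshold for detection statistics.
#' @return A list of class `seg_eval_report`: `stats` (one-row tibble),
#'   `match`, `bland_altman` (or `NULL` when fewer than 2 matches).
#' @export
evaluate_segmentation <- function(pred, truth, window = NULL,
                                  min_area_frac = 0.5, iou_threshold = 0.5) {
  if (!is.null(window)) {
    pred <- window_filter(pred, window, min_area_frac)
    truth <- window_filter(truth, window, min_area_frac)
  }
  match <- match_instances(pred, truth, iou_threshold)
  det <- detection_stats(match)
  map <- if (length(truth$masks) == 0) NaN else
    as.numeric(mean_ap(pred, truth))
  ba <- NULL
  if (nrow(match$pairs) >= 2) {
    pa <- instance_areas(pred)[match$pairs$pred_id]
    ta <- instance_areas(truth)[match$pairs$truth_id]
    ba <- bland_altman(linear_size_from_area(pa), linear_size_from_area(ta))
  }
  stats <- dplyr::mutate(det,
    map = map,
    overlapping_pairs_pred = overlapping_pairs(pred),
    overlapping_pairs_truth = overlapping_pairs(truth))
  structure(list(stats = stats, match = match, bland_altman = ba),
            class = "seg_eval_report")
}

#' @export
print.seg_eval_report <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0(
    "<seg_eval_report: detection rate %.1f%%, false/100 %.2f, mAP %.3f,\n",
    "  pairs pred/truth %d/%d, n_pred %d, n_truth %d>\n"),
    s$detection_rate, s$false_per_100, s$map,
    s$overlapping_pairs_pred, s$overlapping_pairs_truth, s$n_pred, s$n_truth))
  invisible(x)
}
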