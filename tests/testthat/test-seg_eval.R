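test_that("identical sets match perfectly and disjoint sets not at all", {
  set.seed(3)
  iset <- random_disc_set(4)
  m <- match_instances(iset, iset, 0.5)
  expect_equal(nrow(m$pairs), 4)
  expect_true(all(m$pairs$iou == 1))
  far_a <- instance_set(list(disc_mask(50, 50, 10, 10, 4)))
  far_b <- instance_set(list(disc_mask(50, 50, 40, 40, 4)))
  m2 <- match_instances(far_a, far_b, 0.5)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_pred, 1L)
  expect_equal(m2$unmatched_truth, 1L)
})

test_that("greedy matching equals the optimal assignment on small scenes", {
  set.seed(14)
  for (rep in 1:15) {
    pred <- random_disc_set(sample(2:5, 1), nr = 40, nc = 40,
                            r_range = c(4, 7), scores = TRUE)
    truth <- random_disc_set(sample(2:5, 1), nr = 40, nc = 40,
                             r_range = c(4, 7))
    got <- nrow(match_instances(pred, truth, 0.5)$pairs)
    expect_equal(got, optimal_match_count(pred, truth, 0.5))
  }
})

test_that("detection statistics are the stated ratios", {
  fake_match <- function(n_truth, n_pred, n_matched) {
    structure(list(pairs = tibble::tibble(pred_id = seq_len(n_matched),
                                          truth_id = seq_len(n_matched),
                                          iou = rep(1, n_matched)),
                   unmatched_pred = seq.int(n_matched + 1,
                                            length.out = max(0, n_pred - n_matched)),
                   unmatched_truth = seq.int(n_matched + 1,
                                             length.out = max(0, n_truth - n_matched)),
                   n_pred = n_pred, n_truth = n_truth),
              class = "match_result")
  }
  s <- detection_stats(fake_match(100, 90, 84))
  expect_equal(s$detection_rate, 84)
  expect_equal(detection_stats(fake_match(12, 13, 12))$false_per_100,
               100 * 1 / 13)
  expect_equal(detection_stats(fake_match(5, 5, 5))$false_per_100, 0)
  # identity: detection_rate + missed rate = 100
  m <- fake_match(40, 35, 31)
  s2 <- detection_stats(m)
  expect_equal(s2$detection_rate + 100 * length(m$unmatched_truth) / m$n_truth,
               100)
  # undefined denominators give NaN
  expect_true(is.nan(detection_stats(fake_match(0, 3, 0))$detection_rate))
})

test_that("mAP is 1 for perfect predictions and 0 for none", {
  set.seed(5)
  truth <- random_disc_set(4)
  perfect <- instance_set(lapply(truth$masks, identity), dim = truth$dim,
                          scores = c(0.9, 0.2, 0.5, 0.7),
                          source = "prediction")
  expect_equal(as.numeric(mean_ap(perfect, truth)), 1)
  none <- instance_set(list(), dim = truth$dim, scores = numeric(0),
                       source = "prediction")
  expect_equal(as.numeric(mean_ap(none, truth)), 0)
  expect_error(mean_ap(perfect, none), "ground truth")
})

test_that("mAP reproduces a hand-enumerated precision-recall curve", {
  nr <- 60; nc <- 60
  t1 <- disc_mask(nr, nc, 15, 15, 6)
  t2 <- disc_mask(nr, nc, 15, 45, 6)
  t3 <- disc_mask(nr, nc, 45, 15, 6)
  truth <- instance_set(list(t1, t2, t3))
  # p1 hits t1 (score .9), p2 is a false positive (.8), p3 hits t2 (.6)
  pred <- instance_set(list(t1, disc_mask(nr, nc, 45, 45, 6), t2),
                       scores = c(0.9, 0.8, 0.6), source = "prediction")
  # sweep order: TP, FP, TP -> precision 1, 1/2, 2/3; recall 1/3, 1/3, 2/3
  # envelope: AP = 1/3 * 1 + 1/3 * 2/3 = 5/9 at every threshold
  got <- mean_ap(pred, truth)
  expect_equal(as.numeric(got), 5 / 9, tolerance = 1e-12)
  expect_equal(unname(attr(got, "ap_by_threshold")), rep(5 / 9, 10))
  # median aggregate agrees here
  expect_equal(as.numeric(mean_ap(pred, truth, aggregate = "median")), 5 / 9)
})

test_that("mAP is invariant to monotone score rescaling", {
  set.seed(31)
  truth <- random_disc_set(5)
  pred <- random_disc_set(6, scores = TRUE)
  a <- as.numeric(mean_ap(pred, truth))
  resc <- pred
  resc$scores <- pred$scores^3 / 2        # strictly monotone
  expect_equal(as.numeric(mean_ap(resc, truth)), a)
})

test_that("low-scored false positives do not change the envelope", {
  set.seed(6)
  truth <- random_disc_set(3, r_range = c(5, 6))
  perfect <- instance_set(truth$masks, dim = truth$dim,
                          scores = c(0.9, 0.8, 0.7), source = "prediction")
  with_fp <- instance_set(c(truth$masks, list(which(disc_mask(60, 60, 52, 52, 4)))),
                          dim = truth$dim, scores = c(0.9, 0.8, 0.7, 0.1),
                          source = "prediction")
  expect_equal(as.numeric(mean_ap(with_fp, truth)), 1)
  # a high-scored false positive does reduce mAP
  fp_first <- instance_set(c(truth$masks, list(which(disc_mask(60, 60, 52, 52, 4)))),
                           dim = truth$dim, scores = c(0.8, 0.7, 0.6, 0.95),
                           source = "prediction")
  expect_lt(as.numeric(mean_ap(fp_first, truth)), 1)
})

test_that("Bland-Altman reproduces the direct formulas", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$lower, 0)
  expect_equal(ba$upper, 0)
  off <- bland_altman(c(3, 5, 9), c(1, 3, 7))
  expect_equal(off$bias, 2)
  expect_equal(off$upper - off$lower, 0)
  set.seed(12)
  a <- rnorm(40, 40, 6); b <- a + rnorm(40, -0.8, 1.4)
  ba2 <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba2$bias, mean(d), tolerance = 1e-9)
  expect_equal(ba2$lower, mean(d) - 1.96 * sd(d), tolerance = 1e-9)
  expect_equal(ba2$upper, mean(d) + 1.96 * sd(d), tolerance = 1e-9)
  expect_true(ba2$lower <= ba2$bias && ba2$bias <= ba2$upper)
  expect_error(bland_altman(1:3, 1:4), "paired")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("overlapping pairs counts dilated intersections", {
  nr <- 50; nc <- 50
  # 1-px gap: dilation by 1 on each side closes it
  gap1 <- instance_set(list(disc_mask(nr, nc, 25, 15, 5),
                            disc_mask(nr, nc, 25, 27, 5)))
  expect_equal(overlapping_pairs(gap1, 1), 1L)
  expect_equal(overlapping_pairs(gap1, 0), 0L)
  # >= 3 px of background stays apart
  gap3 <- instance_set(list(disc_mask(nr, nc, 25, 15, 5),
                            disc_mask(nr, nc, 25, 30, 5)))
  expect_equal(overlapping_pairs(gap3, 1), 0L)
  # monotone in the dilation radius
  expect_gte(overlapping_pairs(gap3, 3), overlapping_pairs(gap3, 1))
  set.seed(19)
  for (rep in 1:10) {
    iset <- random_disc_set(sample(3:8, 1), nr = 64, nc = 64)
    for (d in 0:2) {
      expect_equal(overlapping_pairs(iset, d), dilated_overlap_oracle(iset, d))
    }
  }
})

test_that("evaluation applies the window rule to predictions and truths", {
  nr <- 100; nc <- 100
  w <- window(20, 20, 80, 80)
  inside_t <- disc_mask(nr, nc, 50, 50, 8)
  straddle_t <- disc_mask(nr, nc, 50, 21, 8)   # just over half in -> kept
  outside_t <- disc_mask(nr, nc, 50, 6, 8)
  truth <- instance_set(list(inside_t, straddle_t, outside_t))
  pred <- instance_set(list(inside_t, outside_t),
                       scores = c(0.9, 0.8), source = "prediction")
  rep <- evaluate_segmentation(pred, truth, window = w)
  expect_equal(rep$stats$n_truth, 2)   # outside truth dropped
  expect_equal(rep$stats$n_pred, 1)    # outside prediction dropped
  expect_equal(rep$stats$detection_rate, 50)
  expect_equal(rep$stats$false_per_100, 0)
  expect_named(glance(rep),
               c("detection_rate", "false_per_100", "n_truth", "n_pred",
                 "n_matched", "map", "overlapping_pairs_pred",
                 "overlapping_pairs_truth"))
})
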