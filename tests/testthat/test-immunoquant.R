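test_that("blobs attach to the nearest particle within the gap", {
  nr <- 80; nc <- 80
  particles <- instance_set(list(disc_mask(nr, nc, 20, 20, 8),
                                 disc_mask(nr, nc, 60, 60, 8)))
  blobs <- instance_set(list(
    disc_mask(nr, nc, 20, 29, 4),   # overlaps particle 1
    disc_mask(nr, nc, 60, 74, 4),   # 2 px from particle 2's edge
    disc_mask(nr, nc, 40, 5, 4)))   # far from everything
  lc <- attach_densities(particles, blobs, max_gap_px = 2)
  expect_equal(lc$n_densities, c(1L, 1L))
  expect_equal(lc$positive, c(TRUE, TRUE))
  expect_equal(attr(lc, "unbound"), 3L)
  expect_equal(attr(lc, "assignment"), c(1L, 2L, NA_integer_))
  # a tighter gap strands the near-miss blob
  lc0 <- attach_densities(particles, blobs, max_gap_px = 0)
  expect_equal(lc0$n_densities, c(1L, 0L))
  expect_equal(attr(lc0, "unbound"), c(2L, 3L))
})

test_that("simulated blob assignments are recovered exactly", {
  sc <- simulate_micrograph(scene_params(
    n_particles = 80, img_shape = c(1000L, 1000L), labelled_fraction = 0.4,
    blobs_per_labelled = 1.5, aggregate_fraction = 0, seed = 77))
  lc <- attach_densities(truth_to_instances(sc$truth), sc$truth$blobs)
  expect_equal(lc$n_densities, sc$truth$particles$n_blobs)
  expect_length(attr(lc, "unbound"), 0)
  expect_equal(labelling_fraction(lc),
               100 * mean(sc$truth$particles$labelled))
})

test_that("labelling fraction is the percentage of positive particles", {
  all_pos <- tibble::tibble(positive = rep(TRUE, 7))
  expect_equal(labelling_fraction(all_pos), 100)
  expect_equal(labelling_fraction(tibble::tibble(positive = rep(FALSE, 5))), 0)
  expect_equal(labelling_fraction(tibble::tibble(positive = c(TRUE, FALSE))), 50)
  expect_error(labelling_fraction(tibble::tibble(positive = logical(0))),
               "no particles")
})

test_that("saturation curves find the stabilised suffix", {
  sat <- saturation_curve(1:5, c(10, 30, 36, 37, 36.5))
  expect_true(attr(sat, "has_plateau"))
  expect_equal(attr(sat, "plateau_n"), 3)
  expect_gte(attr(sat, "plateau"), 36)
  expect_lte(attr(sat, "plateau"), 37)
  # constant curve: the plateau is that constant
  flat <- saturation_curve(1:4, rep(22, 4))
  expect_equal(attr(flat, "plateau"), 22)
  expect_equal(attr(flat, "plateau_n"), 4)
  # strictly increasing with no stabilisation
  rising <- saturation_curve(1:4, c(5, 20, 40, 70))
  expect_false(attr(rising, "has_plateau"))
  expect_true(is.na(attr(rising, "plateau")))
  expect_error(saturation_curve(1:2, c(1, 2)), "at least 3")
})

test_that("per-bin positive fractions cover occupied bins only", {
  sizes <- c(14.5, 15.9, 20.1, 21.0, 27.3)
  tab <- positive_fraction_by_bin(sizes, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(tab$bin_lower, c(14, 20, 26))
  expect_equal(tab$n, c(2L, 2L, 1L))
  expect_equal(tab$pct_positive, c(100, 50, 0))
  all_pos <- positive_fraction_by_bin(sizes, rep(TRUE, 5))
  expect_true(all(all_pos$pct_positive == 100))
  none <- positive_fraction_by_bin(sizes, rep(FALSE, 5))
  expect_true(all(none$pct_positive == 0))
})

test_that("aggregate censuses categorise touching chains", {
  nr <- 120; nc <- 120
  singles <- lapply(seq(10, 90, by = 20),
                    function(x) disc_mask(nr, nc, 15, x, 5))
  expect_equal(unname(aggregate_census(instance_set(singles))$counts),
               c(5L, 0L, 0L, 0L))
  # one chain of 6 touching discs -> a single >=4 event
  chain <- lapply(seq(20, 20 + 5 * 9, by = 9),
                  function(x) disc_mask(nr, nc, 60, x, 5))
  cen <- aggregate_census(instance_set(chain))
  expect_equal(unname(cen$counts), c(0L, 0L, 0L, 1L))
  expect_equal(cen$sizes, 6L)
  # adjacent pixels (Chebyshev distance 1) touch at the default
  # tolerance; one background pixel between masks breaks the contact
  pair_adjacent <- instance_set(list(disc_mask(nr, nc, 100, 30, 5),
                                     disc_mask(nr, nc, 100, 41, 5)))
  expect_equal(unname(aggregate_census(pair_adjacent)$counts[2]), 1L)
  pair_gap <- instance_set(list(disc_mask(nr, nc, 100, 30, 5),
                                disc_mask(nr, nc, 100, 42, 5)))
  expect_equal(unname(aggregate_census(pair_gap)$counts[1]), 2L)
})

test_that("the census equals a union-find oracle on random scenes", {
  set.seed(21)
  for (rep in 1:12) {
    iset <- random_disc_set(sample(4:9, 1), nr = 70, nc = 70)
    cen <- aggregate_census(iset)
    expect_equal(sort(cen$sizes), census_oracle(iset))
  }
})

test_that("census chi-square matches the textbook statistic", {
  a <- census_from_sizes(c(rep(1, 40), rep(2, 12), rep(3, 5), rep(5, 3)))
  b <- census_from_sizes(c(rep(1, 10), rep(2, 8), rep(3, 9), rep(4, 20)))
  res <- chi_square_census(a, b)
  expect_equal(res$df, 3L)
  tab <- rbind(a$counts, b$counts)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-9)
  # symmetry in the two censuses
  expect_equal(chi_square_census(b, a)$statistic, res$statistic)
  # identical censuses give exactly zero
  expect_equal(chi_square_census(a, a)$statistic, 0)
  # random tables against the same formula
  set.seed(8)
  for (i in 1:10) {
    s1 <- census_from_sizes(sample(1:5, 40, replace = TRUE))
    s2 <- census_from_sizes(sample(1:5, 55, replace = TRUE))
    t2 <- rbind(s1$counts, s2$counts)
    e2 <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    expect_equal(chi_square_census(s1, s2)$statistic,
                 sum((t2 - e2)^2 / e2), tolerance = 1e-9)
  }
})

test_that("empty census categories are pooled with reduced df", {
  a <- census_from_sizes(c(1, 1, 1, 2, 2))       # no 3s, no >=4s
  b <- census_from_sizes(c(1, 1, 2, 2, 2))
  res <- chi_square_census(a, b)
  expect_equal(res$df, 1L)
  expect_equal(ncol(res$table), 2)
  # all-singles censuses collapse entirely: zero statistic, zero df
  s <- chi_square_census(census_from_sizes(rep(1, 9)),
                         census_from_sizes(rep(1, 4)))
  expect_equal(s$statistic, 0)
  expect_equal(s$df, 0L)
})

test_that("redistribution percent is the drop in the small-category share", {
  a <- census_from_sizes(c(rep(1, 50), rep(2, 10), rep(3, 4)))
  expect_equal(redistribution_percent(a, a), 0, ignore_attr = TRUE)
  # everything moves from singles into large aggregates
  before <- census_from_sizes(rep(1, 40))
  after <- census_from_sizes(rep(5, 8))
  expect_equal(redistribution_percent(before, after), 100,
               ignore_attr = TRUE)
  # hand-computed mixed case (particle weighting)
  b1 <- census_from_sizes(c(1, 1, 1, 1, 2, 2, 4))       # 12 particles, 8 small
  b2 <- census_from_sizes(c(1, 2, 3, 6))                # 12 particles, 6 small
  got <- redistribution_percent(b1, b2)
  expect_equal(as.numeric(got), 100 * (8 / 12 - 6 / 12))
  # event weighting reported alongside
  expect_equal(attr(got, "event_weighted"), 100 * (6 / 7 - 3 / 4))
})

test_that("distribution comparisons match stats oracles", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1.5, 2.5, 3.5, 4.5, 5.5),
            c = c(2, 3, 4, 5, 6))
  res <- compare_size_distributions(g)
  expect_equal(res$kruskal$H, kw_h_oracle(g), tolerance = 1e-9)
  expect_equal(res$kruskal$df, 2)
  expect_equal(nrow(res$pairwise_ks), 3)
  # identical groups: H ~ 0 and D = 0
  same <- compare_size_distributions(list(x = 1:6, y = 1:6))
  expect_equal(same$pairwise_ks$D, 0)
  expect_lt(same$kruskal$H, 1e-9)
  # disjoint supports: D = 1
  disj <- compare_size_distributions(list(lo = 1:5, hi = 11:15))
  expect_equal(disj$pairwise_ks$D, 1)
  expect_error(compare_size_distributions(list(1:3)), "2 groups")
  expect_error(compare_size_distributions(list(1:3, 4)), "n >= 2")
})
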