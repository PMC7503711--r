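test_that("spheroid correction is the mean of the three spheroid axes", {
  model <- spheroid_model()
  # factor with the default LDL reference shape, exactly
  expect_equal(spheroid_equivalent_diameter(1), (2 + 12.1 / 21.4) / 3)
  # linearity: f(aD) = a f(D)
  d <- c(14, 23.41, 40.2, 77)
  expect_equal(spheroid_equivalent_diameter(3.7 * d),
               3.7 * spheroid_equivalent_diameter(d))
  # a sphere needs no correction
  expect_equal(spheroid_equivalent_diameter(24, spheroid_model(20, 20)), 24)
  expect_error(spheroid_equivalent_diameter(-1), "positive")
  expect_error(spheroid_model(10, 12), "exceed")
})

test_that("horizontal calliper is the inclusive column extent in nm", {
  # 41-px-wide axis-aligned ellipse at 0.5 nm/px -> 20.5 nm
  m <- ellipse_mask(60, 60, 30, 30, a = 20.2, b = 12)
  expect_equal(diff(range(which(colSums(m) > 0))) + 1, 41)
  expect_equal(horizontal_calliper(m, 0.5), 20.5)
  # single pixel at 1 nm/px
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(horizontal_calliper(single, 1), 1)
  expect_error(horizontal_calliper(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("calliper of a rotated ellipse matches the analytic projection", {
  a <- 18; b <- 10
  for (theta in c(0, 0.4, 1.0, 1.3)) {
    m <- ellipse_mask(90, 90, 45.3, 45.7, a, b, theta)
    analytic <- 2 * sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
    expect_lt(abs(horizontal_calliper(m, 1) - analytic), 1.01)
  }
})

test_that("moment-equivalent axes recover known shapes", {
  circ <- disc_mask(60, 60, 30, 30, 15)
  ax <- fit_axes(circ, 1)
  expect_equal(unname(ax["ratio"]), 1, tolerance = 0.02)
  ell <- ellipse_mask(100, 100, 50, 50, a = 30, b = 15, theta = 0.7)
  ax2 <- fit_axes(ell, 0.5)
  expect_equal(unname(ax2["ratio"]), 2, tolerance = 0.05)
  expect_equal(unname(ax2["major"]), 30, tolerance = 1)  # 2a * 0.5 nm/px
  # collinear masks are degenerate
  line <- matrix(FALSE, 10, 10); line[5, 2:8] <- TRUE
  expect_error(fit_axes(line, 1), "degenerate")
  tiny <- matrix(FALSE, 5, 5); tiny[2, 2] <- TRUE
  expect_error(fit_axes(tiny, 1), "5 pixels")
})

test_that("linear size is the square root of pixel area", {
  expect_equal(round(linear_size_from_area(c(1632, 13164, 368)), 1),
               c(40.4, 114.7, 19.2))
  expect_equal(linear_size_from_area(0), 0)
  expect_error(linear_size_from_area(-4), "non-negative")
})

test_that("size summaries use sample SD and percent histograms", {
  s <- summarize_sizes(c(23.41, 23.82, 24.00))
  expect_equal(round(s$mean, 2), 23.74)
  expect_equal(s$sd, sd(c(23.41, 23.82, 24.00)))
  # single value: sd and cv are zero
  s1 <- summarize_sizes(42)
  expect_equal(s1$sd, 0)
  expect_equal(s1$cv_percent, 0)
  # histogram invariants on a spread-out sample
  set.seed(11)
  v <- rnorm(500, 24, 3)
  sh <- summarize_sizes(v)
  expect_equal(sum(sh$histogram$rel_freq_pct), 100, tolerance = 1e-9)
  expect_true(all(sh$histogram$bin_lower %% 2 == 0))
  # bins are half-open [lower, lower + 2)
  sb <- summarize_sizes(c(14, 15.999, 16))
  expect_equal(sb$histogram$bin_lower, c(14, 16))
  expect_equal(sb$histogram$count, c(2L, 1L))
  # cv consistency: cv * mean / 100 reproduces sd
  expect_equal(sh$cv_percent * sh$mean / 100, sh$sd, tolerance = 1e-9)
  expect_error(summarize_sizes(numeric(0)), "at least one")
  # broom-style accessors
  expect_named(glance(sh), c("n", "mean_nm", "sd_nm", "cv_percent"))
  expect_equal(tidy(sh), sh$histogram)
})

test_that("edge profiles sample at 1-px steps with nearest-pixel lookup", {
  mg <- micrograph(matrix(77, 32, 32), 0.5)
  pr <- edge_profile(mg, c(2, 10), c(20, 10))
  expect_true(all(pr$intensity == 77))
  expect_equal(nrow(pr), 19)
  expect_equal(pr$position_nm[2] - pr$position_nm[1], 0.5)
  # zero-length segment: a single sample
  expect_equal(nrow(edge_profile(mg, c(5, 5), c(5, 5))), 1)
  expect_error(edge_profile(mg, c(-1, 0), c(5, 5)), "outside")
})

test_that("a profile across a simulated rim shows the dark rim minimum", {
  sc <- simulate_micrograph(scene_params(
    n_particles = 1, img_shape = c(160L, 160L), clutter_density = 0,
    aggregate_fraction = 0, noise_sd = 0, blur_sigma = 0, seed = 3))
  p <- sc$truth$particles
  y <- round(p$center_y)
  pr <- edge_profile(sc$micrograph, c(p$center_x - 30, y),
                     c(p$center_x + 30, y))
  # minimum sits on the rim, below both background and interior grey
  expect_lt(min(pr$intensity), 100)
  expect_gt(pr$intensity[1], 190)
  expect_equal(contrast_range(pr), max(pr$intensity) - min(pr$intensity))
})

test_that("contrast range is max minus min", {
  expect_equal(contrast_range(c(10, 50, 10)), 40)
  expect_equal(contrast_range(rep(7, 5)), 0)
  expect_error(contrast_range(numeric(0)), "empty")
})

test_that("thin films show stronger edge contrast than thick films", {
  ranges <- vapply(c("thin", "thick"), function(mode) {
    sc <- simulate_micrograph(scene_params(
      n_particles = 12, img_shape = c(500L, 500L), film_mode = mode,
      clutter_density = 0, aggregate_fraction = 0, noise_sd = 3, seed = 5))
    p <- sc$truth$particles
    mean(vapply(seq_len(nrow(p)), function(i) {
      y <- round(p$center_y[i])
      contrast_range(edge_profile(sc$micrograph,
                                  c(p$center_x[i] - 28, y),
                                  c(p$center_x[i] + 28, y)))
    }, 1.0))
  }, 1.0)
  expect_gt(ranges["thin"], ranges["thick"])
})

test_that("the SEC trend fit is exact OLS", {
  x <- 5:12
  y <- -1.1122 * x + 33.162
  fit <- sec_trend_fit(data.frame(x, y))
  expect_equal(fit$slope, -1.1122, tolerance = 1e-9)
  expect_equal(fit$intercept, 33.162, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # two points always fit exactly
  expect_equal(sec_trend_fit(data.frame(x = c(1, 2), y = c(3, 7)))$r_squared, 1)
  # closed-form OLS oracle on noisy points
  set.seed(4)
  xs <- runif(20, 0, 10); ys <- 2.5 * xs + rnorm(20)
  f <- sec_trend_fit(data.frame(xs, ys))
  beta <- cov(xs, ys) / var(xs)
  alpha <- mean(ys) - beta * mean(xs)
  r2 <- cor(xs, ys)^2
  expect_equal(f$slope, beta, tolerance = 1e-9)
  expect_equal(f$intercept, alpha, tolerance = 1e-9)
  expect_equal(f$r_squared, r2, tolerance = 1e-9)
  # degenerate inputs
  expect_error(sec_trend_fit(data.frame(x = c(1, 1), y = c(2, 3))),
               "distinct")
  expect_true(is.nan(sec_trend_fit(data.frame(x = 1:4, y = rep(2, 4)))$r_squared))
  expect_named(glance(f), c("slope", "intercept", "r_squared", "n"))
})

test_that("measure_particles returns one consistent row per instance", {
  iset <- instance_set(list(disc_mask(80, 80, 20, 20, 10),
                            ellipse_mask(80, 80, 55, 50, 14, 8, 0.3)))
  tab <- measure_particles(iset, 0.5)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$linear_size_px, sqrt(tab$area_px2))
  expect_true(all(tab$major_nm >= tab$minor_nm))
  expect_true(all(tab$ratio >= 1))
  expect_equal(tab$calliper_nm[1], horizontal_calliper(disc_mask(80, 80, 20, 20, 10), 0.5))
})
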