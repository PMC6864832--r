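gauss_gaze <- function(n, mu = c(0, 0), sigma = c(10, 10), seed = 1) {
  set.seed(seed)
  data.frame(x_gaze = rnorm(n, mu[1], sigma[1]),
             y_gaze = rnorm(n, mu[2], sigma[2]), valid = TRUE)
}

test_that("a point mass lands in a single bin holding all samples", {
  g <- data.frame(x_gaze = rep(7.3, 10), y_gaze = rep(-2.1, 10), valid = TRUE)
  h <- build_histogram(g, bin_width = 5)
  expect_equal(sum(h$counts), 10)
  expect_equal(sum(h$counts > 0), 1)
})

test_that("samples on a bin edge fall into the upper bin", {
  g <- data.frame(x_gaze = c(4.999, 5), y_gaze = c(0, 0), valid = TRUE)
  h <- build_histogram(g, bin_width = 5)
  ix <- floor((g$x_gaze - h$x_edges[1]) / 5) + 1
  expect_equal(ix, c(1, 2))
  expect_equal(rowSums(h$counts), c(1, 1))
})

test_that("binning agrees with a naive per-sample assignment", {
  g <- gauss_gaze(1000, mu = c(3, -4), sigma = c(12, 7), seed = 42)
  bw <- 4
  h <- build_histogram(g, bw)
  naive <- matrix(0L, length(h$x_edges) - 1, length(h$y_edges) - 1)
  for (i in seq_len(nrow(g))) {
    ix <- floor((g$x_gaze[i] - h$x_edges[1]) / bw) + 1
    iy <- floor((g$y_gaze[i] - h$y_edges[1]) / bw) + 1
    naive[ix, iy] <- naive[ix, iy] + 1L
  }
  expect_equal(h$counts, naive)
  expect_equal(sum(h$counts), 1000)
  expect_equal(sum(rowSums(h$counts)), h$n)
  expect_equal(sum(colSums(h$counts)), h$n)
})

test_that("histogram refuses sessions with no valid samples", {
  g <- data.frame(x_gaze = NA_real_, y_gaze = NA_real_, valid = FALSE)
  expect_error(build_histogram(g), class = "gr_empty_session_error")
})

test_that("the Gaussian fit recovers known parameters", {
  g <- gauss_gaze(10000, mu = c(5, -2), sigma = c(10, 6), seed = 7)
  f <- fit_gaussian(g)
  expect_lt(abs(f$mu_x - 5), 0.3)
  expect_lt(abs(f$sigma_x - 10), 0.3)
  expect_lt(abs(f$mu_y + 2), 0.2)
  expect_lt(abs(f$sigma_y - 6), 0.2)
  # 95% interval width is the Gaussian quantile identity 3.92 sigma
  expect_equal(diff(f$ci_x), 2 * qnorm(0.975) * f$sigma_x, tolerance = 1e-12)
})

test_that("mirrored samples have zero mean and degenerate fits error", {
  g <- data.frame(x_gaze = c(-3, 3, -3, 3), y_gaze = c(-1, 1, 1, -1), valid = TRUE)
  f <- fit_gaussian(g)
  expect_equal(f$mu_x, 0)
  expect_equal(f$mu_y, 0)

  g0 <- data.frame(x_gaze = rep(1, 5), y_gaze = rnorm(5), valid = TRUE)
  expect_error(fit_gaussian(g0), class = "gr_degenerate_error")
  expect_error(fit_gaussian(g[1:2, ]), class = "gr_degenerate_error")
})

test_that("a point-mass histogram spans exactly one bin per axis", {
  g <- data.frame(x_gaze = rep(1, 9), y_gaze = rep(2, 9), valid = TRUE)
  r <- range_from_threshold(build_histogram(g, 5), 0.05)
  expect_equal(r$X, 5)
  expect_equal(r$Y, 5)
  expect_equal(r$area, 25)
  expect_lte(r$Xmin, 1); expect_gte(r$Xmax, 1)
})

test_that("the threshold range approaches the Gaussian closed form", {
  # the marginal of a Gaussian falls to 5% of its peak at 2.448 sigma
  g <- gauss_gaze(20000, sigma = c(10, 10), seed = 3)
  r <- range_from_threshold(build_histogram(g, 2), 0.05)
  closed <- 2 * sqrt(2 * log(20)) * 10
  expect_lt(abs(r$X - closed) / closed, 0.1)
  expect_lt(abs(r$Y - closed) / closed, 0.1)
  expect_equal(r$area, r$X * r$Y, tolerance = 1e-12)
})

test_that("the range statistic is peak-relative, monotone and conservative", {
  g <- gauss_gaze(5000, sigma = c(12, 8), seed = 9)
  h <- build_histogram(g, 5)

  # scale invariance: doubling every count changes nothing
  h2 <- h
  h2$counts <- h$counts * 2L
  expect_equal(unclass(range_from_threshold(h, 0.05))[1:7],
               unclass(range_from_threshold(h2, 0.05))[1:7])

  # lowering the threshold never shrinks the range
  ths <- c(0.5, 0.2, 0.1, 0.05, 0.01)
  rs <- lapply(ths, function(th) range_from_threshold(h, th))
  for (i in seq_along(rs)[-1]) {
    expect_gte(rs[[i]]$X, rs[[i - 1]]$X)
    expect_gte(rs[[i]]$Y, rs[[i - 1]]$Y)
    expect_gte(rs[[i]]$area, rs[[i - 1]]$area)
  }

  expect_error(range_from_threshold(h, 0), class = "gr_argument_error")
  expect_error(range_from_threshold(h, 1), class = "gr_argument_error")
})

test_that("subject comparison ranks areas against the reference", {
  wide <- gaze_range(gauss_gaze(8000, sigma = c(12, 8), seed = 11), 2.5)
  same <- gaze_range(gauss_gaze(8000, sigma = c(12, 8), seed = 11), 2.5)
  narrow <- gaze_range(gauss_gaze(8000, sigma = c(6, 4), seed = 12), 2.5)

  cmp <- compare_subjects(list(instructor = wide, twin = same, B = narrow))
  expect_equal(cmp$subject[1], "instructor")
  expect_equal(cmp$area_ratio[cmp$subject == "twin"], 1.0)
  # halving sigma on both axes quarters the area
  expect_lt(abs(cmp$area_ratio[cmp$subject == "B"] - 0.25), 0.08)
  expect_true(cmp$narrow[cmp$subject == "B"])
  expect_false(cmp$narrow[cmp$subject == "twin"])

  # input order does not matter
  cmp2 <- compare_subjects(list(instructor = wide, B = narrow, twin = same))
  expect_equal(cmp, cmp2)

  expect_error(compare_subjects(list(a = wide)), class = "gr_argument_error")
  expect_error(compare_subjects(setNames(list(wide, narrow), c("a", "a"))),
               class = "gr_argument_error")
})
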