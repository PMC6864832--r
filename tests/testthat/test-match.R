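test_that("an exact template copy is found at its anchor with score 1", {
  set.seed(11)
  frame <- matrix(runif(200 * 260), 200, 260)
  templ <- make_templates(17)[["1"]]
  frame <- paste_template(frame, templ, x = 120, y = 40)
  det <- match_template(frame, templ)
  expect_equal(c(det$x, det$y), c(120, 40))
  expect_gt(det$score, 0.999)
})

test_that("a uniform frame yields no detection", {
  frame <- matrix(0.5, 120, 160)
  templ <- make_templates(17)[["2"]]
  expect_null(match_template(frame, templ))
})

test_that("a template larger than the region is an argument error", {
  frame <- matrix(0.5, 120, 160)
  templ <- matrix(runif(25), 5, 5)
  r <- search_region(0, 0, 4, 4)
  expect_error(match_template(frame, templ, r), class = "gr_argument_error")
})

test_that("compiled scanner matches the brute-force oracle score map", {
  templ <- make_templates(9)[["4"]]
  for (seed in 1:8) {
    set.seed(seed)
    frame <- matrix(runif(60 * 70), 60, 70)
    x <- sample(0:(70 - 9), 1)
    y <- sample(0:(60 - 9), 1)
    frame <- paste_template(frame, templ, x, y)
    fast <- gazerange:::ncc_score_map(frame, templ)
    slow <- ncc_oracle(frame, templ)
    expect_equal(fast, slow, tolerance = 1e-9)
    det <- match_template(frame, templ)
    expect_equal(c(det$x, det$y), c(x, y))
  }
})

test_that("restricting the search region does not change the found location", {
  set.seed(21)
  templ <- make_templates(11)[["3"]]
  frame <- matrix(runif(100 * 140), 100, 140)
  frame <- paste_template(frame, templ, x = 90, y = 30)
  full <- match_template(frame, templ)
  windowed <- match_template(frame, templ, search_region(70, 10, 120, 60))
  expect_equal(c(full$x, full$y), c(windowed$x, windowed$y))
  expect_equal(full$score, windowed$score, tolerance = 1e-12)
})

test_that("three-section split covers the region with the prescribed expansion", {
  r <- search_region(0, 0, 50, 300)
  s <- split_into_sections(r, template_height = 1)
  expect_named(s, c("center", "upper", "bottom"))
  expect_region_equal(s$center, 0, 100, 50, 200)
  expect_region_equal(s$upper, 0, 0, 50, 100)
  expect_region_equal(s$bottom, 0, 200, 50, 300)

  s <- split_into_sections(r, template_height = 21)
  expect_region_equal(s$center, 0, 80, 50, 220)
  expect_region_equal(s$upper, 0, 0, 50, 120)
  expect_region_equal(s$bottom, 0, 180, 50, 300)

  # sections never leave the parent region
  for (b in s) {
    expect_gte(b$y0, r$y0)
    expect_lte(b$y1, r$y1)
  }
})

test_that("a marker straddling a section boundary is only found with expansion", {
  set.seed(31)
  templ <- make_templates(17)[["1"]]
  frame <- matrix(runif(240 * 100), 240, 100)
  # bands of a 240-high region split at y = 80 and 160; anchor 70 straddles 80
  frame <- paste_template(frame, templ, x = 40, y = 70)
  region <- search_region(0, 0, 100, 240)

  unexpanded <- list(search_region(0, 0, 100, 80),
                     search_region(0, 80, 100, 160),
                     search_region(0, 160, 100, 240))
  hits <- lapply(unexpanded, function(b) match_template(frame, templ, b))
  expect_true(all(vapply(hits, is.null, logical(1))))

  sections <- split_into_sections(region, nrow(templ))
  hits <- Filter(Negate(is.null),
                 lapply(sections, function(b) match_template(frame, templ, b)))
  expect_gt(length(hits), 0)
  expect_equal(c(hits[[1]]$x, hits[[1]]$y), c(40, 70))
})

test_that("search planning honours the marker ordering constraints", {
  spec <- default_scene()
  tm <- make_templates(spec$template_size)
  fd <- c(240L, 320L)

  # no prior information: Marker1 searches the full frame, Marker4 too
  plan <- plan_search_regions(NULL, NULL, fd, tm)
  expect_region_equal(plan[["1"]][[1]], 0, 0, 320, 240)
  expect_region_equal(plan[["4"]][[1]], 0, 0, 320, 240)

  # Marker1/2 just found: Marker4 is excluded from the frame entirely
  prev <- rbind(gazerange:::marker_detection(1, 60, 100, 1),
                gazerange:::marker_detection(2, 300, 100, 1))
  plan <- plan_search_regions(prev, NULL, fd, tm)
  expect_length(plan[["4"]], 0)
  # and Marker3 must lie strictly right of both
  expect_gte(plan[["3"]][[1]]$x0, 301)

  # zero displacement: Marker2's own window is centred on its last position
  prev1 <- gazerange:::marker_detection(2, 150, 100, 1)
  plan <- plan_search_regions(prev1, prev1, fd, tm, margin = 40)
  r <- plan[["2"]][[1]]
  expect_region_equal(r, 150 - 40, 100 - 40, 150 + 17 + 40, 100 + 17 + 40)

  # motion extension: +40 px in x grows the right edge by gain * 40
  prev2 <- gazerange:::marker_detection(2, 110, 100, 1)
  plan <- plan_search_regions(prev1, prev2, fd, tm, margin = 40,
                              extension_gain = 1.5)
  r_ext <- plan[["2"]][[1]]
  expect_equal(r_ext$x1, r$x1 + 1.5 * 40)
  expect_equal(r_ext$x0, r$x0)

  # leftward motion grows the left edge instead
  prev2l <- gazerange:::marker_detection(2, 190, 100, 1)
  plan <- plan_search_regions(prev1, prev2l, fd, tm, margin = 40,
                              extension_gain = 1.5)
  expect_equal(plan[["2"]][[1]]$x0, r$x0 - 1.5 * 40)
  expect_equal(plan[["2"]][[1]]$x1, r$x1)
})

test_that("markers found in the current frame constrain later searches", {
  spec <- default_scene()
  tm <- make_templates(spec$template_size)
  found <- gazerange:::marker_detection(3, 200, 100, 1)
  plan <- plan_search_regions(NULL, NULL, c(240L, 320L), tm, found = found)
  expect_gte(plan[["4"]][[1]]$x0, 201)
})
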