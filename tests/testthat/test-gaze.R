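sample_stream <- function(t, event = "sample") {
  tibble::tibble(t_ms = t, x_px = 500, y_px = 400, event = event)
}

test_that("blink scrubbing removes padded half-open windows", {
  # 1000 Hz stream over [0, 1000); blink [500, 600), pad 100
  s <- sample_stream(0:999)
  blink <- dplyr::bind_rows(
    sample_stream(500, "blink_start"), sample_stream(600, "blink_end"))
  out <- scrub_blinks(dplyr::arrange(dplyr::bind_rows(s, blink), t_ms),
                      pad_ms = 100)
  expect_equal(nrow(out), 1000 - 300)  # [400, 700) removed
  expect_false(any(out$t_ms >= 400 & out$t_ms < 700))
  expect_true(all(out$event == "sample"))
  # no blinks -> unchanged
  expect_equal(scrub_blinks(s), s)
  # overlapping pads merge into one gap without double removal
  two <- dplyr::bind_rows(s,
                          sample_stream(300, "blink_start"),
                          sample_stream(350, "blink_end"),
                          sample_stream(400, "blink_start"),
                          sample_stream(450, "blink_end")) |>
    dplyr::arrange(t_ms)
  out2 <- scrub_blinks(two, pad_ms = 100)
  expect_equal(nrow(out2), 1000 - length(200:549))
  expect_error(scrub_blinks(sample_stream(c(5, 1, 3))), "time-ordered")
})

test_that("fixation density peaks at fixations and ignores duration scale", {
  one <- tibble::tibble(x_px = 300, y_px = 200, duration_ms = 250)
  m <- fixation_density(one)
  expect_equal(max(m$values), 1)
  expect_equal(which(m$values == 1), (300 - 1) * 768 + 200)
  # radial decay from the peak
  expect_gt(m$values[200, 300], m$values[200, 340])
  expect_gt(m$values[200, 340], m$values[200, 400])

  # two equal fixations >= 8 sigma apart -> two ~unit peaks
  two <- tibble::tibble(x_px = c(200, 800), y_px = c(380, 380),
                        duration_ms = c(300, 300))
  m2 <- fixation_density(two, sigma_px = 18.75)
  expect_gt(m2$values[380, 200], 0.999)
  expect_gt(m2$values[380, 800], 0.999)

  # doubling durations leaves the normalized map unchanged
  m3 <- fixation_density(dplyr::mutate(two, duration_ms = 2 * duration_ms))
  expect_equal(m3$values, m2$values, tolerance = 1e-12)
  # ordering of fixation records is irrelevant
  m4 <- fixation_density(two[2:1, ])
  expect_equal(m4$values, m2$values)
  expect_error(fixation_density(one[0, ]), "no fixations")
})

test_that("group density is the pointwise mean of participant maps", {
  f1 <- tibble::tibble(x_px = 300, y_px = 200, duration_ms = 100)
  f2 <- tibble::tibble(x_px = 700, y_px = 500, duration_ms = 100)
  m1 <- fixation_density(f1)
  m2 <- fixation_density(f2)
  g <- group_density(list(m1, m2))
  expect_equal(g$values, (m1$values + m2$values) / 2)
  expect_equal(group_density(list(m1, m1))$values, m1$values)
  zero <- raw_density_map(matrix(0, 768, 1024))
  expect_equal(group_density(list(m1, zero))$values, m1$values / 2)
})

test_that("the adult fixation zone follows the overlap fraction rule", {
  mk <- function(v) raw_density_map(matrix(v, 2, 2))
  # 10 adults; one pixel supra-threshold in exactly 7, another in 6
  maps <- lapply(1:10, function(i) {
    mk(c(if (i <= 7) 1 else 0, if (i <= 6) 1 else 0, 1, 0))
  })
  afz <- adult_fixation_zone(maps, overlap = 0.7)
  expect_true(afz$mask[1, 1])    # 7/10 >= 0.7
  expect_false(afz$mask[2, 1])   # 6/10 < 0.7
  expect_true(afz$mask[1, 2])    # unanimous
  expect_false(afz$mask[2, 2])   # never fixated
  # identical adults -> AFZ equals the common supra-eps support
  same <- lapply(1:4, function(i) mk(c(1, 0.5, 0.005, 0)))
  afz2 <- adult_fixation_zone(same, overlap = 0.7, presence_eps = 0.01)
  expect_equal(as.vector(afz2$mask), c(TRUE, TRUE, FALSE, FALSE))
  # overlap 0 -> union of supports
  afz3 <- adult_fixation_zone(maps, overlap = 0)
  expect_equal(sum(afz3$mask), 4)
  # AFZ shrinks monotonically as the overlap criterion rises
  sizes <- vapply(c(0.1, 0.5, 0.7, 0.9, 1),
                  function(o) sum(adult_fixation_zone(maps, o)$mask),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("outside-AFZ ratio weights fixation time correctly", {
  mask <- matrix(FALSE, 768, 1024)
  mask[300:500, 400:700] <- TRUE
  afz <- structure(list(mask = mask, overlap = 0.7, presence_eps = 0.01,
                        n_adults = 1), class = "afz_mask")
  inside <- tibble::tibble(x_px = 550, y_px = 400, duration_ms = 100)
  outside <- tibble::tibble(x_px = 100, y_px = 100, duration_ms = 100)
  expect_equal(outside_afz_ratio(inside, afz), 0)
  expect_equal(outside_afz_ratio(outside, afz), 1)
  both <- dplyr::bind_rows(inside, outside)
  expect_equal(outside_afz_ratio(both, afz), 0.5)
  # durations 100/200/700 with only the 700 ms fixation outside -> 0.7
  mix <- tibble::tibble(x_px = c(500, 600, 50), y_px = c(350, 450, 50),
                        duration_ms = c(100, 200, 700))
  expect_equal(outside_afz_ratio(mix, afz), 0.7)
  expect_equal(outside_afz_ratio(mix, afz, weight = "count"), 1 / 3)
})

test_that("bias vectors point from the adult centre to the child centre", {
  adult_fix <- tibble::tibble(x_px = 512, y_px = 384, duration_ms = 200)
  am <- fixation_density(adult_fix)
  afz <- adult_fixation_zone(list(am))
  # identical maps -> zero vector
  expect_lt(bias_vector(am, am, afz)$magnitude, 1e-9)
  # child displaced +30 px right, -30 px in screen y (up) -> 45 degrees
  cm <- fixation_density(tibble::tibble(x_px = 542, y_px = 354,
                                        duration_ms = 200))
  bv <- bias_vector(cm, am, afz)
  expect_equal(bv$angle, 45, tolerance = 1)
  expect_equal(bv$magnitude, sqrt(2) * 30, tolerance = 1)
  expect_gt(bv$dy, 0)  # upward in visual-field convention
})

test_that("angular distance from the null quadrant wraps correctly", {
  # 15 degrees into the upper-right quadrant is 105 degrees from lower-left
  expect_equal(angular_distance_from_quadrant(15, "lower-left"), 105)
  expect_equal(angular_distance_from_quadrant(45, "lower-left"), 135)
  expect_equal(angular_distance_from_quadrant(200, "lower-left"), 0)
  expect_equal(angular_distance_from_quadrant(300, "lower-right"), 0)
  expect_equal(angular_distance_from_quadrant(90, "lower-right"), 90)
  expect_equal(angular_distance_from_quadrant(135, "lower-right"), 135)
  expect_equal(angular_distance_from_quadrant(170, "lower-left"), 10)
  # wrap-around: just past 360-boundary of lower-right
  expect_equal(angular_distance_from_quadrant(10, "lower-right"), 10)
})

test_that("the null-quadrant test summarises distances and occupancy", {
  qt <- null_quadrant_test(c(45, 100, 210, 30), "lower-left")
  expect_equal(qt$distances,
               angular_distance_from_quadrant(c(45, 100, 210, 30),
                                              "lower-left"))
  expect_equal(qt$frac_inside, 0.25)
  expect_equal(qt$chance, 0.25)
  td <- tidy(qt)
  expect_true(all(c("statistic", "p.value", "frac_inside") %in% names(td)))
  expect_error(null_quadrant_test(45), "at least 2")
})
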