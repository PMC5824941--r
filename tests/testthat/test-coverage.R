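fit_row <- function(x, y, size, id = "v1") {
  tibble::tibble(voxel_id = id, x = x, y = y, size = size)
}

test_that("voxel density is a unit-peak Gaussian of the effective size", {
  grid <- coverage_grid(7, 141)  # 0.1 dva cells, includes exact centres
  m <- voxel_density(fit_row(3, 0, 1), grid)
  v <- as_tibble(m)
  near <- function(a, b) abs(a - b) < 1e-9
  expect_equal(v$value[near(v$x, 3) & near(v$y, 0)], 1)
  expect_equal(v$value[near(v$x, 4) & near(v$y, 0)], exp(-0.5),
               tolerance = 1e-12)
  # mass check: integral ~ 2*pi*size^2
  cell <- (14 / 140)^2
  expect_equal(sum(m$values) * cell, 2 * pi * 1^2, tolerance = 0.01)
})

test_that("bootstrap coverage of a singleton ROI is exactly its density", {
  grid <- coverage_grid(7, 141)  # centre lies on the grid: peak cell = 1
  f <- fit_row(1, 2, 1.5)
  d <- voxel_density(f, grid)
  for (seed in c(1, 99)) {
    m <- roi_coverage(f, grid, n_boot = 7, seed = seed)
    expect_equal(m$values, d$values, tolerance = 1e-12)
  }
  expect_error(roi_coverage(f[0, ], grid), "no fitted voxels")
})

test_that("bootstrap mean approaches the exact composition expectation", {
  # 2 voxels, draws of size 2: compositions {11, 12, 22} with weights
  # 1/4, 1/2, 1/4; oracle computed by direct enumeration
  grid <- coverage_grid(7, 48)
  fits <- dplyr::bind_rows(fit_row(-2, 0, 1, "a"), fit_row(3, 1, 2, "b"))
  d <- prfgaze:::density_columns(fits, grid)
  norm1 <- function(v) v / max(v)
  oracle <- 0.25 * norm1(d[, 1]) + 0.5 * norm1(rowMeans(d)) +
    0.25 * norm1(d[, 2])
  oracle <- matrix(norm1(oracle), 48, 48)
  m <- roi_coverage(fits, grid, n_boot = 1500, seed = 5)
  # per-pixel Monte-Carlo se ~ 0.007; bound at ~6 sigma over the grid
  expect_lt(max(abs(m$values - oracle)), 0.04)
})

test_that("group averaging flips right-hemisphere maps over the meridian", {
  grid <- coverage_grid(7, 64)
  m1 <- roi_coverage(fit_row(2, 1, 1), grid, n_boot = 1,
                     provenance = list(hemisphere = "L"))
  # identical maps average to themselves
  g <- group_coverage(list(m1, m1), flip_rh = TRUE)
  expect_equal(g$values, m1$values)
  # a map and its mirror, flip applied to the mirrored one -> original
  m2 <- roi_coverage(fit_row(-2, 1, 1), grid, n_boot = 1,
                     provenance = list(hemisphere = "R"))
  g2 <- group_coverage(list(m1, m2), flip_rh = TRUE)
  expect_equal(g2$values, m1$values, tolerance = 1e-12)
  # two asymmetric maps without flipping: plain pointwise mean
  g3 <- group_coverage(list(m1, m2), flip_rh = FALSE)
  expect_equal(g3$values, (m1$values + m2$values) / 2)
  expect_error(group_coverage(list(m1, roi_coverage(fit_row(0, 0, 1),
                                                    coverage_grid(7, 32),
                                                    n_boot = 1))),
               "different grids")
})

test_that("coverage extent scales the covered proportion by pi r^2", {
  grid <- coverage_grid(7, 128)
  zero <- raw_coverage_map(matrix(0, 128, 128), grid)
  expect_equal(coverage_extent(zero), 0)
  full <- raw_coverage_map(matrix(1, 128, 128), grid)
  expect_equal(coverage_extent(full), pi * 49, tolerance = 1e-12)
  # half-field x > 0: half the disc area (grid has no x = 0 column)
  co <- prfgaze:::grid_flat(grid)
  half <- raw_coverage_map(matrix((co$x > 0) * 1, 128, 128), grid)
  expect_equal(coverage_extent(half), pi * 49 / 2, tolerance = 0.5)
  # monotone nonincreasing in the binarization threshold
  vals <- matrix(stats::runif(128 * 128), 128)
  m <- raw_coverage_map(vals, grid)
  ths <- c(0.01, 0.1, 0.5, 0.9)
  ext <- vapply(ths, function(t) coverage_extent(m, binarize_at = t),
                numeric(1))
  expect_true(all(diff(ext) <= 0))
})

test_that("centre of mass matches point-mass and two-point oracles", {
  grid <- coverage_grid(7, 141)
  z <- matrix(0, 141, 141)
  at <- function(x, y) c(which(abs(grid$y - y) < 1e-9),
                         which(abs(grid$x - x) < 1e-9))
  m <- z; m[at(3, 0)[1], at(3, 0)[2]] <- 1
  com <- coverage_com(raw_coverage_map(m, grid))
  expect_equal(com$x, 3)
  expect_equal(com$y, 0)
  expect_equal(com$distance, 3)
  # equal masses at (2,0) and (0,2) -> CoM (1,1), distance sqrt(2)
  m2 <- z
  m2[at(2, 0)[1], at(2, 0)[2]] <- 1
  m2[at(0, 2)[1], at(0, 2)[2]] <- 1
  com2 <- coverage_com(raw_coverage_map(m2, grid))
  expect_equal(c(com2$x, com2$y, com2$distance), c(1, 1, sqrt(2)))
  # radially symmetric map centred at origin -> distance ~ 0
  sym <- voxel_density(fit_row(0, 0, 2), grid)
  expect_lt(coverage_com(sym)$distance, 1e-3)  # grid discretization
  expect_error(coverage_com(raw_coverage_map(z, grid)), "zero")
})

test_that("centre of mass is equivariant under the meridian flip", {
  grid <- coverage_grid(7, 64)
  m <- roi_coverage(fit_row(2.5, -1, 1.2), grid, n_boot = 1)
  flipped <- raw_coverage_map(m$values[, 64:1], grid)
  a <- coverage_com(m)
  b <- coverage_com(flipped)
  expect_equal(b$x, -a$x, tolerance = 1e-9)
  expect_equal(b$y, a$y, tolerance = 1e-9)
  expect_equal(b$distance, a$distance, tolerance = 1e-9)
})

test_that("jackknife SE matches the classical closed form for the mean", {
  expect_equal(jackknife_se(c(5, 5, 5, 5)), 0)
  expect_equal(jackknife_se(c(1, 2, 3)), 1 / sqrt(3))
  set.seed(8)
  v <- stats::rnorm(17)
  expect_equal(jackknife_se(v), stats::sd(v) / sqrt(17), tolerance = 1e-12)
  expect_equal(jackknife_se(v), jackknife_se(sample(v)))
  expect_error(jackknife_se(1), "at least 2")
})
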