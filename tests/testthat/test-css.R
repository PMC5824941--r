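test_that("prediction is zero for blank stimuli and scales as overlap^n", {
  xs <- seq(-7, 7, length.out = 9)
  blank <- raw_movie(replicate(6, matrix(0, 9, 9), simplify = FALSE),
                     xs, xs, field_radius = 7)
  prf <- list(x = 0, y = 1, sigma = 2, n = 0.5, g = 1.5)
  expect_equal(predict_timecourse(prf, blank), rep(0, 6))

  # doubling every frame's overlap scales the n = 0.5 output by sqrt(2)
  frames <- replicate(6, matrix(stats::runif(81) < 0.5, 9, 9) * 1,
                      simplify = FALSE)
  ap1 <- raw_movie(frames, xs, xs, field_radius = 7)
  ap2 <- raw_movie(lapply(frames, function(f) 2 * f), xs, xs,
                   field_radius = 7)
  expect_equal(predict_timecourse(prf, ap2),
               sqrt(2) * predict_timecourse(prf, ap1), tolerance = 1e-12)

  expect_error(predict_timecourse(list(x = 0, y = 0, sigma = NA, n = 1,
                                       g = 1), ap1), "finite")
})

test_that("prediction equals a pencil-and-paper drive + convolution", {
  # 3 frames on a 5x5 grid; oracle computed with explicit loops
  xs <- seq(-2, 2, length.out = 5)
  f1 <- matrix(0, 5, 5); f1[, 2] <- 1       # vertical strip x = -1
  f2 <- matrix(0, 5, 5); f2[3, ] <- 1       # horizontal strip y = 0
  f3 <- matrix(1, 5, 5)                     # full field
  ap <- raw_movie(list(f1, f2, f3), xs, xs, field_radius = 3)
  prf <- list(x = 0.5, y = -0.5, sigma = 1.2, n = 0.7, g = 2)

  gauss <- function(px, py) {
    exp(-((px - prf$x)^2 + (py - prf$y)^2) / (2 * prf$sigma^2))
  }
  drive <- numeric(3)
  for (t in 1:3) {
    fr <- list(f1, f2, f3)[[t]]
    acc <- 0
    for (i in 1:5) for (j in 1:5) {
      acc <- acc + fr[i, j] * gauss(xs[j], xs[i])
    }
    drive[t] <- acc^prf$n
  }
  k <- hrf_kernel(hrf_spec(), tr = 2)
  oracle <- numeric(3)
  for (t in 1:3) {
    for (l in 1:t) oracle[t] <- oracle[t] + drive[l] * k[t - l + 1]
  }
  expect_equal(predict_timecourse(prf, ap), prf$g * oracle,
               tolerance = 1e-12)
})

test_that("variance explained matches its closed forms and error contract", {
  obs <- c(1, 2, 3, 4)
  expect_equal(variance_explained(obs, obs), 1)
  expect_equal(variance_explained(obs, rep(mean(obs), 4)), 0,
               ignore_attr = TRUE)
  expect_equal(variance_explained(obs, c(1, 2, 3, 5)), 0.8)
  # negative raw R^2 clamps to zero with a flag
  bad <- variance_explained(obs, c(10, -10, 10, -10))
  expect_equal(as.numeric(bad), 0)
  expect_true(attr(bad, "clamped"))
  expect_error(variance_explained(rep(1, 4), obs), "constant")
})

test_that("noise-free on-grid parameters are recovered exactly", {
  ap <- small_movie()
  hrf <- hrf_spec()
  grid <- small_grid(refine = FALSE)
  truth <- list(x = 2, y = -2, sigma = 1, n = 0.5, g = 1.3)
  tc <- predict_timecourse(truth, ap, hrf)
  fit <- fit_prf(tc, ap, hrf, grid)
  expect_equal(fit$x, truth$x)
  expect_equal(fit$y, truth$y)
  expect_equal(fit$sigma, truth$sigma)
  expect_equal(fit$n, truth$n)
  expect_equal(fit$g, truth$g, tolerance = 1e-6)
  expect_gt(fit$ve, 1 - 1e-9)
})

test_that("refinement recovers off-grid parameters within tolerance", {
  ap <- small_movie()
  hrf <- hrf_spec()
  truth <- list(x = 1.7, y = -2.6, sigma = 1.4, n = 0.6, g = 0.9)
  tc <- predict_timecourse(truth, ap, hrf)
  fit <- fit_prf(tc, ap, hrf, small_grid(refine = TRUE))
  expect_lt(abs(fit$x - truth$x), 0.1)
  expect_lt(abs(fit$y - truth$y), 0.1)
  expect_lt(abs(fit$sigma - truth$sigma) / truth$sigma, 0.05)
  expect_gt(fit$ve, 0.99)
})

test_that("population fitting is a faithful, order-equivariant batch", {
  ap <- small_movie()
  hrf <- hrf_spec()
  grid <- small_grid(refine = FALSE)
  truth <- sample_ground_truth_prfs(n_voxels = 3, seed = 13)
  tcs <- simulate_bold(truth, ap, hrf, noise_sd = 0.05, seed = 14)

  pop <- fit_population(tcs, ap, hrf, grid)
  expect_equal(nrow(pop), 3)
  expect_equal(pop$voxel_id, truth$voxel_id)
  # singleton batch identical to fit_prf
  one <- fit_prf(tcs$values[2, ], ap, hrf, grid)
  expect_equal(pop[2, names(one)], one)
  # permuted input -> permuted identical output
  perm <- c(3, 1, 2)
  pop_perm <- fit_population(tcs$values[perm, , drop = FALSE], ap, hrf, grid)
  expect_equal(pop_perm[, c("x", "y", "sigma", "n", "g", "ve")],
               pop[perm, c("x", "y", "sigma", "n", "g", "ve")])
  # non-finite voxel flagged, batch not aborted
  vals <- tcs$values
  vals[1, 3] <- NA
  flagged <- fit_population(vals, ap, hrf, grid)
  expect_equal(flagged$flag[1], "nonfinite")
  expect_equal(flagged$ve[1], 0)
  expect_equal(flagged$flag[2:3], c("ok", "ok"))
})

test_that("an all-zero stimulus produces a flagged null fit", {
  xs <- seq(-7, 7, length.out = 9)
  blank <- raw_movie(replicate(8, matrix(0, 9, 9), simplify = FALSE),
                     xs, xs, field_radius = 7)
  fit <- fit_prf(stats::rnorm(8), blank,
                 grid = small_grid(refine = FALSE))
  expect_equal(fit$flag, "null")
  expect_equal(fit$ve, 0)
})

test_that("exclusion filters implement the three rules exactly", {
  tab <- tibble::tibble(
    voxel_id = paste0("v", 1:5),
    ve = c(0.5, 0.04, 0.5, 0.5, 0.06),
    ecc = c(3, 3, 8, 3, 6.9),
    sigma = c(1, 1, 1, 0.21, 0.3))
  out <- filter_fits(tab)
  expect_equal(out$voxel_id, c("v1", "v5"))
  log <- exclusion_log(out)
  expect_equal(log$excluded_low_ve, 1)
  expect_equal(log$excluded_outside_field, 1)
  expect_equal(log$excluded_sigma_floor, 1)
  expect_equal(log$n_out, 2)
  # all-zero ve -> empty survivors
  expect_equal(nrow(filter_fits(dplyr::mutate(tab, ve = 0))), 0)
  # centre exactly on the field edge is retained
  edge <- tibble::tibble(voxel_id = "e", ve = 0.5, ecc = 7, sigma = 1)
  expect_equal(nrow(filter_fits(edge)), 1)
})

test_that("effective size follows sigma/sqrt(n) and shrinks with n", {
  expect_equal(effective_size(1.5, 1), 1.5)
  expect_equal(effective_size(2, 0.25), 4)
  n_seq <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(effective_size(2, n_seq)) < 0))
  expect_error(effective_size(-1, 0.5))
})
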