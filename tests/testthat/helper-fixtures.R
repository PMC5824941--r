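# Small shared fixtures, built in code at test time.

# Compact bar movie: quick to fit against, still 8 sweeps.
small_movie <- function(grid_px = 41, steps = 8, n_blank = 0) {
  generate_bar_apertures(grid_px = grid_px, steps_per_sweep = steps,
                         n_blank = n_blank)
}

# Coarse but adequate fitting grid for unit tests.
small_grid <- function(refine = TRUE) {
  fit_grid_spec(x = seq(-6, 6, length.out = 7),
                y = seq(-6, 6, length.out = 7),
                sigma = c(0.5, 1, 2, 4), n = c(0.5, 1), refine = refine)
}

# Hand-rolled aperture movie from an explicit frame list (H x W matrices).
raw_movie <- function(frame_list, xs, ys, field_radius, tr = 2) {
  frames <- array(0, dim = c(length(ys), length(xs), length(frame_list)))
  for (k in seq_along(frame_list)) frames[, , k] <- frame_list[[k]]
  prfgaze:::new_aperture_movie(
    frames = frames, x = xs, y = ys, field_radius = field_radius, tr = tr,
    pixels_per_dva = (length(xs) - 1) / (2 * field_radius),
    sweep_labels = seq_along(frame_list))
}

# Coverage map with explicit values on a given grid.
raw_coverage_map <- function(values, grid) {
  prfgaze:::new_coverage_map(values, grid)
}

# Density map with explicit values.
raw_density_map <- function(values, sigma_px = 18.75) {
  prfgaze:::new_density_map(values, sigma_px)
}

# Independent brute-force 2D two-sample KS statistic (explicit loops).
ks2d_brute <- function(a, b) {
  ox <- c(a$x, b$x)
  oy <- c(a$y, b$y)
  d <- 0
  for (i in seq_along(ox)) {
    for (q in 1:4) {
      inq <- function(px, py) {
        switch(q,
               px > ox[i] & py > oy[i],
               px < ox[i] & py > oy[i],
               px < ox[i] & py < oy[i],
               px > ox[i] & py < oy[i])
      }
      fa <- mean(inq(a$x, a$y))
      fb <- mean(inq(b$x, b$y))
      d <- max(d, abs(fa - fb))
    }
  }
  d
}

random_points <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(x = stats::rnorm(n), y = stats::rnorm(n))
}
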