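#' Bar-sweep aperture movies
#'
#' Generates the binarized stimulus movie for a bar-sweep retinotopic
#' mapping run: a bar of fixed width sweeps across a circular visual field
#' at each of several orientations, in the two directions orthogonal to the
#' bar. The default protocol is 4 orientations (0, 45, 90, 135 degrees),
#' each swept in both directions (8 sweeps), 12 steps per sweep plus 6
#' trailing blank frames, i.e. 102 frames at TR 2 s (a 3 min 24 s run).
#'
#' Coordinates are in degrees of visual angle (dva): x positive rightward,
#' y positive upward, origin at fixation. A pixel is "on" when its centre
#' lies inside the bar and inside the circular field.
#'
#' @param field_radius Radius of the stimulated field, dva.
#' @param bar_width Bar width, dva.
#' @param bar_length Bar length, dva (default spans the full field).
#' @param orientations Bar orientations in degrees. Orientation 0 is a
#'   vertical bar sweeping horizontally; the sweep direction is orthogonal
#'   to the bar.
#' @param steps_per_sweep Number of equally spaced bar positions per sweep,
#'   edge to edge.
#' @param grid_px Pixels per side of the square stimulus grid.
#' @param tr Sampling interval (repetition time), seconds.
#' @param n_blank Number of blank (all-zero) frames appended after the
#'   sweeps.
#' @param strict Reject bars wider than the field diameter.
#' @return An object of class `aperture_movie`: a list with `frames`
#'   (H x W x T binary array), pixel-centre coordinate vectors `x` and `y`
#'   (dva, ascending), `field_radius`, `tr`, `pixels_per_dva`, and
#'   `sweep_labels` (integer per frame; 0 marks blanks).
#' @examples
#' ap <- generate_bar_apertures(grid_px = 41)
#' n_sweeps(ap)  # 8
#' @export
generate_bar_apertures <- function(field_radius = 7, bar_width = 2,
                                   bar_length = 2 * field_radius,
                                   orientations = c(0, 45, 90, 135),
                                   steps_per_sweep = 12, grid_px = 101,
                                   tr = 2, n_blank = 6, strict = TRUE) {
  stopifnot(bar_width > 0, grid_px >= 32, length(orientations) >= 1,
            steps_per_sweep >= 2, field_radius > 0, tr > 0, n_blank >= 0)
  if (strict && bar_width > 2 * field_radius) {
    stop("bar_width exceeds the field diameter (", 2 * field_radius, " dva)")
  }

  xs <- seq(-field_radius, field_radius, length.out = grid_px)
  ys <- xs
  grid_x <- matrix(rep(xs, each = grid_px), nrow = grid_px)   # col j = xs[j]
  grid_y <- matrix(rep(ys, times = grid_px), nrow = grid_px)  # row i = ys[i]
  in_field <- grid_x^2 + grid_y^2 <= field_radius^2

  # bar traverses edge-to-edge while staying inside the field span
  lim <- max(field_radius - bar_width / 2, 0)
  centers <- seq(-lim, lim, length.out = steps_per_sweep)
  sweeps <- tidyr::expand_grid(orientation = orientations,
                               direction = c(1L, -1L))

  frames_list <- purrr::pmap(sweeps, function(orientation, direction) {
    th <- orientation * pi / 180
    # u: position along the sweep axis; v: along the bar's long axis
    u <- grid_x * cos(th) + grid_y * sin(th)
    v <- -grid_x * sin(th) + grid_y * cos(th)
    cs <- if (direction == 1L) centers else rev(centers)
    lapply(cs, function(ctr) {
      (abs(u - ctr) <= bar_width / 2) & (abs(v) <= bar_length / 2) & in_field
    })
  })
  frames_list <- purrr::flatten(frames_list)
  n_sw <- nrow(sweeps)
  t_total <- n_sw * steps_per_sweep + n_blank

  frames <- array(0, dim = c(grid_px, grid_px, t_total))
  for (k in seq_along(frames_list)) frames[, , k] <- frames_list[[k]] * 1

  new_aperture_movie(
    frames = frames, x = xs, y = ys, field_radius = field_radius, tr = tr,
    pixels_per_dva = (grid_px - 1) / (2 * field_radius),
    sweep_labels = c(rep(seq_len(n_sw), each = steps_per_sweep),
                     rep(0L, n_blank))
  )
}

new_aperture_movie <- function(frames, x, y, field_radius, tr,
                               pixels_per_dva, sweep_labels) {
  stopifnot(length(dim(frames)) == 3,
            dim(frames)[1] == length(y), dim(frames)[2] == length(x),
            dim(frames)[3] == length(sweep_labels))
  structure(list(frames = frames, x = x, y = y, field_radius = field_radius,
                 tr = tr, pixels_per_dva = pixels_per_dva,
                 sweep_labels = as.integer(sweep_labels)),
            class = "aperture_movie")
}

#' @export
print.aperture_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat("<aperture_movie> ", d[3], " frames of ", d[1], "x", d[2],
      " px, field radius ", x$field_radius, " dva, TR ", x$tr, " s, ",
      n_sweeps(x), " sweeps\n", sep = "")
  invisible(x)
}

#' Number of frames / sweeps in an aperture movie
#' @param apertures An `aperture_movie`.
#' @return Integer count.
#' @export
n_frames <- function(apertures) dim(apertures$frames)[3]

#' @rdname n_frames
#' @export
n_sweeps <- function(apertures) {
  length(unique(apertures$sweep_labels[apertures$sweep_labels > 0L]))
}

#' Repeat an aperture movie over several runs
#'
#' Concatenates `n_runs` copies of a movie in time, continuing the sweep
#' labels, to represent the full multi-run session protocol.
#'
#' @param apertures An `aperture_movie`.
#' @param n_runs Number of runs.
#' @return An `aperture_movie` with `n_runs` times the frames.
#' @export
repeat_movie <- function(apertures, n_runs = 4) {
  stopifnot(inherits(apertures, "aperture_movie"), n_runs >= 1)
  tt <- n_frames(apertures)
  frames <- array(rep(apertures$frames, n_runs),
                  dim = c(dim(apertures$frames)[1:2], tt * n_runs))
  labs <- apertures$sweep_labels
  per_run <- max(labs)
  all_labs <- unlist(lapply(seq_len(n_runs) - 1L, function(r) {
    ifelse(labs > 0L, labs + r * per_run, 0L)
  }))
  new_aperture_movie(frames, apertures$x, apertures$y,
                     apertures$field_radius, apertures$tr,
                     apertures$pixels_per_dva, all_labs)
}

# Flatten frames to a T x P matrix (P pixels, column-major over H x W).
aperture_matrix <- function(apertures) {
  d <- dim(apertures$frames)
  t(matrix(apertures$frames, nrow = d[1] * d[2]))
}

# Pixel-centre coordinates aligned with aperture_matrix columns.
aperture_coords <- function(apertures) {
  h <- length(apertures$y)
  list(x = rep(apertures$x, each = h),
       y = rep(apertures$y, times = length(apertures$x)))
}

#' Haemodynamic response function
#'
#' `hrf_spec()` describes a double-gamma HRF (a positive gamma peak minus a
#' scaled gamma undershoot); `hrf_kernel()` samples it at the movie's TR and
#' normalizes the kernel to unit peak.
#'
#' @param peak_delay Time-to-peak of the positive lobe, s.
#' @param undershoot_delay Time-to-peak of the undershoot, s.
#' @param peak_disp,undershoot_disp Dispersions (gamma scale), s.
#' @param ratio Undershoot amplitude relative to the peak.
#' @param duration Kernel support, s.
#' @return `hrf_spec()`: an object of class `hrf_spec`. `hrf_kernel()`: a
#'   numeric vector sampled at `tr` from 0 to `duration`.
#' @examples
#' k <- hrf_kernel(hrf_spec(), tr = 2)
#' max(k)  # 1
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1,
                     ratio = 1 / 6, duration = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_disp > 0,
            undershoot_disp > 0, ratio >= 0, duration > peak_delay)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, duration = duration),
            class = "hrf_spec")
}

#' @rdname hrf_spec
#' @param hrf An `hrf_spec`.
#' @param tr Sampling interval, s.
#' @export
hrf_kernel <- function(hrf = hrf_spec(), tr = 2) {
  stopifnot(inherits(hrf, "hrf_spec"), tr > 0)
  tt <- seq(0, hrf$duration, by = tr)
  h <- stats::dgamma(tt, shape = hrf$peak_delay / hrf$peak_disp,
                     scale = hrf$peak_disp) -
    hrf$ratio * stats::dgamma(tt, shape = hrf$undershoot_delay / hrf$undershoot_disp,
                              scale = hrf$undershoot_disp)
  pk <- max(h)
  if (!is.finite(pk) || pk <= 0) stop("degenerate HRF kernel")
  h / pk
}

# Causal convolution of a drive with a kernel, truncated to length(drive).
convolve_causal <- function(drive, kernel) {
  n <- length(drive)
  out <- stats::convolve(drive, rev(kernel), type = "open")
  out[seq_len(n)]
}

#' Convert screen-pixel to visual-field coordinates
#'
#' Screen pixels have y increasing downward; visual-field convention has y
#' increasing upward. This helper owns that flip: it maps pixel
#' displacements (or positions relative to a screen origin) to field
#' coordinates by negating y.
#'
#' @param dx_px,dy_px Displacements in screen-pixel convention.
#' @return A list with `dx` and `dy` in visual-field convention (y up).
#' @export
screen_to_field <- function(dx_px, dy_px) {
  list(dx = dx_px, dy = -dy_px)
}
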