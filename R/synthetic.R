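# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  expr <- substitute(expr)
  if (!is.null(seed)) {
    old <- .GlobalEnv$.Random.seed
    on.exit(
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv),
      add = TRUE)
    set.seed(seed)
  }
  eval(expr, parent.frame())
}

#' Voxel-by-time BOLD container
#'
#' A light container pairing a voxels x T response matrix with its TR and
#' per-voxel labels. `as_tibble()` returns the long (voxel, time, bold)
#' form for tidy workflows.
#'
#' @param values Voxels x T numeric matrix.
#' @param tr Repetition time, s.
#' @param voxel_ids,roi_labels,hemisphere Optional per-voxel metadata
#'   (recycled if length 1).
#' @return An object of class `voxel_timecourses`.
#' @export
voxel_timecourses <- function(values, tr, voxel_ids = NULL,
                              roi_labels = NA_character_,
                              hemisphere = NA_character_) {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)), tr > 0)
  nv <- nrow(values)
  if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_len(nv))
  structure(list(values = values, tr = tr,
                 voxel_ids = rep_len(as.character(voxel_ids), nv),
                 roi_labels = rep_len(as.character(roi_labels), nv),
                 hemisphere = rep_len(as.character(hemisphere), nv)),
            class = "voxel_timecourses")
}

#' @export
print.voxel_timecourses <- function(x, ...) {
  cat("<voxel_timecourses> ", nrow(x$values), " voxels x ", ncol(x$values),
      " timepoints, TR ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.voxel_timecourses <- function(x, ...) {
  tibble::tibble(voxel_id = rep(x$voxel_ids, times = ncol(x$values)),
                 roi_label = rep(x$roi_labels, times = ncol(x$values)),
                 hemisphere = rep(x$hemisphere, times = ncol(x$values)),
                 frame = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
                 time_s = rep((seq_len(ncol(x$values)) - 1) * x$tr,
                              each = nrow(x$values)),
                 bold = as.vector(x$values))
}

#' Sample a ground-truth pRF population
#'
#' Draws voxel pRFs whose effective size increases linearly with
#' eccentricity — `size = slope * ecc + intercept + noise(scatter)` — with
#' eccentricities uniform over `ecc_range` and polar angles uniform over
#' the hemifield contralateral to the hemisphere label (left hemisphere
#' voxels represent the right visual field). The CSS exponent is held at
#' `n_mean` and the Gaussian width derived as `sigma = size * sqrt(n)`.
#'
#' @param roi_spec List with `slope` (dva/dva), `intercept` (dva),
#'   `ecc_range` (dva, length 2), `n_mean` (CSS exponent), `scatter`
#'   (residual sd of size about the line, dva).
#' @param n_voxels Number of voxels to draw.
#' @param hemisphere `"L"` or `"R"`.
#' @param roi_label ROI name carried through the pipeline.
#' @param seed Optional integer seed (fixed seed gives identical tables).
#' @return A tibble with columns `voxel_id`, `roi_label`, `hemisphere`,
#'   `x`, `y`, `sigma`, `n`, `g`, `ecc`, `size`.
#' @export
sample_ground_truth_prfs <- function(roi_spec = list(slope = 0.2,
                                                     intercept = 0.5,
                                                     ecc_range = c(0.5, 6.5),
                                                     n_mean = 0.5,
                                                     scatter = 0.1),
                                     n_voxels, hemisphere = "L",
                                     roi_label = "V1", seed = NULL) {
  stopifnot(n_voxels >= 0, hemisphere %in% c("L", "R"),
            length(roi_spec$ecc_range) == 2,
            roi_spec$n_mean > 0, roi_spec$n_mean <= 1)
  if (roi_spec$scatter < 0) stop("scatter must be non-negative")
  line_ends <- roi_spec$slope * roi_spec$ecc_range + roi_spec$intercept
  if (any(line_ends <= 0)) {
    stop("size-eccentricity line must be positive over ecc_range")
  }
  empty <- tibble::tibble(voxel_id = character(), roi_label = character(),
                          hemisphere = character(), x = numeric(),
                          y = numeric(), sigma = numeric(), n = numeric(),
                          g = numeric(), ecc = numeric(), size = numeric())
  if (n_voxels == 0) return(empty)

  with_seed(seed, {
    ecc <- stats::runif(n_voxels, roi_spec$ecc_range[1], roi_spec$ecc_range[2])
    theta <- if (hemisphere == "L") {
      stats::runif(n_voxels, -pi / 2, pi / 2)       # right visual field
    } else {
      stats::runif(n_voxels, pi / 2, 3 * pi / 2)    # left visual field
    }
    size <- roi_spec$slope * ecc + roi_spec$intercept +
      stats::rnorm(n_voxels, 0, roi_spec$scatter)
    size <- pmax(size, 0.05)
    g <- stats::runif(n_voxels, 0.5, 1.5)
    tibble::tibble(
      voxel_id = paste0(roi_label, "_", hemisphere, "_", seq_len(n_voxels)),
      roi_label = roi_label, hemisphere = hemisphere,
      x = ecc * cos(theta), y = ecc * sin(theta),
      sigma = size * sqrt(roi_spec$n_mean), n = roi_spec$n_mean, g = g,
      ecc = ecc, size = size)
  })
}

#' Simulate BOLD timecourses from a ground-truth pRF table
#'
#' Forward-models each voxel with the CSS model (identical to
#' [predict_timecourse()]) and adds independent Gaussian noise per
#' timepoint. Temporal autocorrelation is deliberately not modelled.
#'
#' @param truth A [sample_ground_truth_prfs()] table (nonempty).
#' @param apertures An [aperture_movie][generate_bar_apertures].
#' @param hrf An [hrf_spec()].
#' @param noise_sd Noise standard deviation in BOLD units; scalar or one
#'   value per voxel.
#' @param seed Optional integer seed.
#' @return A [voxel_timecourses()] object (rows match `truth`).
#' @export
simulate_bold <- function(truth, apertures, hrf = hrf_spec(), noise_sd = 0,
                          seed = NULL) {
  stopifnot(nrow(truth) >= 1, all(noise_sd >= 0))
  if (hrf$duration < apertures$tr) {
    stop("HRF support shorter than the movie TR: sampling-rate mismatch")
  }
  nv <- nrow(truth)
  tt <- n_frames(apertures)
  fm <- aperture_matrix(apertures)
  co <- aperture_coords(apertures)
  hmat <- conv_matrix(hrf_kernel(hrf, apertures$tr), tt)

  sig <- matrix(0, nv, tt)
  chunk <- 200L
  for (i0 in seq(1L, nv, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nv)
    d2 <- outer(co$x, truth$x[idx], "-")^2 + outer(co$y, truth$y[idx], "-")^2
    g <- exp(sweep(d2, 2, -1 / (2 * truth$sigma[idx]^2), "*"))
    drive <- sweep(fm %*% g, 2, truth$n[idx], "^")
    sig[idx, ] <- t(hmat %*% drive) * truth$g[idx]
  }

  sd_vec <- rep_len(noise_sd, nv)
  vals <- with_seed(seed, {
    sig + matrix(stats::rnorm(nv * tt, 0, rep(sd_vec, times = tt)), nv, tt)
  })
  voxel_timecourses(vals, apertures$tr, truth$voxel_id, truth$roi_label,
                    truth$hemisphere)
}

#' Synthetic gaze generator configuration
#'
#' Describes one participant group's free-viewing behaviour: fixations
#' scatter isotropically around each stimulus centre, displaced by a
#' group-level offset (screen-pixel convention: x rightward, y downward).
#'
#' @param n_participants Participants in the group.
#' @param n_fixations Fixations per participant per stimulus.
#' @param center_offset Group fixation bias `(dx, dy)` in screen px.
#' @param spread Isotropic fixation scatter sd, px.
#' @param fixation_duration_range Min/max fixation duration, ms.
#' @param seed Optional integer seed.
#' @return An object of class `gaze_config`.
#' @export
gaze_config <- function(n_participants = 6, n_fixations = 40,
                        center_offset = c(0, 0), spread = 25,
                        fixation_duration_range = c(150, 600), seed = NULL) {
  stopifnot(n_participants >= 1, n_fixations >= 1, spread > 0,
            length(center_offset) == 2,
            length(fixation_duration_range) == 2,
            all(fixation_duration_range > 0),
            diff(fixation_duration_range) >= 0)
  structure(list(n_participants = n_participants, n_fixations = n_fixations,
                 center_offset = center_offset, spread = spread,
                 fixation_duration_range = fixation_duration_range,
                 seed = seed),
            class = "gaze_config")
}

#' Simulate fixation records for a participant group
#'
#' Draws fixations around each stimulus box centre plus the group's
#' `center_offset`, with isotropic Gaussian spread; durations uniform over
#' the configured range; timestamps consecutive within a stimulus viewing.
#' Coordinates are clamped to the screen grid.
#'
#' @param cfg A [gaze_config()].
#' @param boxes Stimulus boxes: a tibble with `stimulus_id`, `cx`, `cy`
#'   (px) and optionally `half_size` (see [stimulus_boxes()]).
#' @param group Group label carried into the output.
#' @param screen Screen grid as `c(rows, cols)` px.
#' @return A tibble of fixations: `participant`, `group`, `stimulus_id`,
#'   `t_ms`, `x_px`, `y_px`, `duration_ms`.
#' @export
simulate_gaze <- function(cfg, boxes = stimulus_boxes(), group = "group",
                          screen = c(768, 1024)) {
  stopifnot(inherits(cfg, "gaze_config"),
            all(c("stimulus_id", "cx", "cy") %in% names(boxes)),
            all(boxes$cx >= 1 & boxes$cx <= screen[2]),
            all(boxes$cy >= 1 & boxes$cy <= screen[1]))
  tx <- boxes$cx + cfg$center_offset[1]
  ty <- boxes$cy + cfg$center_offset[2]
  if (any(tx < 1 | tx > screen[2] | ty < 1 | ty > screen[1])) {
    stop("center_offset pushes fixation mass off the screen grid")
  }
  with_seed(cfg$seed, {
    purrr::map_dfr(seq_len(cfg$n_participants), function(p) {
      purrr::map_dfr(seq_len(nrow(boxes)), function(b) {
        nf <- cfg$n_fixations
        x <- pmin(pmax(stats::rnorm(nf, tx[b], cfg$spread), 1), screen[2])
        y <- pmin(pmax(stats::rnorm(nf, ty[b], cfg$spread), 1), screen[1])
        dur <- stats::runif(nf, cfg$fixation_duration_range[1],
                            cfg$fixation_duration_range[2])
        tibble::tibble(participant = sprintf("%s_p%02d", group, p),
                       group = group,
                       stimulus_id = boxes$stimulus_id[b],
                       t_ms = cumsum(c(0, dur[-nf])),
                       x_px = x, y_px = y, duration_ms = dur)
      })
    })
  })
}

#' Centrally placed stimulus boxes
#'
#' Square stimulus regions near the screen centre, optionally jittered in
#' position (as free-viewing stimuli typically are).
#'
#' @param n Number of stimuli.
#' @param center Screen-centre pixel `(cx, cy)`.
#' @param half_size Half side length, px.
#' @param jitter Uniform positional jitter amplitude, px.
#' @param seed Optional integer seed.
#' @return A tibble with `stimulus_id`, `cx`, `cy`, `half_size`.
#' @export
stimulus_boxes <- function(n = 2, center = c(512, 384), half_size = 150,
                           jitter = 20, seed = NULL) {
  with_seed(seed, {
    tibble::tibble(
      stimulus_id = sprintf("stim%02d", seq_len(n)),
      cx = center[1] + stats::runif(n, -jitter, jitter),
      cy = center[2] + stats::runif(n, -jitter, jitter),
      half_size = half_size)
  })
}

#' Expand fixations into a raw gaze sample stream with blink events
#'
#' Converts fixation records into time-stamped samples at `rate_hz`, and
#' optionally injects blink intervals (marked by `blink_start` /
#' `blink_end` event rows) between fixations — the raw-stream form that
#' [scrub_blinks()] consumes.
#'
#' @param fixations A [simulate_gaze()] tibble.
#' @param rate_hz Sampling rate.
#' @param blink_prob Probability of a blink after each fixation.
#' @param blink_duration_ms Min/max blink duration.
#' @param seed Optional integer seed.
#' @return A tibble with `participant`, `stimulus_id`, `t_ms`, `x_px`,
#'   `y_px`, `event` (`"sample"`, `"blink_start"`, `"blink_end"`).
#' @export
gaze_samples <- function(fixations, rate_hz = 250, blink_prob = 0,
                         blink_duration_ms = c(100, 200), seed = NULL) {
  stopifnot(rate_hz > 0, blink_prob >= 0, blink_prob <= 1)
  step <- 1000 / rate_hz
  with_seed(seed, {
    fixations |>
      dplyr::group_by(.data$participant, .data$stimulus_id) |>
      dplyr::group_modify(function(df, key) {
        out <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
          ts <- seq(df$t_ms[i], df$t_ms[i] + df$duration_ms[i] - step / 2,
                    by = step)
          rows <- tibble::tibble(t_ms = ts, x_px = df$x_px[i],
                                 y_px = df$y_px[i], event = "sample")
          if (stats::runif(1) < blink_prob) {
            bdur <- stats::runif(1, blink_duration_ms[1],
                                 blink_duration_ms[2])
            b0 <- df$t_ms[i] + df$duration_ms[i]
            rows <- dplyr::bind_rows(rows, tibble::tibble(
              t_ms = c(b0, b0 + bdur), x_px = NA_real_, y_px = NA_real_,
              event = c("blink_start", "blink_end")))
          }
          rows
        })
        dplyr::arrange(out, .data$t_ms)
      }) |>
      dplyr::ungroup()
  })
}
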