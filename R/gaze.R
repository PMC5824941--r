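#' Remove blink-contaminated gaze samples
#'
#' Drops every sample falling within `[blink_start - pad_ms,
#' blink_end + pad_ms)` (half-open) around each blink, merging overlapping
#' scrub windows so no sample is double-counted. Applied per participant
#' and stimulus when those columns are present.
#'
#' @param samples Raw gaze stream: tibble with `t_ms` and `event`
#'   (`"sample"`, `"blink_start"`, `"blink_end"`), time-ordered within
#'   each participant/stimulus.
#' @param pad_ms Scrub window on either end of the blink, ms.
#' @return The cleaned stream (sample rows only).
#' @export
scrub_blinks <- function(samples, pad_ms = 100) {
  stopifnot("t_ms" %in% names(samples), "event" %in% names(samples),
            pad_ms >= 0)
  keys <- intersect(c("participant", "stimulus_id"), names(samples))
  scrub_one <- function(df, ...) {
    if (is.unsorted(df$t_ms)) stop("gaze samples must be time-ordered")
    starts <- df$t_ms[df$event == "blink_start"] - pad_ms
    ends <- df$t_ms[df$event == "blink_end"] + pad_ms
    if (length(starts) != length(ends)) {
      stop("unpaired blink_start/blink_end events")
    }
    keep <- df$event == "sample"
    if (length(starts) > 0) {
      # merge overlapping windows
      o <- order(starts)
      starts <- starts[o]
      ends <- cummax(ends[o])
      for (i in seq_along(starts)) {
        keep <- keep & !(df$t_ms >= starts[i] & df$t_ms < ends[i])
      }
    }
    df[keep, , drop = FALSE]
  }
  if (length(keys) > 0) {
    samples |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::group_modify(scrub_one) |>
      dplyr::ungroup()
  } else {
    scrub_one(samples)
  }
}

# Column-normalized 1D Gaussian smoothing matrix (output i from input j).
gauss_smooth_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  m <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  sweep(m, 2, colSums(m), "/")
}

new_density_map <- function(values, sigma_px, provenance = list()) {
  structure(list(values = values, sigma_px = sigma_px,
                 screen = dim(values), provenance = provenance),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map> ", x$screen[1], "x", x$screen[2],
      " px, smoothing sigma ", x$sigma_px, " px, max ",
      signif(max(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.density_map <- function(x, ...) {
  tibble::tibble(x_px = rep(seq_len(x$screen[2]), each = x$screen[1]),
                 y_px = rep(seq_len(x$screen[1]), times = x$screen[2]),
                 value = as.vector(x$values))
}

#' Fixation-density map for one participant
#'
#' Plots fixations as a duration-weighted 2D histogram on the screen
#' pixel grid, smooths with a Gaussian filter, and normalizes by the
#' participant's maximum so the peak is 1.
#'
#' @param fixations Tibble with `x_px`, `y_px`, `duration_ms` (screen
#'   pixel convention, y down).
#' @param sigma_px Smoothing sigma, px.
#' @param screen Grid as `c(rows, cols)`.
#' @param weight `"duration"` (fixation time) or `"count"` (one per
#'   fixation).
#' @return An object of class `density_map` (values in \[0, 1\], max 1).
#' @export
fixation_density <- function(fixations, sigma_px = 18.75,
                             screen = c(768, 1024),
                             weight = c("duration", "count")) {
  weight <- match.arg(weight)
  if (nrow(fixations) == 0) stop("no fixations: density undefined")
  stopifnot(sigma_px > 0)
  rows <- pmin(pmax(round(fixations$y_px), 1), screen[1])
  cols <- pmin(pmax(round(fixations$x_px), 1), screen[2])
  w <- if (weight == "duration") fixations$duration_ms else
    rep(1, nrow(fixations))
  stopifnot(all(w > 0))
  hist <- matrix(0, screen[1], screen[2])
  for (i in seq_along(rows)) {
    hist[rows[i], cols[i]] <- hist[rows[i], cols[i]] + w[i]
  }
  sy <- gauss_smooth_matrix(screen[1], sigma_px)
  sx <- gauss_smooth_matrix(screen[2], sigma_px)
  sm <- sy %*% hist %*% t(sx)
  new_density_map(sm / max(sm), sigma_px)
}

#' Group-average fixation density
#'
#' Pointwise mean of per-participant max-normalized density maps for one
#' stimulus.
#'
#' @param maps List of `density_map`s on the same grid.
#' @return A `density_map` (pointwise mean; not renormalized).
#' @export
group_density <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(purrr::map_lgl(maps, inherits, "density_map")))
  dims <- purrr::map(maps, "screen")
  if (!all(purrr::map_lgl(dims, identical, dims[[1]]))) {
    stop("density maps are on different grids")
  }
  vals <- Reduce(`+`, purrr::map(maps, "values")) / length(maps)
  new_density_map(vals, maps[[1]]$sigma_px,
                  provenance = list(group = TRUE, n = length(maps)))
}

#' Adult fixation zone (AFZ)
#'
#' For each pixel, the fraction of adult participants whose normalized
#' fixation density exceeds `presence_eps`; the AFZ is the set of pixels
#' where that fraction reaches the `overlap` criterion (70% of adults by
#' default).
#'
#' @param adult_maps List of per-adult `density_map`s for one stimulus.
#' @param overlap Required fraction of adults (inclusive).
#' @param presence_eps Density above which an adult counts as having
#'   fixated a pixel (fraction of that adult's max-normalized density).
#' @return An object of class `afz_mask`: logical matrix `mask` plus the
#'   per-pixel adult `fraction` map and the parameters.
#' @export
adult_fixation_zone <- function(adult_maps, overlap = 0.70,
                                presence_eps = 0.01) {
  stopifnot(length(adult_maps) >= 1, overlap >= 0, overlap <= 1,
            all(purrr::map_lgl(adult_maps, inherits, "density_map")))
  pres <- purrr::map(adult_maps, ~ (.x$values > presence_eps) * 1)
  frac <- Reduce(`+`, pres) / length(pres)
  structure(list(mask = frac >= overlap, fraction = frac,
                 overlap = overlap, presence_eps = presence_eps,
                 n_adults = length(adult_maps)),
            class = "afz_mask")
}

#' @export
print.afz_mask <- function(x, ...) {
  cat("<afz_mask> ", sum(x$mask), " px at overlap >= ", x$overlap,
      " across ", x$n_adults, " adults\n", sep = "")
  invisible(x)
}

#' Fraction of fixation time outside the adult fixation zone
#'
#' `(fixation time outside AFZ) / (total fixation time)` for one child and
#' stimulus: 0 means all fixations fell inside the AFZ, 1 all outside.
#' Compared against the 30% chance level implied by the AFZ's 70% overlap
#' definition.
#'
#' @param child_fix One child's fixations for the stimulus (`x_px`,
#'   `y_px`, `duration_ms`).
#' @param afz An [adult_fixation_zone()] mask.
#' @param weight `"duration"` or `"count"`.
#' @return Fraction in \[0, 1\].
#' @export
outside_afz_ratio <- function(child_fix, afz,
                              weight = c("duration", "count")) {
  weight <- match.arg(weight)
  stopifnot(inherits(afz, "afz_mask"), nrow(child_fix) >= 1)
  scr <- dim(afz$mask)
  rows <- pmin(pmax(round(child_fix$y_px), 1), scr[1])
  cols <- pmin(pmax(round(child_fix$x_px), 1), scr[2])
  w <- if (weight == "duration") child_fix$duration_ms else
    rep(1, nrow(child_fix))
  if (sum(w) <= 0) stop("total fixation time is zero")
  inside <- afz$mask[cbind(rows, cols)]
  sum(w[!inside]) / sum(w)
}

density_com_px <- function(values) {
  tot <- sum(values)
  if (tot <= 0) stop("density map has zero mass")
  nr <- nrow(values)
  nc <- ncol(values)
  cx <- sum(rep(seq_len(nc), each = nr) * as.vector(values)) / tot
  cy <- sum(rep(seq_len(nr), times = nc) * as.vector(values)) / tot
  c(x = cx, y = cy)
}

#' Fixation bias vector from the adult centre to the child centre
#'
#' The adult centre is the centre of mass of the adult group density
#' restricted to the adult fixation zone; the child centre is the centre
#' of mass of the child group density. The vector from the former to the
#' latter is reported in visual-field convention (y up), with its angle
#' (degrees, counterclockwise from rightward, in \[0, 360)) and magnitude
#' in pixels.
#'
#' @param child_map Child group `density_map`.
#' @param adult_map Adult group `density_map`.
#' @param afz The stimulus's [adult_fixation_zone()].
#' @param stimulus_id Optional label carried into the output.
#' @return A one-row tibble: `stimulus_id`, `dx`, `dy` (px, y up),
#'   `angle` (deg), `magnitude` (px).
#' @export
bias_vector <- function(child_map, adult_map, afz,
                        stimulus_id = NA_character_) {
  stopifnot(inherits(child_map, "density_map"),
            inherits(adult_map, "density_map"), inherits(afz, "afz_mask"))
  adult_center <- density_com_px(adult_map$values * afz$mask)
  child_center <- density_com_px(child_map$values)
  v <- screen_to_field(child_center["x"] - adult_center["x"],
                       child_center["y"] - adult_center["y"])
  ang <- (atan2(v$dy, v$dx) * 180 / pi) %% 360
  tibble::tibble(stimulus_id = stimulus_id,
                 dx = unname(v$dx), dy = unname(v$dy),
                 angle = unname(ang),
                 magnitude = unname(sqrt(v$dx^2 + v$dy^2)))
}

quadrant_bounds <- function(null_quadrant = c("lower-left", "lower-right")) {
  switch(match.arg(null_quadrant),
         "lower-left" = c(180, 270),
         "lower-right" = c(270, 360))
}

#' Angular distance of a vector from a visual-field quadrant
#'
#' Minimal absolute angular separation (wrapped on the circle) between an
#' angle and the nearest boundary of the quadrant; 0 for angles inside
#' it. A vector pointing 15 degrees into the upper-right quadrant is 105
#' degrees from the lower-left quadrant.
#'
#' @param angle Angle(s) in degrees.
#' @param null_quadrant `"lower-left"` or `"lower-right"`.
#' @return Angular distance(s) in degrees, in \[0, 135\].
#' @export
angular_distance_from_quadrant <- function(angle,
                                           null_quadrant = "lower-left") {
  b <- quadrant_bounds(null_quadrant)
  a <- angle %% 360
  inside <- a >= b[1] & a <= b[2]
  circ <- function(x, y) pmin(abs(x - y), 360 - abs(x - y))
  d <- pmin(circ(a, b[1]), circ(a, b[2]))
  ifelse(inside, 0, d)
}

#' Test bias vectors against the null quadrant
#'
#' Computes each bias vector's angular distance from the null quadrant
#' (the quadrant containing the region's visual-field coverage:
#' lower-left for faces, lower-right for words) and runs a one-sample
#' t-test of the distances against `mu`. Under uniformly random vector
#' angles, 25% would fall inside the quadrant.
#'
#' @param vectors Tibble of [bias_vector()] rows (>= 2), or a numeric
#'   vector of angles in degrees.
#' @param null_quadrant `"lower-left"` or `"lower-right"`.
#' @param mu Null mean angular distance for the t-test.
#' @return An object of class `quadrant_test` with `distances`,
#'   `frac_inside`, `chance` (0.25), and the t-test `t`, `df`, `p`.
#' @export
null_quadrant_test <- function(vectors, null_quadrant = "lower-left",
                               mu = 0) {
  angles <- if (is.numeric(vectors)) vectors else vectors$angle
  if (length(angles) < 2) stop("need at least 2 bias vectors")
  d <- angular_distance_from_quadrant(angles, null_quadrant)
  tt <- stats::t.test(d, mu = mu)
  structure(list(distances = d,
                 frac_inside = mean(d == 0), chance = 0.25,
                 null_quadrant = null_quadrant, mu = mu,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "quadrant_test")
}

#' @export
print.quadrant_test <- function(x, ...) {
  cat("<quadrant_test> mean distance from ", x$null_quadrant, " quadrant = ",
      signif(mean(x$distances), 4), " deg; t(", signif(x$df, 4), ") = ",
      signif(x$t, 4), ", p = ", signif(x$p, 4), "; ",
      signif(100 * x$frac_inside, 3), "% inside (chance 25%)\n", sep = "")
  invisible(x)
}

#' @export
tidy.quadrant_test <- function(x, ...) {
  tibble::tibble(mean_distance = mean(x$distances),
                 frac_inside = x$frac_inside, chance = x$chance,
                 statistic = x$t, df = x$df, p.value = x$p,
                 null_quadrant = x$null_quadrant)
}
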