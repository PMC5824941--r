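#' Predict a BOLD timecourse under the CSS pRF model
#'
#' The compressive spatial summation (CSS) model places an isotropic 2D
#' Gaussian receptive field (unit peak) at `(x, y)` with width `sigma`.
#' Each stimulus frame's overlap with the Gaussian is raised to the
#' exponent `n` (subadditive spatial summation for n < 1), the resulting
#' neural drive is convolved causally with the HRF, and scaled by the
#' gain `g`.
#'
#' @param prf A list or one-row data frame with fields `x`, `y`, `sigma`
#'   (dva), `n` (exponent in (0, 1]), `g` (gain).
#' @param apertures An [aperture_movie][generate_bar_apertures].
#' @param hrf An [hrf_spec()].
#' @return Numeric vector of length `n_frames(apertures)`.
#' @examples
#' ap <- generate_bar_apertures(grid_px = 41, steps_per_sweep = 6, n_blank = 0)
#' tc <- predict_timecourse(list(x = 1, y = 0, sigma = 1, n = 0.5, g = 1), ap)
#' @export
predict_timecourse <- function(prf, apertures, hrf = hrf_spec()) {
  prf <- as.list(prf)
  vals <- unlist(prf[c("x", "y", "sigma", "n", "g")])
  if (length(vals) != 5 || any(!is.finite(vals))) {
    stop("prf must have finite x, y, sigma, n, g")
  }
  stopifnot(prf$sigma > 0, prf$n > 0)
  fm <- aperture_matrix(apertures)
  co <- aperture_coords(apertures)
  gss <- exp(-((co$x - prf$x)^2 + (co$y - prf$y)^2) / (2 * prf$sigma^2))
  drive <- as.vector(fm %*% gss)^prf$n
  prf$g * convolve_causal(drive, hrf_kernel(hrf, apertures$tr))
}

#' Variance explained (R-squared about the mean)
#'
#' Fraction of the observed timecourse's variance (about its mean)
#' captured by the prediction: `1 - SS_res / SS_tot`. Negative raw values
#' are clamped to 0 and flagged via the `"clamped"` attribute.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2);
#'   `observed` must not be constant.
#' @return A fraction in \[0, 1\].
#' @examples
#' variance_explained(c(1, 2, 3, 4), c(1, 2, 3, 5))  # 0.8
#' @export
variance_explained <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2,
            all(is.finite(observed)), all(is.finite(predicted)))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) stop("observed timecourse is constant; R^2 undefined")
  ve <- 1 - sum((observed - predicted)^2) / ss_tot
  if (ve < 0) structure(0, clamped = TRUE) else ve
}

#' Fitting grid for the CSS model
#'
#' Describes the exhaustive search stage of [fit_prf()]: candidate pRF
#' centres, log-spaced widths starting at the model's sigma floor, and
#' exponents, plus the optional bounded derivative-free refinement.
#'
#' @param x,y Candidate centre coordinates, dva. Defaults to an evenly
#'   spaced grid over the stimulated field (resolved against the aperture
#'   movie at fit time).
#' @param sigma Candidate widths, dva; default log-spaced from
#'   `sigma_floor` to the field radius.
#' @param n Candidate exponents.
#' @param refine Run bounded optimisation from the best grid point.
#' @param sigma_floor Minimum admissible sigma, dva; also the smallest grid
#'   value.
#' @param n_xy Number of centre grid points per axis when `x`/`y` are
#'   defaulted.
#' @param n_sigma Number of sigma grid values when `sigma` is defaulted.
#' @param max_iter,tolerance Refinement iteration cap and convergence
#'   tolerance.
#' @return An object of class `fit_grid_spec`.
#' @export
fit_grid_spec <- function(x = NULL, y = NULL, sigma = NULL,
                          n = c(0.25, 0.5, 0.75, 1), refine = TRUE,
                          sigma_floor = 0.21, n_xy = 15, n_sigma = 10,
                          max_iter = 200, tolerance = 1e-8) {
  stopifnot(length(n) >= 1, all(n > 0), all(n <= 1), sigma_floor > 0,
            n_xy >= 3, n_sigma >= 2)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) >= 1, all(sigma > 0))
    sigma_floor <- min(sigma)
  }
  structure(list(x = x, y = y, sigma = sigma, n = sort(n), refine = refine,
                 sigma_floor = sigma_floor, n_xy = n_xy, n_sigma = n_sigma,
                 max_iter = max_iter, tolerance = tolerance),
            class = "fit_grid_spec")
}

# Fill defaulted grid axes from the movie geometry.
resolve_grid <- function(grid, apertures) {
  r <- apertures$field_radius
  if (is.null(grid$x)) grid$x <- seq(-r, r, length.out = grid$n_xy)
  if (is.null(grid$y)) grid$y <- seq(-r, r, length.out = grid$n_xy)
  if (is.null(grid$sigma)) {
    grid$sigma <- exp(seq(log(grid$sigma_floor), log(r),
                          length.out = grid$n_sigma))
  }
  grid
}

# Lower-triangular Toeplitz convolution matrix for an HRF kernel.
conv_matrix <- function(kernel, t_total) {
  h <- matrix(0, t_total, t_total)
  for (j in seq_len(t_total)) {
    i <- j:min(t_total, j + length(kernel) - 1)
    h[i, j] <- kernel[seq_along(i)]
  }
  h
}

# Precompute unit-gain candidate predictions for a (movie, HRF, grid).
build_candidates <- function(apertures, hrf, grid) {
  grid <- resolve_grid(grid, apertures)
  fm <- aperture_matrix(apertures)
  co <- aperture_coords(apertures)
  kern <- hrf_kernel(hrf, apertures$tr)
  hmat <- conv_matrix(kern, nrow(fm))

  sp <- tidyr::expand_grid(x = grid$x, y = grid$y, sigma = grid$sigma)
  drv <- matrix(0, nrow(fm), nrow(sp))
  chunk <- 400L
  for (i0 in seq(1L, nrow(sp), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(sp))
    d2 <- outer(co$x, sp$x[idx], "-")^2 + outer(co$y, sp$y[idx], "-")^2
    g <- exp(sweep(d2, 2, -1 / (2 * sp$sigma[idx]^2), "*"))
    drv[, idx] <- fm %*% g
  }

  params <- tidyr::expand_grid(n = grid$n, sp)
  pred <- matrix(0, nrow(fm), nrow(params))
  for (k in seq_along(grid$n)) {
    cols <- (k - 1L) * nrow(sp) + seq_len(nrow(sp))
    pred[, cols] <- hmat %*% (drv^grid$n[k])
  }
  list(pred = pred, params = params, pp = colSums(pred^2),
       hmat = hmat, fm = fm, co = co, grid = grid,
       field_radius = apertures$field_radius)
}

# Refinement objective: 1 - ve for positive-gain least squares fit.
css_objective <- function(par, cand, tc, ss_tot, offset) {
  sigma <- exp(par[3])
  gss <- exp(-((cand$co$x - par[1])^2 + (cand$co$y - par[2])^2) /
               (2 * sigma^2))
  drive <- as.vector(cand$fm %*% gss)^par[4]
  pred <- as.vector(cand$hmat %*% drive)
  cc <- sum(pred * tc)
  pp <- sum(pred^2)
  if (pp <= 0 || cc <= 0) return(1 + offset / ss_tot)
  1 - (cc^2 / pp - offset) / ss_tot
}

null_fit_row <- function(grid, flag) {
  tibble::tibble(x = 0, y = 0, sigma = grid$sigma_floor, n = 1, g = 0,
                 ve = 0, ecc = 0, size = grid$sigma_floor, flag = flag)
}

# Shared grid-search + refinement engine; tc_mat is voxels x T.
css_fit_engine <- function(tc_mat, cand) {
  grid <- cand$grid
  n_vox <- nrow(tc_mat)
  ss_raw <- rowSums(tc_mat^2)
  ss_tot <- ss_raw - nrow(cand$pred) * rowMeans(tc_mat)^2
  offset <- ss_raw - ss_tot  # T * mean^2

  cc <- crossprod(cand$pred, t(tc_mat))           # candidates x voxels
  score <- cc^2 / ifelse(cand$pp > 0, cand$pp, Inf)
  score[cc <= 0] <- 0

  purrr::map_dfr(seq_len(n_vox), function(v) {
    tc <- tc_mat[v, ]
    if (any(!is.finite(tc))) return(null_fit_row(grid, "nonfinite"))
    if (ss_tot[v] <= 0) return(null_fit_row(grid, "constant"))
    sc <- score[, v]
    if (all(sc <= 0)) return(null_fit_row(grid, "null"))
    best <- which.max(sc)  # first-encountered tie-break in grid order
    par <- c(cand$params$x[best], cand$params$y[best],
             log(cand$params$sigma[best]), cand$params$n[best])
    if (isTRUE(grid$refine)) {
      r <- cand$field_radius
      opt <- tryCatch(
        stats::optim(par, css_objective, cand = cand, tc = tc,
                     ss_tot = ss_tot[v], offset = offset[v],
                     method = "L-BFGS-B",
                     lower = c(-1.5 * r, -1.5 * r, log(grid$sigma_floor),
                               0.05),
                     upper = c(1.5 * r, 1.5 * r, log(2 * r), 1),
                     control = list(maxit = grid$max_iter,
                                    factr = grid$tolerance / 1e-15)),
        error = function(e) NULL)
      if (!is.null(opt) &&
          opt$value <= css_objective(par, cand, tc, ss_tot[v], offset[v])) {
        par <- opt$par
      }
    }
    sigma <- exp(par[3])
    gss <- exp(-((cand$co$x - par[1])^2 + (cand$co$y - par[2])^2) /
                 (2 * sigma^2))
    pred <- as.vector(cand$hmat %*% (as.vector(cand$fm %*% gss)^par[4]))
    ppv <- sum(pred^2)
    ccv <- sum(pred * tc)
    if (ppv <= 0 || ccv <= 0) return(null_fit_row(grid, "null"))
    g <- ccv / ppv
    ve_raw <- 1 - sum((tc - g * pred)^2) / ss_tot[v]
    tibble::tibble(x = par[1], y = par[2], sigma = sigma, n = par[4], g = g,
                   ve = max(ve_raw, 0),
                   ecc = sqrt(par[1]^2 + par[2]^2),
                   size = effective_size(sigma, par[4]),
                   flag = if (ve_raw < 0) "ve_clamped" else "ok")
  })
}

#' Fit the CSS pRF model to a single voxel timecourse
#'
#' Two-stage fit: an exhaustive grid search over (x, y, sigma, n) with the
#' gain solved in closed form per candidate (positive least-squares scalar
#' projection), followed by bounded derivative-free refinement from the
#' best grid point. Ties are broken by the first candidate in deterministic
#' grid order.
#'
#' @param tc Numeric timecourse of length `n_frames(apertures)`.
#' @param apertures An [aperture_movie][generate_bar_apertures].
#' @param hrf An [hrf_spec()].
#' @param grid A [fit_grid_spec()].
#' @return A one-row tibble with `x`, `y`, `sigma`, `n`, `g`, `ve`,
#'   derived `ecc` and `size` (= sigma/sqrt(n)), and a `flag` column
#'   ("ok", "null", "nonfinite", "constant", or "ve_clamped").
#' @export
fit_prf <- function(tc, apertures, hrf = hrf_spec(), grid = fit_grid_spec()) {
  stopifnot(length(tc) == n_frames(apertures))
  cand <- build_candidates(apertures, hrf, grid)
  css_fit_engine(matrix(tc, nrow = 1), cand)
}

#' Fit the CSS model to every voxel of a timecourse set
#'
#' Shares one precomputed candidate-prediction matrix across voxels, then
#' fits each voxel independently in input order. Per-voxel failures are
#' propagated as flagged rows rather than aborting the batch.
#'
#' @param tcs A [voxel_timecourses()] object, or a voxels x T matrix.
#' @param candidates Precomputed candidate predictions (internal; lets
#'   several populations fitted against the same movie, HRF and grid
#'   share the grid-search stage).
#' @inheritParams fit_prf
#' @return A tibble with one row per voxel: `voxel_id`, `roi_label`,
#'   `hemisphere`, and the [fit_prf()] columns.
#' @export
fit_population <- function(tcs, apertures, hrf = hrf_spec(),
                           grid = fit_grid_spec(), candidates = NULL) {
  if (inherits(tcs, "voxel_timecourses")) {
    meta <- tibble::tibble(voxel_id = tcs$voxel_ids,
                           roi_label = tcs$roi_labels,
                           hemisphere = tcs$hemisphere)
    vals <- tcs$values
  } else {
    vals <- as.matrix(tcs)
    meta <- tibble::tibble(voxel_id = paste0("v", seq_len(nrow(vals))),
                           roi_label = NA_character_,
                           hemisphere = NA_character_)
  }
  stopifnot(nrow(vals) >= 1, ncol(vals) == n_frames(apertures))
  cand <- if (is.null(candidates)) build_candidates(apertures, hrf, grid)
          else candidates
  dplyr::bind_cols(meta, css_fit_engine(vals, cand))
}

#' Apply the standard pRF exclusion filters
#'
#' Keeps voxels whose model fit explains more than `ve_min` of the
#' variance, whose centre lies inside the stimulated field
#' (eccentricity <= `ecc_max`), and whose sigma sits above the model's
#' floor value. Per-rule exclusion counts are attached as the
#' `"exclusion_log"` attribute (see [exclusion_log()]).
#'
#' @param fits A pRF fit tibble (from [fit_population()]).
#' @param ve_min Variance-explained threshold (exclusive).
#' @param ecc_max Maximum centre eccentricity, dva (inclusive).
#' @param sigma_floor Sigma floor, dva (exclusive).
#' @return The surviving rows, with an `exclusion_log` attribute.
#' @export
filter_fits <- function(fits, ve_min = 0.05, ecc_max = 7,
                        sigma_floor = 0.21) {
  fail_ve <- !(fits$ve > ve_min)
  fail_ecc <- !(fits$ecc <= ecc_max)
  fail_sigma <- !(fits$sigma > sigma_floor)
  out <- fits[!(fail_ve | fail_ecc | fail_sigma), , drop = FALSE]
  attr(out, "exclusion_log") <- list(
    n_in = nrow(fits), n_out = nrow(out),
    excluded_low_ve = sum(fail_ve),
    excluded_outside_field = sum(fail_ecc),
    excluded_sigma_floor = sum(fail_sigma),
    ve_min = ve_min, ecc_max = ecc_max, sigma_floor = sigma_floor)
  out
}

#' @rdname filter_fits
#' @param x A table returned by [filter_fits()].
#' @export
exclusion_log <- function(x) attr(x, "exclusion_log")

#' Effective pRF size under compressive summation
#'
#' The CSS model's effective receptive-field size, `sigma / sqrt(n)`:
#' compression (n < 1) widens the region of space that drives the voxel
#' relative to the Gaussian's nominal width.
#'
#' @param sigma Gaussian width, dva (> 0).
#' @param n CSS exponent (> 0).
#' @return Effective size in dva.
#' @examples
#' effective_size(2, 0.25)  # 4
#' @export
effective_size <- function(sigma, n) {
  stopifnot(all(sigma > 0), all(n > 0))
  sigma / sqrt(n)
}
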