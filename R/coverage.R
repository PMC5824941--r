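#' Visual-field sampling grid for coverage maps
#'
#' Square grid of cell-centre coordinates spanning
#' `[-field_radius, field_radius]` on both axes (visual-field convention,
#' y up).
#'
#' @param field_radius Field radius, dva.
#' @param n Grid points per side.
#' @return An object of class `coverage_grid` with coordinate vectors
#'   `x`, `y` (ascending), `field_radius`, `n`.
#' @export
coverage_grid <- function(field_radius = 7, n = 128) {
  stopifnot(field_radius > 0, n >= 8)
  xs <- seq(-field_radius, field_radius, length.out = n)
  structure(list(x = xs, y = xs, field_radius = field_radius, n = n),
            class = "coverage_grid")
}

new_coverage_map <- function(values, grid, combine_rule = "mean",
                             provenance = list()) {
  stopifnot(inherits(grid, "coverage_grid"),
            nrow(values) == length(grid$y), ncol(values) == length(grid$x))
  structure(list(values = values, grid = grid, combine_rule = combine_rule,
                 provenance = provenance),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat("<coverage_map> ", nrow(x$values), "x", ncol(x$values),
      " over [-", x$grid$field_radius, ", ", x$grid$field_radius,
      "] dva, combine rule '", x$combine_rule, "', max ",
      signif(max(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.coverage_map <- function(x, ...) {
  co <- grid_flat(x$grid)
  vals <- as.vector(x$values)
  tibble::tibble(x = co$x, y = co$y, value = vals)
}

# Flattened coordinates aligned with as.vector(values) (column-major).
grid_flat <- function(grid) {
  h <- length(grid$y)
  list(x = rep(grid$x, each = h), y = rep(grid$y, times = length(grid$x)))
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y))
}

# P x V matrix of unit-peak densities, one column per fitted voxel.
density_columns <- function(fits, grid) {
  co <- grid_flat(grid)
  d2 <- outer(co$x, fits$x, "-")^2 + outer(co$y, fits$y, "-")^2
  exp(sweep(d2, 2, -1 / (2 * fits$size^2), "*"))
}

#' Unit-peak density of a single fitted pRF
#'
#' Isotropic Gaussian at the fitted centre with width equal to the CSS
#' effective size, peak value exactly 1.
#'
#' @param fit One fitted voxel (one-row tibble with `x`, `y`, `size`).
#' @param grid A [coverage_grid()].
#' @return A `coverage_map` for the single voxel.
#' @export
voxel_density <- function(fit, grid = coverage_grid()) {
  stopifnot(nrow(fit) == 1, fit$size > 0)
  vals <- matrix(density_columns(fit, grid), length(grid$y), length(grid$x))
  new_coverage_map(vals, grid, combine_rule = "single",
                   provenance = list(voxel_id = fit$voxel_id))
}

#' Bootstrapped visual field coverage of an ROI
#'
#' For each bootstrap iteration, `n` voxels are drawn with replacement
#' from the ROI's `n` filtered fits, their unit-peak densities combined
#' pointwise (`mean` or `max`), and the combined map renormalized to peak
#' 1. The final coverage is the mean over iterations, again renormalized
#' to peak 1.
#'
#' @param fits Filtered pRF fits for one participant's ROI (nonempty).
#' @param grid A [coverage_grid()].
#' @param combine_rule `"mean"` (average density across pRFs) or `"max"`
#'   (maximum pRF density).
#' @param n_boot Bootstrap iterations (default 50).
#' @param seed Optional integer seed.
#' @param provenance Optional list of labels (participant, ROI,
#'   hemisphere) carried on the map.
#' @return A `coverage_map` with values in \[0, 1\] and max 1.
#' @export
roi_coverage <- function(fits, grid = coverage_grid(),
                         combine_rule = c("mean", "max"), n_boot = 50,
                         seed = NULL, provenance = list()) {
  combine_rule <- match.arg(combine_rule)
  if (nrow(fits) == 0) stop("no fitted voxels: cannot compute coverage")
  stopifnot(n_boot >= 1)
  dens <- density_columns(fits, grid)
  nv <- ncol(dens)
  acc <- with_seed(seed, {
    total <- 0
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nv, nv, replace = TRUE)
      comb <- if (combine_rule == "mean") {
        rowMeans(dens[, idx, drop = FALSE])
      } else {
        do.call(pmax, as.data.frame(dens[, idx, drop = FALSE]))
      }
      total <- total + comb / max(comb)
    }
    total / n_boot
  })
  vals <- matrix(acc / max(acc), length(grid$y), length(grid$x))
  new_coverage_map(vals, grid, combine_rule, provenance)
}

#' Group-average coverage with hemifield flipping
#'
#' Averages per-participant coverage maps pointwise. With
#' `flip_rh = TRUE`, maps whose provenance hemisphere is `"R"` are first
#' mirrored over the vertical meridian so both hemispheres share the
#' contralateral convention. The group map is not renormalized (inputs
#' are already peak-1).
#'
#' @param maps List of `coverage_map`s sharing one grid.
#' @param flip_rh Mirror right-hemisphere maps about x = 0 first.
#' @return A `coverage_map` (pointwise mean).
#' @export
group_coverage <- function(maps, flip_rh = TRUE) {
  stopifnot(length(maps) >= 1,
            all(purrr::map_lgl(maps, inherits, "coverage_map")))
  g0 <- maps[[1]]$grid
  if (!all(purrr::map_lgl(maps, ~ grids_identical(.x$grid, g0)))) {
    stop("coverage maps are on different grids")
  }
  vals <- purrr::map(maps, function(m) {
    v <- m$values
    if (flip_rh && identical(m$provenance$hemisphere, "R")) {
      v <- v[, rev(seq_len(ncol(v))), drop = FALSE]
    }
    v
  })
  new_coverage_map(Reduce(`+`, vals) / length(vals), g0,
                   combine_rule = maps[[1]]$combine_rule,
                   provenance = list(group = TRUE, n = length(maps)))
}

#' Visual-field extent of a coverage map
#'
#' Binarizes the map (coverage below `binarize_at` set to zero) and scales
#' the covered proportion of in-field grid points by the stimulated area
#' `pi * field_radius^2`, giving square degrees of visual angle.
#'
#' @param map A `coverage_map`.
#' @param binarize_at Density threshold; values >= threshold count as
#'   covered.
#' @param field_radius Field radius, dva (defaults to the map's).
#' @return Extent in square dva.
#' @export
coverage_extent <- function(map, binarize_at = 0.01, field_radius = NULL) {
  if (is.null(field_radius)) field_radius <- map$grid$field_radius
  co <- grid_flat(map$grid)
  in_field <- co$x^2 + co$y^2 <= field_radius^2
  prop <- mean(as.vector(map$values)[in_field] >= binarize_at)
  prop * pi * field_radius^2
}

#' Centre of mass of a coverage map
#'
#' Density-weighted centroid over in-field grid points; its Euclidean
#' distance from the origin indexes the foveal bias of the coverage.
#'
#' @param map A `coverage_map` with positive total in-field mass.
#' @return A tibble with `x`, `y` (dva) and `distance` from fixation.
#' @export
coverage_com <- function(map) {
  co <- grid_flat(map$grid)
  in_field <- co$x^2 + co$y^2 <= map$grid$field_radius^2
  w <- as.vector(map$values)[in_field]
  if (sum(w) <= 0) stop("coverage map has zero in-field mass")
  cx <- sum(co$x[in_field] * w) / sum(w)
  cy <- sum(co$y[in_field] * w) / sum(w)
  tibble::tibble(x = cx, y = cy, distance = sqrt(cx^2 + cy^2))
}

#' Leave-one-out jackknife standard error
#'
#' Recomputes the statistic on each leave-one-out subsample and returns
#' `sqrt((n - 1) / n * sum((theta_i - mean(theta))^2))`. For the mean this
#' equals the classical `sd/sqrt(n)`.
#'
#' @param values Per-participant statistic values (n >= 2).
#' @param statistic_fn Function applied to each subsample.
#' @return The jackknife standard error.
#' @examples
#' jackknife_se(c(1, 2, 3))  # 1/sqrt(3)
#' @export
jackknife_se <- function(values, statistic_fn = mean) {
  n <- length(values)
  if (n < 2) stop("jackknife requires at least 2 participants")
  loo <- vapply(seq_len(n), function(i) statistic_fn(values[-i]), numeric(1))
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}
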