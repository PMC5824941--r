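#' Variance-weighted pRF size vs. eccentricity regression
#'
#' Linear regression of effective pRF size on eccentricity in which each
#' voxel's contribution is weighted by the variance explained of its model
#' fit. Fit per participant and ROI; slopes and intercepts are then
#' averaged across participants downstream.
#'
#' @param fits pRF fit tibble with `ecc`, `size`, `ve` columns.
#' @param ve_min Voxels at or below this variance explained are dropped
#'   before fitting.
#' @return An object of class `size_ecc_fit` with `slope`, `intercept`,
#'   `n_points`, and the underlying `lm` fit.
#' @export
size_ecc_fit <- function(fits, ve_min = 0.05) {
  d <- dplyr::filter(fits, .data$ve > ve_min)
  if (nrow(d) < 2 || length(unique(d$ecc)) < 2) {
    stop("size-eccentricity fit needs >= 2 voxels with distinct eccentricities")
  }
  fit <- stats::lm(size ~ ecc, data = d, weights = d$ve)
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) stop("degenerate size-eccentricity fit")
  structure(list(slope = unname(cf["ecc"]),
                 intercept = unname(cf["(Intercept)"]),
                 n_points = nrow(d), model = fit),
            class = "size_ecc_fit")
}

#' @export
print.size_ecc_fit <- function(x, ...) {
  cat("<size_ecc_fit> size = ", signif(x$slope, 4), " * ecc + ",
      signif(x$intercept, 4), " (", x$n_points,
      " voxels, ve-weighted)\n", sep = "")
  invisible(x)
}

#' @export
tidy.size_ecc_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.size_ecc_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = s$r.squared, n_points = x$n_points)
}

as_xy <- function(points, name) {
  if (is.matrix(points)) points <- tibble::tibble(x = points[, 1],
                                                  y = points[, 2])
  if (!all(c("x", "y") %in% names(points)) || nrow(points) < 1) {
    stop(name, " must be a nonempty set of (x, y) points")
  }
  points
}

# Empirical fraction of (px, py) in each open quadrant around each origin.
quadrant_fracs <- function(ox, oy, px, py) {
  gx <- outer(ox, px, "<")
  lx <- outer(ox, px, ">")
  gy <- outer(oy, py, "<")
  ly <- outer(oy, py, ">")
  cbind(rowMeans(gx & gy), rowMeans(lx & gy),
        rowMeans(lx & ly), rowMeans(gx & ly))
}

ks2d_statistic <- function(a, b) {
  ox <- c(a$x, b$x)
  oy <- c(a$y, b$y)
  max(abs(quadrant_fracs(ox, oy, a$x, a$y) -
            quadrant_fracs(ox, oy, b$x, b$y)))
}

# Survival function of the Kolmogorov distribution.
ks_q <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
}

#' Two-dimensional two-sample Kolmogorov-Smirnov test
#'
#' Nonparametric comparison of two bivariate samples. The statistic D is
#' the largest absolute difference between the two samples' empirical
#' fractions over the four axis-aligned quadrants anchored at every data
#' point of either sample. The p-value comes from a label-permutation
#' null (default) or from the classic large-sample approximation with the
#' correlation correction.
#'
#' @param points_a,points_b Data frames (or 2-column matrices) of `x`, `y`
#'   points.
#' @param p_method `"permutation"` or `"asymptotic"`.
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed for the permutation null.
#' @return An object of class `ks2d_result` with `D`, `p`, `n_a`, `n_b`,
#'   `method`.
#' @export
ks2d_two_sample <- function(points_a, points_b,
                            p_method = c("permutation", "asymptotic"),
                            n_perm = 1000, seed = NULL) {
  p_method <- match.arg(p_method)
  a <- as_xy(points_a, "points_a")
  b <- as_xy(points_b, "points_b")
  na <- nrow(a)
  nb <- nrow(b)
  d_obs <- ks2d_statistic(a, b)

  p <- if (p_method == "permutation") {
    px <- c(a$x, b$x)
    py <- c(a$y, b$y)
    n <- na + nb
    gx <- outer(px, px, "<")
    lx <- outer(px, px, ">")
    gy <- outer(py, py, "<")
    ly <- outer(py, py, ">")
    qall <- rbind(gx & gy, lx & gy, lx & ly, gx & ly) * 1  # 4n x n
    rs <- rowSums(qall)
    labels <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        l <- numeric(n)
        l[sample.int(n, na)] <- 1
        l
      }, numeric(n))
    })
    va <- qall %*% labels                                  # 4n x n_perm
    d_perm <- apply(abs(va / na - (rs - va) / nb), 2, max)
    (1 + sum(d_perm >= d_obs - 1e-12)) / (n_perm + 1)
  } else {
    n_eff <- na * nb / (na + nb)
    safe_cor <- function(s) {
      if (nrow(s) < 2 || stats::sd(s$x) == 0 || stats::sd(s$y) == 0) 0
      else stats::cor(s$x, s$y)
    }
    r2 <- (safe_cor(a)^2 + safe_cor(b)^2) / 2
    sq <- sqrt(n_eff)
    ks_q(d_obs * sq / (1 + sqrt(1 - r2) * (0.25 - 0.75 / sq)))
  }

  structure(list(D = d_obs, p = p, n_a = na, n_b = nb, method = p_method,
                 n_perm = if (p_method == "permutation") n_perm else NA),
            class = "ks2d_result")
}

#' @export
print.ks2d_result <- function(x, ...) {
  cat("<ks2d_result> D = ", signif(x$D, 4), ", p = ", signif(x$p, 4),
      " (", x$method, "), n = ", x$n_a, " vs ", x$n_b, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ks2d_result <- function(x, ...) {
  tibble::tibble(statistic = x$D, p.value = x$p, n_a = x$n_a, n_b = x$n_b,
                 method = x$method)
}

#' @export
glance.ks2d_result <- function(x, ...) tidy.ks2d_result(x)

#' Sample visual-field points from coverage maps
#'
#' Draws density-weighted grid-point samples from each participant's
#' coverage map and pools them, producing the bivariate point sets the
#' two-dimensional KS test compares across groups.
#'
#' @param maps A `coverage_map` or list of them (one per participant).
#' @param samples_per_map Points drawn per map.
#' @param seed Optional integer seed.
#' @return A tibble with `x`, `y` (dva) and `map` index.
#' @export
coverage_to_points <- function(maps, samples_per_map = 500, seed = NULL) {
  if (inherits(maps, "coverage_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1, samples_per_map >= 1)
  with_seed(seed, {
    purrr::map_dfr(seq_along(maps), function(i) {
      m <- maps[[i]]
      w <- as.vector(m$values)
      if (sum(w) <= 0) stop("coverage map ", i, " has zero mass")
      co <- grid_flat(m$grid)
      idx <- sample.int(length(w), samples_per_map, replace = TRUE,
                        prob = w)
      tibble::tibble(x = co$x[idx], y = co$y[idx], map = i)
    })
  })
}

#' Pearson correlation between a derived measure and age
#'
#' @param values Per-participant scalar (e.g. mean pRF size).
#' @param ages Participant ages, years.
#' @return A tibble with `r`, `n`, `p`.
#' @export
pearson_age_correlation <- function(values, ages) {
  stopifnot(length(values) == length(ages))
  if (length(values) < 3) stop("need at least 3 participants")
  if (stats::sd(values) == 0 || stats::sd(ages) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(values, ages)
  tibble::tibble(r = unname(ct$estimate), n = length(values),
                 p = ct$p.value)
}
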