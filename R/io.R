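#' Read and write tab-delimited result tables
#'
#' Plain-text table IO with a commented `# key: value` header. Declared
#' columns round-trip losslessly; unknown columns are preserved.
#'
#' @param df A data frame.
#' @param path File path.
#' @param comments Named list written as `# key: value` header lines.
#' @return `write_table_tsv()` returns `path` invisibly;
#'   `read_table_tsv()` returns a tibble.
#' @export
write_table_tsv <- function(df, path, comments = list()) {
  lines <- character(0)
  if (length(comments) > 0) {
    lines <- paste0("# ", names(comments), ": ",
                    vapply(comments, function(x) paste(x, collapse = " "),
                           character(1)))
  }
  writeLines(lines, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @param required Column names that must be present; a missing one raises
#'   an error naming it.
#' @export
read_table_tsv <- function(path, required = character()) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read and write coverage maps as plain text
#'
#' A coverage map is stored as `# key: value` sidecar lines (grid size,
#' field radius, combine rule) followed by the tab-delimited value matrix.
#'
#' @param map A `coverage_map`.
#' @param path File path.
#' @return `write_coverage_map()` returns `path` invisibly;
#'   `read_coverage_map()` returns the reconstructed `coverage_map`.
#' @export
write_coverage_map <- function(map, path) {
  stopifnot(inherits(map, "coverage_map"))
  header <- c(paste0("# field_radius: ", map$grid$field_radius),
              paste0("# n: ", map$grid$n),
              paste0("# combine_rule: ", map$combine_rule))
  writeLines(header, path)
  utils::write.table(map$values, path, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_map
#' @export
read_coverage_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get_key <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m) == 0) stop("coverage map header missing key: ", key)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  vals <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")],
                                      sep = "\t"))
  dimnames(vals) <- NULL
  grid <- coverage_grid(field_radius = as.numeric(get_key("field_radius")),
                        n = as.integer(get_key("n")))
  new_coverage_map(vals, grid, combine_rule = get_key("combine_rule"))
}

#' Pipeline configuration
#'
#' Bundles every tunable constant of the end-to-end synthetic analysis:
#' stimulus geometry, fitting thresholds (variance explained > 0.05,
#' eccentricity <= 7 dva, sigma floor 0.21 dva), coverage settings
#' (binarize at 0.01, 50 bootstrap iterations), gaze settings (100 ms
#' blink pad, 18.75 px smoothing, 70% AFZ overlap), synthetic population
#' sizes, and the master seed from which every stage seed is derived.
#'
#' @param ... Overrides of the documented defaults (unknown keys are
#'   rejected).
#' @return An object of class `prf_config`.
#' @export
prf_config <- function(...) {
  cfg <- list(
    field_radius = 7, tr = 2, bar_width = 2, grid_px = 101,
    steps_per_sweep = 12, n_blank = 6,
    ve_min = 0.05, ecc_max = 7, sigma_floor = 0.21,
    coverage_binarize = 0.01, coverage_n = 128, n_boot = 50,
    combine_rule = "mean", refine = TRUE,
    n_voxels = 60, n_participants = 3, noise_frac = 0.1,
    roi_spec = list(slope = 0.2, intercept = 0.5, ecc_range = c(0.5, 6.5),
                    n_mean = 0.5, scatter = 0.1),
    samples_per_map = 300, n_perm_ks = 199,
    n_gaze_participants = 4, n_fixations = 40, gaze_spread = 25,
    child_offset = c(60, -60), n_stimuli = 2,
    afz_overlap = 0.70, afz_presence_eps = 0.01,
    blink_pad_ms = 100, smoothing_px = 18.75,
    null_quadrant = "lower-left",
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  with(cfg, stopifnot(
    field_radius > 0, tr > 0, bar_width > 0, grid_px >= 32,
    ve_min >= 0, ve_min <= 1, ecc_max > 0, sigma_floor > 0,
    coverage_binarize >= 0, coverage_binarize <= 1,
    afz_overlap >= 0, afz_overlap <= 1, blink_pad_ms >= 0,
    smoothing_px > 0, n_boot >= 1, noise_frac >= 0,
    n_voxels >= 1, n_participants >= 1, n_gaze_participants >= 1,
    n_stimuli >= 1, seed == round(seed)))
  structure(cfg, class = "prf_config")
}

# Deterministic per-stage seed below 2^31.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + k * 10007) %% 2147483647)
}

#' @export
print.prf_config <- function(x, ...) {
  cat("<prf_config> seed ", x$seed, ", ", x$n_participants,
      " participants/group x ", x$n_voxels, " voxels, ",
      x$n_gaze_participants, " gaze participants/group\n", sep = "")
  invisible(x)
}
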