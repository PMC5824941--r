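#' Run the end-to-end synthetic analysis pipeline
#'
#' Orchestrates simulate -> fit -> filter -> coverage -> group statistics
#' -> gaze analysis on synthetic data with known ground truth: generates
#' the bar-sweep aperture movie, simulates two participant groups
#' ("children", "adults") of CSS voxel populations, fits and filters
#' pRFs, builds bootstrapped coverage maps with extent / centre-of-mass /
#' jackknife statistics and the two-dimensional KS group comparison, and
#' runs the fixation-density / AFZ / bias-vector gaze analysis with a
#' configured child fixation bias.
#'
#' Every stochastic stage consumes a named seed derived from
#' `config$seed`, so a fixed config reproduces every artifact bit for
#' bit.
#'
#' @param config A [prf_config()].
#' @param out_dir Optional directory; when given, fit tables, coverage
#'   maps, stats tables, the manifest and the report are written there as
#'   plain text.
#' @param verbose Print stage progress.
#' @return An object of class `prf_pipeline`: a list with `config`,
#'   `manifest`, `truth`, `fits`, `filtered`, `coverage` (per-participant
#'   maps), `group_maps`, `stats`, `gaze`, and the text `report`.
#' @export
run_pipeline <- function(config = prf_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "prf_config"))
  say <- function(...) if (verbose) message(...)
  seeds <- list(truth = stage_seed(config$seed, 1),
                noise = stage_seed(config$seed, 2),
                boot = stage_seed(config$seed, 3),
                ks = stage_seed(config$seed, 4),
                gaze = stage_seed(config$seed, 5),
                boxes = stage_seed(config$seed, 6))

  say("stage: stimulus apertures")
  ap <- generate_bar_apertures(field_radius = config$field_radius,
                               bar_width = config$bar_width,
                               grid_px = config$grid_px,
                               steps_per_sweep = config$steps_per_sweep,
                               tr = config$tr, n_blank = config$n_blank)
  hrf <- hrf_spec()
  grid <- fit_grid_spec(refine = config$refine,
                        sigma_floor = config$sigma_floor)

  say("stage: simulate + fit voxel populations")
  groups <- c("children", "adults")
  participants <- tidyr::expand_grid(group = groups,
                                     pid = seq_len(config$n_participants))
  participants$participant <- paste0(participants$group, "_p",
                                     participants$pid)
  participants$hemisphere <- ifelse(participants$pid %% 2 == 1, "L", "R")

  cand <- build_candidates(ap, hrf, grid)
  per_part <- purrr::pmap(participants, function(group, pid, participant,
                                                 hemisphere) {
    k <- which(participants$participant == participant)
    truth <- sample_ground_truth_prfs(config$roi_spec, config$n_voxels,
                                      hemisphere = hemisphere,
                                      seed = stage_seed(seeds$truth, k))
    clean <- simulate_bold(truth, ap, hrf, noise_sd = 0)
    sig_sd <- apply(clean$values, 1, stats::sd)
    tcs <- simulate_bold(truth, ap, hrf,
                         noise_sd = config$noise_frac * sig_sd,
                         seed = stage_seed(seeds$noise, k))
    fits <- fit_population(tcs, ap, hrf, grid, candidates = cand) |>
      dplyr::mutate(group = group, participant = participant,
                    .before = 1)
    list(truth = dplyr::mutate(truth, group = group,
                               participant = participant, .before = 1),
         fits = fits)
  })
  truth_all <- purrr::map_dfr(per_part, "truth")
  fits_all <- purrr::map_dfr(per_part, "fits")
  filtered <- filter_fits(fits_all, ve_min = config$ve_min,
                          ecc_max = config$ecc_max,
                          sigma_floor = config$sigma_floor)
  excl <- exclusion_log(filtered)

  report <- c("Synthetic pRF coverage and gaze-bias pipeline",
              paste0("seed: ", config$seed),
              paste0("voxels fit: ", nrow(fits_all),
                     "; survivors after exclusion filters: ",
                     nrow(filtered)))

  stats_out <- list(exclusions = excl)
  cov_maps <- list()
  group_maps <- list()
  gaze_out <- list()

  if (nrow(filtered) == 0) {
    report <- c(report,
                "WARNING: zero voxels survived the exclusion filters; ",
                "coverage and group statistics skipped")
  } else {
    say("stage: coverage maps")
    cgrid <- coverage_grid(config$field_radius, config$coverage_n)
    keep <- dplyr::group_by(filtered, .data$group, .data$participant)
    cov_maps <- dplyr::group_split(keep) |>
      purrr::map(function(d) {
        k <- which(participants$participant == d$participant[1])
        roi_coverage(d, cgrid, combine_rule = config$combine_rule,
                     n_boot = config$n_boot,
                     seed = stage_seed(seeds$boot, k),
                     provenance = list(participant = d$participant[1],
                                       group = d$group[1],
                                       hemisphere = d$hemisphere[1]))
      })
    names(cov_maps) <- purrr::map_chr(cov_maps,
                                      ~ .x$provenance$participant)
    by_group <- split(cov_maps,
                      purrr::map_chr(cov_maps, ~ .x$provenance$group))
    group_maps <- purrr::map(by_group, group_coverage, flip_rh = TRUE)

    say("stage: coverage statistics")
    cov_stats <- purrr::map_dfr(cov_maps, function(m) {
      com <- coverage_com(m)
      tibble::tibble(group = m$provenance$group,
                     participant = m$provenance$participant,
                     extent_sqdva = coverage_extent(
                       m, binarize_at = config$coverage_binarize),
                     com_x = com$x, com_y = com$y,
                     com_distance = com$distance)
    })
    group_summ <- cov_stats |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_extent = mean(.data$extent_sqdva),
        se_extent = if (dplyr::n() >= 2)
          jackknife_se(.data$extent_sqdva) else NA_real_,
        mean_com_distance = mean(.data$com_distance),
        se_com_distance = if (dplyr::n() >= 2)
          jackknife_se(.data$com_distance) else NA_real_,
        .groups = "drop")

    size_fits <- filtered |>
      dplyr::group_by(.data$group, .data$participant) |>
      dplyr::group_modify(function(d, key) {
        f <- tryCatch(size_ecc_fit(d, ve_min = config$ve_min),
                      error = function(e) NULL)
        if (is.null(f)) {
          tibble::tibble(slope = NA_real_, intercept = NA_real_,
                         n_points = 0L)
        } else {
          tibble::tibble(slope = f$slope, intercept = f$intercept,
                         n_points = f$n_points)
        }
      }) |>
      dplyr::ungroup()
    size_group <- size_fits |>
      dplyr::filter(is.finite(.data$slope)) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean_slope = mean(.data$slope),
                       mean_intercept = mean(.data$intercept),
                       .groups = "drop")

    say("stage: 2D KS group comparison")
    pts <- purrr::imap(by_group, function(maps, g) {
      coverage_to_points(unname(maps),
                         samples_per_map = config$samples_per_map,
                         seed = stage_seed(seeds$ks,
                                           match(g, names(by_group))))
    })
    ks <- ks2d_two_sample(pts[[1]], pts[[2]], p_method = "permutation",
                          n_perm = config$n_perm_ks,
                          seed = stage_seed(seeds$ks, 99))
    welch <- list(
      extent = stats::t.test(extent_sqdva ~ group, data = cov_stats),
      com = stats::t.test(com_distance ~ group, data = cov_stats))

    stats_out <- c(stats_out, list(
      coverage = cov_stats, coverage_group = group_summ,
      size_fits = size_fits, size_fits_group = size_group,
      ks2d = ks, welch = welch))

    report <- c(report,
                paste0("coverage extent (sq dva) by group: ",
                       paste(sprintf("%s %.1f +/- %.2f", group_summ$group,
                                     group_summ$mean_extent,
                                     group_summ$se_extent),
                             collapse = "; ")),
                paste0("coverage CoM distance (dva) by group: ",
                       paste(sprintf("%s %.2f +/- %.3f", group_summ$group,
                                     group_summ$mean_com_distance,
                                     group_summ$se_com_distance),
                             collapse = "; ")),
                paste0("size vs ecc (group mean): ",
                       paste(sprintf("%s slope %.3f intercept %.3f",
                                     size_group$group, size_group$mean_slope,
                                     size_group$mean_intercept),
                             collapse = "; ")),
                sprintf("2D KS children vs adults: D = %.3f, p = %.3f",
                        ks$D, ks$p))
  }

  say("stage: gaze analysis")
  boxes <- stimulus_boxes(n = config$n_stimuli, seed = seeds$boxes)
  adult_cfg <- gaze_config(n_participants = config$n_gaze_participants,
                           n_fixations = config$n_fixations,
                           center_offset = c(0, 0),
                           spread = config$gaze_spread,
                           seed = stage_seed(seeds$gaze, 1))
  child_cfg <- gaze_config(n_participants = config$n_gaze_participants,
                           n_fixations = config$n_fixations,
                           center_offset = config$child_offset,
                           spread = config$gaze_spread,
                           seed = stage_seed(seeds$gaze, 2))
  adult_fix <- simulate_gaze(adult_cfg, boxes, group = "adults")
  child_fix <- simulate_gaze(child_cfg, boxes, group = "children")

  per_stim <- purrr::map(boxes$stimulus_id, function(sid) {
    a_maps <- adult_fix |>
      dplyr::filter(.data$stimulus_id == sid) |>
      dplyr::group_split(.data$participant) |>
      purrr::map(fixation_density, sigma_px = config$smoothing_px)
    c_maps <- child_fix |>
      dplyr::filter(.data$stimulus_id == sid) |>
      dplyr::group_split(.data$participant) |>
      purrr::map(fixation_density, sigma_px = config$smoothing_px)
    afz <- adult_fixation_zone(a_maps, overlap = config$afz_overlap,
                               presence_eps = config$afz_presence_eps)
    ratios <- child_fix |>
      dplyr::filter(.data$stimulus_id == sid) |>
      dplyr::group_split(.data$participant) |>
      purrr::map_dbl(outside_afz_ratio, afz = afz)
    bv <- bias_vector(group_density(c_maps), group_density(a_maps), afz,
                      stimulus_id = sid)
    list(afz = afz, ratios = ratios, bias = bv)
  })
  ratios_tbl <- tibble::tibble(
    stimulus_id = rep(boxes$stimulus_id,
                      each = config$n_gaze_participants),
    participant = rep(sort(unique(child_fix$participant)),
                      times = config$n_stimuli),
    outside_ratio = unlist(purrr::map(per_stim, "ratios")))
  vectors <- purrr::map_dfr(per_stim, "bias")
  qt <- if (nrow(vectors) >= 2) {
    null_quadrant_test(vectors, null_quadrant = config$null_quadrant)
  } else NULL

  gaze_out <- list(boxes = boxes, adult_fixations = adult_fix,
                   child_fixations = child_fix,
                   afz = purrr::map(per_stim, "afz"),
                   outside_ratios = ratios_tbl, bias_vectors = vectors,
                   quadrant_test = qt)
  report <- c(report,
              sprintf("mean outside-AFZ ratio in children: %.3f (chance 0.30)",
                      mean(ratios_tbl$outside_ratio)),
              sprintf("mean bias-vector angle: %.1f deg, magnitude %.1f px",
                      mean(vectors$angle), mean(vectors$magnitude)))
  if (!is.null(qt)) {
    report <- c(report,
                sprintf(
                  "distance from %s null quadrant: mean %.1f deg (t = %.2f, p = %.3g)",
                  qt$null_quadrant, mean(qt$distances), qt$t, qt$p))
  }

  manifest <- list(
    tool = "prfgaze",
    version = as.character(utils::packageVersion("prfgaze")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed, stage_seeds = seeds,
    timestamp = format(Sys.time(), tz = "UTC"))

  out <- structure(list(config = config, manifest = manifest,
                        apertures = ap, truth = truth_all, fits = fits_all,
                        filtered = filtered, coverage = cov_maps,
                        group_maps = group_maps, stats = stats_out,
                        gaze = gaze_out, report = report),
                   class = "prf_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.prf_pipeline <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}

# Persist pipeline artifacts as plain-text files.
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(config_hash = result$manifest$config_hash,
              seed = result$manifest$seed)
  write_table_tsv(result$fits, file.path(out_dir, "fits.tsv"), hdr)
  write_table_tsv(result$filtered, file.path(out_dir, "fits_filtered.tsv"),
                  hdr)
  for (nm in names(result$coverage)) {
    write_coverage_map(result$coverage[[nm]],
                       file.path(out_dir, paste0("coverage_", nm, ".tsv")))
  }
  if (!is.null(result$stats$coverage)) {
    write_table_tsv(result$stats$coverage,
                    file.path(out_dir, "coverage_stats.tsv"), hdr)
    write_table_tsv(result$stats$size_fits,
                    file.path(out_dir, "size_ecc_fits.tsv"), hdr)
  }
  if (!is.null(result$gaze$bias_vectors)) {
    write_table_tsv(result$gaze$bias_vectors,
                    file.path(out_dir, "bias_vectors.tsv"), hdr)
    write_table_tsv(result$gaze$outside_ratios,
                    file.path(out_dir, "outside_afz_ratios.tsv"), hdr)
  }
  mf <- result$manifest
  writeLines(c(paste0("tool: ", mf$tool),
               paste0("version: ", mf$version),
               paste0("config_hash: ", mf$config_hash),
               paste0("seed: ", mf$seed),
               paste0("stage_seeds: ",
                      paste(names(mf$stage_seeds), unlist(mf$stage_seeds),
                            sep = "=", collapse = " ")),
               paste0("timestamp: ", mf$timestamp)),
             file.path(out_dir, "manifest.txt"))
  writeLines(result$report, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
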