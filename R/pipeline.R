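#' Measurement pipeline configuration
#'
#' Options shared by the measurement stages.
#'
#' @param low,high Density window (default 200-2000, interpreted on the
#'   calibrated BMD map).
#' @param threshold_space `"bmd"` (default) applies the window to calibrated
#'   values; `"hu"` applies the same numbers to raw HU instead.
#' @param calibration_mode `"two_point"` or `"least_squares"`.
#' @param water_correct Use the water-corrected two-point variant (see
#'   [fit_calibration()]).
#' @param roi_radius,homogeneity_limit,min_roi_pixels,min_roi_radius M1 ROI
#'   parameters.
#' @param jitter_amplitude Half-width of the uniform sub-pixel replicate
#'   jitter of the M1 candidate grid (pixels).
#' @param n_replicates Replicates per region (default 3).
#' @param connectivity In-plane connectivity for region growing.
#' @param volume_normalize Volume-normalize BMD before the trait screen.
#' @param lambda Deming error-variance ratio.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(low = 200, high = 2000,
                            threshold_space = c("bmd", "hu"),
                            calibration_mode = c("two_point", "least_squares"),
                            water_correct = FALSE,
                            roi_radius = 2, homogeneity_limit = 0.15,
                            min_roi_pixels = 12, min_roi_radius = 2,
                            jitter_amplitude = 0.35,
                            n_replicates = 3, connectivity = 8,
                            volume_normalize = TRUE, lambda = 1) {
  structure(list(low = low, high = high,
                 threshold_space = match.arg(threshold_space),
                 calibration_mode = match.arg(calibration_mode),
                 water_correct = water_correct,
                 roi_radius = roi_radius, homogeneity_limit = homogeneity_limit,
                 min_roi_pixels = min_roi_pixels, min_roi_radius = min_roi_radius,
                 jitter_amplitude = jitter_amplitude,
                 n_replicates = as.integer(n_replicates),
                 connectivity = connectivity,
                 volume_normalize = volume_normalize, lambda = lambda),
            class = "pipeline_config")
}

#' Standardized diaphyseal slice indices
#'
#' The three measurement levels at 25% (proximal), 50% (medial) and 75%
#' (distal) of the slice count, measured from the proximal end. Rounding is
#' to the nearest slice with exact halves going to the lower index; results
#' are clamped to `[1, n_slices]` (1-based).
#'
#' @param n_slices Number of slices in the volume.
#' @return Named integer vector `(proximal, medial, distal)`.
#' @export
region_slice_indices <- function(n_slices) {
  idx <- clamp(round_half_down(c(0.25, 0.50, 0.75) * n_slices), 1L, n_slices)
  stats::setNames(as.integer(idx), c("proximal", "medial", "distal"))
}

#' Measure one bone with both methods
#'
#' Calibrates the volume from its own in-field phantom, then measures the
#' three standardized slices with three replicates each using the quadrant
#' method (M1) and the region-growing method (M2).
#'
#' @param volume A [ct_volume()].
#' @param layout The [phantom_layout()] used in the scan.
#' @param bone_id Identifier copied into the output rows.
#' @param config A [pipeline_config()].
#' @param jitter_seed Seed for the M1 replicate jitters of this bone.
#' @return List with `records` (one row per bone x method x region x
#'   replicate), `roi_detail` (one row per M1 ROI), `calibration`, and
#'   `failures` (data frame of skipped slices, zero rows when clean).
#' @export
measure_bone <- function(volume, layout, bone_id = 1,
                         config = pipeline_config(), jitter_seed = 1) {
  stopifnot(inherits(volume, "ct_volume"))
  reading <- read_phantom(volume, layout)
  model <- fit_calibration(reading, mode = config$calibration_mode,
                           water_correct = config$water_correct)
  d <- dim(volume$voxels)
  excl <- phantom_mask(layout, d[2:3], margin_px = 2)
  slices <- region_slice_indices(d[1])
  nrep <- config$n_replicates
  jitters <- with_seed(jitter_seed,
    matrix(stats::runif(2 * nrep * length(slices),
                        -config$jitter_amplitude, config$jitter_amplitude),
           ncol = 2))
  records <- list(); roi_detail <- list(); failures <- list()
  for (ri in seq_along(slices)) {
    region <- names(slices)[ri]
    z <- slices[[ri]]
    hu_slice <- volume$voxels[z, , ]
    bmd_slice <- hu_to_bmd(hu_slice, model)
    tv <- if (config$threshold_space == "hu") hu_slice else bmd_slice
    # M1
    m1_mask <- tryCatch(bone_mask(tv, config$low, config$high, exclude = excl),
                        error = function(e) e)
    for (rep_i in seq_len(nrep)) {
      jit <- jitters[(ri - 1) * nrep + rep_i, ]
      res <- if (inherits(m1_mask, "error")) m1_mask else tryCatch(
        m1_slice_bmd(bmd_slice, low = config$low, high = config$high,
                     exclude = excl, radius = config$roi_radius,
                     homogeneity_limit = config$homogeneity_limit,
                     min_pixels = config$min_roi_pixels,
                     min_radius = config$min_roi_radius,
                     jitter = jit, mask = m1_mask),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- data.frame(
          bone_id = bone_id, method = "M1", region = region, replicate = rep_i,
          message = conditionMessage(res))
        next
      }
      records[[length(records) + 1]] <- data.frame(
        bone_id = bone_id, method = "M1", region = region, slice_index = z,
        replicate = rep_i, mean_bmd = res$slice_bmd,
        sd_bmd = pop_sd(vapply(res$rois, function(r) r$mean, numeric(1))),
        seed_row = NA_integer_, seed_col = NA_integer_,
        min_bmd = NA_real_, max_bmd = NA_real_, n_pixels = NA_integer_,
        area_mm2 = NA_real_, volume_mm3 = NA_real_)
      for (qn in names(res$rois)) {
        roi <- res$rois[[qn]]
        roi_detail[[length(roi_detail) + 1]] <- data.frame(
          bone_id = bone_id, method = "M1", region = region, slice_index = z,
          replicate = rep_i, quadrant = qn,
          roi_row = roi$center[["row"]], roi_col = roi$center[["col"]],
          roi_radius = roi$radius, mean_bmd = roi$mean, sd_bmd = roi$sd,
          n_pixels = roi$n_pixels)
      }
    }
    # M2
    for (rep_i in seq_len(nrep)) {
      res <- tryCatch(
        m2_slice_bmd(bmd_slice, replicate = rep_i, low = config$low,
                     high = config$high, exclude = excl,
                     connectivity = config$connectivity,
                     spacing = volume$spacing, threshold_values = tv),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- data.frame(
          bone_id = bone_id, method = "M2", region = region, replicate = rep_i,
          message = conditionMessage(res))
        next
      }
      s <- res$stats
      records[[length(records) + 1]] <- data.frame(
        bone_id = bone_id, method = "M2", region = region, slice_index = z,
        replicate = rep_i, mean_bmd = s$mean, sd_bmd = s$sd,
        seed_row = res$seed[["row"]], seed_col = res$seed[["col"]],
        min_bmd = s$min, max_bmd = s$max, n_pixels = s$n_pixels,
        area_mm2 = s$area_mm2, volume_mm3 = s$volume_mm3)
    }
  }
  empty_fail <- data.frame(bone_id = integer(), method = character(),
                           region = character(), replicate = integer(),
                           message = character())
  list(records = if (length(records)) do.call(rbind, records) else NULL,
       roi_detail = if (length(roi_detail)) do.call(rbind, roi_detail) else NULL,
       calibration = model,
       failures = if (length(failures)) do.call(rbind, failures) else empty_fail)
}

#' Aggregate replicate records into bone summaries
#'
#' Aggregation follows the study order strictly: replicates average into a
#' region value, region values average (unweighted) into the whole-bone
#' value — never a pooled grand mean of raw records. Replicate CV (percent,
#' sample SD) is reported per (bone, method, region).
#'
#' @param records Measurement records from [measure_bone()]/[run_pipeline()].
#' @return List of data frames `regions` (bone x method x region:
#'   `region_bmd`, `replicate_cv`, `n_replicates`) and `whole` (bone x
#'   method: `whole_bmd`, `n_regions`).
#' @export
summarize_bones <- function(records) {
  key <- interaction(records$bone_id, records$method, records$region, drop = TRUE)
  regions <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(bone_id = g$bone_id[1], method = g$method[1], region = g$region[1],
               region_bmd = mean(g$mean_bmd),
               replicate_cv = if (mean(g$mean_bmd) != 0)
                 100 * stats::sd(g$mean_bmd) / mean(g$mean_bmd) else NA_real_,
               n_replicates = nrow(g))
  }))
  key2 <- interaction(regions$bone_id, regions$method, drop = TRUE)
  whole <- do.call(rbind, lapply(split(regions, key2), function(g) {
    data.frame(bone_id = g$bone_id[1], method = g$method[1],
               whole_bmd = mean(g$region_bmd), n_regions = nrow(g))
  }))
  rownames(regions) <- rownames(whole) <- NULL
  list(regions = regions[order(regions$bone_id, regions$method, regions$region), ],
       whole = whole[order(whole$bone_id, whole$method), ])
}

#' Mean replicate coefficient of variation per method
#'
#' The CV across the three replicate values of each (bone, region) cell,
#' averaged over all cells, per method — the within-method precision figure
#' (expected well below 5% under the default generator).
#'
#' @param records Measurement records.
#' @return Named numeric vector, one mean CV% per method.
#' @export
replicate_cv <- function(records) {
  bs <- summarize_bones(records)
  vapply(split(bs$regions$replicate_cv, bs$regions$method),
         function(v) mean(v, na.rm = TRUE), numeric(1))
}

#' Run the full synthetic pipeline
#'
#' Simulate, calibrate, measure, aggregate, compare and regress: generates a
#' synthetic cohort bone by bone (volumes are streamed, not retained),
#' measures each with both methods, aggregates replicates to regions to
#' whole-bone values, computes the descriptive tables, the method-agreement
#' report and the trait regression screen, and (optionally) writes the
#' standardized result files. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param tm A [trait_model()].
#' @param seed Master seed for the whole run.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed): writes
#'   `measurements.csv`, `roi_detail.csv`, `bone_summary_regions.csv`,
#'   `bone_summary_whole.csv`, `descriptive_overall.csv`,
#'   `descriptive_by_region.csv`, `traits.csv`, `trait_screen.csv`,
#'   `agreement.json`, `manifest.json`.
#' @param verbose Print per-bone progress.
#' @return A `qct_run` list: `measurements`, `roi_detail`, `bone_summary`,
#'   `descriptives`, `agreement`, `trait_table`, `trait_screen`,
#'   `replicate_cv`, `true_bmd`, `manifest`.
#' @export
run_pipeline <- function(spec = cohort_spec(), tm = trait_model(), seed = 1,
                         config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  seeds <- derive_seeds(seed, 2L * spec$n_bones + 1L)
  bone_seeds <- seeds[seq_len(spec$n_bones)]
  jitter_seeds <- seeds[spec$n_bones + seq_len(spec$n_bones)]
  trait_seed <- seeds[2L * spec$n_bones + 1L]

  rec_list <- list(); roi_list <- list(); fail_list <- list()
  true_bmd <- numeric(spec$n_bones)
  for (i in seq_len(spec$n_bones)) {
    b <- make_tibia_volume(spec, seed = bone_seeds[i])
    true_bmd[i] <- b$truth$true_mean_bmd
    m <- measure_bone(b$volume, spec$layout, bone_id = i, config = config,
                      jitter_seed = jitter_seeds[i])
    rec_list[[i]] <- m$records
    roi_list[[i]] <- m$roi_detail
    if (nrow(m$failures)) fail_list[[length(fail_list) + 1]] <- m$failures
    if (verbose) message(sprintf("bone %d/%d: true BMD %.1f", i, spec$n_bones,
                                 true_bmd[i]))
    rm(b, m)
  }
  measurements <- do.call(rbind, rec_list)
  roi_detail <- do.call(rbind, roi_list)
  failures <- if (length(fail_list)) do.call(rbind, fail_list) else NULL
  for (m in c("M1", "M2")) {
    if (!any(measurements$method == m))
      stop(sprintf("method %s produced no records; aborting run", m), call. = FALSE)
  }

  bs <- summarize_bones(measurements)
  desc <- descriptive_table(bs)
  wide <- merge(bs$whole[bs$whole$method == "M1", c("bone_id", "whole_bmd")],
                bs$whole[bs$whole$method == "M2", c("bone_id", "whole_bmd")],
                by = "bone_id", suffixes = c("_m1", "_m2"))
  # the agreement suite and the regression screen need >= 3 complete pairs
  agreement <- if (nrow(wide) >= 3)
    agreement_report(wide$whole_bmd_m1, wide$whole_bmd_m2,
                     lambda = config$lambda) else NULL
  trait_table <- simulate_traits(tm, true_bmd, seed = trait_seed)
  bmd_table <- data.frame(bone_id = bs$whole$bone_id, method = bs$whole$method,
                          bmd = bs$whole$whole_bmd)
  screen <- if (nrow(wide) >= 3)
    trait_screen(trait_table, bmd_table,
                 volume_normalize = config$volume_normalize) else NULL
  rep_cv <- replicate_cv(measurements)

  manifest <- list(seed = seed, n_bones = spec$n_bones,
                   n_records = stats::setNames(
                     as.list(table(measurements$method)),
                     names(table(measurements$method))),
                   n_failures = if (is.null(failures)) 0L else nrow(failures),
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("tibiaqct")))
  run <- structure(list(measurements = measurements, roi_detail = roi_detail,
                        bone_summary = bs, descriptives = desc,
                        agreement = agreement, trait_table = trait_table,
                        trait_screen = screen, replicate_cv = rep_cv,
                        true_bmd = true_bmd, failures = failures,
                        manifest = manifest),
                   class = "qct_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.qct_run <- function(x, ...) {
  cat(sprintf("<qct_run> %d bones, %d measurement records (%s)\n",
              x$manifest$n_bones, nrow(x$measurements),
              paste(sprintf("%s: %d", names(x$manifest$n_records),
                            unlist(x$manifest$n_records)), collapse = ", ")))
  cat(sprintf("  mean replicate CV%%: %s\n",
              paste(sprintf("%s %.2f", names(x$replicate_cv), x$replicate_cv),
                    collapse = ", ")))
  print(x$descriptives$overall, row.names = FALSE, digits = 6)
  if (!is.null(x$agreement)) {
    cat("\n")
    print(x$agreement)
  }
  invisible(x)
}

#' Write the standardized result files of a run
#'
#' @param run A `qct_run` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(run$measurements, "measurements.csv")
  if (!is.null(run$roi_detail)) wcsv(run$roi_detail, "roi_detail.csv")
  wcsv(run$bone_summary$regions, "bone_summary_regions.csv")
  wcsv(run$bone_summary$whole, "bone_summary_whole.csv")
  wcsv(run$descriptives$overall, "descriptive_overall.csv")
  wcsv(run$descriptives$by_region, "descriptive_by_region.csv")
  wcsv(run$trait_table, "traits.csv")
  if (!is.null(run$trait_screen)) wcsv(run$trait_screen, "trait_screen.csv")
  ag <- run$agreement
  if (!is.null(ag)) jsonlite::write_json(
    list(pearson = ag$pearson, ccc = ag$ccc, bland_altman = ag$bland_altman,
         deming = ag$deming[c("alpha", "beta", "alpha_ci", "beta_ci", "lambda", "n")],
         per_method = ag$per_method, meta = ag$meta),
    file.path(out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
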