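#' Run the full analysis on one sample's staining rounds
#'
#' Registration of the six rounds, fusion into a virtual multiplexed
#' image, nucleus detection on the counterstain, compartment-restricted
#' marker calling with exclusive phenotyping, cytokeratin tumour masking,
#' A/B/C zoning, and per-sample contexture metrics.
#'
#' @param rounds named list of [stain_round()] objects (the full panel).
#' @param basis a [stain_basis()].
#' @param thresholds per-marker OD thresholds (default 0.15).
#' @param band_width_um stromal band width (default 30).
#' @param roi_mask optional logical ROI; default is the valid-pixel mask
#'   of the fused image (every analysed pixel is covered by all rounds).
#' @param register run registration (set `FALSE` only for pre-aligned
#'   rounds, which then get identity transforms).
#' @param nucleus_params list of overrides passed to [detect_nuclei()].
#' @param ck_threshold OD threshold of the tumour mask.
#' @param min_roi_area_um2 QC floor on the ROI area.
#' @param ... passed to [register_rounds()].
#' @return list of class `sample_analysis`: `vdi`, `detections`, `cells`
#'   (phenotyped + zoned), `masks`, `metrics`, `qc_pass`.
#' @export
analyze_sample <- function(rounds, basis = stain_basis(),
                           thresholds = NULL, band_width_um = 30,
                           roi_mask = NULL, register = TRUE,
                           nucleus_params = list(), ck_threshold = 0.3,
                           min_roi_area_um2 = 1e5, ...) {
  transforms <- if (register) {
    register_rounds(rounds, basis, ...)
  } else {
    tfs <- lapply(rounds, function(r) round_transform())
    names(tfs) <- vapply(rounds, function(r) r$marker_name, character(1))
    tfs
  }
  vdi <- build_vdi(rounds, transforms, basis)
  if (is.null(roi_mask)) roi_mask <- vdi$valid_mask
  detections <- do.call(detect_nuclei, c(
    list(hematoxylin_od = vdi$hematoxylin_od,
         pixel_size_um = vdi$pixel_size_um, valid_mask = vdi$valid_mask),
    nucleus_params))
  cells <- phenotype_cells(vdi, detections, thresholds)
  tumour_mask <- build_tumor_mask(vdi$markers[["CK"]], roi_mask,
                                  vdi$pixel_size_um,
                                  threshold = ck_threshold)
  masks <- partition_zones(tumour_mask, roi_mask, band_width_um,
                           vdi$pixel_size_um)
  cells <- assign_cells_to_zones(cells, masks)
  metrics <- compute_sample_metrics(cells, masks$areas)
  structure(
    list(vdi = vdi, detections = detections, cells = cells, masks = masks,
         metrics = metrics, qc_pass = qc_filter(metrics, min_roi_area_um2)),
    class = "sample_analysis"
  )
}

#' @export
print.sample_analysis <- function(x, ...) {
  print(x$vdi)
  print(x$metrics)
  cat("QC pass:", x$qc_pass, "\n")
  invisible(x)
}

#' Analyse a sample directory of single-stain images
#'
#' Expects one `<marker>.tiff` (or `.png`) per panel marker, as written
#' by [write_slide()].
#'
#' @param dir directory of round images.
#' @param pixel_size_um microns per pixel of the scans.
#' @param ... passed to [analyze_sample()].
#' @return a `sample_analysis` list.
#' @export
analyze_sample_dir <- function(dir, pixel_size_um, ...) {
  rounds <- lapply(marker_panel(), function(m) {
    for (ext in c(".tiff", ".tif", ".png")) {
      p <- file.path(dir, paste0(m, ext))
      if (file.exists(p)) return(read_stain_round(p, m, pixel_size_um))
    }
    stop("no image found for marker ", m, " in ", dir)
  })
  names(rounds) <- marker_panel()
  analyze_sample(rounds, ...)
}

#' Write per-cell and per-sample results
#'
#' `cells.csv` (cell table with marker ODs, flags, phenotype, zone),
#' `metrics.csv` / `metrics.json` (one-row sample metrics) and
#' `zones.png` (label image).
#'
#' @param analysis a [analyze_sample()] result.
#' @param dir output directory.
#' @param sample_id identifier written into the metrics row.
#' @return `dir`, invisibly.
#' @export
write_sample_results <- function(analysis, dir, sample_id = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(analysis$cells),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  row <- metrics_as_row(analysis$metrics, sample_id)
  utils::write.csv(row, file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(row), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_zone_masks(analysis$masks, file.path(dir, "zones.png"))
  write_transforms(analysis$vdi$transforms,
                   file.path(dir, "transforms.json"))
  invisible(dir)
}

#' Cohort-level statistics over a cohort table and expression matrix
#'
#' Runs the standard battery: paired day15-vs-baseline sTIL shift per HR
#' stratum (t-interval + paired Wilcoxon), surgery-vs-day15 shift by pCR,
#' TIL-dynamics classification, univariate logistic OR of pCR on day-15
#' sTILs (per 10 points), and - when expression is supplied -
#' housekeeping normalisation plus quantitative SAM against sTILs.
#'
#' @param cohort data frame with `patient_id`, `timepoint`, `hr_status`,
#'   `pam50`, `pcr`, `stils_pct`.
#' @param expression optional raw count matrix (genes x samples, columns
#'   `<patient>_<timepoint>`).
#' @param sam_fdr FDR threshold for SAM (default 0.01).
#' @param sam_permutations permutations (default 1000).
#' @param seed seed for SAM permutations.
#' @return list of class `cohort_stats`: `shifts` (tidy data frame of
#'   paired results), `or_pcr` (an `odds_ratio`), `dynamics` (table),
#'   `sam` (a `sam_result` or NULL).
#' @export
cohort_statistics <- function(cohort, expression = NULL, sam_fdr = 0.01,
                              sam_permutations = 1000, seed = 1) {
  wide <- stats::reshape(
    cohort[, c("patient_id", "timepoint", "stils_pct")],
    idvar = "patient_id", timevar = "timepoint", direction = "wide")
  names(wide) <- sub("^stils_pct\\.", "", names(wide))
  meta <- unique(cohort[, c("patient_id", "hr_status", "pcr")])
  wide <- merge(wide, meta, by = "patient_id")
  rows <- list()
  add <- function(label, x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return()
    pd <- paired_mean_difference_ci(x[ok], y[ok])
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = label, n_pairs = pd$n_pairs,
      mean_difference = pd$mean_difference, ci_low = pd$ci_low,
      ci_high = pd$ci_high, p_value = pd$p_value)
  }
  add("day15_vs_baseline_all", wide$baseline, wide$day15)
  for (h in unique(wide$hr_status))
    add(paste0("day15_vs_baseline_HR_", h),
        wide$baseline[wide$hr_status == h], wide$day15[wide$hr_status == h])
  add("surgery_vs_day15_pcr", wide$day15[wide$pcr], wide$surgery[wide$pcr])
  add("surgery_vs_day15_rd", wide$day15[!wide$pcr], wide$surgery[!wide$pcr])
  shifts <- do.call(rbind, rows)
  or_pcr <- tryCatch(
    logistic_or_pcr(wide$pcr, wide$day15, unit_scale = 10),
    error = function(e) NULL)
  dynamics <- table(classify_til_dynamics(wide$baseline, wide$day15))
  sam <- NULL
  if (!is.null(expression)) {
    key <- paste(cohort$patient_id, cohort$timepoint, sep = "_")
    keep <- match(colnames(expression), key)
    stils <- cohort$stils_pct[keep]
    ok <- !is.na(stils)
    norm <- normalize_expression(expression[, ok, drop = FALSE])
    sam <- sam_til_association(norm, stils[ok], fdr_threshold = sam_fdr,
                               n_permutations = sam_permutations,
                               seed = seed)
  }
  structure(list(shifts = shifts, or_pcr = or_pcr, dynamics = dynamics,
                 sam = sam),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("paired sTIL shifts:\n")
  print(x$shifts, row.names = FALSE)
  if (!is.null(x$or_pcr)) {
    cat("pCR odds ratio (day-15 sTILs): ")
    print(x$or_pcr)
  }
  cat("TIL dynamics (baseline -> day15):\n")
  print(x$dynamics)
  if (!is.null(x$sam)) print(x$sam)
  invisible(x)
}
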