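#' @title Sample-level immune contexture metrics
#' @description
#' Reduces the per-cell phenotype table to the readouts reported per
#' sample: marker densities (cells/mm^2) overall and per zone, Ki67+
#' fractions, exclusive CD3 subset proportions, the proliferating
#' Foxp3/CD8 ratio, the proliferating-immune fraction, and QC. Densities
#' use marker-level (overlapping) positivity — a Treg counts toward CD3,
#' CD4 and Foxp3 densities — while subset proportions use the exclusive
#' phenotypes. Fractions with zero denominators are NA (missing), never
#' 0, and propagate as missing into the statistics layer.
#' @name contexture-metrics
NULL

immune_phenotypes <- function() c("CD8_T", "CD4_T", "Treg", "CD3_only")

#' Compute per-sample contexture metrics
#'
#' @param cells a `phenotyped_cells` data frame with a `zone` column (from
#'   [assign_cells_to_zones()]). Cells with zone `"none"` or indeterminate
#'   marker calls are excluded from densities and counted in QC.
#' @param areas a `zone_areas` object (from [partition_zones()]).
#' @param tumour_area_fraction optional fraction of the ROI covered by
#'   tumour; defaults to `area_A / roi_area`.
#' @return object of class `sample_metrics`: a list with `density`
#'   (marker x zone matrix plus `total` column, cells/mm^2), `pct_ki67`
#'   (marker x zone/total matrix, percent), `subset_proportions` (named,
#'   sums to 1, NA when no CD3+ cells), `ratio_prolif_foxp3_cd8`,
#'   `prolif_immune_fraction`, `roi_area_um2`, `tumour_area_fraction`,
#'   `n_cells`, `conflict_count`, `indeterminate_count`, `zone_none_count`.
#' @export
compute_sample_metrics <- function(cells, areas,
                                   tumour_area_fraction = NULL) {
  stopifnot(inherits(areas, "zone_areas"))
  if (areas$roi_area_um2 <= 0) stop("zero ROI area")
  markers <- c("CD3", "CD4", "CD8", "Foxp3")
  zones <- c("A", "B", "C")
  n_all <- nrow(cells)
  indeterminate <- if ("indeterminate" %in% names(cells))
    cells$indeterminate else rep(FALSE, n_all)
  zone_none <- cells$zone == "none"
  use <- !zone_none & !indeterminate
  cc <- cells[use, , drop = FALSE]
  pos <- function(df, m) {
    v <- df[[paste0(m, "_pos")]]
    !is.na(v) & v
  }
  ki <- pos(cc, "Ki67")
  area_mm2 <- c(areas$area_um2 / 1e6,
                total = areas$roi_area_um2 / 1e6)
  density <- matrix(NA_real_, length(markers), length(zones) + 1L,
                    dimnames = list(markers, c(zones, "total")))
  pct_ki67 <- density
  for (m in markers) {
    p <- pos(cc, m)
    for (z in c(zones, "total")) {
      inz <- if (z == "total") rep(TRUE, nrow(cc)) else cc$zone == z
      a <- area_mm2[[z]]
      density[m, z] <- if (a > 0) sum(p & inz) / a else NA_real_
      npos <- sum(p & inz)
      pct_ki67[m, z] <- if (npos > 0) 100 * sum(p & inz & ki) / npos
                        else NA_real_
    }
  }
  n_cd3 <- sum(pos(cc, "CD3"))
  subset_counts <- vapply(immune_phenotypes(), function(ph)
    sum(cc$phenotype == ph), numeric(1))
  subset_proportions <- if (sum(subset_counts) > 0)
    subset_counts / sum(subset_counts)
  else stats::setNames(rep(NA_real_, 4L), immune_phenotypes())
  # proliferating Foxp3 / proliferating CD8 (marker-level, Ki67 co-expr.)
  prolif_foxp3 <- sum(pos(cc, "Foxp3") & ki)
  prolif_cd8 <- sum(pos(cc, "CD8") & ki)
  ratio_prolif_foxp3_cd8 <- if (prolif_cd8 > 0) prolif_foxp3 / prolif_cd8
                            else NA_real_
  immune <- cc$phenotype %in% immune_phenotypes()
  tumour <- cc$phenotype == "tumour"
  denom <- sum(ki & (immune | tumour))
  prolif_immune_fraction <- if (denom > 0) sum(ki & immune) / denom
                            else NA_real_
  if (is.null(tumour_area_fraction))
    tumour_area_fraction <-
      as.numeric(areas$area_um2[["A"]] / areas$roi_area_um2)
  structure(
    list(density = density, pct_ki67 = pct_ki67,
         subset_proportions = subset_proportions,
         ratio_prolif_foxp3_cd8 = ratio_prolif_foxp3_cd8,
         prolif_immune_fraction = prolif_immune_fraction,
         roi_area_um2 = areas$roi_area_um2,
         tumour_area_fraction = tumour_area_fraction,
         n_cells = n_all,
         conflict_count = sum(cells$conflict %||% FALSE),
         indeterminate_count = sum(indeterminate),
         zone_none_count = sum(zone_none)),
    class = "sample_metrics"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sample_metrics <- function(x, ...) {
  cat(sprintf("sample metrics: %d cells, ROI %.3g um^2 (tumour %.1f%%)\n",
              x$n_cells, x$roi_area_um2, 100 * x$tumour_area_fraction))
  cat("densities (cells/mm^2):\n")
  print(round(x$density, 1))
  cat("Ki67+ fractions (%):\n")
  print(round(x$pct_ki67, 1))
  cat("CD3 subset proportions:",
      paste(sprintf("%s %.2f", names(x$subset_proportions),
                    x$subset_proportions), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten sample metrics to a one-row data frame
#'
#' Long column names: `density_<marker>_<zone>`, `pct_ki67_<marker>_<zone>`,
#' `prop_<subset>`, plus the scalar fields.
#'
#' @param metrics a [compute_sample_metrics()] result.
#' @param sample_id optional identifier column.
#' @return one-row data frame.
#' @export
metrics_as_row <- function(metrics, sample_id = NA_character_) {
  row <- list(sample_id = sample_id)
  for (m in rownames(metrics$density))
    for (z in colnames(metrics$density)) {
      row[[paste0("density_", m, "_", z)]] <- metrics$density[m, z]
      row[[paste0("pct_ki67_", m, "_", z)]] <- metrics$pct_ki67[m, z]
    }
  for (s in names(metrics$subset_proportions))
    row[[paste0("prop_", s)]] <- metrics$subset_proportions[[s]]
  row$ratio_prolif_foxp3_cd8 <- metrics$ratio_prolif_foxp3_cd8
  row$prolif_immune_fraction <- metrics$prolif_immune_fraction
  row$roi_area_um2 <- metrics$roi_area_um2
  row$tumour_area_fraction <- metrics$tumour_area_fraction
  row$n_cells <- metrics$n_cells
  row$conflict_count <- metrics$conflict_count
  row$indeterminate_count <- metrics$indeterminate_count
  row$zone_none_count <- metrics$zone_none_count
  row$qc_pass <- qc_filter(metrics)
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' ROI-area quality filter
#'
#' Samples whose total region of interest is below the minimum area are
#' excluded from cohort analyses. The boundary is closed: an ROI of
#' exactly the minimum passes.
#'
#' @param metrics a [compute_sample_metrics()] result (or a number, the
#'   ROI area in um^2).
#' @param min_roi_area_um2 minimum area (default 100,000 um^2).
#' @return logical: `TRUE` if the sample passes QC.
#' @export
qc_filter <- function(metrics, min_roi_area_um2 = 1e5) {
  area <- if (inherits(metrics, "sample_metrics")) metrics$roi_area_um2
          else as.numeric(metrics)
  isTRUE(area >= min_roi_area_um2)
}

#' Classify sTIL dynamics between two timepoints
#'
#' No tolerance band: any rise is an increase, any fall a decrease, and
#' only an identical score is stable (pathologist scores are granular, so
#' exact ties are meaningful).
#'
#' @param stils_t1,stils_t2 sTIL percentages in `[0, 100]` (vectorised).
#' @return factor with levels `increase`, `stable`, `decrease`; NA when
#'   either input is missing.
#' @export
classify_til_dynamics <- function(stils_t1, stils_t2) {
  stopifnot(length(stils_t1) == length(stils_t2))
  ok <- !is.na(stils_t1) & !is.na(stils_t2)
  if (any(stils_t1[ok] < 0 | stils_t1[ok] > 100 |
          stils_t2[ok] < 0 | stils_t2[ok] > 100))
    stop("sTILs must be in [0, 100]")
  out <- rep(NA_character_, length(stils_t1))
  out[ok & stils_t2 > stils_t1] <- "increase"
  out[ok & stils_t2 == stils_t1] <- "stable"
  out[ok & stils_t2 < stils_t1] <- "decrease"
  factor(out, levels = c("increase", "stable", "decrease"))
}
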