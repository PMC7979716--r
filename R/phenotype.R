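#' @title Compartment-restricted marker calling and exclusive phenotyping
#' @description
#' Marker positivity is called per cell from the mean chromogen OD over
#' the marker's subcellular compartment: nuclear disk for the
#' transcription factors (Ki67, Foxp3), a membrane ring for CD3/CD4/CD8,
#' and the nucleus dilated by 2 um for cytoplasmic cytokeratin. A cell is
#' positive when mean OD >= threshold (closed boundary). Compartments are
#' disks/annuli around the detected centroid using the equivalent radius,
#' consistent with the circular-nucleus model of the detector.
#' @name marker-calling
NULL

marker_compartment <- function(marker) {
  switch(marker,
    Ki67 = , Foxp3 = "nuclear",
    CD3 = , CD4 = , CD8 = "ring",
    CK = "cytoplasmic",
    stop("unknown marker '", marker, "'"))
}

# per-cell compartment pixel values from a cropped window
compartment_values <- function(od_map, cx_um, cy_um, r_um, marker,
                               pixel_size_um, ring_width_um = 1.5,
                               ck_dilation_um = 2, valid_mask = NULL) {
  comp <- marker_compartment(marker)
  r_in <- switch(comp, nuclear = 0, ring = r_um, cytoplasmic = 0)
  r_out <- switch(comp, nuclear = r_um, ring = r_um + ring_width_um,
                  cytoplasmic = r_um + ck_dilation_um)
  d <- dim(od_map)
  cx_px <- cx_um / pixel_size_um + 0.5
  cy_px <- cy_um / pixel_size_um + 0.5
  rr <- ceiling(r_out / pixel_size_um) + 1L
  cols <- max(1L, floor(cx_px) - rr):min(d[2], ceiling(cx_px) + rr)
  rows <- max(1L, floor(cy_px) - rr):min(d[1], ceiling(cy_px) + rr)
  dx <- (cols - cx_px) * pixel_size_um
  dy <- (rows - cy_px) * pixel_size_um
  dist <- sqrt(outer(dy^2, dx^2, `+`))
  sel <- dist <= r_out & dist > r_in
  if (!any(sel)) return(list(values = numeric(), n_masked = 0L))
  win <- od_map[rows, cols, drop = FALSE]
  if (!is.null(valid_mask)) {
    vm <- valid_mask[rows, cols, drop = FALSE]
    n_masked <- sum(sel & !vm)
    sel <- sel & vm
    return(list(values = win[sel], n_masked = n_masked))
  }
  list(values = win[sel], n_masked = 0L)
}

#' Call marker positivity for detected nuclei
#'
#' @param detections a [detect_nuclei()] result (or a data frame with
#'   `cell_id`, `centroid_x_um`, `centroid_y_um`,
#'   `equivalent_diameter_um`).
#' @param marker_od_map H x W chromogen OD matrix for this marker.
#' @param marker marker name (determines the compartment).
#' @param threshold OD threshold; `mean_od >= threshold` is positive.
#' @param pixel_size_um microns per pixel.
#' @param ring_width_um membrane ring width (default 1.5).
#' @param ck_dilation_um CK measurement dilation (default 2).
#' @param valid_mask optional logical mask; a compartment entirely outside
#'   it yields an indeterminate call (positive = NA).
#' @return data frame: `cell_id`, `marker`, `compartment`, `mean_od`,
#'   `positive` (logical, NA when indeterminate).
#' @export
call_marker_positivity <- function(detections, marker_od_map, marker,
                                   threshold, pixel_size_um,
                                   ring_width_um = 1.5, ck_dilation_um = 2,
                                   valid_mask = NULL) {
  cells <- if (inherits(detections, "nucleus_detections"))
    detections$cells else detections
  n <- nrow(cells)
  mean_od <- rep(NA_real_, n)
  positive <- rep(NA, n)
  for (i in seq_len(n)) {
    cv <- compartment_values(
      marker_od_map, cells$centroid_x_um[i], cells$centroid_y_um[i],
      cells$equivalent_diameter_um[i] / 2, marker, pixel_size_um,
      ring_width_um, ck_dilation_um, valid_mask)
    if (length(cv$values) == 0L) next  # indeterminate: fully masked
    mean_od[i] <- mean(cv$values)
    positive[i] <- mean_od[i] >= threshold
  }
  data.frame(cell_id = cells$cell_id, marker = marker,
             compartment = marker_compartment(marker),
             mean_od = mean_od, positive = positive)
}

#' Assign an exclusive phenotype from marker flags
#'
#' CD3+ cells map to exactly one T-cell subset; CD3- cells are tumour when
#' CK+ and "other" otherwise. Conflicting CD4+CD8+ flag patterns (not
#' expected biologically and unaddressed by simple threshold gating) are
#' resolved in favour of the marker with the higher mean OD, ties to CD8,
#' and counted. A Foxp3+ flag on a CD4- CD3+ cell keeps phenotype
#' `CD3_only` (it still counts toward marker-level Foxp3 density).
#'
#' @param cd3,cd4,cd8,foxp3,ck logical flag vectors (complete, no NA).
#' @param cd4_od,cd8_od mean ODs used only to break CD4+CD8+ conflicts.
#' @return list with `phenotype` (factor: `CD8_T`, `CD4_T`, `Treg`,
#'   `CD3_only`, `tumour`, `other`) and `conflict` (logical vector:
#'   flag pattern needed the precedence rule).
#' @export
assign_phenotype <- function(cd3, cd4, cd8, foxp3, ck,
                             cd4_od = rep(0, length(cd3)),
                             cd8_od = rep(0, length(cd3))) {
  n <- length(cd3)
  stopifnot(lengths(list(cd4, cd8, foxp3, ck)) == n,
            !anyNA(cd3), !anyNA(cd4), !anyNA(cd8), !anyNA(foxp3), !anyNA(ck))
  phen <- character(n)
  conflict <- logical(n)
  # CD3+ branch
  both <- cd3 & cd4 & cd8
  conflict[both] <- TRUE
  use_cd8 <- cd8 & (!cd4 | (both & (cd8_od >= cd4_od)))
  use_cd4 <- cd4 & !use_cd8
  phen[cd3 & use_cd8] <- "CD8_T"
  conflict[cd3 & use_cd8 & foxp3] <- TRUE  # Foxp3+CD8+ resolved to CD8_T
  phen[cd3 & use_cd4 & foxp3] <- "Treg"
  phen[cd3 & use_cd4 & !foxp3] <- "CD4_T"
  phen[cd3 & !cd4 & !cd8] <- "CD3_only"
  # CD3- branch
  phen[!cd3 & ck] <- "tumour"
  phen[!cd3 & !ck] <- "other"
  list(phenotype = factor(phen, levels = phenotype_levels()),
       conflict = conflict)
}

phenotype_levels <- function()
  c("CD8_T", "CD4_T", "Treg", "CD3_only", "tumour", "other")

#' Phenotype all cells of a virtual multiplexed image
#'
#' Runs [call_marker_positivity()] for every marker of the panel and
#' [assign_phenotype()] on the resulting flags.
#'
#' @param vdi a [build_vdi()] result.
#' @param detections a [detect_nuclei()] result.
#' @param thresholds named numeric vector of per-marker OD thresholds
#'   (default 0.15 for each marker).
#' @param ring_width_um,ck_dilation_um compartment geometry.
#' @return data frame of class `phenotyped_cells`: per cell, centroid,
#'   diameter, per-marker `<marker>_od` and `<marker>_pos` columns,
#'   `phenotype`, `conflict`, `indeterminate`. Attributes
#'   `conflict_count` and `indeterminate_count` summarise QC.
#' @export
phenotype_cells <- function(vdi, detections, thresholds = NULL,
                            ring_width_um = 1.5, ck_dilation_um = 2) {
  panel <- names(vdi$markers)
  if (is.null(thresholds)) thresholds <- default_thresholds(panel)
  stopifnot(all(panel %in% names(thresholds)))
  cells <- detections$cells
  out <- cells
  for (m in panel) {
    call <- call_marker_positivity(
      detections, vdi$markers[[m]], m, thresholds[[m]],
      vdi$pixel_size_um, ring_width_um, ck_dilation_um, vdi$valid_mask)
    out[[paste0(m, "_od")]] <- call$mean_od
    out[[paste0(m, "_pos")]] <- call$positive
  }
  indeterminate <- Reduce(`|`, lapply(panel, function(m)
    is.na(out[[paste0(m, "_pos")]])))
  flg <- function(m) {
    v <- out[[paste0(m, "_pos")]]
    v[is.na(v)] <- FALSE
    v
  }
  odc <- function(m) {
    v <- out[[paste0(m, "_od")]]
    v[is.na(v)] <- 0
    v
  }
  ph <- assign_phenotype(flg("CD3"), flg("CD4"), flg("CD8"),
                         flg("Foxp3"), flg("CK"),
                         cd4_od = odc("CD4"), cd8_od = odc("CD8"))
  out$phenotype <- ph$phenotype
  out$conflict <- ph$conflict
  out$indeterminate <- indeterminate
  structure(out, class = c("phenotyped_cells", "data.frame"),
            conflict_count = sum(ph$conflict),
            indeterminate_count = sum(indeterminate))
}

#' Default per-marker OD thresholds
#'
#' Fixed thresholds keep runs deterministic; 0.15 OD sits well above the
#' deconvolution background and well below typical chromogen amplitudes.
#'
#' @param markers marker names.
#' @param value threshold value applied to each.
#' @return named numeric vector.
#' @export
default_thresholds <- function(markers = marker_panel(), value = 0.15) {
  stats::setNames(rep(value, length(markers)), markers)
}

#' Otsu-based automatic per-marker thresholds
#'
#' Optional alternative to fixed thresholds: Otsu's method on the in-ROI
#' OD histogram of each marker map, with a floor so empty markers do not
#' produce degenerate cutoffs.
#'
#' @param vdi a [build_vdi()] result.
#' @param floor minimum returned threshold.
#' @return named numeric vector of thresholds.
#' @export
otsu_thresholds <- function(vdi, floor = 0.1) {
  vapply(vdi$markers, function(m) {
    v <- m[vdi$valid_mask]
    v <- v[is.finite(v)]
    th <- EBImage::otsu(EBImage::Image(matrix(pmin(v, 3) / 3)), levels = 256)
    max(floor, th * 3)
  }, numeric(1))
}
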