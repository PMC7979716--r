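#' @title Spatial zoning around the cytokeratin tumour mask
#' @description
#' The region of interest is partitioned into three zones built from the
#' cytokeratin (CK) tumour mask: intratumoural (A), proximal peritumoural
#' stroma within `band_width_um` of the tumour (B, default 30 um) and
#' distal stroma beyond it (C). Zone B uses the exact Euclidean distance
#' transform (centre-to-centre pixel distances), a closed boundary
#' (distance <= band is B), and the three zones exactly partition the ROI.
#' @name spatial-zones
NULL

disk_brush <- function(radius_um, pixel_size_um) {
  r <- max(1L, round(radius_um / pixel_size_um))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

#' Build the tumour mask from the cytokeratin OD map
#'
#' Thresholds CK OD inside the ROI, applies morphological closing to
#' bridge gaps between adjacent tumour cells, removes small objects and
#' optionally fills holes (gland lumina count as tumour area).
#'
#' @param ck_od H x W CK chromogen OD matrix.
#' @param roi_mask logical H x W region-of-interest mask.
#' @param pixel_size_um microns per pixel.
#' @param threshold OD threshold for CK positivity (> 0). The default of
#'   0.3, half a typical chromogen amplitude, localises the tumour
#'   boundary without bias (a threshold far below the plateau pushes the
#'   boundary outward through the soft edge of the stain).
#' @param min_object_area_um2 objects smaller than this are dropped.
#' @param fill_holes fill enclosed holes.
#' @param closing_radius_um radius of the morphological closing.
#' @return logical H x W tumour mask (subset of `roi_mask`).
#' @export
build_tumor_mask <- function(ck_od, roi_mask, pixel_size_um,
                             threshold = 0.3, min_object_area_um2 = 100,
                             fill_holes = TRUE, closing_radius_um = 2) {
  stopifnot(threshold > 0, all(dim(ck_od) == dim(roi_mask)))
  if (!any(roi_mask)) stop("empty ROI")
  m <- (ck_od >= threshold) & roi_mask
  if (!any(m)) return(m)
  img <- EBImage::Image(m * 1)
  if (closing_radius_um > 0)
    img <- EBImage::closing(img, disk_brush(closing_radius_um, pixel_size_um))
  if (fill_holes) img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  if (min_object_area_um2 > 0 && max(lab) > 0) {
    areas <- tabulate(as.integer(lab[lab > 0]), nbins = max(lab))
    keep <- which(areas * pixel_size_um^2 >= min_object_area_um2)
    img <- EBImage::Image((as.matrix(lab) %in% keep) * 1,
                          dim = dim(ck_od))
  }
  (as.matrix(img) > 0) & roi_mask
}

#' Partition the ROI into zones A, B and C
#'
#' A = tumour mask (clipped to the ROI); B = ROI pixels outside A whose
#' Euclidean distance to the nearest tumour pixel is at most
#' `band_width_um`; C = the remaining ROI. Distances are centre-to-centre
#' pixel distances times `pixel_size_um` (exact disk metric, not iterated
#' structuring-element dilation). The partition property (A, B, C pairwise
#' disjoint, union = ROI) is asserted on every call.
#'
#' @param tumour_mask logical H x W mask.
#' @param roi_mask logical H x W mask.
#' @param band_width_um width of the proximal band (default 30).
#' @param pixel_size_um microns per pixel.
#' @return object of class `region_masks`: list with logical masks `A`,
#'   `B`, `C`, `roi_mask`, `band_width_um`, `pixel_size_um` and `areas`
#'   (class `zone_areas`: `area_um2` named by zone plus `roi_area_um2`).
#' @export
partition_zones <- function(tumour_mask, roi_mask, band_width_um = 30,
                            pixel_size_um = 1) {
  stopifnot(band_width_um > 0, pixel_size_um > 0,
            all(dim(tumour_mask) == dim(roi_mask)))
  if (!any(roi_mask)) stop("zero-area ROI")
  A <- tumour_mask & roi_mask
  if (any(A)) {
    # distmap: Euclidean distance of each non-tumour pixel to the nearest
    # tumour pixel (exact EDT)
    d_px <- as.matrix(EBImage::distmap(EBImage::Image((!A) * 1)))
    B <- roi_mask & !A & (d_px * pixel_size_um <= band_width_um)
  } else {
    B <- matrix(FALSE, nrow(roi_mask), ncol(roi_mask))
  }
  C <- roi_mask & !A & !B
  stopifnot(!any(A & B), !any(A & C), !any(B & C),
            all((A | B | C) == roi_mask))
  px_area <- pixel_size_um^2
  areas <- structure(
    list(area_um2 = c(A = sum(A), B = sum(B), C = sum(C)) * px_area,
         roi_area_um2 = sum(roi_mask) * px_area),
    class = "zone_areas"
  )
  structure(
    list(A = A, B = B, C = C, roi_mask = roi_mask,
         band_width_um = band_width_um, pixel_size_um = pixel_size_um,
         areas = areas),
    class = "region_masks"
  )
}

#' Attach zone labels to phenotyped cells
#'
#' Each cell gets the zone of the pixel containing its nucleus centroid
#' (half-open pixel boxes: micron coordinate x falls in pixel column
#' `floor(x / pixel_size) + 1`). Centroids outside the ROI get zone
#' `"none"` and are excluded from densities (counted in QC).
#'
#' @param cells data frame with `centroid_x_um`, `centroid_y_um`.
#' @param masks a [partition_zones()] result.
#' @return `cells` with a `zone` column (`"A"`, `"B"`, `"C"`, `"none"`).
#' @export
assign_cells_to_zones <- function(cells, masks) {
  px <- masks$pixel_size_um
  d <- dim(masks$roi_mask)
  col <- floor(cells$centroid_x_um / px) + 1L
  row <- floor(cells$centroid_y_um / px) + 1L
  zone <- rep("none", nrow(cells))
  inside <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1]
  idx <- cbind(row[inside], col[inside])
  z <- rep("none", sum(inside))
  z[masks$A[idx]] <- "A"
  z[masks$B[idx]] <- "B"
  z[masks$C[idx]] <- "C"
  zone[inside] <- z
  cells$zone <- zone
  cells
}

#' Automatic tissue ROI from the counterstain
#'
#' Fallback for the pathologist's manual ROI: pixels with hematoxylin OD
#' above a floor, morphologically closed, holes filled, small specks
#' removed. For synthetic slides the valid-pixel mask of the virtual
#' image is usually the better ROI; this detector is for real scans with
#' empty glass around the tissue.
#'
#' @param hematoxylin_od H x W OD matrix.
#' @param pixel_size_um microns per pixel.
#' @param od_floor minimum OD considered tissue.
#' @param closing_radius_um closing radius.
#' @param min_object_area_um2 specks smaller than this are dropped.
#' @return logical H x W mask.
#' @export
detect_tissue_roi <- function(hematoxylin_od, pixel_size_um,
                              od_floor = 0.05, closing_radius_um = 10,
                              min_object_area_um2 = 1000) {
  m <- hematoxylin_od >= od_floor
  if (!any(m)) return(m)
  img <- EBImage::closing(EBImage::Image(m * 1),
                          disk_brush(closing_radius_um, pixel_size_um))
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  if (max(lab) > 0) {
    areas <- tabulate(as.integer(lab[lab > 0]), nbins = max(lab))
    keep <- which(areas * pixel_size_um^2 >= min_object_area_um2)
    return(matrix(as.matrix(lab) %in% keep, nrow(m), ncol(m)))
  }
  as.matrix(img) > 0
}

#' Write zone masks as an 8-bit label PNG
#'
#' Labels: 0 outside ROI, 1 zone A, 2 zone B, 3 zone C.
#'
#' @param masks a [partition_zones()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_zone_masks <- function(masks, path) {
  lab <- matrix(0L, nrow(masks$A), ncol(masks$A))
  lab[masks$A] <- 1L
  lab[masks$B] <- 2L
  lab[masks$C] <- 3L
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' Read zone masks written by [write_zone_masks()]
#'
#' @param path PNG path.
#' @param band_width_um,pixel_size_um metadata to attach.
#' @return a `region_masks` object.
#' @export
read_zone_masks <- function(path, band_width_um = 30, pixel_size_um = 1) {
  lab <- round(png::readPNG(path) * 255)
  if (length(dim(lab)) == 3L) lab <- lab[, , 1]
  A <- lab == 1; B <- lab == 2; C <- lab == 3
  px_area <- pixel_size_um^2
  areas <- structure(
    list(area_um2 = c(A = sum(A), B = sum(B), C = sum(C)) * px_area,
         roi_area_um2 = sum(A | B | C) * px_area),
    class = "zone_areas"
  )
  structure(
    list(A = A, B = B, C = C, roi_mask = A | B | C,
         band_width_um = band_width_um, pixel_size_um = pixel_size_um,
         areas = areas),
    class = "region_masks"
  )
}
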