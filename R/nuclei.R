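#' Detect nuclei on the hematoxylin counterstain
#'
#' Form-and-size nucleus detector: the hematoxylin OD map is smoothed,
#' thresholded, and touching nuclei are split by watershed on the distance
#' transform. Components are filtered by equivalent diameter and
#' circularity (`4 * pi * area / perimeter^2`), and detections whose
#' centroid falls outside the valid-pixel mask are dropped.
#'
#' @param hematoxylin_od H x W OD matrix.
#' @param pixel_size_um microns per pixel (> 0).
#' @param od_threshold OD threshold separating nuclei from background.
#' @param min_diameter_um,max_diameter_um equivalent-diameter bounds.
#' @param min_circularity circularity floor in `[0, 1]`.
#' @param smooth_sigma_um Gaussian smoothing sigma.
#' @param valid_mask optional logical mask restricting detections.
#' @return object of class `nucleus_detections`: list with `cells` (data
#'   frame: `cell_id`, `centroid_x_um`, `centroid_y_um`,
#'   `equivalent_diameter_um`, `circularity`) and `labels` (H x W integer
#'   label matrix, 0 = background, values matching `cell_id`).
#' @export
detect_nuclei <- function(hematoxylin_od, pixel_size_um,
                          od_threshold = 0.15, min_diameter_um = 4,
                          max_diameter_um = 14, min_circularity = 0.6,
                          smooth_sigma_um = 0.75, valid_mask = NULL) {
  stopifnot(pixel_size_um > 0)
  empty <- list(
    cells = data.frame(cell_id = integer(), centroid_x_um = numeric(),
                       centroid_y_um = numeric(),
                       equivalent_diameter_um = numeric(),
                       circularity = numeric()),
    labels = matrix(0L, nrow(hematoxylin_od), ncol(hematoxylin_od)))
  class(empty) <- "nucleus_detections"
  img <- EBImage::Image(hematoxylin_od)
  sigma_px <- smooth_sigma_um / pixel_size_um
  if (sigma_px > 0.2)
    img <- EBImage::gblur(img, sigma = sigma_px)
  bin <- img >= od_threshold
  if (!any(bin)) return(empty)
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  n <- max(lab)
  if (n == 0) return(empty)
  fs <- EBImage::computeFeatures.shape(lab)
  fm <- EBImage::computeFeatures.moment(lab)
  area_px <- fs[, "s.area"]
  perim_px <- pmax(fs[, "s.perimeter"], 1)
  diam_um <- 2 * sqrt(area_px / pi) * pixel_size_um
  circ <- pmin(1, 4 * pi * area_px / perim_px^2)
  keep <- diam_um >= min_diameter_um & diam_um <= max_diameter_um &
    circ >= min_circularity
  # EBImage moments: m.cx along dim1 (rows), m.cy along dim2 (cols)
  cy_px <- fm[, "m.cx"]
  cx_px <- fm[, "m.cy"]
  if (!is.null(valid_mask)) {
    r <- pmin(pmax(round(cy_px), 1), nrow(valid_mask))
    c <- pmin(pmax(round(cx_px), 1), ncol(valid_mask))
    keep <- keep & valid_mask[cbind(r, c)]
  }
  ids <- which(keep)
  labels <- as.matrix(lab)
  labels[!(labels %in% ids)] <- 0L
  relabel <- integer(n)
  relabel[ids] <- seq_along(ids)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  # pixel centre (row r, col c) sits at micron coords ((c-0.5), (r-0.5))*px
  cells <- data.frame(
    cell_id = seq_along(ids),
    centroid_x_um = (cx_px[ids] - 0.5) * pixel_size_um,
    centroid_y_um = (cy_px[ids] - 0.5) * pixel_size_um,
    equivalent_diameter_um = diam_um[ids],
    circularity = circ[ids]
  )
  structure(list(cells = cells, labels = labels),
            class = "nucleus_detections")
}

#' @export
print.nucleus_detections <- function(x, ...) {
  cat(sprintf("nucleus detections: %d cells\n", nrow(x$cells)))
  invisible(x)
}
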