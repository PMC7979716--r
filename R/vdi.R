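#' Marker panel of the six-plex assay
#'
#' The staining order of the sequential six-round panel: four T-cell
#' lineage markers, the proliferation marker Ki67 and cytokeratin (CK) for
#' tumour recognition. Hematoxylin counterstain is present in every round.
#'
#' @return character vector of marker names in staining order.
#' @export
marker_panel <- function() c("Foxp3", "CD3", "CD8", "CD4", "Ki67", "CK")

#' One digitised single-stain round
#'
#' @param rgb_pixels H x W x 3 array of 8-bit intensities (0..255).
#' @param marker_name one of [marker_panel()].
#' @param pixel_size_um microns per pixel (> 0).
#' @param round_index position in the staining order (1..6).
#' @return object of class `stain_round`.
#' @export
stain_round <- function(rgb_pixels, marker_name, pixel_size_um,
                        round_index = match(marker_name, marker_panel())) {
  if (!marker_name %in% marker_panel())
    stop("unknown marker name '", marker_name, "'")
  stopifnot(length(dim(rgb_pixels)) == 3L, dim(rgb_pixels)[3] == 3L,
            pixel_size_um > 0)
  structure(
    list(rgb_pixels = rgb_pixels, marker_name = marker_name,
         pixel_size_um = as.numeric(pixel_size_um),
         round_index = as.integer(round_index)),
    class = "stain_round"
  )
}

#' Read a single-stain round from a TIFF or PNG file
#'
#' @param path 8-bit RGB TIFF or PNG file.
#' @param marker_name marker stained in this round.
#' @param pixel_size_um microns per pixel.
#' @return a [stain_round()].
#' @export
read_stain_round <- function(path, marker_name, pixel_size_um) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  stain_round(round(img * 255), marker_name, pixel_size_um)
}

write_rgb_image <- function(rgb, path) {
  ext <- tolower(tools::file_ext(path))
  img <- rgb / 255
  img[img < 0] <- 0; img[img > 1] <- 1
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Fuse registered rounds into a virtual multiplexed image
#'
#' Each round is unmixed into chromogen and hematoxylin OD, warped into
#' the reference frame with bilinear interpolation, and stacked by marker.
#' The hematoxylin map of the reference round is kept as the common
#' counterstain. The valid-pixel mask is the intersection of the warped
#' footprints of all rounds; downstream analyses are restricted to it.
#'
#' @param rounds list of [stain_round()] (same dimensions).
#' @param transforms named list of [round_transform()] from
#'   [register_rounds()], one per round.
#' @param basis a [stain_basis()].
#' @param reference_marker marker whose hematoxylin map becomes the
#'   reference counterstain (default the round with the identity
#'   transform).
#' @return object of class `vdi`: list with `markers` (named list of H x W
#'   chromogen OD matrices), `hematoxylin_od`, `valid_mask`,
#'   `pixel_size_um`, `transforms`.
#' @export
build_vdi <- function(rounds, transforms, basis = stain_basis(),
                      reference_marker = NULL) {
  stopifnot(length(rounds) == length(transforms))
  markers <- vapply(rounds, function(r) r$marker_name, character(1))
  if (!is.null(names(transforms))) transforms <- transforms[markers]
  d <- dim(rounds[[1]]$rgb_pixels)[1:2]
  for (r in rounds) {
    if (!all(dim(r$rgb_pixels)[1:2] == d))
      stop("round dimensions differ beyond the padding contract")
  }
  if (is.null(reference_marker)) {
    idn <- vapply(transforms, is_identity_transform, logical(1))
    reference_marker <- if (any(idn)) markers[which(idn)[1]] else markers[1]
  }
  maps <- vector("list", length(rounds))
  names(maps) <- markers
  valid <- matrix(TRUE, d[1], d[2])
  hema_ref <- NULL
  for (i in seq_along(rounds)) {
    od <- rgb_to_od(rounds[[i]]$rgb_pixels)
    sep <- separate_stains(od, basis)
    tf <- transforms[[i]]
    maps[[i]] <- warp_image(sep$chromogen_od, tf)
    valid <- valid & warp_footprint(sep$chromogen_od, tf)
    if (markers[i] == reference_marker)
      hema_ref <- warp_image(sep$hematoxylin_od, tf)
  }
  structure(
    list(markers = maps, hematoxylin_od = hema_ref, valid_mask = valid,
         pixel_size_um = rounds[[1]]$pixel_size_um,
         transforms = transforms, reference_marker = reference_marker),
    class = "vdi"
  )
}

#' @export
print.vdi <- function(x, ...) {
  d <- dim(x$hematoxylin_od)
  cat(sprintf(
    "virtual multiplexed image: %d x %d px (%.3g um/px), markers: %s\n",
    d[1], d[2], x$pixel_size_um, paste(names(x$markers), collapse = ", ")))
  cat(sprintf("valid pixels: %.1f%%\n", 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Persist a virtual multiplexed image as a multi-page float TIFF
#'
#' Pages are the per-marker chromogen OD maps followed by the hematoxylin
#' map and the valid mask; page names, transforms and pixel size live in
#' the JSON sidecar `<path>.json`.
#'
#' @param vdi a [build_vdi()] result.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
save_vdi <- function(vdi, path) {
  od_max <- 3
  pages <- c(vdi$markers,
             list(hematoxylin = vdi$hematoxylin_od,
                  valid_mask = vdi$valid_mask * 1))
  page_names <- names(pages)
  pages <- lapply(pages, function(m) {
    m[m < 0] <- 0; m[m > od_max] <- od_max
    m / od_max
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_transforms(vdi$transforms, paste0(path, ".json"),
                   pixel_size_um = vdi$pixel_size_um,
                   reference_marker = vdi$reference_marker,
                   pages = page_names)
  invisible(path)
}

#' Load a virtual multiplexed image saved by [save_vdi()]
#'
#' @param path TIFF path written by [save_vdi()].
#' @return a `vdi` object.
#' @export
load_vdi <- function(path) {
  od_max <- 3
  meta <- read_transforms(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nm <- unlist(meta$pages)
  pages <- lapply(pages, function(p) {
    attributes(p)[setdiff(names(attributes(p)), "dim")] <- NULL
    p * od_max
  })
  names(pages) <- nm
  structure(
    list(markers = pages[setdiff(nm, c("hematoxylin", "valid_mask"))],
         hematoxylin_od = pages[["hematoxylin"]],
         valid_mask = pages[["valid_mask"]] > 0.5,
         pixel_size_um = meta$pixel_size_um,
         transforms = meta$transforms,
         reference_marker = meta$reference_marker),
    class = "vdi"
  )
}

#' Write per-round transforms to JSON
#'
#' @param transforms named list of [round_transform()].
#' @param path output file.
#' @param ... extra scalar metadata stored alongside.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(transforms, path, ...) {
  obj <- list(
    transforms = lapply(transforms, function(tf) {
      list(dx_px = tf$dx_px, dy_px = tf$dy_px,
           rotation_deg = tf$rotation_deg, scale = tf$scale,
           score = if (is.finite(tf$score)) tf$score else NULL)
    }),
    ...
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read transforms written by [write_transforms()]
#'
#' @param path JSON file.
#' @return list with `transforms` (named list of [round_transform()]) plus
#'   any stored metadata.
#' @export
read_transforms <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  obj$transforms <- lapply(obj$transforms, function(t) {
    round_transform(t$dx_px, t$dy_px, t$rotation_deg, t$scale,
                    score = if (is.null(t$score)) NA_real_ else t$score)
  })
  obj
}
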