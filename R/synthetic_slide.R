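#' Configuration of a synthetic six-round slide
#'
#' Defines the ground-truth cell map and the acquisition model for a
#' simulated sequential-staining experiment: one slide is "stained,
#' scanned and destained" six times, once per marker, each round slightly
#' misaligned against the others, with hematoxylin counterstain present
#' in every round.
#'
#' Defaults describe a 512 x 512 um field at 20x-like resolution
#' (0.5 um/px) with three tumour nests, an immune infiltrate whose
#' CD3+ subset mix mirrors proportions reported for HER2+ breast cancer
#' (roughly 47/30/11/13 CD8_T/CD4_T/Treg/CD3_only), and Ki67 rates that
#' decrease with distance from tumour.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param pixel_size_um microns per pixel (> 0).
#' @param tumour_nests data frame with `centre_x_um`, `centre_y_um`,
#'   `radius_um`; nests must lie inside the image.
#' @param n_cells_per_phenotype named counts for `CD8_T`, `CD4_T`,
#'   `Treg`, `CD3_only`, `other`; tumour cells fill the nests on a
#'   packed grid unless a `tumour` count is also given.
#' @param intratumoural_fraction fraction of each immune phenotype placed
#'   inside tumour nests (zone A); the remainder is stromal.
#' @param ki67_rate_by_zone named fractions in `[0, 1]` for zones A, B, C
#'   applied to immune cells by their true zone.
#' @param tumour_ki67_rate Ki67 rate of tumour cells (tumour is the main
#'   proliferative compartment).
#' @param chromogen_amplitude_od chromogen OD at a positive compartment.
#' @param hematoxylin_amplitude_od nuclear counterstain OD.
#' @param nucleus_diameter_um nucleus diameter (circles).
#' @param ring_width_um membrane-marker ring width.
#' @param ck_radius_um radius of the cytokeratin cytoplasmic blob; also
#'   the half-width of the ground-truth tumour mask around tumour cells.
#' @param round_misalignment named list (by marker) of
#'   `c(dx_px, dy_px, rotation_deg)` giving each round's true transform
#'   in the registration convention (reference frame to round frame).
#' @param noise_sd_od additive Gaussian OD noise (per RGB channel).
#' @param background_rgb background (white) intensity.
#' @param chromogen stain name or OD vector for [stain_basis()].
#' @param seed integer; fixes all randomness of the slide.
#' @return object of class `slide_config`.
#' @export
slide_config <- function(
    image_height_px = 1024, image_width_px = 1024, pixel_size_um = 0.5,
    tumour_nests = data.frame(
      centre_x_um = c(140, 365, 255),
      centre_y_um = c(150, 170, 385),
      radius_um = c(85, 70, 95)),
    n_cells_per_phenotype = c(CD8_T = 160, CD4_T = 100, Treg = 40,
                              CD3_only = 45, other = 60),
    intratumoural_fraction = 0.15,
    ki67_rate_by_zone = c(A = 0.25, B = 0.15, C = 0.08),
    tumour_ki67_rate = 0.45,
    chromogen_amplitude_od = 0.6,
    hematoxylin_amplitude_od = 0.5,
    nucleus_diameter_um = 7,
    ring_width_um = 1.5,
    ck_radius_um = 6,
    round_misalignment = list(
      Foxp3 = c(0, 0, 0), CD3 = c(3, -2, 0.4), CD8 = c(-4, 3, -0.6),
      CD4 = c(5, -3, 0.8), Ki67 = c(-2, -4, -0.3), CK = c(4, 4, 0.5)),
    noise_sd_od = 0.02,
    background_rgb = 255,
    chromogen = "DAB",
    seed = 1) {
  stopifnot(image_height_px >= 64, image_width_px >= 64, pixel_size_um > 0,
            noise_sd_od >= 0, chromogen_amplitude_od > 0,
            hematoxylin_amplitude_od > 0)
  # accept list-shaped inputs (e.g. parsed from a YAML config)
  tumour_nests <- as.data.frame(tumour_nests)
  n_cells_per_phenotype <- unlist(n_cells_per_phenotype)
  ki67_rate_by_zone <- unlist(ki67_rate_by_zone)
  round_misalignment <- lapply(round_misalignment, unlist)
  if (length(n_cells_per_phenotype) &&
      is.null(names(n_cells_per_phenotype)))
    stop("n_cells_per_phenotype must be named by phenotype")
  stopifnot(all(n_cells_per_phenotype >= 0),
            intratumoural_fraction >= 0, intratumoural_fraction <= 1)
  stopifnot(all(ki67_rate_by_zone >= 0 & ki67_rate_by_zone <= 1),
            all(c("A", "B", "C") %in% names(ki67_rate_by_zone)),
            tumour_ki67_rate >= 0, tumour_ki67_rate <= 1)
  w_um <- image_width_px * pixel_size_um
  h_um <- image_height_px * pixel_size_um
  with(tumour_nests, stopifnot(
    all(centre_x_um - radius_um >= 0), all(centre_x_um + radius_um <= w_um),
    all(centre_y_um - radius_um >= 0), all(centre_y_um + radius_um <= h_um)))
  stopifnot(all(marker_panel() %in% names(round_misalignment)))
  structure(
    list(image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         pixel_size_um = pixel_size_um, tumour_nests = tumour_nests,
         n_cells_per_phenotype = n_cells_per_phenotype,
         intratumoural_fraction = intratumoural_fraction,
         ki67_rate_by_zone = ki67_rate_by_zone,
         tumour_ki67_rate = tumour_ki67_rate,
         chromogen_amplitude_od = chromogen_amplitude_od,
         hematoxylin_amplitude_od = hematoxylin_amplitude_od,
         nucleus_diameter_um = nucleus_diameter_um,
         ring_width_um = ring_width_um, ck_radius_um = ck_radius_um,
         round_misalignment = round_misalignment,
         noise_sd_od = noise_sd_od, background_rgb = background_rgb,
         chromogen = chromogen, seed = as.integer(seed)),
    class = "slide_config"
  )
}

slide_basis <- function(config) stain_basis(config$chromogen)

true_transforms <- function(config) {
  lapply(config$round_misalignment, function(v)
    round_transform(v[1], v[2], v[3]))
}

# draw value into an annulus/disk around (cx, cy) um; returns the matrix
draw_annulus <- function(mat, cx_um, cy_um, r_in_um, r_out_um, value,
                         pixel_size_um) {
  d <- dim(mat)
  cx_px <- cx_um / pixel_size_um + 0.5
  cy_px <- cy_um / pixel_size_um + 0.5
  rr <- ceiling(r_out_um / pixel_size_um) + 1L
  cols <- max(1L, floor(cx_px) - rr):min(d[2], ceiling(cx_px) + rr)
  rows <- max(1L, floor(cy_px) - rr):min(d[1], ceiling(cy_px) + rr)
  if (!length(cols) || !length(rows)) return(mat)
  dx <- (cols - cx_px) * pixel_size_um
  dy <- (rows - cy_px) * pixel_size_um
  dist <- sqrt(outer(dy^2, dx^2, `+`))
  sel <- dist <= r_out_um & dist > r_in_um
  win <- mat[rows, cols, drop = FALSE]
  win[sel] <- pmax(win[sel], value)
  mat[rows, cols] <- win
  mat
}

# per-marker compartment geometry for rendering, mirrored by the analyzer
render_compartment <- function(marker, config) {
  r_nuc <- config$nucleus_diameter_um / 2
  switch(marker_compartment(marker),
    nuclear = c(0, r_nuc),
    ring = c(r_nuc, r_nuc + config$ring_width_um),
    cytoplasmic = c(0, config$ck_radius_um))
}

#' Render one single-stain round of a synthetic slide
#'
#' Forward model of a chromogenic scan: every cell contributes nuclear
#' hematoxylin OD; cells positive for the round's marker additionally
#' contribute chromogen OD in the marker's compartment (nuclear disk for
#' Ki67/Foxp3, membrane ring for CD3/CD4/CD8, cytoplasmic blob for CK).
#' The configured misalignment is applied (the ideal OD fields are warped
#' into the round's frame), Gaussian OD noise is added per channel, and
#' the Beer-Lambert model inverted by [rgb_to_od()] converts OD to 8-bit
#' RGB.
#'
#' @param ground_truth a `slide_truth` object from [generate_slide()] (or
#'   its `cells` / `transforms` components assembled alike).
#' @param marker one of [marker_panel()].
#' @param config the [slide_config()].
#' @param hema_ideal optional precomputed ideal-frame hematoxylin OD map
#'   (identical across rounds; [generate_slide()] renders it once).
#' @return a [stain_round()].
#' @export
render_round <- function(ground_truth, marker, config, hema_ideal = NULL) {
  if (!marker %in% marker_panel())
    stop("unknown marker name '", marker, "'")
  cells <- ground_truth$cells
  d <- c(config$image_height_px, config$image_width_px)
  px <- config$pixel_size_um
  chrom <- matrix(0, d[1], d[2])
  hema <- if (is.null(hema_ideal)) ideal_hema_map(cells, config)
          else hema_ideal
  comp <- render_compartment(marker, config)
  flag <- cells[[paste0(tolower(marker), "_true")]]
  for (i in which(flag)) {
    chrom <- draw_annulus(chrom, cells$x_um[i], cells$y_um[i],
                          comp[1], comp[2],
                          config$chromogen_amplitude_od, px)
  }
  tf <- ground_truth$transforms[[marker]]
  if (!is_identity_transform(tf)) {
    inv <- invert_transform(tf)
    chrom <- warp_image(chrom, inv)
    hema <- warp_image(hema, inv)
  }
  od <- synthesize_od(chrom, hema, slide_basis(config))
  if (config$noise_sd_od > 0) {
    idx <- match(marker, marker_panel())
    set.seed((config$seed * 97L + idx * 1009L) %% .Machine$integer.max)
    od <- od + stats::rnorm(length(od), sd = config$noise_sd_od)
    od[od < 0] <- 0
  }
  rgb <- round(od_to_rgb(od, config$background_rgb))
  stain_round(rgb, marker, px)
}

ideal_hema_map <- function(cells, config) {
  hema <- matrix(0, config$image_height_px, config$image_width_px)
  r_nuc <- config$nucleus_diameter_um / 2
  for (i in seq_len(nrow(cells)))
    hema <- draw_annulus(hema, cells$x_um[i], cells$y_um[i], 0, r_nuc,
                         config$hematoxylin_amplitude_od,
                         config$pixel_size_um)
  hema
}

place_tumour_cells <- function(config) {
  spacing <- 8
  jitter <- 0.4
  pts <- NULL
  for (k in seq_len(nrow(config$tumour_nests))) {
    nest <- config$tumour_nests[k, ]
    reach <- nest$radius_um - config$ck_radius_um
    if (reach <= 0) next
    gx <- seq(nest$centre_x_um - nest$radius_um,
              nest$centre_x_um + nest$radius_um, by = spacing)
    gy <- seq(nest$centre_y_um - nest$radius_um,
              nest$centre_y_um + nest$radius_um, by = spacing)
    g <- expand.grid(x = gx, y = gy)
    g$x <- g$x + stats::runif(nrow(g), -jitter, jitter)
    g$y <- g$y + stats::runif(nrow(g), -jitter, jitter)
    keep <- sqrt((g$x - nest$centre_x_um)^2 +
                 (g$y - nest$centre_y_um)^2) <= reach
    pts <- rbind(pts, g[keep, ])
  }
  pts
}

# rejection-sample n points from candidate positions with minimum-distance
# constraints against two sets of already-placed cells (e.g. immune at
# 8.5 um, tumour at 9 um) and among themselves
place_points <- function(n, propose, existing, min_dist_existing = 8.5,
                         min_dist_self = 8.5, existing2 = NULL,
                         min_dist2 = 9) {
  xs <- numeric(0); ys <- numeric(0)
  ex <- existing$x; ey <- existing$y
  e2x <- existing2$x; e2y <- existing2$y
  attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > 600L * max(1L, n))
      stop("requested cell count unplaceable in available area")
    p <- propose()
    if (is.null(p)) next
    if (length(ex) &&
        min((ex - p[1])^2 + (ey - p[2])^2) < min_dist_existing^2) next
    if (length(e2x) &&
        min((e2x - p[1])^2 + (e2y - p[2])^2) < min_dist2^2) next
    if (length(xs) &&
        min((xs - p[1])^2 + (ys - p[2])^2) < min_dist_self^2) next
    xs <- c(xs, p[1]); ys <- c(ys, p[2])
  }
  data.frame(x = xs, y = ys)
}

# uniform proposal deep inside a random nest (margin from the nest edge
# keeps the stromal pocket around an intratumoural cell fully enclosed by
# tumour cells, so hole filling is deterministic for truth and analyzer)
propose_in_nest <- function(config, nest_margin_um = 18) {
  nests <- config$tumour_nests
  reach <- nests$radius_um - nest_margin_um
  ok <- which(reach > 0)
  if (!length(ok)) stop("nests too small for intratumoural placement")
  function() {
    k <- ok[sample.int(length(ok), 1)]
    r <- nests$radius_um[k]
    repeat {
      x <- stats::runif(1, -r, r); y <- stats::runif(1, -r, r)
      if (x^2 + y^2 <= reach[k]^2)
        return(c(nests$centre_x_um[k] + x, nests$centre_y_um[k] + y))
    }
  }
}

# uniform proposal over an eligibility mask (pixel picked uniformly, then
# sub-pixel jitter)
propose_in_mask <- function(mask, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty placement region")
  function() {
    i <- sample.int(nrow(idx), 1)
    c((idx[i, 2] - 0.5) * pixel_size_um + stats::runif(1, -0.3, 0.3),
      (idx[i, 1] - 0.5) * pixel_size_um + stats::runif(1, -0.3, 0.3))
  }
}

# ground-truth tumour mask: the analyzer's own mask routine applied to
# the noise-free ideal cytokeratin field, so truth and analysis share
# one mask semantics and differ only by acquisition effects
truth_tumour_mask <- function(xy, config) {
  d <- c(config$image_height_px, config$image_width_px)
  m <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(xy)))
    m <- draw_annulus(m, xy$x[i], xy$y[i], 0, config$ck_radius_um,
                      config$chromogen_amplitude_od, config$pixel_size_um)
  build_tumor_mask(m, matrix(TRUE, d[1], d[2]), config$pixel_size_um,
                   threshold = config$chromogen_amplitude_od / 2)
}

#' Generate a ground-truthed synthetic slide
#'
#' Places tumour cells on a jittered packed grid inside the configured
#' nests and immune/stromal cells by minimum-distance rejection sampling
#' (8.5 um spacing: nuclei never overlap and same-marker compartment
#' cross-talk between neighbours stays well below threshold), builds the
#' true
#' tumour mask and A/B/C zones (via [partition_zones()] — generator and
#' analyzer share one zone definition), samples Ki67 by zone, and renders
#' all six stain rounds.
#'
#' @param config a [slide_config()].
#' @return list with `rounds` (named list of [stain_round()]) and
#'   `ground_truth` (class `slide_truth`): `cells` data frame (`cell_id`,
#'   `x_um`, `y_um`, per-marker `*_true` flags, `phenotype`, `zone`),
#'   `tumour_mask`, `masks` (a `region_masks`), `transforms`, `config`.
#' @export
generate_slide <- function(config = slide_config()) {
  stopifnot(inherits(config, "slide_config"))
  set.seed(config$seed)
  counts <- config$n_cells_per_phenotype
  immune_phen <- c("CD8_T", "CD4_T", "Treg", "CD3_only")
  px <- config$pixel_size_um
  d_img <- c(config$image_height_px, config$image_width_px)
  # 1) intratumoural immune cells, deep inside the nests: their stromal
  # micro-pockets stay fully enclosed by tumour cells, so hole filling
  # (and hence the zone A label) is deterministic for truth and analyzer
  frac_a <- config$intratumoural_fraction
  count_of <- function(ph)
    if (ph %in% names(counts)) counts[[ph]] else 0
  imm <- NULL
  for (ph in immune_phen) {
    n_a <- round(frac_a * count_of(ph))
    if (n_a > 0) {
      # 20 um spacing: intratumoural lymphocytes are scattered single
      # cells whose stromal pockets stay isolated (never percolate into
      # channels whose sealing could differ between truth and analysis)
      p <- place_points(n_a, propose_in_nest(config),
                        existing = list(x = imm$x, y = imm$y),
                        min_dist_existing = 20, min_dist_self = 20)
      p$phenotype <- ph
      imm <- rbind(imm, p)
    }
  }
  # 2) tumour grid, avoiding the intratumoural immune cells (9 um: their
  # measurement compartments and the closing of the CK mask can never
  # reach an immune centroid)
  tum <- place_tumour_cells(config)
  if (!is.null(imm) && nrow(tum)) {
    keep <- vapply(seq_len(nrow(tum)), function(i)
      min((imm$x - tum$x[i])^2 + (imm$y - tum$y[i])^2) >= 9^2,
      logical(1))
    tum <- tum[keep, , drop = FALSE]
  }
  if ("tumour" %in% names(counts) && !is.na(counts[["tumour"]])) {
    nt <- counts[["tumour"]]
    if (nt > nrow(tum))
      stop("requested cell count unplaceable in available area")
    tum <- tum[sample(nrow(tum), nt), , drop = FALSE]
  }
  # 3) true tumour mask and zones (shared definition with the analyzer)
  tumour_mask <- truth_tumour_mask(tum, config)
  roi <- matrix(TRUE, d_img[1], d_img[2])
  masks <- partition_zones(tumour_mask, roi, band_width_um = 30,
                           pixel_size_um = px)
  # 4) stromal cells: uniform over the stroma, keeping a 2 um buffer
  # around the 30 um B/C contour (sub-pixel mask differences never flip
  # a zone label) and a 10 um margin from the image border
  d_um <- as.matrix(EBImage::distmap(
    EBImage::Image((!tumour_mask) * 1))) * px
  border <- matrix(FALSE, d_img[1], d_img[2])
  mg <- ceiling(10 / px)
  border[(mg + 1):(d_img[1] - mg), (mg + 1):(d_img[2] - mg)] <- TRUE
  stroma_ok <- !tumour_mask & border & (d_um <= 28 | d_um >= 32)
  for (ph in immune_phen) {
    n_s <- count_of(ph) - round(frac_a * count_of(ph))
    if (n_s > 0) {
      p <- place_points(n_s, propose_in_mask(stroma_ok, px),
                        existing = list(x = imm$x, y = imm$y),
                        existing2 = tum, min_dist2 = 9)
      p$phenotype <- ph
      imm <- rbind(imm, p)
    }
  }
  # "other" (CD3- stromal) cells stay >= 12 um from the tumour mask so
  # cytokeratin spill can never make them CK+ (which would phenotype
  # them as tumour)
  n_other <- count_of("other")
  if (n_other > 0) {
    p <- place_points(n_other, propose_in_mask(stroma_ok & d_um >= 12, px),
                      existing = list(x = imm$x, y = imm$y),
                      existing2 = tum, min_dist2 = 9)
    p$phenotype <- "other"
    imm <- rbind(imm, p)
  }
  tum$phenotype <- "tumour"
  cells <- rbind(imm, tum)
  cells <- data.frame(cell_id = seq_len(nrow(cells)), x_um = cells$x,
                      y_um = cells$y, phenotype = cells$phenotype)
  cells <- assign_cells_to_zones(
    data.frame(cells, centroid_x_um = cells$x_um,
               centroid_y_um = cells$y_um), masks)
  cells$centroid_x_um <- cells$centroid_y_um <- NULL
  # marker flags
  ph <- cells$phenotype
  cells$cd3_true <- ph %in% immune_phen
  cells$cd8_true <- ph == "CD8_T"
  cells$cd4_true <- ph %in% c("CD4_T", "Treg")
  cells$foxp3_true <- ph == "Treg"
  cells$ck_true <- ph == "tumour"
  rate <- ifelse(ph == "tumour", config$tumour_ki67_rate,
                 config$ki67_rate_by_zone[cells$zone])
  rate[is.na(rate)] <- 0
  cells$ki67_true <- stats::runif(nrow(cells)) < rate
  truth <- structure(
    list(cells = cells, tumour_mask = tumour_mask, masks = masks,
         transforms = true_transforms(config), config = config),
    class = "slide_truth"
  )
  hema_ideal <- ideal_hema_map(cells, config)
  rounds <- lapply(marker_panel(), function(m)
    render_round(truth, m, config, hema_ideal = hema_ideal))
  names(rounds) <- marker_panel()
  list(rounds = rounds, ground_truth = truth)
}

#' @export
print.slide_truth <- function(x, ...) {
  cat(sprintf("synthetic slide truth: %d cells (%s)\n", nrow(x$cells),
              paste(sprintf("%s %d", levels(factor(x$cells$phenotype)),
                            table(x$cells$phenotype)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic slide to a directory
#'
#' Writes one 8-bit RGB TIFF per marker (`<marker>.tiff`),
#' `ground_truth.csv` and `transforms.json`.
#'
#' @param slide a [generate_slide()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(slide$rounds))
    write_rgb_image(slide$rounds[[m]]$rgb_pixels,
                    file.path(dir, paste0(m, ".tiff")))
  utils::write.csv(slide$ground_truth$cells,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  write_transforms(slide$ground_truth$transforms,
                   file.path(dir, "transforms.json"),
                   pixel_size_um = slide$ground_truth$config$pixel_size_um)
  invisible(dir)
}
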