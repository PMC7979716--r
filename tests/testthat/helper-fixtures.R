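# shared fixtures: a small synthetic slide (256 x 256 um field) reused
# across test files, generated once per run

`%||%` <- function(a, b) if (is.null(a)) b else a

widen_stils <- function(cohort) {
  w <- stats::reshape(cohort[, c("patient_id", "timepoint", "stils_pct")],
                      idvar = "patient_id", timevar = "timepoint",
                      direction = "wide")
  names(w) <- sub("^stils_pct\\.", "", names(w))
  w
}

small_slide_config <- function(seed = 42, noise_sd_od = 0.02, ...) {
  slide_config(
    image_height_px = 512, image_width_px = 512, pixel_size_um = 0.5,
    tumour_nests = data.frame(
      centre_x_um = c(75, 180, 120),
      centre_y_um = c(75, 95, 190),
      radius_um = c(55, 45, 52)),
    n_cells_per_phenotype = c(CD8_T = 30, CD4_T = 20, Treg = 10,
                              CD3_only = 10, other = 16),
    seed = seed, noise_sd_od = noise_sd_od, ...)
}

.fixture_env <- new.env(parent = emptyenv())

cached_small_slide <- function() {
  if (is.null(.fixture_env$slide))
    .fixture_env$slide <- generate_slide(small_slide_config())
  .fixture_env$slide
}

cached_small_analysis <- function() {
  if (is.null(.fixture_env$analysis))
    .fixture_env$analysis <- analyze_sample(cached_small_slide()$rounds)
  .fixture_env$analysis
}

# truth cell table in the analyzer's column layout, for metric comparison
truth_cell_table <- function(truth) {
  tt <- truth$cells
  data.frame(
    zone = tt$zone, phenotype = tt$phenotype,
    CD3_pos = tt$cd3_true, CD4_pos = tt$cd4_true, CD8_pos = tt$cd8_true,
    Foxp3_pos = tt$foxp3_true, Ki67_pos = tt$ki67_true,
    CK_pos = tt$ck_true, indeterminate = FALSE, conflict = FALSE)
}

# nearest-neighbour match of detections to ground truth (<= 4 um)
match_cells_to_truth <- function(cells, truth) {
  tt <- truth$cells
  vapply(seq_len(nrow(cells)), function(i) {
    d2 <- (tt$x_um - cells$centroid_x_um[i])^2 +
      (tt$y_um - cells$centroid_y_um[i])^2
    j <- which.min(d2)
    if (d2[j] < 16) j else NA_integer_
  }, integer(1))
}

# brute-force per-pixel minimum distance to a mask, in chunks (oracle for
# the distance-transform-based zone partition)
brute_force_distance <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, d[1], d[2])
  if (nrow(idx) == 0) return(out)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  chunk <- 4096L
  for (s in seq(1, length(rows), by = chunk)) {
    e <- min(s + chunk - 1L, length(rows))
    dr <- outer(rows[s:e], idx[, 1], `-`)
    dc <- outer(cols[s:e], idx[, 2], `-`)
    out[cbind(rows[s:e], cols[s:e])] <-
      sqrt(.rowMins(dr * dr + dc * dc))
  }
  out
}

.rowMins <- function(m) do.call(pmin, as.data.frame(m))

# random blob-like tumour/ROI mask pair for the zone-partition oracle
random_mask_pair <- function(seed, dim = c(256, 256)) {
  set.seed(seed)
  tumour <- matrix(FALSE, dim[1], dim[2])
  for (k in seq_len(sample(2:5, 1))) {
    cx <- runif(1, 30, dim[2] - 30)
    cy <- runif(1, 30, dim[1] - 30)
    r <- runif(1, 8, 28)
    cols <- pmax(1, floor(cx - r)):pmin(dim[2], ceiling(cx + r))
    rows <- pmax(1, floor(cy - r)):pmin(dim[1], ceiling(cy + r))
    dd <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
    tumour[rows, cols] <- tumour[rows, cols] | (dd <= r)
  }
  roi <- matrix(FALSE, dim[1], dim[2])
  roi[20:(dim[1] - 20), 20:(dim[2] - 20)] <- TRUE
  list(tumour = tumour & roi, roi = roi)
}
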