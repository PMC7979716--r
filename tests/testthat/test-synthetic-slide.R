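test_that("slide generation is deterministic under a fixed seed", {
  cfg <- small_slide_config(seed = 5)
  a <- generate_slide(cfg)
  b <- generate_slide(cfg)
  expect_identical(a$ground_truth$cells, b$ground_truth$cells)
  for (m in marker_panel())
    expect_identical(a$rounds[[m]]$rgb_pixels, b$rounds[[m]]$rgb_pixels)
})

test_that("requested phenotype counts are honoured", {
  truth <- cached_small_slide()$ground_truth
  counts <- table(truth$cells$phenotype)
  want <- truth$config$n_cells_per_phenotype
  for (ph in names(want)) expect_equal(unname(counts[[ph]]), want[[ph]])
  # every cell exactly one phenotype; flags consistent with it
  expect_equal(sum(counts), nrow(truth$cells))
  with(truth$cells, {
    expect_true(all(cd3_true == (phenotype %in%
      c("CD8_T", "CD4_T", "Treg", "CD3_only"))))
    expect_true(all(foxp3_true == (phenotype == "Treg")))
    expect_true(all(ck_true == (phenotype == "tumour")))
  })
})

test_that("ground-truth zones come from the shared partition definition", {
  truth <- cached_small_slide()$ground_truth
  masks <- partition_zones(truth$tumour_mask,
                           matrix(TRUE, nrow(truth$tumour_mask),
                                  ncol(truth$tumour_mask)),
                           band_width_um = 30,
                           pixel_size_um = truth$config$pixel_size_um)
  relab <- assign_cells_to_zones(
    data.frame(centroid_x_um = truth$cells$x_um,
               centroid_y_um = truth$cells$y_um), masks)
  expect_equal(relab$zone, truth$cells$zone)
})

test_that("configured Ki67 rates are matched within binomial error", {
  cfg <- small_slide_config(seed = 11,
                            ki67_rate_by_zone = c(A = 0.3, B = 0.2,
                                                  C = 0.1))
  truth <- generate_slide(cfg)$ground_truth
  imm <- truth$cells[truth$cells$phenotype %in%
                       c("CD8_T", "CD4_T", "Treg", "CD3_only"), ]
  for (z in c("A", "B", "C")) {
    inz <- imm[imm$zone == z, ]
    n <- nrow(inz)
    p <- cfg$ki67_rate_by_zone[[z]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(inz$ki67_true) - p), 3 * se + 1e-9)
  }
})

test_that("rendered chromogen matches the forward model", {
  cfg <- small_slide_config(seed = 13, noise_sd_od = 0)
  cfg$round_misalignment <- lapply(cfg$round_misalignment,
                                   function(v) c(0, 0, 0))
  slide <- generate_slide(cfg)
  truth <- slide$ground_truth
  b <- stain_basis()
  # a Ki67+ cell centre: unmixed OD equals direct pixel inversion within
  # 1e-3, and the configured amplitude within quantization error
  pos <- truth$cells[truth$cells$ki67_true, ][1, ]
  r <- pos$y_um / cfg$pixel_size_um + 0.5
  c <- pos$x_um / cfg$pixel_size_um + 0.5
  rgb <- slide$rounds$Ki67$rgb_pixels
  od_px <- rgb_to_od(rgb[round(r), round(c), , drop = FALSE],
                     background = cfg$background_rgb)
  sep <- separate_stains(od_px, b)
  M <- cbind(b$chromogen_od_vector, b$hematoxylin_od_vector)
  direct <- solve(crossprod(M), t(M) %*% as.numeric(od_px))
  expect_lt(abs(sep$chromogen_od[1, 1] - direct[1]), 1e-3)
  expect_lt(abs(sep$chromogen_od[1, 1] - cfg$chromogen_amplitude_od),
            1.5e-2)
  # a Ki67- immune cell: no chromogen at its nucleus beyond background
  neg <- truth$cells[!truth$cells$ki67_true &
                       truth$cells$phenotype == "CD3_only", ][1, ]
  odn <- rgb_to_od(rgb[round(neg$y_um / cfg$pixel_size_um + 0.5),
                       round(neg$x_um / cfg$pixel_size_um + 0.5), ,
                       drop = FALSE],
                   background = cfg$background_rgb)
  sepn <- separate_stains(odn, b)
  expect_lt(sepn$chromogen_od[1, 1], 0.05)
  expect_error(render_round(truth, "CD99", cfg), "unknown marker")
})

test_that("a configured misalignment warps the identity render", {
  cfg <- small_slide_config(seed = 17, noise_sd_od = 0)
  mis <- cfg$round_misalignment
  mis$CD8 <- c(5, -3, 1)
  cfg$round_misalignment <- mis
  cfg0 <- cfg
  mis$CD8 <- c(0, 0, 0)
  cfg0$round_misalignment <- mis
  slide <- generate_slide(cfg)
  slide0 <- generate_slide(cfg0)
  b <- stain_basis()
  od_mis <- separate_stains(rgb_to_od(slide$rounds$CD8$rgb_pixels,
                                      background = 255), b)
  od_idn <- separate_stains(rgb_to_od(slide0$rounds$CD8$rgb_pixels,
                                      background = 255), b)
  tf <- round_transform(5, -3, 1)
  warped <- warp_image(od_idn$chromogen_od, invert_transform(tf))
  fp <- warp_footprint(od_idn$chromogen_od, invert_transform(tf))
  # agreement up to 8-bit quantization and interpolation of a hard edge
  diff <- abs(od_mis$chromogen_od - warped)[fp]
  expect_lt(mean(diff), 0.005)
  expect_lt(stats::quantile(diff, 0.999), 0.2)
})

test_that("impossible cell counts are refused", {
  cfg <- small_slide_config()
  cfg$n_cells_per_phenotype[["CD8_T"]] <- 100000
  expect_error(generate_slide(cfg), "unplaceable")
})

test_that("slides write to disk and read back identically", {
  slide <- cached_small_slide()
  dir <- file.path(tempdir(), "slide_out")
  write_slide(slide, dir)
  expect_setequal(list.files(dir),
                  c(paste0(marker_panel(), ".tiff"), "ground_truth.csv",
                    "transforms.json"))
  rt <- read_stain_round(file.path(dir, "CD8.tiff"), "CD8", 0.5)
  expect_identical(rt$rgb_pixels, slide$rounds$CD8$rgb_pixels * 1)
  meta <- read_transforms(file.path(dir, "transforms.json"))
  expect_equal(meta$transforms$CD4$dx_px,
               slide$ground_truth$transforms$CD4$dx_px)
  unlink(dir, recursive = TRUE)
})
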