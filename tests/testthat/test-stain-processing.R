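test_that("optical density conversion follows the Beer-Lambert form", {
  white <- array(255, c(2, 2, 3))
  expect_equal(rgb_to_od(white, background = 255),
               array(0, c(2, 2, 3)))
  # (I + 1) = (bg + 1) / 10  =>  OD exactly 1 on that channel
  bg <- 199
  img <- array(bg, c(1, 1, 3))
  img[1, 1, 2] <- (bg + 1) / 10 - 1
  od <- rgb_to_od(img, background = bg)
  expect_equal(od[1, 1, 2], 1)
  expect_equal(od[1, 1, 1], 0)
  # black saturates at -log10(1/256) and the ceiling clips it
  expect_equal(rgb_to_od(array(0, c(1, 1, 3)), background = 255,
                         od_max = 3)[1, 1, ],
               rep(log10(256), 3))
  expect_equal(rgb_to_od(array(0, c(1, 1, 3)), background = 255,
                         od_max = 2)[1, 1, ],
               c(2, 2, 2))
  expect_error(rgb_to_od(white, background = 0), "positive")
})

test_that("od_to_rgb inverts rgb_to_od away from the clip", {
  set.seed(1)
  od <- array(runif(3 * 50, 0, 2), c(5, 10, 3))
  rgb <- od_to_rgb(od, 255)
  expect_equal(rgb_to_od(rgb, background = 255), od, tolerance = 1e-12)
})

test_that("stain separation is exact on synthesized mixtures", {
  b <- stain_basis()
  # all-white input: both maps zero
  zero <- separate_stains(array(0, c(4, 4, 3)), b)
  expect_equal(zero$chromogen_od, matrix(0, 4, 4))
  expect_equal(zero$hematoxylin_od, matrix(0, 4, 4))
  # pure hematoxylin pixel
  od <- synthesize_od(matrix(0, 1, 1), matrix(0.7, 1, 1), b)
  sep <- separate_stains(od, b)
  expect_equal(sep$chromogen_od[1, 1], 0, tolerance = 1e-6)
  expect_equal(sep$hematoxylin_od[1, 1], 0.7, tolerance = 1e-6)
  # mixture pixel
  od <- synthesize_od(matrix(0.4, 1, 1), matrix(0.6, 1, 1), b)
  sep <- separate_stains(od, b)
  expect_equal(sep$chromogen_od[1, 1], 0.4, tolerance = 1e-6)
  expect_equal(sep$hematoxylin_od[1, 1], 0.6, tolerance = 1e-6)
})

test_that("unmix-mix identity holds for random non-negative fields", {
  for (bname in c("DAB", "AEC")) {
    b <- stain_basis(bname)
    set.seed(7)
    ch <- matrix(runif(400, 0, 1.5), 20, 20)
    he <- matrix(runif(400, 0, 1.5), 20, 20)
    sep <- separate_stains(synthesize_od(ch, he, b), b)
    expect_lt(max(abs(sep$chromogen_od - ch)), 1e-6)
    expect_lt(max(abs(sep$hematoxylin_od - he)), 1e-6)
    expect_false(anyNA(sep$chromogen_od))
    expect_true(all(sep$chromogen_od >= 0 & sep$chromogen_od <= 3))
  }
})

test_that("a near-collinear stain basis is rejected", {
  v <- c(0.65, 0.70, 0.29)
  expect_error(stain_basis(v, v * c(1.02, 1, 0.98)), "collinear")
})

test_that("similarity transforms compose and invert correctly", {
  tf <- round_transform(7.5, -3.25, 2.4)
  inv <- invert_transform(tf)
  p <- apply_transform(tf, c(10, 200, 66.5), c(30, 101, 250.2),
                       c(256, 256))
  q <- apply_transform(inv, p$x, p$y, c(256, 256))
  expect_equal(q$x, c(10, 200, 66.5), tolerance = 1e-10)
  expect_equal(q$y, c(30, 101, 250.2), tolerance = 1e-10)
  expect_error(round_transform(scale = 1.2), "implausible scale")
})

test_that("warping round-trips smooth images and masks behave", {
  set.seed(3)
  img <- as.matrix(EBImage::gblur(EBImage::Image(
    matrix(runif(256 * 256), 256, 256)), sigma = 4))
  tf <- round_transform(6.3, -4.7, 1.5)
  w <- warp_image(img, tf)
  back <- warp_image(w, invert_transform(tf))
  interior <- 40:216
  expect_lt(max(abs(back[interior, interior] - img[interior, interior])),
            0.02)
  # nearest-neighbour keeps masks binary
  mask <- img > 0.5
  wm <- warp_image(mask * 1, tf, filter = "nearest")
  expect_true(all(wm %in% c(0, 1)))
  # footprint shrinks with translation
  expect_lt(sum(warp_footprint(img, tf)), length(img))
})

test_that("the virtual image stacks unmixed rounds on one grid", {
  slide <- cached_small_slide()
  idn <- lapply(slide$rounds, function(r) round_transform())
  names(idn) <- names(slide$rounds)
  vdi <- build_vdi(slide$rounds, idn)
  expect_setequal(names(vdi$markers), marker_panel())
  # identity transforms: per-marker map equals the round's unmixed map
  b <- stain_basis()
  ck <- separate_stains(rgb_to_od(slide$rounds$CK$rgb_pixels), b)
  expect_equal(vdi$markers$CK, ck$chromogen_od)
  expect_true(all(vdi$valid_mask))
  # real transforms: valid mask is the intersection of footprints
  vdi2 <- build_vdi(slide$rounds, slide$ground_truth$transforms)
  fps <- vapply(names(slide$rounds), function(m)
    sum(warp_footprint(vdi2$markers[[m]],
                       slide$ground_truth$transforms[[m]])),
    numeric(1))
  expect_lte(sum(vdi2$valid_mask), min(fps))
  expect_false(anyNA(vdi2$markers$CD3))
})

test_that("a virtual image survives the float-TIFF round trip", {
  slide <- cached_small_slide()
  vdi <- build_vdi(slide$rounds, slide$ground_truth$transforms)
  path <- file.path(tempdir(), "vdi.tiff")
  save_vdi(vdi, path)
  back <- load_vdi(path)
  expect_equal(names(back$markers), names(vdi$markers))
  expect_equal(back$markers$CD8, vdi$markers$CD8, tolerance = 1e-6)
  expect_equal(back$valid_mask, vdi$valid_mask)
  expect_equal(back$transforms$CD4$dx_px, vdi$transforms$CD4$dx_px)
  unlink(c(path, paste0(path, ".json")))
})
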