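test_that("a blank counterstain yields no detections", {
  det <- detect_nuclei(matrix(0, 128, 128), pixel_size_um = 0.5)
  expect_equal(nrow(det$cells), 0)
})

test_that("rendered nuclei are detected at their true positions", {
  # 40 well-separated nuclei on a clean counterstain
  set.seed(21)
  px <- 0.5
  hema <- matrix(0, 512, 512)
  xs <- ys <- numeric(0)
  while (length(xs) < 40) {
    x <- runif(1, 15, 241); y <- runif(1, 15, 241)
    if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= 12^2) {
      xs <- c(xs, x); ys <- c(ys, y)
      hema <- ngiplex:::draw_annulus(hema, x, y, 0, 3.5, 0.5, px)
    }
  }
  det <- detect_nuclei(hema, px)
  expect_equal(nrow(det$cells), 40)
  for (i in seq_len(40)) {
    d <- sqrt(min((det$cells$centroid_x_um - xs[i])^2 +
                  (det$cells$centroid_y_um - ys[i])^2))
    expect_lt(d, 2)
  }
  expect_true(all(det$cells$equivalent_diameter_um > 4 &
                  det$cells$equivalent_diameter_um < 14))
})

test_that("undersized objects are rejected by the size filter", {
  px <- 0.5
  hema <- ngiplex:::draw_annulus(matrix(0, 128, 128), 20, 20, 0, 1, 0.5,
                                 px)  # diameter 2 um, below min 4
  det <- detect_nuclei(hema, px, min_diameter_um = 4)
  expect_equal(nrow(det$cells), 0)
})

test_that("marker positivity uses the closed threshold boundary", {
  px <- 0.5
  cells <- data.frame(cell_id = 1L, centroid_x_um = 20,
                      centroid_y_um = 20, equivalent_diameter_um = 7)
  zero_map <- matrix(0, 80, 80)
  call <- call_marker_positivity(cells, zero_map, "CD8", 0.15, px)
  expect_false(call$positive)
  # uniform map exactly at the threshold: positive (>= rule)
  call2 <- call_marker_positivity(cells, matrix(0.15, 80, 80), "CD8",
                                  0.15, px)
  expect_true(call2$positive)
  expect_equal(call2$mean_od, 0.15)
  # rendered membrane ring recovered within 15% of its amplitude
  ring <- ngiplex:::draw_annulus(zero_map, 20, 20, 3.5, 5, 0.6, px)
  call3 <- call_marker_positivity(cells, ring, "CD8", 0.15, px)
  expect_true(call3$positive)
  expect_lt(abs(call3$mean_od - 0.6) / 0.6, 0.15)
  # compartment fully outside the valid mask: indeterminate
  vm <- matrix(FALSE, 80, 80)
  call4 <- call_marker_positivity(cells, ring, "CD8", 0.15, px,
                                  valid_mask = vm)
  expect_true(is.na(call4$positive))
})

test_that("phenotype assignment is exclusive, exhaustive and follows the gate", {
  f <- function(cd3, cd4, cd8, foxp3, ck, cd4_od = 0, cd8_od = 0)
    as.character(assign_phenotype(cd3, cd4, cd8, foxp3, ck,
                                  cd4_od, cd8_od)$phenotype)
  expect_equal(f(TRUE, TRUE, FALSE, TRUE, FALSE), "Treg")
  expect_equal(f(TRUE, TRUE, FALSE, FALSE, FALSE), "CD4_T")
  expect_equal(f(TRUE, FALSE, TRUE, FALSE, FALSE), "CD8_T")
  expect_equal(f(TRUE, FALSE, FALSE, FALSE, FALSE), "CD3_only")
  expect_equal(f(TRUE, FALSE, FALSE, TRUE, FALSE), "CD3_only")
  expect_equal(f(FALSE, FALSE, FALSE, FALSE, TRUE), "tumour")
  expect_equal(f(FALSE, FALSE, FALSE, FALSE, FALSE), "other")
  # CD4+CD8+ conflicts resolve by mean OD, ties to CD8, and are counted
  expect_equal(f(TRUE, TRUE, TRUE, FALSE, FALSE, cd4_od = 0.9,
                 cd8_od = 0.3), "CD4_T")
  expect_equal(f(TRUE, TRUE, TRUE, FALSE, FALSE, cd4_od = 0.3,
                 cd8_od = 0.9), "CD8_T")
  expect_equal(f(TRUE, TRUE, TRUE, FALSE, FALSE, cd4_od = 0.5,
                 cd8_od = 0.5), "CD8_T")
  res <- assign_phenotype(TRUE, TRUE, TRUE, FALSE, FALSE, 0.9, 0.3)
  expect_true(res$conflict)
  # exhaustive over all 32 flag patterns, always exactly one category
  grid <- expand.grid(cd3 = c(TRUE, FALSE), cd4 = c(TRUE, FALSE),
                      cd8 = c(TRUE, FALSE), foxp3 = c(TRUE, FALSE),
                      ck = c(TRUE, FALSE))
  out <- assign_phenotype(grid$cd3, grid$cd4, grid$cd8, grid$foxp3,
                          grid$ck)
  expect_false(anyNA(out$phenotype))
  expect_true(all(out$phenotype %in%
    c("CD8_T", "CD4_T", "Treg", "CD3_only", "tumour", "other")))
})

test_that("raising a threshold never increases the positive count", {
  analysis <- cached_small_analysis()
  vdi <- analysis$vdi
  det <- analysis$detections
  counts <- vapply(c(0.1, 0.15, 0.25, 0.4), function(th) {
    call <- call_marker_positivity(det, vdi$markers$CD3, "CD3", th,
                                   vdi$pixel_size_um,
                                   valid_mask = vdi$valid_mask)
    sum(call$positive, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("marker-level counts dominate exclusive subset counts", {
  cells <- cached_small_analysis()$cells
  n_cd8 <- sum(cells$CD8_pos, na.rm = TRUE)
  n_cd4 <- sum(cells$CD4_pos, na.rm = TRUE)
  expect_gte(n_cd8, sum(cells$phenotype == "CD8_T"))
  expect_gte(n_cd4, sum(cells$phenotype %in% c("CD4_T", "Treg")))
})

test_that("otsu thresholds respect their floor", {
  vdi <- cached_small_analysis()$vdi
  th <- otsu_thresholds(vdi, floor = 0.1)
  expect_named(th, names(vdi$markers))
  expect_true(all(th >= 0.1))
})
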