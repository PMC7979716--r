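mk_areas <- function(a, b, c_) {
  structure(list(area_um2 = c(A = a, B = b, C = c_),
                 roi_area_um2 = a + b + c_),
            class = "zone_areas")
}

mk_cells <- function(n, zone = "B", phenotype = "CD8_T", cd3 = TRUE,
                     cd4 = FALSE, cd8 = TRUE, foxp3 = FALSE, ki67 = FALSE,
                     ck = FALSE) {
  if (n == 0)
    return(data.frame(zone = character(), phenotype = character(),
                      CD3_pos = logical(), CD4_pos = logical(),
                      CD8_pos = logical(), Foxp3_pos = logical(),
                      Ki67_pos = logical(), CK_pos = logical(),
                      indeterminate = logical(), conflict = logical()))
  data.frame(zone = rep(zone, n), phenotype = phenotype, CD3_pos = cd3,
             CD4_pos = cd4, CD8_pos = cd8, Foxp3_pos = foxp3,
             Ki67_pos = ki67, CK_pos = ck, indeterminate = FALSE,
             conflict = FALSE)
}

test_that("an empty cell table gives zero densities and missing fractions", {
  m <- compute_sample_metrics(mk_cells(0), mk_areas(1e5, 1e5, 1e5))
  expect_true(all(m$density == 0))
  expect_true(all(is.na(m$pct_ki67)))
  expect_true(all(is.na(m$subset_proportions)))
  expect_true(is.na(m$ratio_prolif_foxp3_cd8))
  expect_error(compute_sample_metrics(mk_cells(0), mk_areas(0, 0, 0)),
               "zero ROI")
})

test_that("densities are plain counts over areas", {
  # 5 CD8 T cells in zone B of 0.005 mm^2 -> 1000 cells/mm^2
  m <- compute_sample_metrics(mk_cells(5), mk_areas(2e3, 5e3, 3e3))
  expect_equal(m$density["CD8", "B"], 1000)
  expect_equal(m$density["CD8", "total"], 5 / 0.01)
  expect_equal(m$density["Foxp3", "B"], 0)
})

test_that("subset proportions are normalised and ratios computed", {
  cells <- rbind(
    mk_cells(6),                                                  # CD8_T
    mk_cells(3, phenotype = "CD4_T", cd4 = TRUE, cd8 = FALSE),
    mk_cells(2, phenotype = "Treg", cd4 = TRUE, cd8 = FALSE,
             foxp3 = TRUE, ki67 = TRUE),
    mk_cells(1, phenotype = "CD3_only", cd8 = FALSE),
    mk_cells(4, zone = "A", phenotype = "tumour", cd3 = FALSE,
             cd8 = FALSE, ck = TRUE, ki67 = TRUE),
    mk_cells(2, phenotype = "CD8_T", ki67 = TRUE))
  m <- compute_sample_metrics(cells, mk_areas(1e5, 1e5, 1e5))
  expect_equal(sum(m$subset_proportions), 1, tolerance = 1e-12)
  expect_equal(unname(m$subset_proportions["CD8_T"]), 8 / 14)
  # proliferating Foxp3 / proliferating CD8 = 2 / 2
  expect_equal(m$ratio_prolif_foxp3_cd8, 1)
  # Ki67+ immune / (Ki67+ immune + Ki67+ tumour) = 4 / 8
  expect_equal(m$prolif_immune_fraction, 0.5)
  expect_equal(m$pct_ki67["CD8", "total"], 100 * 2 / 8)
})

test_that("zone counts conserve totals for every marker", {
  cells <- rbind(mk_cells(4, zone = "A"), mk_cells(7, zone = "B"),
                 mk_cells(9, zone = "C"),
                 mk_cells(5, zone = "B", phenotype = "Treg", cd4 = TRUE,
                          cd8 = FALSE, foxp3 = TRUE))
  m <- compute_sample_metrics(cells, mk_areas(1e5, 1e5, 1e5))
  for (mk in rownames(m$density)) {
    tot <- m$density[mk, "total"] * m$roi_area_um2 / 1e6
    per_zone <- sum(m$density[mk, c("A", "B", "C")] *
                    c(1e5, 1e5, 1e5) / 1e6)
    expect_equal(tot, per_zone)
  }
})

test_that("indeterminate and out-of-ROI cells are excluded and counted", {
  cells <- rbind(mk_cells(5), mk_cells(2, zone = "none"))
  cells$indeterminate[1] <- TRUE
  m <- compute_sample_metrics(cells, mk_areas(1e5, 1e5, 1e5))
  expect_equal(m$density["CD8", "B"] * 0.1, 4)  # 5 - 1 indeterminate
  expect_equal(m$zone_none_count, 2)
  expect_equal(m$indeterminate_count, 1)
})

test_that("the ROI-area QC boundary is closed at the minimum", {
  expect_false(qc_filter(99999))
  expect_true(qc_filter(100000))
  expect_false(qc_filter(0))
  m <- compute_sample_metrics(mk_cells(1), mk_areas(4e4, 4e4, 4e4))
  expect_true(qc_filter(m))            # 120,000 um^2
  expect_false(qc_filter(m, 2e5))
})

test_that("TIL dynamics classify with no tolerance band", {
  expect_equal(as.character(classify_til_dynamics(10, 10)), "stable")
  expect_equal(as.character(classify_til_dynamics(5, 20)), "increase")
  expect_equal(as.character(classify_til_dynamics(20, 5)), "decrease")
  expect_true(is.na(classify_til_dynamics(NA, 10)))
  expect_equal(as.character(classify_til_dynamics(c(10, 5, 20),
                                                  c(10, 20, 5))),
               c("stable", "increase", "decrease"))
  expect_error(classify_til_dynamics(150, 10), "0, 100")
})

test_that("metrics flatten to a schema-stable row", {
  m <- compute_sample_metrics(mk_cells(5), mk_areas(1e5, 1e5, 1e5))
  row <- metrics_as_row(m, "s1")
  expect_equal(nrow(row), 1)
  expect_equal(row$density_CD8_B, 50)
  expect_true(row$qc_pass)
  expect_true(all(c("prop_CD8_T", "ratio_prolif_foxp3_cd8",
                    "roi_area_um2", "conflict_count") %in% names(row)))
})
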