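test_that("an axis-aligned square polygon rasterizes to the exact voxel count", {
  g <- acq_geometry()
  vox <- voxel_size_mm(g)           # 2.65625 mm
  sq <- rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20)) * vox
  roi <- roi_polygon(setNames(list(sq), 1)[1], label = "square")
  m <- rasterize_roi(roi, g)
  expect_equal(sum(m), 100)         # 10 x 10 voxel centres inside
  expect_true(all(which(m, arr.ind = TRUE)[, 1] == 1))
})

test_that("cylinder masks match the brute-force centre-distance oracle", {
  g <- acq_geometry()
  vox <- voxel_size_mm(g)
  ## centre on the voxel-centre of (row 64, col 64) (1-based)
  ctr <- c((64 - 0.5) * vox, (64 - 0.5) * vox, 0)
  roi <- roi_cylinder(ctr, diameter = 30, height = 30)
  m <- rasterize_roi(roi, g)
  ## oracle: exhaustive centre-distance check on slice 1
  cx <- (seq_len(g$recon_matrix) - 0.5) * vox
  d2 <- outer((cx - ctr[2])^2, (cx - ctr[1])^2, `+`)
  expect_equal(sum(m[1, , ]), sum(d2 <= 15^2))
  expect_gt(sum(m[1, , ]), 80)     # ~ pi * (15/2.656)^2 = 100 voxels
  ## 35 mm slice pitch exceeds the 15 mm half-height: single slice included
  expect_equal(sum(apply(m, 1, any)), 1)
})

test_that("rasterization is consistent under translation by one voxel pitch", {
  g <- acq_geometry(recon_matrix = 64L, acq_matrix = 64L, n_slices = 1L)
  vox <- voxel_size_mm(g)
  tri <- rbind(c(30, 30), c(70, 35), c(45, 72))
  m1 <- rasterize_roi(roi_polygon(list(tri)), g)
  m2 <- rasterize_roi(roi_polygon(list(tri + vox)), g)   # shift by one pitch
  expect_equal(m2[1, 2:64, 2:64], m1[1, 1:63, 1:63])
})

test_that("cylinder voxel count is invariant under quarter rotations", {
  g <- acq_geometry(recon_matrix = 63L, acq_matrix = 63L, n_slices = 1L)
  vox <- voxel_size_mm(g)
  ctr <- c((32 - 0.5) * vox, (32 - 0.5) * vox, 0)       # exact grid centre
  m <- rasterize_roi(roi_cylinder(ctr, 40, 30), g)[1, , ]
  expect_equal(m, t(m)[, ncol(m):1])                    # 90-degree rotation
  expect_equal(sum(m), sum(t(m)))
})

test_that("invalid ROIs are rejected and empty rasterizations warned", {
  g <- acq_geometry()
  expect_error(roi_polygon(list(rbind(c(0, 0), c(1, 1)))), ">= 3")
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))  # self-intersecting
  expect_error(roi_polygon(list(bow)), "self-intersecting")
  expect_error(rasterize_roi(roi_cylinder(c(5, 5, 0), 30, 30), g),
               "outside the field of view")
  tiny <- rbind(c(50, 50), c(50.1, 50), c(50, 50.1)) - 49.9
  expect_warning(rasterize_roi(roi_polygon(list(tiny)), g), "empty")
})

test_that("ROI summaries reduce to direct recomputation", {
  g <- small_geometry(n_coils = 1L, recon = 8L)
  dm <- c(1, 8, 8)
  mk_kmap <- function(vals) structure(
    list(k_pl = array(vals, dm), residual_norm = array(0, dm),
         inv_t1_eff = 1 / 30, mask = array(TRUE, dm), n_failed = 0L),
    class = "kpl_map")
  maps <- structure(list(pyruvate = array(runif(64, 1, 2), dm),
                         lactate = array(runif(64, 0, 1), dm),
                         total_carbon = array(0, dm), provenance = "t"),
                    class = "metabolite_maps")
  maps$total_carbon <- maps$pyruvate + maps$lactate
  ne <- noise_estimate(0.1, 0.05)
  mask <- array(FALSE, dm); mask[1, 2, 2:6] <- TRUE
  s <- summarize_roi(mask, mk_kmap(seq_len(64) / 64), maps, ne, label = "x")
  vals <- (seq_len(64) / 64)[mask]
  expect_equal(s$kpl_median, median(vals))
  expect_equal(c(s$kpl_min, s$kpl_max), range(vals))
  expect_equal(s$lac_pyr, sum(maps$lactate[mask]) / sum(maps$pyruvate[mask]))
  expect_equal(s$snr_pyruvate, compute_snr(maps$pyruvate[mask], ne))
  ## constant map: median = value, degenerate range
  s2 <- summarize_roi(mask, mk_kmap(0.007), maps, ne)
  expect_equal(c(s2$kpl_median, s2$kpl_min, s2$kpl_max), rep(0.007, 3))
})

test_that("the viable-fraction rule excludes strictly below 0.75", {
  bt <- data.frame(patient_id = "P1",
                   viable_fraction = c(0.74, 0.75, 0.80),
                   kpl = c(1, 2, 3))
  pt <- patient_level_table(bt)
  expect_equal(pt$n_excluded, 1)
  expect_equal(pt$n_included, 2)
  expect_equal(pt$kpl_median, 2.5)
})

test_that("patient medians match brute-force recomputation and ignore order", {
  set.seed(3)
  bt <- data.frame(patient_id = rep(sprintf("P%d", 1:4), each = 5),
                   viable_fraction = runif(20, 0.5, 1),
                   kpl = rnorm(20, 0.008, 0.002),
                   mct1_pct = runif(20, 0, 10))
  pt <- patient_level_table(bt)
  for (p in unique(bt$patient_id)) {
    sel <- bt$patient_id == p & bt$viable_fraction >= 0.75
    expect_equal(pt$kpl_median[pt$patient_id == p],
                 if (any(sel)) median(bt$kpl[sel]) else NA_real_)
    expect_equal(pt$mct1_pct_median[pt$patient_id == p],
                 if (any(sel)) median(bt$mct1_pct[sel]) else NA_real_)
  }
  perm <- sample(nrow(bt))
  pt2 <- patient_level_table(bt[perm, ])
  m <- match(pt$patient_id, pt2$patient_id)
  expect_equal(pt$kpl_median, pt2$kpl_median[m])
  ## single biopsy reduces to that biopsy
  one <- data.frame(patient_id = "Q", viable_fraction = 0.9, kpl = 0.004)
  expect_equal(patient_level_table(one)$kpl_median, 0.004)
})
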