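test_that("optical densities follow Beer-Lambert with clamping", {
  img <- array(255, c(2, 2, 3))
  expect_equal(rgb_to_od(img), array(0, c(2, 2, 3)), ignore_attr = TRUE)
  img[1, 1, ] <- 25.5
  od <- rgb_to_od(img)
  expect_equal(od[1, 1, ], rep(1, 3), tolerance = 1e-12)
  img[2, 2, ] <- 0
  od <- rgb_to_od(img)
  expect_equal(od[2, 2, ], rep(3, 3))        # cap
  expect_equal(attr(od, "n_clamped"), 3)
  ## random image matches direct recomputation
  set.seed(8)
  ri <- array(runif(48, 1, 255), c(4, 4, 3))
  expect_equal(as.vector(rgb_to_od(ri)), as.vector(-log10(ri / 255)),
               tolerance = 1e-12)
})

test_that("stain deconvolution inverts Beer-Lambert mixing exactly", {
  cl <- stain_classifier()
  V <- cl$stain_vectors
  mk <- function(h, d) {
    od <- outer(rep(1, 4), rep(1, 4)) |> array(c(4, 4))
    flat <- cbind(as.vector(h * od), as.vector(d * od)) %*% t(V)
    array(255 * 10^(-flat), c(4, 4, 3))
  }
  pure_dab <- quantify_ihc(mk(0, 0.42), cl)
  dec <- deconvolve_stains(rgb_to_od(mk(0, 0.42)), cl)
  expect_equal(dec$dab, matrix(0.42, 4, 4), tolerance = 1e-6)
  expect_equal(dec$hematoxylin, matrix(0, 4, 4), tolerance = 1e-6)
  dec2 <- deconvolve_stains(rgb_to_od(mk(0.3, 0)), cl)
  expect_equal(dec2$dab, matrix(0, 4, 4), tolerance = 1e-6)
  ## mixed image: closure within 1e-6 on unquantized intensities
  dec3 <- deconvolve_stains(rgb_to_od(mk(0.25, 0.55)), cl)
  expect_equal(dec3$hematoxylin, matrix(0.25, 4, 4), tolerance = 1e-6)
  expect_equal(dec3$dab, matrix(0.55, 4, 4), tolerance = 1e-6)
  expect_error(stain_classifier(stain_vectors = cbind(c(1, 1, 1), c(1, 1, 1.001))),
               "collinear")
})

test_that("class boundaries are inclusive at the printed thresholds", {
  cl <- stain_classifier()
  od <- matrix(c(0, 0.2163, 0.2164, 0.3273, 0.3274, 0.4937, 0.4938, 0.60),
               nrow = 1)
  cls <- classify_pixels(od, cl)
  expect_equal(as.vector(cls), c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("percent positive partitions tissue area exactly", {
  cls <- matrix(NA_integer_, 10, 10)
  cls[1:8, ] <- 0L
  cls[1:2, ] <- 1L
  cls[3, ] <- 3L
  res <- percent_positive(cls)
  expect_equal(res$tissue_area, 80)
  expect_equal(sum(res$area_fractions), 1, tolerance = 1e-9)
  expect_equal(res$percent_positive, 100 * 30 / 80)
  all_strong <- matrix(3L, 4, 4)
  expect_equal(percent_positive(all_strong)$percent_positive, 100)
  none <- matrix(0L, 4, 4)
  expect_equal(percent_positive(none)$percent_positive, 0)
  expect_error(percent_positive(matrix(NA_integer_, 2, 2)), "empty")
})

test_that("percent positive is monotone in any pixel's DAB OD", {
  cl <- stain_classifier()
  set.seed(2)
  od <- matrix(runif(100, 0, 0.6), 10, 10)
  base <- percent_positive(classify_pixels(od, cl))$percent_positive
  od2 <- od
  od2[4, 7] <- od2[4, 7] + 0.3
  up <- percent_positive(classify_pixels(od2, cl))$percent_positive
  expect_gte(up, base)
})

test_that("connected-component counting is 8-connective with an area floor", {
  m <- matrix(0, 10, 10)
  expect_equal(count_cells(m, min_od = 0.3, min_area = 1), 0L)
  m[2:4, 2:4] <- 0.8                       # one 9-px blob
  expect_equal(count_cells(m, 0.3, 5), 1L)
  m[5, 5] <- 0.8                           # diagonal touch joins the blob
  expect_equal(count_cells(m, 0.3, 5), 1L)
  m[8, 8] <- 0.8                           # isolated pixel below min_area
  expect_equal(count_cells(m, 0.3, 5), 1L)
  expect_equal(count_cells(m, 0.3, 1), 2L)
})

test_that("generator ground truth is recovered by the quantifier", {
  ih <- generate_ihc_image(c(weak = 0.30, moderate = 0.10, strong = 0),
                           tissue_fraction = 0.9, nuclei_count = 50,
                           size = 160, seed = 21)
  q <- quantify_ihc(round(ih$image))       # through 8-bit quantization
  expect_equal(q$percent_positive, 100 * sum(ih$realized_fractions),
               tolerance = 1)
  expect_identical(q$cell_count, ih$nucleus_count)
  ## zero target fractions give zero percent positive
  ih0 <- generate_ihc_image(c(weak = 0, moderate = 0, strong = 0), seed = 3)
  q0 <- quantify_ihc(round(ih0$image))
  expect_equal(q0$percent_positive, 0)
  ## the painted ODs land strictly inside their class intervals
  dec <- deconvolve_stains(rgb_to_od(round(ih$image)), stain_classifier())
  truth <- ih$class_map
  expect_true(all(dec$dab[!is.na(truth) & truth == 1L] >= 0.2164))
  expect_true(all(dec$dab[!is.na(truth) & truth == 1L] < 0.3274))
})

test_that("the generator is seeded and validates fractions", {
  a <- generate_ihc_image(seed = 5)
  b <- generate_ihc_image(seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$nucleus_count, b$nucleus_count)
  expect_error(generate_ihc_image(c(weak = 0.6, moderate = 0.3, strong = 0.2)),
               "sum to at most 1")
})
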