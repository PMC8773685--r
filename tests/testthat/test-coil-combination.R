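# Rank-one multi-coil data built from known sensitivities: the SVD weights
# must recover the sensitivities and capture the full array energy.
make_rank1_image <- function(geometry, sens_vec, seed = 1) {
  nf <- geometry$n_frames
  n <- geometry$recon_matrix
  ns <- geometry$n_slices
  nc <- geometry$n_coils
  set.seed(seed)
  rho <- matrix(complex(real = rnorm(2 * nf), imaginary = rnorm(2 * nf)),
                nrow = 2)                   # metabolite x frame signal
  data <- array(0 + 0i, dim = c(2, nc, nf, ns, n, n))
  for (coil in seq_len(nc)) data[, coil, , , , ] <- sens_vec[coil] *
    array(rho, dim = c(2, nf, ns, n, n))
  dynamic_metabolic_image(data, geometry)
}

test_that("a single coil passes through unchanged with unit weights", {
  g <- small_geometry(n_coils = 1L, recon = 8L)
  img <- make_rank1_image(g, 1 + 0i)
  w <- compute_coil_weights(img)
  expect_true(all(w$weights == 1 + 0i))
  cb <- apply_coil_weights(img, w)
  expect_equal(cb$data, array(img$data[, 1, , , , ], dim = dim(img$data)[-2]),
               tolerance = 1e-12)
})

test_that("SVD weights recover unit-norm sensitivities on rank-one data", {
  g <- small_geometry(n_coils = 4L, recon = 8L)
  s <- complex(real = c(0.5, -0.3, 0.2, 0.4), imaginary = c(0.1, 0.4, -0.5, 0.2))
  s <- s / sqrt(sum(Mod(s)^2))
  img <- make_rank1_image(g, s)
  w <- compute_coil_weights(img)
  ## phase convention: compare after aligning to the reference coil
  s_conv <- s * Conj(s[1]) / Mod(s[1])
  for (v in seq_len(8)) {
    expect_lt(max(Mod(w$weights[, 1, v, v] - s_conv)), 1e-8)
  }
})

test_that("combination captures the full array energy of rank-one data", {
  g <- small_geometry(n_coils = 4L, recon = 8L)
  s <- complex(real = c(1, 2, -1, 0.5), imaginary = c(0, 1, 0.5, -2))
  img <- make_rank1_image(g, s)
  cb <- apply_coil_weights(img, compute_coil_weights(img))
  ## |combined|^2 summed over frames equals the coil-summed energy
  e_multi <- apply(Mod(img$data)^2, c(4, 5, 6), sum)
  e_comb <- apply(Mod(cb$data)^2, c(3, 4, 5), sum)
  expect_equal(e_comb, e_multi, tolerance = 1e-6)
})

test_that("two equal real sensitivities give equal weights 1/sqrt(2)", {
  g <- small_geometry(n_coils = 2L, recon = 8L)
  img <- make_rank1_image(g, c(1 + 0i, 1 + 0i))
  w <- compute_coil_weights(img)
  expect_equal(as.vector(w$weights[, 1, 3, 5]),
               rep(1 / sqrt(2) + 0i, 2), tolerance = 1e-10)
})

test_that("weights ignore global scaling and phase; magnitudes are invariant", {
  g <- small_geometry(n_coils = 3L, recon = 8L)
  s <- complex(real = c(0.8, 0.1, -0.4), imaginary = c(0.2, -0.6, 0.3))
  img1 <- make_rank1_image(g, s)
  img2 <- img1
  img2$data <- img2$data * 3.7                  # positive scalar
  w1 <- compute_coil_weights(img1)
  w2 <- compute_coil_weights(img2)
  expect_equal(w1$weights, w2$weights, tolerance = 1e-10)
  img3 <- img1
  img3$data <- img3$data * exp(1i * 1.1)        # global phase rotation
  cb1 <- apply_coil_weights(img1, w1)
  cb3 <- apply_coil_weights(img3, compute_coil_weights(img3))
  expect_equal(Mod(cb1$data), Mod(cb3$data), tolerance = 1e-9)
})

test_that("all-zero voxels fall back to a unit weight on the reference coil", {
  g <- small_geometry(n_coils = 3L, recon = 8L)
  data <- array(0 + 0i, dim = c(2, 3, g$n_frames, 1, 8, 8))
  img <- dynamic_metabolic_image(data, g)
  w <- compute_coil_weights(img)
  expect_true(all(w$weights[1, , , ] == 1 + 0i))
  expect_true(all(w$weights[2:3, , , ] == 0 + 0i))
})

test_that("time-summed maps match a brute-force per-voxel summation", {
  g <- small_geometry(n_coils = 2L, recon = 8L)
  set.seed(42)
  data <- array(complex(real = rnorm(2 * 2 * g$n_frames * 64),
                        imaginary = rnorm(2 * 2 * g$n_frames * 64)),
                dim = c(2, 2, g$n_frames, 1, 8, 8))
  img <- dynamic_metabolic_image(data, g)
  cb <- apply_coil_weights(img, compute_coil_weights(img))
  mp <- sum_time_maps(cb)
  for (v in list(c(1, 1), c(3, 7), c(8, 8))) {
    expect_equal(mp$pyruvate[1, v[1], v[2]],
                 Mod(sum(cb$data[1, , 1, v[1], v[2]])), tolerance = 1e-12)
    expect_equal(mp$lactate[1, v[1], v[2]],
                 Mod(sum(cb$data[2, , 1, v[1], v[2]])), tolerance = 1e-12)
  }
  expect_equal(mp$total_carbon, mp$pyruvate + mp$lactate)
  expect_true(all(mp$pyruvate >= 0))
})

test_that("constant real signal sums linearly over frames and zero maps to zero", {
  g <- small_geometry(n_coils = 1L, recon = 8L)
  data <- array(0.7 + 0i, dim = c(2, 1, g$n_frames, 1, 8, 8))
  img <- dynamic_metabolic_image(data, g)
  cb <- apply_coil_weights(img, compute_coil_weights(img))
  mp <- sum_time_maps(cb)
  expect_equal(mp$pyruvate[1, 4, 4], g$n_frames * 0.7, tolerance = 1e-9)
  zero <- dynamic_metabolic_image(array(0 + 0i, dim = dim(data)), g)
  mz <- sum_time_maps(apply_coil_weights(zero, compute_coil_weights(zero)))
  expect_true(all(mz$total_carbon == 0))
})
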