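test_that("zero lactate yields a zero exchange rate from both estimators", {
  s <- noiseless_courses(0)
  f1 <- fit_kpl_frequency_domain(s$pyruvate, s$lactate, 4)
  f2 <- fit_kpl_time_domain_oracle(s$pyruvate, s$lactate, 4)
  expect_lt(abs(f1$k_pl_hat), 1e-9)
  expect_lt(abs(f2$k_pl_hat), 1e-9)
})

test_that("degenerate inputs are rejected", {
  s <- noiseless_courses(0.0065)
  expect_error(fit_kpl_frequency_domain(rep(0, 20), s$lactate, 4),
               "unidentifiable")
  expect_error(fit_kpl_time_domain_oracle(rep(0, 20), s$lactate, 4),
               "unidentifiable")
  expect_error(fit_kpl_frequency_domain(s$pyruvate, s$lactate[-1], 4),
               "same length")
  expect_error(fit_kpl_frequency_domain(s$pyruvate[1:3], s$lactate[1:3], 4),
               "at least 4")
})

test_that("noiseless recovery is within 2 percent at clinical parameter levels", {
  for (kpl in c(0.0065, 0.0152)) {
    s <- noiseless_courses(kpl, 30)
    f1 <- fit_kpl_frequency_domain(s$pyruvate, s$lactate, 4)
    f2 <- fit_kpl_time_domain_oracle(s$pyruvate, s$lactate, 4)
    expect_lt(abs(f1$k_pl_hat / kpl - 1), 0.02)
    expect_lt(abs(f2$k_pl_hat / kpl - 1), 0.02)
    expect_equal(f1$inv_t1_eff_hat, 1 / 30, tolerance = 0.05)
  }
})

test_that("both estimators are invariant to a common positive rescaling", {
  s <- noiseless_courses(0.009, 24)
  for (c0 in c(0.001, 7, 1e4)) {
    f0 <- fit_kpl_frequency_domain(s$pyruvate, s$lactate, 4)
    fc <- fit_kpl_frequency_domain(c0 * s$pyruvate, c0 * s$lactate, 4)
    expect_equal(fc$k_pl_hat, f0$k_pl_hat, tolerance = 1e-10)
    expect_equal(fc$inv_t1_eff_hat, f0$inv_t1_eff_hat, tolerance = 1e-10)
    t0 <- fit_kpl_time_domain_oracle(s$pyruvate, s$lactate, 4)
    tc <- fit_kpl_time_domain_oracle(c0 * s$pyruvate, c0 * s$lactate, 4)
    expect_equal(tc$k_pl_hat, t0$k_pl_hat, tolerance = 1e-8)
  }
})

test_that("fixed-decay fitting recovers kPL on RF-depleted complex courses", {
  g <- acq_geometry()
  for (kpl in c(0.0043, 0.013)) {
    s <- noiseless_courses(kpl, 30, rf_depletion = TRUE)
    r <- effective_decay_rate(30, g)
    f <- fit_kpl_frequency_domain(as.complex(s$pyruvate),
                                  as.complex(s$lactate), 4, t1_eff = 1 / r)
    expect_lt(abs(f$k_pl_hat / kpl - 1), 0.02)
    expect_true("fixed_t1_eff" %in% f$flags)
  }
})

test_that("joint and fixed fits tolerate a shared complex phase", {
  s <- noiseless_courses(0.008, 30, rf_depletion = TRUE)
  ph <- exp(1i * 0.8)
  r <- effective_decay_rate(30, acq_geometry())
  f0 <- fit_kpl_frequency_domain(as.complex(s$pyruvate), as.complex(s$lactate),
                                 4, t1_eff = 1 / r)
  f1 <- fit_kpl_frequency_domain(ph * s$pyruvate, ph * s$lactate,
                                 4, t1_eff = 1 / r)
  expect_equal(f1$k_pl_hat, f0$k_pl_hat, tolerance = 1e-9)
})

test_that("median kPL bias stays under 10 percent at the study's SNR level", {
  ## complex-course Monte Carlo at summed-map pyruvate SNR ~ 27
  g <- acq_geometry()
  s <- noiseless_courses(0.0065, 30, rf_depletion = TRUE)
  S <- sum(s$pyruvate)
  sigma <- S / (27 * sqrt(2 * 20 * (2 - pi / 2)) + sqrt(20 * pi / 2))
  r <- effective_decay_rate(30, g)
  set.seed(2024)
  est <- replicate(200, {
    pn <- s$pyruvate + complex(real = rnorm(20, 0, sigma),
                               imaginary = rnorm(20, 0, sigma))
    ln <- s$lactate + complex(real = rnorm(20, 0, sigma),
                              imaginary = rnorm(20, 0, sigma))
    fit_kpl_frequency_domain(pn, ln, 4, t1_eff = 1 / r)$k_pl_hat
  })
  expect_lt(abs(median(est) / 0.0065 - 1), 0.10)
})

test_that("negative estimates are flagged rather than clipped", {
  ## lactate anti-correlated with the convolution basis forces kPL < 0
  s <- noiseless_courses(0.0065, 30)
  f <- fit_kpl_frequency_domain(s$pyruvate, -0.5 * s$lactate, 4, t1_eff = 30)
  expect_lt(f$k_pl_hat, 0)
  expect_true("negative_kpl" %in% f$flags)
})

test_that("lac/pyr ratio reproduces constructed map ratios", {
  maps <- structure(list(pyruvate = array(2, c(1, 4, 4)),
                         lactate = array(0.7, c(1, 4, 4)),
                         total_carbon = array(2.7, c(1, 4, 4)),
                         provenance = "test"), class = "metabolite_maps")
  mask <- array(TRUE, c(1, 4, 4))
  expect_equal(lac_pyr_ratio(maps, mask), 0.35)
  maps$lactate <- maps$pyruvate
  expect_equal(lac_pyr_ratio(maps, mask), 1)
  maps$lactate <- array(0, c(1, 4, 4))
  expect_equal(lac_pyr_ratio(maps, mask), 0)
  expect_error(lac_pyr_ratio(maps, array(FALSE, c(1, 4, 4))), "empty")
})

test_that("voxel-wise mapping matches truth on a uniform noiseless phantom", {
  g <- small_geometry(n_coils = 2L, recon = 16L)
  sc <- default_phantom_scene(g, tumor_kpl = 0.009, kidney_kpl = 0.009,
                              body_kpl = 0.009, noise_sd = 0, seed = 1)
  img <- simulate_phantom(sc, default_bolus(), g)
  cb <- apply_coil_weights(img, compute_coil_weights(img))
  body <- sc$label_map != 0
  km <- fit_kpl_map(cb, body, t1_eff = 30)
  vals <- km$k_pl[body]
  expect_true(all(is.finite(vals)))
  expect_lt(max(abs(vals / 0.009 - 1)), 0.02)
  expect_true(all(is.na(km$k_pl[!body])))
})

test_that("an empty mask produces an all-missing map with a warning", {
  g <- small_geometry(n_coils = 2L, recon = 16L)
  sc <- default_phantom_scene(g, noise_sd = 0, seed = 1)
  img <- simulate_phantom(sc, default_bolus(), g)
  cb <- apply_coil_weights(img, compute_coil_weights(img))
  expect_warning(km <- fit_kpl_map(cb, array(FALSE, dim = dim(sc$label_map))),
                 "empty mask")
  expect_true(all(is.na(km$k_pl)))
})
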