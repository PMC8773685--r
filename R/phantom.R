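## Seed hygiene: run stochastic code under a local RNG state so that seeded
## generators are pure functions of (inputs, seed) without clobbering the
## caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Phantom scene: regions, kinetics, coils and noise
#'
#' Describes a digital phantom on the reconstructed grid: an integer region
#' label map (0 = background/air), per-region kinetic parameters and
#' pyruvate delivery amplitudes, complex coil sensitivity maps, the complex
#' noise standard deviation, and the seed making the simulation
#' reproducible.
#'
#' @param label_map Integer array `[slice, row, col]`; 0 is background.
#' @param regions Named list: for each non-zero label (as character), a list
#'   with elements `params` (a [kinetic_params()]) and `delivery` (pyruvate
#'   delivery amplitude, > 0).
#' @param coil_sens Complex array `[coil, slice, row, col]`, non-zero over
#'   the body support.
#' @param noise_sd Standard deviation of the complex Gaussian noise added
#'   per real/imaginary component, coil, frame and voxel (>= 0).
#' @param seed Integer seed.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(label_map, regions, coil_sens, noise_sd, seed) {
  stopifnot(length(dim(label_map)) == 3, noise_sd >= 0,
            length(dim(coil_sens)) == 4,
            identical(dim(coil_sens)[2:4], dim(label_map)))
  labs <- sort(unique(as.integer(label_map[label_map != 0])))
  for (l in labs) {
    reg <- regions[[as.character(l)]]
    if (is.null(reg) || !inherits(reg$params, "kinetic_params") ||
        !is.finite(reg$delivery) || reg$delivery <= 0)
      stop(sprintf("region %d lacks valid kinetic parameters or delivery", l))
  }
  body <- label_map != 0
  sens_mag <- apply(Mod(coil_sens), c(2, 3, 4), max)
  if (any(sens_mag[body] == 0))
    stop("coil sensitivities vanish over part of the body support")
  structure(list(label_map = label_map, regions = regions,
                 coil_sens = coil_sens, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

#' Smooth ring-array coil sensitivities
#'
#' Gaussian-profile complex sensitivities for `n_coils` elements arranged in
#' a ring around the in-plane grid, with a coil-specific smooth phase ramp.
#' Emulates an abdominal receive array.
#'
#' @param geometry An [acq_geometry()] object (`n_coils`, `recon_matrix`,
#'   `n_slices`).
#' @param width Gaussian width as a fraction of the grid size.
#' @return Complex array `[coil, slice, row, col]`.
#' @export
ring_coil_sensitivities <- function(geometry, width = 0.8) {
  n <- geometry$recon_matrix
  nc <- geometry$n_coils
  ns <- geometry$n_slices
  ctr <- (n + 1) / 2
  rad <- 0.75 * n / 2
  sens <- array(0 + 0i, dim = c(nc, ns, n, n))
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  for (k in seq_len(nc)) {
    th <- 2 * pi * (k - 1) / nc
    cy <- ctr + rad * sin(th)
    cx <- ctr + rad * cos(th)
    d2 <- (rr - cy)^2 + (cc - cx)^2
    mag <- exp(-d2 / (2 * (width * n / 2)^2))
    phs <- 0.5 * pi * ((rr - ctr) * sin(th) + (cc - ctr) * cos(th)) / n + th
    plane <- mag * exp(1i * phs)
    for (s in seq_len(ns)) sens[k, s, , ] <- plane
  }
  sens
}

#' Default renal phantom scene
#'
#' Builds a simple axial phantom on the reconstructed grid: an elliptical
#' body (label 1), a contralateral normal kidney disk (label 2) and a tumor
#' disk (label 3), with ring-array coil sensitivities. Default kinetics put
#' the tumor at the clear-cell carcinoma level and the kidney at the normal-
#' parenchyma level.
#'
#' @param geometry An [acq_geometry()] object.
#' @param tumor_kpl,kidney_kpl,body_kpl Exchange rates (1/s) per region.
#' @param t1_eff Effective lactate relaxation time (s), shared by regions.
#' @param noise_sd Complex noise standard deviation per component.
#' @param seed Integer seed.
#' @param tumor_radius_frac Tumor radius as a fraction of the grid size.
#' @return A [phantom_scene()].
#' @export
default_phantom_scene <- function(geometry,
                                  tumor_kpl = 0.0065,
                                  kidney_kpl = 0.0043,
                                  body_kpl = 0.001,
                                  t1_eff = 30,
                                  noise_sd = 0,
                                  seed = 1L,
                                  tumor_radius_frac = 0.14) {
  n <- geometry$recon_matrix
  ns <- geometry$n_slices
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  lab <- array(0L, dim = c(ns, n, n))
  body <- ((rr - ctr) / (0.42 * n))^2 + ((cc - ctr) / (0.46 * n))^2 <= 1
  kid <- sqrt((rr - ctr)^2 + (cc - (ctr - 0.25 * n))^2) <= 0.10 * n
  tum <- sqrt((rr - ctr)^2 + (cc - (ctr + 0.22 * n))^2) <= tumor_radius_frac * n
  plane <- ifelse(tum, 3L, ifelse(kid, 2L, ifelse(body, 1L, 0L)))
  for (s in seq_len(ns)) lab[s, , ] <- plane
  regions <- list(
    "1" = list(params = kinetic_params(body_kpl, t1_eff), delivery = 0.4),
    "2" = list(params = kinetic_params(kidney_kpl, t1_eff), delivery = 1),
    "3" = list(params = kinetic_params(tumor_kpl, t1_eff), delivery = 1)
  )
  phantom_scene(lab, regions, ring_coil_sensitivities(geometry),
                noise_sd, seed)
}

#' Simulate a dynamic multi-coil phantom acquisition
#'
#' Evaluates the noiseless two-site exchange courses of each region (with RF
#' depletion), scales them by the region's delivery amplitude, multiplies by
#' each coil's complex sensitivity and adds independent complex Gaussian
#' noise (standard deviation `noise_sd` per real/imaginary component) for
#' every coil, frame and voxel. Deterministic for a fixed scene seed.
#'
#' @param scene A [phantom_scene()].
#' @param bolus A [gamma_variate_bolus()].
#' @param geometry An [acq_geometry()] whose grid matches the scene.
#' @param rf_depletion Passed to [simulate_two_site_exchange()].
#' @return A [dynamic_metabolic_image()]. The noiseless per-region courses
#'   are attached as attribute `"truth"` (ground-truth closure).
#' @export
simulate_phantom <- function(scene, bolus, geometry, rf_depletion = TRUE) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(geometry, "acq_geometry"))
  dm <- dim(scene$label_map)
  if (!identical(dm, c(geometry$n_slices, geometry$recon_matrix,
                       geometry$recon_matrix)))
    stop("scene grid does not match the acquisition geometry")
  if (dim(scene$coil_sens)[1] != geometry$n_coils)
    stop("scene coil count does not match the acquisition geometry")
  nf <- geometry$n_frames
  nc <- geometry$n_coils
  labs <- sort(unique(as.integer(scene$label_map[scene$label_map != 0])))
  courses <- lapply(labs, function(l) {
    reg <- scene$regions[[as.character(l)]]
    s <- simulate_two_site_exchange(reg$params, bolus, geometry,
                                    rf_depletion = rf_depletion)
    rbind(s$pyruvate, s$lactate) * reg$delivery
  })
  names(courses) <- as.character(labs)
  ## noiseless single-channel image [metabolite, frame, slice, row, col]
  noiseless <- array(0, dim = c(2, nf, prod(dm)))
  for (l in labs) {
    sel <- which(scene$label_map == l)                    # voxel linear index
    crs <- courses[[as.character(l)]]                     # 2 x nf
    noiseless[, , sel] <- array(crs, dim = c(2, nf, length(sel)))
  }
  dim(noiseless) <- c(2, nf, dm)
  data <- array(0 + 0i, dim = c(2, nc, nf, dm))
  for (coil in seq_len(nc)) {
    sens <- scene$coil_sens[coil, , , ]
    wfull <- aperm(array(sens, dim = c(dm, 2, nf)), c(4, 5, 1, 2, 3))
    data[, coil, , , , ] <- wfull * noiseless
  }
  if (scene$noise_sd > 0) {
    nel <- length(data)
    noise <- with_seed(scene$seed, {
      complex(real = stats::rnorm(nel, 0, scene$noise_sd),
              imaginary = stats::rnorm(nel, 0, scene$noise_sd))
    })
    data <- data + array(noise, dim = dim(data))
  }
  img <- dynamic_metabolic_image(data, geometry)
  attr(img, "truth") <- list(courses = courses, label_map = scene$label_map)
  img
}

#' Noise level yielding a target summed-map pyruvate SNR
#'
#' Inverts the SNR formula of [compute_snr()] for the time-summed pyruvate
#' map: given the noiseless summed pyruvate magnitude of a region, returns
#' the per-component complex noise standard deviation at which the region's
#' Formula-based SNR is approximately the target. The background statistics
#' of the summed map follow a Rayleigh distribution with scale
#' `noise_sd * sqrt(n_frames)`.
#'
#' @param scene A [phantom_scene()] (its `noise_sd` is ignored).
#' @param bolus,geometry As in [simulate_phantom()].
#' @param target_snr Desired pyruvate SNR in the region.
#' @param region_label Region whose mean summed pyruvate defines the signal
#'   (default 3, the tumor of [default_phantom_scene()]).
#' @return Scalar noise standard deviation.
#' @export
noise_sd_for_snr <- function(scene, bolus, geometry, target_snr,
                             region_label = 3L) {
  stopifnot(target_snr > 0)
  reg <- scene$regions[[as.character(region_label)]]
  if (is.null(reg)) stop("region label not present in scene")
  s <- simulate_two_site_exchange(reg$params, bolus, geometry)
  ## matched-filter combination captures the coil-norm of the sensitivities
  sel <- scene$label_map == region_label
  gain <- sqrt(apply(Mod(scene$coil_sens)^2, c(2, 3, 4), sum))
  S <- sum(s$pyruvate) * reg$delivery * mean(gain[sel])
  nf <- geometry$n_frames
  ## On background voxels the SVD weights align with the noise itself, so the
  ## combined background follows the top-singular-value projection of a
  ## 2 x n_coils complex Gaussian matrix, not a plain Rayleigh law. Its
  ## first-component statistics are obtained by a small seeded Monte Carlo.
  bg <- with_seed(20210101L, {
    vapply(seq_len(4000), function(i) {
      M <- matrix(complex(real = stats::rnorm(2 * geometry$n_coils),
                          imaginary = stats::rnorm(2 * geometry$n_coils)),
                  nrow = 2)
      sv <- svd(M, nu = 1, nv = 0)
      sv$d[1] * Mod(sv$u[1, 1])
    }, numeric(1))
  })
  m1 <- mean(bg)
  s1 <- stats::sd(bg)
  ## target = (S - mean_bg) / (sqrt(2) sd_bg)
  S / ((target_snr * sqrt(2) * s1 + m1) * sqrt(nf))
}

#' Ground-truth kPL map of a phantom scene
#'
#' Voxel-level true exchange rates exactly as used to render the phantom
#' (ground-truth closure): each voxel carries its region's `k_pl`,
#' background is `NA`.
#'
#' @param scene A [phantom_scene()].
#' @return Numeric array `[slice, row, col]`.
#' @export
scene_kpl_truth_map <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  out <- array(NA_real_, dim = dim(scene$label_map))
  for (l in sort(unique(as.integer(scene$label_map[scene$label_map != 0])))) {
    out[scene$label_map == l] <- scene$regions[[as.character(l)]]$params$k_pl
  }
  out
}
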