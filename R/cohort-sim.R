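#' Link specifications for the synthetic cohort
#'
#' `grade_kpl_link()` maps a WHO/ISUP grade to a median kPL with lognormal
#' biological scatter; the defaults place grades 1-4 across the clear-cell
#' carcinoma range and make the link monotone. `mct1_kpl_link()` maps kPL to
#' a percent-positive MCT1 expression linearly with Gaussian noise (clipped
#' at zero).
#'
#' @param kpl_by_grade Named numeric vector of median kPL (1/s) per grade
#'   "1".."4"; must be non-decreasing for a monotone link.
#' @param sd_log Lognormal scatter (sd of log kPL) around the grade median.
#' @return A link specification list.
#' @export
grade_kpl_link <- function(kpl_by_grade = c("1" = 0.0030, "2" = 0.0045,
                                            "3" = 0.0080, "4" = 0.0130),
                           sd_log = 0.10) {
  stopifnot(length(kpl_by_grade) == 4, all(kpl_by_grade > 0), sd_log >= 0)
  list(kpl_by_grade = kpl_by_grade, sd_log = sd_log)
}

#' @rdname grade_kpl_link
#' @param intercept,slope Linear map from kPL (1/s) to percent positive
#'   MCT1.
#' @param noise_sd Gaussian noise sd on the percent scale.
#' @export
mct1_kpl_link <- function(intercept = 1, slope = 600, noise_sd = 0.8) {
  list(intercept = intercept, slope = slope, noise_sd = noise_sd)
}

#' Default scaled-down acquisition geometry for cohort simulation
#'
#' The clinical timing, flip-angle and RF-excitation schedule are retained
#' (20 frames at 4 s starting 12 s post injection, 15 degrees, five
#' excitations per frame); the spatial grid is reduced to a single slice of
#' 32 x 32 voxels with 4 coils so that multi-patient cohorts stay cheap to
#' simulate and fit.
#'
#' @return An [acq_geometry()].
#' @export
cohort_geometry <- function() {
  acq_geometry(recon_matrix = 32L, acq_matrix = 32L, n_slices = 1L,
               n_coils = 4L, excitations_per_frame = 5L)
}

#' Generate a synthetic multi-patient cohort with imaging phantoms
#'
#' Draws per-patient overall grades and median kPL values through the
#' grade link, per-biopsy grades (allowing within-tumor heterogeneity, one
#' grade below the overall grade), biopsy-level kPL from the biopsy grade,
#' MCT1 expression from the kPL link, plus MCT4, cell density and viable
#' tumor fraction. Each patient receives a [phantom_scene()] whose tumor
#' carries the patient's kPL and in which each biopsy is embedded as a
#' small subregion carrying the biopsy's kPL at the biopsy location, so that
#' imaging-derived kPL at the biopsy site matches the biopsy truth up to
#' noise. All draws are governed by `seed`.
#'
#' @param n_patients Number of patients (>= 3).
#' @param biopsies_per_patient Integer range `c(min, max)`.
#' @param grade_link A [grade_kpl_link()].
#' @param mct1_link An [mct1_kpl_link()].
#' @param seed Integer seed.
#' @param geometry Acquisition geometry for the phantoms (default
#'   [cohort_geometry()]).
#' @param target_pyr_snr Pyruvate SNR of the tumor on the time-summed map;
#'   sets each scene's noise level via [noise_sd_for_snr()]. Use 0 for
#'   noiseless phantoms.
#' @param bolus Bolus model shared by all patients.
#' @param grades Overall grades to cycle through (default 2, 3, 4 as in a
#'   renal-tumor surgical series).
#' @param tumor_radius_frac Tumour radius as a fraction of the grid size.
#' @return List of class `synthetic_cohort`: `patients` and `biopsies` data
#'   frames, `scenes` (one [phantom_scene()] per patient), `geometry`,
#'   `bolus`.
#' @export
generate_cohort <- function(n_patients = 6,
                            biopsies_per_patient = c(3, 9),
                            grade_link = grade_kpl_link(),
                            mct1_link = mct1_kpl_link(),
                            seed = 1L,
                            geometry = cohort_geometry(),
                            target_pyr_snr = 27,
                            bolus = gamma_variate_bolus(),
                            grades = c(2, 3, 4),
                            tumor_radius_frac = 0.16) {
  stopifnot(n_patients >= 3, length(biopsies_per_patient) == 2,
            biopsies_per_patient[1] >= 1,
            biopsies_per_patient[2] >= biopsies_per_patient[1])
  if (mct1_link$slope == 0 && mct1_link$noise_sd == 0)
    warning("degenerate MCT1 link: zero slope with zero noise")
  kbg <- grade_link$kpl_by_grade
  if (all(diff(kbg) == 0) && grade_link$sd_log == 0)
    warning("degenerate grade link: flat with zero noise")

  n <- geometry$recon_matrix
  sub_rad <- max(1, round(0.04 * n))   # biopsy subregion radius, voxels

  out <- with_seed(seed, {
    pat_grade <- rep_len(grades, n_patients)
    pat_kpl <- kbg[as.character(pat_grade)] *
      exp(stats::rnorm(n_patients, 0, grade_link$sd_log))
    patients <- data.frame(
      patient_id = sprintf("P%02d", seq_len(n_patients)),
      tumor_type = "ccRCC",
      grade = pat_grade,
      true_kpl = as.numeric(pat_kpl))
    scenes <- vector("list", n_patients)
    biopsies <- NULL
    for (i in seq_len(n_patients)) {
      sc <- default_phantom_scene(geometry, tumor_kpl = patients$true_kpl[i],
                                  seed = seed + 1000L + i,
                                  tumor_radius_frac = tumor_radius_frac)
      tum <- which(sc$label_map == 3L, arr.ind = TRUE)
      ## tumour centre/extent for placing biopsy subregions fully inside
      ctr <- colMeans(tum)
      rad_vox <- max(sqrt((tum[, 2] - ctr[2])^2 + (tum[, 3] - ctr[3])^2))
      nb <- sample(seq(biopsies_per_patient[1], biopsies_per_patient[2]), 1)
      ## candidate centres: tumour voxels at least sub_rad inside the border;
      ## greedy dart throwing keeps the biopsy subregions disjoint
      inner <- tum[sqrt((tum[, 2] - ctr[2])^2 + (tum[, 3] - ctr[3])^2) <=
                     rad_vox - sub_rad, , drop = FALSE]
      cand <- inner[sample(nrow(inner)), , drop = FALSE]
      pick <- cand[1, , drop = FALSE]
      for (ci in seq_len(nrow(cand))) {
        if (nrow(pick) >= nb) break
        d <- sqrt((pick[, 2] - cand[ci, 2])^2 + (pick[, 3] - cand[ci, 3])^2)
        if (all(d >= 2 * sub_rad + 1)) pick <- rbind(pick, cand[ci, ])
      }
      nb <- nrow(pick)
      bgr <- ifelse(stats::runif(nb) < 0.3,
                    pmax(1, patients$grade[i] - 1), patients$grade[i])
      bkpl <- unname(kbg[as.character(bgr)]) *
        exp(stats::rnorm(nb, 0, grade_link$sd_log))
      lab <- sc$label_map
      regions <- sc$regions
      ## embed biopsy subregions into the tumour
      rr <- matrix(seq_len(n), n, n)
      cc <- t(rr)
      for (j in seq_len(nb)) {
        d <- sqrt((rr - pick[j, 2])^2 + (cc - pick[j, 3])^2)
        plane <- lab[pick[j, 1], , ]
        plane[d <= sub_rad & plane == 3L] <- 100L + j
        lab[pick[j, 1], , ] <- plane
        regions[[as.character(100L + j)]] <-
          list(params = kinetic_params(bkpl[j],
                                       regions[["3"]]$params$t1_eff),
               delivery = regions[["3"]]$delivery)
      }
      sc <- phantom_scene(lab, regions, sc$coil_sens, 0, seed + 2000L + i)
      if (target_pyr_snr > 0) {
        sc$noise_sd <- noise_sd_for_snr(sc, bolus, geometry, target_pyr_snr,
                                        region_label = 3L)
      }
      scenes[[i]] <- sc
      vox <- voxel_size_mm(geometry)
      biopsies <- rbind(biopsies, data.frame(
        patient_id = patients$patient_id[i],
        biopsy_id = sprintf("%s-B%02d", patients$patient_id[i], seq_len(nb)),
        slice = pick[, 1], row = pick[, 2], col = pick[, 3],
        x_mm = (pick[, 3] - 0.5) * vox,
        y_mm = (pick[, 2] - 0.5) * vox,
        z_mm = (pick[, 1] - 1) * slice_pitch_mm(geometry),
        grade = bgr,
        true_kpl = as.numeric(bkpl),
        region_label = 100L + seq_len(nb),
        mct1_pct = pmax(0, mct1_link$intercept + mct1_link$slope * bkpl +
                          stats::rnorm(nb, 0, mct1_link$noise_sd)),
        mct4_pct = stats::runif(nb, 20, 50),
        cell_density = stats::runif(nb, 1000, 4000),
        viable_fraction = stats::runif(nb, 0.6, 1)))
    }
    list(patients = patients, biopsies = biopsies, scenes = scenes)
  })
  structure(c(out, list(geometry = geometry, bolus = bolus, seed = seed)),
            class = "synthetic_cohort")
}
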