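#' Write time-summed metabolite maps as NIfTI
#'
#' One NIfTI-1 file per map (`pyruvate.nii.gz` is avoided: files are written
#' uncompressed as `pyruvate.nii`, `lactate.nii`, `total_carbon.nii`), with
#' the array reordered to the NIfTI (x = col, y = row, z = slice) axis
#' convention and the in-plane voxel size and slice pitch recorded in the
#' header.
#'
#' @param maps A `metabolite_maps` object.
#' @param geometry The [acq_geometry()] of the maps.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_metabolite_maps <- function(maps, geometry, dir) {
  stopifnot(inherits(maps, "metabolite_maps"), inherits(geometry, "acq_geometry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- voxel_size_mm(geometry)
  paths <- character(0)
  for (nm in c("pyruvate", "lactate", "total_carbon")) {
    vol <- aperm(maps[[nm]], c(3, 2, 1))            # x = col, y = row, z = slice
    img <- RNifti::asNifti(vol, pixdim = c(vox, vox, slice_pitch_mm(geometry)))
    p <- file.path(dir, paste0(nm, ".nii"))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a metabolite map written by [write_metabolite_maps()]
#'
#' @param path NIfTI file path.
#' @return Numeric array `[slice, row, col]`.
#' @export
read_metabolite_map <- function(path) {
  vol <- RNifti::readNifti(path)
  dm <- dim(vol)
  if (length(dm) == 2) dm <- c(dm, 1L)     # single-slice volumes read as 2-D
  aperm(array(as.numeric(vol), dim = dm), c(3, 2, 1))
}

#' JSON sidecar for acquisition geometry and noise statistics
#'
#' @param geometry An [acq_geometry()].
#' @param path Output `.json` path.
#' @param noise Optional [noise_estimate()] stored alongside.
#' @return Invisibly, `path`.
#' @export
write_geometry_json <- function(geometry, path, noise = NULL) {
  stopifnot(inherits(geometry, "acq_geometry"))
  obj <- unclass(geometry)
  if (!is.null(noise)) obj$noise_estimate <- unclass(noise)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  noise <- NULL
  if (!is.null(obj$noise_estimate)) {
    noise <- do.call(noise_estimate, obj$noise_estimate[
      c("mean_noise", "sd_noise", "n_voxels", "region")])
    obj$noise_estimate <- NULL
  }
  geom <- do.call(acq_geometry, obj)
  list(geometry = geom, noise = noise)
}

#' Write cohort tables as CSV
#'
#' Writes `patients.csv` and `biopsies.csv` with the documented column
#' schema (patient_id, biopsy_id, slice/row/col, physical mm coordinates,
#' grade, kpl, mct1_pct, mct4_pct, cell_density, viable_fraction).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  bp <- file.path(dir, "biopsies.csv")
  utils::write.csv(cohort$patients, pp, row.names = FALSE)
  utils::write.csv(cohort$biopsies, bp, row.names = FALSE)
  invisible(c(pp, bp))
}

#' Write a synthetic IHC image, its masks and ground truth
#'
#' The RGB image and the ground-truth class masks are written as PNG; the
#' scalar ground truth (fractions, nucleus count) as a JSON sidecar.
#'
#' @param ihc An `ihc_image` from [generate_ihc_image()].
#' @param dir Output directory.
#' @param stem File-name stem (default `"ihc"`).
#' @return Invisibly, the written file paths.
#' @export
write_ihc_png <- function(ihc, dir, stem = "ihc") {
  stopifnot(inherits(ihc, "ihc_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  png::writePNG(ihc$image / 255, img_path)
  cls <- ihc$class_map
  cls[is.na(cls)] <- 4L                      # not-tissue code in the mask PNG
  mask_path <- file.path(dir, paste0(stem, "_classes.png"))
  png::writePNG(cls / 4, mask_path)
  truth_path <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(list(target_fractions = as.list(ihc$target_fractions),
                            realized_fractions = as.list(ihc$realized_fractions),
                            nucleus_count = ihc$nucleus_count),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, mask_path, truth_path))
}

#' Read an RGB PNG as a 0-255 intensity array
#'
#' @param path PNG file path.
#' @return Numeric array `[rows, cols, 3]` scaled to 0-255.
#' @export
read_ihc_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3] * 255
}

#' Write a dynamic multi-coil image as NIfTI volumes
#'
#' One 4-D NIfTI file per metabolite and coil, named
#' `<metabolite>_coil<k>_<part>.nii` with separate real and imaginary parts
#' (NIfTI-1 stores real volumes), axes ordered (x = col, y = row,
#' z = slice, t = frame), plus a `geometry.json` sidecar.
#'
#' @param image A [dynamic_metabolic_image()].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_dynamic_image <- function(image, dir) {
  stopifnot(inherits(image, "dynamic_metabolic_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- image$geometry
  vox <- voxel_size_mm(g)
  paths <- character(0)
  mets <- c("pyruvate", "lactate")
  for (m in 1:2) for (coil in seq_len(g$n_coils)) {
    vol <- aperm(array(image$data[m, coil, , , , ],
                       dim = dim(image$data)[3:6]), c(4, 3, 2, 1))
    for (part in c("real", "imag")) {
      v <- if (part == "real") Re(vol) else Im(vol)
      p <- file.path(dir, sprintf("%s_coil%02d_%s.nii", mets[m], coil, part))
      RNifti::writeNifti(
        RNifti::asNifti(v, pixdim = c(vox, vox, slice_pitch_mm(g),
                                      g$frame_spacing)), p)
      paths <- c(paths, p)
    }
  }
  paths <- c(paths, write_geometry_json(g, file.path(dir, "geometry.json")))
  invisible(paths)
}
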