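#' Dynamic multi-coil metabolic image container
#'
#' Complex-valued dynamic data for two metabolites (pyruvate, lactate)
#' acquired over multiple receive coils. The data array is indexed
#' `[metabolite, coil, frame, slice, row, col]`.
#'
#' @param data Complex array with dimensions
#'   `c(2, n_coils, n_frames, n_slices, nrow, ncol)`.
#' @param geometry An [acq_geometry()] object consistent with `data`.
#' @return An object of class `dynamic_metabolic_image` with elements
#'   `data`, `geometry` and `times` (the frame time axis).
#' @export
dynamic_metabolic_image <- function(data, geometry) {
  stopifnot(inherits(geometry, "acq_geometry"), is.complex(data))
  dm <- dim(data)
  if (length(dm) != 6 || dm[1] != 2)
    stop("data must be a 6-D complex array [metabolite, coil, frame, slice, row, col]")
  if (dm[2] != geometry$n_coils || dm[3] != geometry$n_frames ||
      dm[4] != geometry$n_slices)
    stop("data dimensions are inconsistent with the acquisition geometry")
  structure(list(data = data, geometry = geometry,
                 times = frame_times(geometry)),
            class = "dynamic_metabolic_image")
}

#' SVD coil-combination weights
#'
#' Computes a per-voxel complex weight vector over coils from the dynamic
#' data summed over all time points (complex sum, which minimizes noise
#' propagation into the weights). For each voxel the matrix of time-summed
#' values (metabolites, and optionally a square spatial neighborhood, stacked
#' as rows) by coils is formed; the weight vector is the conjugate of its
#' dominant right-singular vector, so that applying the weights acts as a
#' matched filter. Weights have unit Euclidean norm per voxel and are phase-
#' normalized so the reference coil's weight is real and non-negative.
#'
#' Voxels with all-zero time-summed data receive a unit weight on the
#' reference coil.
#'
#' @param image A [dynamic_metabolic_image()].
#' @param neighborhood Odd side length (in voxels) of the square spatial
#'   neighborhood whose time-summed values are stacked into the SVD (default
#'   1, i.e. single voxel).
#' @param ref_coil Reference coil index for the phase convention.
#' @return An object of class `coil_weights`: complex array
#'   `[coil, slice, row, col]` plus the phase-convention tag.
#' @export
compute_coil_weights <- function(image, neighborhood = 1, ref_coil = 1) {
  stopifnot(inherits(image, "dynamic_metabolic_image"))
  neighborhood <- as.integer(neighborhood)
  if (neighborhood < 1 || neighborhood %% 2 == 0)
    stop("neighborhood must be a positive odd integer")
  dm <- dim(image$data)
  nc <- dm[2]; ns <- dm[4]; nr <- dm[5]; ncl <- dm[6]
  stopifnot(ref_coil >= 1, ref_coil <= nc)
  ## complex sum over frames -> [metabolite, coil, slice, row, col]
  ts <- apply(image$data, c(1, 2, 4, 5, 6), sum)
  w <- array(0 + 0i, dim = c(nc, ns, nr, ncl))
  hw <- (neighborhood - 1L) %/% 2L
  for (s in seq_len(ns)) {
    for (r in seq_len(nr)) {
      rr <- max(1, r - hw):min(nr, r + hw)
      for (cl in seq_len(ncl)) {
        cc <- max(1, cl - hw):min(ncl, cl + hw)
        ## rows: metabolite x neighborhood voxels; cols: coils
        M <- matrix(aperm(ts[, , s, rr, cc, drop = FALSE],
                          c(1, 4, 5, 2, 3)), ncol = nc)
        if (all(M == 0)) {
          v <- rep(0 + 0i, nc); v[ref_coil] <- 1 + 0i
          w[, s, r, cl] <- v
          next
        }
        sv <- svd(M, nu = 0, nv = 1)
        v <- Conj(sv$v[, 1])
        ph <- v[ref_coil]
        if (Mod(ph) < 1e-12) ph <- v[which.max(Mod(v))]
        v <- v * Conj(ph) / Mod(ph)
        w[, s, r, cl] <- v / sqrt(sum(Mod(v)^2))
      }
    }
  }
  structure(list(weights = w, ref_coil = as.integer(ref_coil),
                 phase_convention = "ref_coil_real_nonneg"),
            class = "coil_weights")
}

#' Apply coil-combination weights
#'
#' Collapses the coil dimension: per voxel, frame and metabolite the output
#' is the inner product of the coil data vector with the conjugated weights.
#' With the matched-filter weights of [compute_coil_weights()] this captures
#' the full coil-array energy of rank-one data.
#'
#' @param image A [dynamic_metabolic_image()].
#' @param weights A `coil_weights` object on the same grid.
#' @return An object of class `combined_dynamic_image` with complex array
#'   `data[metabolite, frame, slice, row, col]`, the geometry and time axis.
#' @export
apply_coil_weights <- function(image, weights) {
  stopifnot(inherits(image, "dynamic_metabolic_image"),
            inherits(weights, "coil_weights"))
  dm <- dim(image$data)
  if (!identical(dim(weights$weights), c(dm[2], dm[4], dm[5], dm[6])))
    stop("weight grid does not match the image grid")
  out <- array(0 + 0i, dim = dm[-2])
  cw <- Conj(weights$weights)
  for (coil in seq_len(dm[2])) {
    wc <- cw[coil, , , , drop = TRUE]
    ## broadcast [slice,row,col] weight over metabolite and frame
    wfull <- aperm(array(wc, dim = c(dm[4], dm[5], dm[6], dm[1], dm[3])),
                   c(4, 5, 1, 2, 3))
    out <- out + wfull * array(image$data[, coil, , , , ], dim = dm[-2])
  }
  structure(list(data = out, geometry = image$geometry, times = image$times),
            class = "combined_dynamic_image")
}

#' Time-summed metabolite maps
#'
#' Sums the combined complex dynamics over all time points per metabolite
#' (complex sum first, magnitude last) and forms the total-carbon map as the
#' voxel-wise sum of the pyruvate and lactate magnitude maps.
#'
#' @param combined A `combined_dynamic_image` from [apply_coil_weights()].
#' @return An object of class `metabolite_maps`: non-negative arrays
#'   `pyruvate`, `lactate` and `total_carbon` indexed `[slice, row, col]`,
#'   with a provenance tag.
#' @export
sum_time_maps <- function(combined) {
  stopifnot(inherits(combined, "combined_dynamic_image"))
  dm <- dim(combined$data)
  csum <- apply(combined$data, c(1, 3, 4, 5), sum)   # metabolite, slice, row, col
  pyr <- Mod(array(csum[1, , , ], dim = dm[3:5]))
  lac <- Mod(array(csum[2, , , ], dim = dm[3:5]))
  structure(list(pyruvate = pyr, lactate = lac, total_carbon = pyr + lac,
                 provenance = "time-summed-then-magnitude"),
            class = "metabolite_maps")
}
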