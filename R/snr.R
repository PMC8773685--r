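#' Background noise estimate
#'
#' Summary statistics of the magnitude background signal, estimated in an
#' extracorporeal region free of spiral artifacts. On magnitude images the
#' background follows a Rayleigh distribution, which motivates the sqrt(2)
#' factor in [compute_snr()].
#'
#' @param mean_noise Mean background magnitude.
#' @param sd_noise Standard deviation of the background magnitude (> 0).
#' @param n_voxels Number of background voxels used.
#' @param region Free-text descriptor of the source region.
#' @return An object of class `noise_estimate`.
#' @export
noise_estimate <- function(mean_noise, sd_noise, n_voxels = NA_integer_,
                           region = "extracorporeal") {
  stopifnot(is.finite(mean_noise), is.finite(sd_noise), sd_noise > 0)
  structure(list(mean_noise = mean_noise, sd_noise = sd_noise,
                 n_voxels = as.integer(n_voxels), region = region),
            class = "noise_estimate")
}

#' Estimate background noise from a magnitude map
#'
#' @param map Non-negative numeric array (a magnitude map, e.g. one component
#'   of [sum_time_maps()]).
#' @param background_mask Logical array of the same shape selecting
#'   background-only voxels.
#' @param min_voxels Minimum number of background voxels required
#'   (default 100).
#' @param region Descriptor stored in the estimate.
#' @return A [noise_estimate()].
#' @export
estimate_noise <- function(map, background_mask, min_voxels = 100,
                           region = "extracorporeal") {
  stopifnot(is.numeric(map), is.logical(background_mask),
            identical(dim(map), dim(background_mask)))
  vals <- map[background_mask]
  if (length(vals) < min_voxels)
    stop(sprintf("need >= %d background voxels, got %d",
                 min_voxels, length(vals)))
  noise_estimate(mean(vals), stats::sd(vals), length(vals), region)
}

#' Per-map background noise estimates
#'
#' Background mean and standard deviation estimated separately on the
#' pyruvate, lactate and total-carbon summed maps (the background level of a
#' sum map differs from that of its components, so each map needs its own
#' estimate).
#'
#' @param maps A `metabolite_maps` object.
#' @param background_mask Logical array selecting background-only voxels.
#' @param min_voxels Passed to [estimate_noise()].
#' @return Named list of [noise_estimate()]s: `pyruvate`, `lactate`,
#'   `total_carbon`.
#' @export
estimate_noise_maps <- function(maps, background_mask, min_voxels = 100) {
  stopifnot(inherits(maps, "metabolite_maps"))
  lapply(maps[c("pyruvate", "lactate", "total_carbon")], estimate_noise,
         background_mask = background_mask, min_voxels = min_voxels)
}

#' Metabolite signal-to-noise ratio
#'
#' SNR of a magnitude ROI relative to background noise:
#' \deqn{\mathrm{SNR} = \frac{\mathrm{mean}(SI_{ROI}) -
#'   \mathrm{mean}(SI_{noise})}{\sqrt{2}\,\mathrm{S.D.}(SI_{noise})},}
#' where the sqrt(2) factor accounts for the narrowed Rayleigh distribution
#' of magnitude background noise. The result may be negative.
#'
#' @param roi_values Non-empty numeric vector of ROI magnitude samples.
#' @param noise A [noise_estimate()].
#' @return Scalar SNR.
#' @examples
#' compute_snr(c(10, 10), noise_estimate(2, 2))  # (10-2)/(sqrt(2)*2)
#' @export
compute_snr <- function(roi_values, noise) {
  stopifnot(inherits(noise, "noise_estimate"))
  if (length(roi_values) == 0) stop("ROI is empty")
  (mean(roi_values) - noise$mean_noise) / (sqrt(2) * noise$sd_noise)
}

#' SNR-threshold fitting mask
#'
#' Selects the voxels whose single-voxel SNR (per [compute_snr()], with the
#' ROI being that voxel alone) on the summed total-carbon map is greater than
#' or equal to the threshold (inclusive). Voxels below the threshold are
#' prone to poor kinetic fits and are excluded from mapping.
#'
#' @param total_carbon_map Numeric array, typically
#'   `sum_time_maps(...)$total_carbon`, or a `metabolite_maps` object (its
#'   total-carbon component is used).
#' @param noise A [noise_estimate()] on the same intensity scale.
#' @param threshold SNR threshold (default 5, inclusive).
#' @return Logical array of the same shape as the map.
#' @export
build_fit_mask <- function(total_carbon_map, noise, threshold = 5) {
  if (inherits(total_carbon_map, "metabolite_maps"))
    total_carbon_map <- total_carbon_map$total_carbon
  stopifnot(is.numeric(total_carbon_map), inherits(noise, "noise_estimate"))
  snr <- (total_carbon_map - noise$mean_noise) / (sqrt(2) * noise$sd_noise)
  snr >= threshold
}
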