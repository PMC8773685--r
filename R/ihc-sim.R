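#' Generate a synthetic H-DAB immunohistochemistry image
#'
#' Composes an RGB micrograph by Beer-Lambert mixing of the hematoxylin and
#' DAB stain directions of the supplied classifier, so that the quantifier
#' and generator share the same color model. The tissue region is a
#' pixel-exact fraction of the image; within it, contiguous segments are
#' painted with DAB optical densities drawn strictly inside the weak,
#' moderate and strong class intervals (with a safety margin against 8-bit
#' quantization), the remainder staying negative. Cell nuclei are rendered
#' as non-overlapping hematoxylin disks placed by dart throwing in the
#' negative segment (with a retry cap, so the realized count may fall short
#' of the request; the realized count is the ground truth).
#'
#' @param target_fractions Named numeric vector
#'   `c(weak=, moderate=, strong=)` of tissue-area fractions (non-negative,
#'   sum at most 1).
#' @param tissue_fraction Fraction of image pixels that are tissue.
#' @param nuclei_count Requested number of nuclei.
#' @param size Image side length in pixels.
#' @param seed Integer seed (generation is a pure function of arguments and
#'   seed).
#' @param classifier The [stain_classifier()] whose stain vectors and
#'   thresholds define the mixing and the class OD intervals.
#' @param margin Safety margin (OD) kept from the class boundaries.
#' @param nucleus_radius Nucleus disk radius in pixels.
#' @return List of class `ihc_image`: `image` (RGB array, 0-255 doubles),
#'   `class_map` (ground-truth 0-3, `NA` outside tissue), `tissue_mask`,
#'   `nucleus_count`, `nucleus_centers`, `target_fractions` and
#'   `realized_fractions`.
#' @export
generate_ihc_image <- function(target_fractions = c(weak = 0.2,
                                                    moderate = 0.1,
                                                    strong = 0.05),
                               tissue_fraction = 0.9,
                               nuclei_count = 40,
                               size = 160,
                               seed = 1L,
                               classifier = stain_classifier(),
                               margin = 0.02,
                               nucleus_radius = 3L) {
  stopifnot(length(target_fractions) == 3,
            all(names(target_fractions) == c("weak", "moderate", "strong")),
            all(target_fractions >= 0))
  if (sum(target_fractions) > 1)
    stop("class fractions must sum to at most 1")
  stopifnot(tissue_fraction > 0, tissue_fraction <= 1, size >= 16)
  th <- classifier$od_thresholds
  V <- classifier$stain_vectors

  npix <- size * size
  n_tissue <- round(tissue_fraction * npix)
  tissue_idx <- seq_len(n_tissue)          # contiguous band, column-major
  counts <- round(target_fractions * n_tissue)
  if (sum(counts) > n_tissue) counts[which.max(counts)] <-
    counts[which.max(counts)] - (sum(counts) - n_tissue)

  cls_flat <- rep(NA_integer_, npix)
  cls_flat[tissue_idx] <- 0L
  pos <- 1L
  lab <- c(weak = 1L, moderate = 2L, strong = 3L)
  bounds <- list(weak = c(th["weak"] + margin, th["moderate"] - margin),
                 moderate = c(th["moderate"] + margin, th["strong"] - margin),
                 strong = c(th["strong"] + margin, 1.2))

  with_seed(seed, {
    dab <- numeric(npix)
    hema <- numeric(npix)
    hema[tissue_idx] <- stats::runif(n_tissue, 0.08, 0.15)
    for (cn in names(lab)) {
      k <- counts[[cn]]
      if (k > 0) {
        idx <- tissue_idx[pos:(pos + k - 1)]
        cls_flat[idx] <- lab[[cn]]
        dab[idx] <- stats::runif(k, bounds[[cn]][1], bounds[[cn]][2])
        pos <- pos + k
      }
    }
    neg_idx <- tissue_idx[cls_flat[tissue_idx] == 0L]
    if (length(neg_idx) > 0)
      dab[neg_idx] <- stats::runif(length(neg_idx), 0,
                                   max(0, th["weak"] - 3 * margin))

    ## nuclei: dart throwing in the negative segment, disjoint disks
    centers <- matrix(numeric(0), ncol = 2)
    neg_set <- rep(FALSE, npix)
    neg_set[neg_idx] <- TRUE
    rad <- nucleus_radius
    sep2 <- (2 * rad + 2)^2
    tries <- 0L
    max_tries <- 60L * max(1L, nuclei_count)
    while (nrow(centers) < nuclei_count && tries < max_tries) {
      tries <- tries + 1L
      r0 <- sample.int(size, 1)
      c0 <- sample.int(size, 1)
      if (r0 <= rad || r0 > size - rad || c0 <= rad || c0 > size - rad) next
      ## full disk must lie in the negative segment
      rr <- (r0 - rad):(r0 + rad)
      cc <- (c0 - rad):(c0 + rad)
      disk <- outer(rr - r0, cc - c0, function(a, b) a^2 + b^2) <= rad^2
      lin <- outer(rr, (cc - 1) * size, `+`)[disk]
      if (!all(neg_set[lin])) next
      if (nrow(centers) > 0 &&
          any((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2 < sep2)) next
      centers <- rbind(centers, c(r0, c0))
      hema[lin] <- stats::runif(sum(disk), 0.6, 0.9)
    }
  })

  od_flat <- cbind(hema, dab) %*% t(V)     # npix x 3
  img <- array(255 * 10^(-od_flat), dim = c(size, size, 3))
  realized <- c(counts / n_tissue)
  names(realized) <- names(target_fractions)
  structure(list(image = img,
                 class_map = matrix(cls_flat, size, size),
                 tissue_mask = matrix(seq_len(npix) %in% tissue_idx,
                                      size, size),
                 nucleus_count = nrow(centers),
                 nucleus_centers = centers,
                 target_fractions = target_fractions,
                 realized_fractions = realized),
            class = "ihc_image")
}
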