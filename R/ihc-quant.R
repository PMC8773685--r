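#' DAB stain classifier configuration
#'
#' Optical-density thresholds separating negative, weak, moderate and strong
#' DAB staining (defaults 0.2164 / 0.3274 / 0.4938, inclusive lower bounds),
#' the unit optical-density direction vectors of the two stains
#' (hematoxylin counterstain and DAB chromogen; defaults are the standard
#' H-DAB reference directions), and the total-OD floor above which a pixel
#' counts as tissue.
#'
#' @param od_thresholds Named numeric vector `c(weak=, moderate=, strong=)`,
#'   strictly increasing and positive.
#' @param stain_vectors 3 x 2 matrix whose columns are the hematoxylin and
#'   DAB OD directions (any positive scale; normalized internally).
#' @param tissue_od_floor Total (summed-channel) OD at or above which a pixel
#'   is tissue (default 0.05).
#' @return An object of class `stain_classifier`.
#' @export
stain_classifier <- function(od_thresholds = c(weak = 0.2164,
                                               moderate = 0.3274,
                                               strong = 0.4938),
                             stain_vectors = cbind(
                               hematoxylin = c(0.650, 0.704, 0.286),
                               dab = c(0.269, 0.568, 0.778)),
                             tissue_od_floor = 0.05) {
  stopifnot(length(od_thresholds) == 3,
            all(names(od_thresholds) == c("weak", "moderate", "strong")),
            od_thresholds[1] > 0, all(diff(od_thresholds) > 0),
            is.matrix(stain_vectors), nrow(stain_vectors) == 3,
            ncol(stain_vectors) == 2, tissue_od_floor > 0)
  V <- apply(stain_vectors, 2, function(v) v / sqrt(sum(v^2)))
  if (abs(sum(V[, 1] * V[, 2])) > 0.995)
    stop("stain vectors are near-collinear; deconvolution is ill-conditioned")
  structure(list(od_thresholds = od_thresholds, stain_vectors = V,
                 tissue_od_floor = tissue_od_floor),
            class = "stain_classifier")
}

#' Convert an RGB image to optical densities
#'
#' Beer-Lambert transform per channel: `OD = -log10(I / I0)`. Pure white maps
#' to zero OD; zero-intensity pixels are clamped to `od_cap` (their count is
#' attached as attribute `n_clamped`).
#'
#' @param image Numeric array `[rows, cols, 3]` of intensities in `(0, I0]`
#'   (zeros tolerated via the cap).
#' @param I0 White reference intensity (default 255).
#' @param od_cap OD assigned to zero-intensity pixels (default 3).
#' @return Array `[rows, cols, 3]` of non-negative optical densities.
#' @export
rgb_to_od <- function(image, I0 = 255, od_cap = 3) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3, I0 > 0)
  if (any(image < 0) || any(image > I0))
    stop("intensities must lie in [0, I0]")
  zero <- image <= 0
  od <- array(od_cap, dim = dim(image))
  od[!zero] <- -log10(image[!zero] / I0)
  od[od < 0] <- 0
  attr(od, "n_clamped") <- sum(zero)
  od
}

#' Color deconvolution into hematoxylin and DAB concentrations
#'
#' Least-squares projection of each pixel's OD vector onto the two unit
#' stain directions. Negative concentrations (noise, unmodelled color) are
#' clipped to zero; the clip count is attached as attribute `n_clipped`.
#'
#' @param od OD array from [rgb_to_od()].
#' @param classifier A [stain_classifier()].
#' @return List with matrices `hematoxylin` and `dab` of per-pixel OD
#'   concentrations along each stain direction.
#' @export
deconvolve_stains <- function(od, classifier) {
  stopifnot(inherits(classifier, "stain_classifier"),
            length(dim(od)) == 3, dim(od)[3] == 3)
  V <- classifier$stain_vectors
  P <- solve(crossprod(V), t(V))              # 2 x 3 pseudo-inverse
  dm <- dim(od)
  flat <- matrix(od, ncol = 3)
  conc <- flat %*% t(P)
  n_clipped <- sum(conc < 0)
  conc[conc < 0] <- 0
  out <- list(hematoxylin = matrix(conc[, 1], dm[1], dm[2]),
              dab = matrix(conc[, 2], dm[1], dm[2]))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Tissue mask from total optical density
#'
#' A pixel is tissue if the sum of its channel ODs reaches the classifier's
#' `tissue_od_floor`.
#'
#' @inheritParams deconvolve_stains
#' @return Logical matrix.
#' @export
tissue_mask_from_od <- function(od, classifier) {
  stopifnot(inherits(classifier, "stain_classifier"))
  apply(od, c(1, 2), sum) >= classifier$tissue_od_floor
}

#' Classify pixels into DAB staining intensity classes
#'
#' Within the tissue mask: DAB OD below the weak threshold is negative (0);
#' `[weak, moderate)` is weak (1); `[moderate, strong)` is moderate (2); at
#' or above the strong threshold is strong (3). Lower bounds are inclusive.
#' Pixels outside the mask are `NA` (not tissue).
#'
#' @param dab_od Matrix of per-pixel DAB OD (from [deconvolve_stains()]).
#' @param classifier A [stain_classifier()].
#' @param tissue Logical matrix; defaults to all-tissue.
#' @return Integer matrix with values 0-3 and `NA` outside tissue.
#' @export
classify_pixels <- function(dab_od, classifier,
                            tissue = NULL) {
  stopifnot(inherits(classifier, "stain_classifier"), is.matrix(dab_od))
  th <- classifier$od_thresholds
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(dab_od), ncol(dab_od))
  stopifnot(identical(dim(tissue), dim(dab_od)))
  cls <- matrix(0L, nrow(dab_od), ncol(dab_od))
  cls[dab_od >= th["weak"]] <- 1L
  cls[dab_od >= th["moderate"]] <- 2L
  cls[dab_od >= th["strong"]] <- 3L
  cls[!tissue] <- NA_integer_
  cls
}

#' Percent positive tissue and class area fractions
#'
#' The areas of weak, moderate and strong staining are summed and divided by
#' the total tissue area to obtain the percentage of positive tissue.
#'
#' @param class_map Integer matrix from [classify_pixels()] (`NA` = not
#'   tissue).
#' @return List of class `ihc_quant_result`: `percent_positive` (0-100),
#'   `area_fractions` (negative/weak/moderate/strong, summing to 1) and
#'   `tissue_area` in pixels.
#' @export
percent_positive <- function(class_map) {
  tis <- !is.na(class_map)
  area <- sum(tis)
  if (area == 0) stop("tissue mask is empty")
  counts <- vapply(0:3, function(k) sum(class_map[tis] == k), numeric(1))
  names(counts) <- c("negative", "weak", "moderate", "strong")
  structure(list(percent_positive = 100 * sum(counts[2:4]) / area,
                 area_fractions = counts / area,
                 tissue_area = area),
            class = "ihc_quant_result")
}

#' Count cell nuclei by connected components
#'
#' Simplified stand-in for a proprietary nucleus counter: 8-connected
#' components of pixels whose hematoxylin OD reaches `min_od`, discarding
#' components smaller than `min_area` pixels.
#'
#' @param hema_od Matrix of hematoxylin OD (from [deconvolve_stains()]).
#' @param min_od OD threshold for nucleus pixels (default 0.3).
#' @param min_area Minimum component size in pixels (default 5).
#' @return Integer count.
#' @export
count_cells <- function(hema_od, min_od = 0.3, min_area = 5) {
  stopifnot(is.matrix(hema_od), min_od > 0, min_area >= 1)
  fg <- which(hema_od >= min_od)
  if (length(fg) == 0) return(0L)
  nr <- nrow(hema_od)
  nc <- ncol(hema_od)
  idmap <- integer(nr * nc)
  idmap[fg] <- seq_along(fg)
  row <- (fg - 1) %% nr + 1
  col <- (fg - 1) %/% nr + 1
  edges <- NULL
  for (d in list(c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- idmap[(c2[ok] - 1) * nr + r2[ok]]
    hit <- nb > 0
    if (any(hit))
      edges <- rbind(edges, cbind(idmap[fg[ok]][hit], nb[hit]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(0), ncol = 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sum(comp$csize >= min_area)
}

#' Quantify an H-DAB immunohistochemistry image
#'
#' Full quantification chain: optical densities, color deconvolution,
#' tissue masking, intensity classification, percent positive tissue, cell
#' count and cell density.
#'
#' @param image RGB array `[rows, cols, 3]` with intensities in `[0, I0]`.
#' @param classifier A [stain_classifier()].
#' @param I0 White reference (default 255).
#' @param min_nucleus_od,min_nucleus_area Passed to [count_cells()].
#' @return An `ihc_quant_result` with additional fields `cell_count` and
#'   `cell_density` (cells per tissue pixel).
#' @export
quantify_ihc <- function(image, classifier = stain_classifier(), I0 = 255,
                         min_nucleus_od = 0.3, min_nucleus_area = 5) {
  od <- rgb_to_od(image, I0 = I0)
  dec <- deconvolve_stains(od, classifier)
  tis <- tissue_mask_from_od(od, classifier)
  cls <- classify_pixels(dec$dab, classifier, tis)
  res <- percent_positive(cls)
  res$cell_count <- count_cells(dec$hematoxylin, min_nucleus_od,
                                min_nucleus_area)
  res$cell_density <- res$cell_count / res$tissue_area
  res$class_map <- cls
  res
}
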