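#' Region-of-interest definitions
#'
#' Two ROI kinds are supported, both specified in physical millimetres on
#' the reconstructed grid:
#' * `roi_polygon()`: a manually drawn planar polygon per slice (tumor or
#'   normal-kidney outlines);
#' * `roi_cylinder()`: a cylinder of given diameter and height centred on a
#'   biopsy location (default 30 mm x 30 mm).
#'
#' Coordinate convention: 0-based voxel indices, voxel centres at
#' `(index + 0.5) * voxel_size` mm in-plane, slice centres at
#' `slice_index * slice_pitch` mm (see [voxel_size_mm()], [slice_pitch_mm()]).
#'
#' @param vertices List indexed by slice number (1-based): each element a
#'   numeric matrix with columns `x`, `y` (mm) and at least 3 rows, or NULL
#'   for slices the polygon does not cover.
#' @param label ROI label (e.g. `"tumor"`, `"normal_kidney"`, a biopsy id).
#' @return An object of class `roi_definition`.
#' @export
roi_polygon <- function(vertices, label = "roi") {
  stopifnot(is.list(vertices))
  for (v in vertices) {
    if (is.null(v)) next
    if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 3)
      stop("each slice polygon needs a matrix of >= 3 (x, y) vertices")
    if (.polygon_self_intersects(v))
      stop("polygon is self-intersecting")
  }
  structure(list(kind = "polygon", vertices = vertices, label = label),
            class = "roi_definition")
}

#' @rdname roi_polygon
#' @param center Numeric length-3 vector `(x, y, z)` in mm: in-plane
#'   position and slice-axis position of the cylinder centre.
#' @param diameter,height Cylinder dimensions in mm (default 30 mm each).
#' @export
roi_cylinder <- function(center, diameter = 30, height = 30, label = "biopsy") {
  stopifnot(length(center) == 3, all(is.finite(center)),
            diameter > 0, height > 0)
  structure(list(kind = "cylinder", center = as.numeric(center),
                 diameter = diameter, height = height, label = label),
            class = "roi_definition")
}

## segment-intersection test for polygon validity (proper crossings only)
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next   # adjacent through closure
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

## even-odd point-in-polygon with inclusive boundary, vectorized over points
.points_in_polygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    ## boundary: point within eps of segment i-j
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2)) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    onedge <- onedge | d2 <= eps^2
    ## even-odd ray crossing
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

#' Rasterize an ROI onto the reconstructed grid
#'
#' Voxel-centre inclusion: a voxel belongs to the mask iff its centre lies
#' inside the polygon (even-odd rule) or, for cylinders, iff its in-plane
#' centre distance from the axis is at most the radius and its slice centre
#' is within half the height of the cylinder centre. Boundary ties (centre
#' exactly on the polygon edge or at distance exactly equal to the radius)
#' are included.
#'
#' @param roi An [roi_polygon()] or [roi_cylinder()].
#' @param geometry An [acq_geometry()] providing the grid.
#' @return Logical array `[slice, row, col]` (rows index y, columns x).
#' @export
rasterize_roi <- function(roi, geometry) {
  stopifnot(inherits(roi, "roi_definition"), inherits(geometry, "acq_geometry"))
  n <- geometry$recon_matrix
  ns <- geometry$n_slices
  vox <- voxel_size_mm(geometry)
  pitch <- slice_pitch_mm(geometry)
  fovmm <- geometry$fov * 10
  cx <- (seq_len(n) - 0.5) * vox     # voxel-centre x per column
  cy <- (seq_len(n) - 0.5) * vox     # voxel-centre y per row
  zc <- (seq_len(ns) - 1) * pitch    # slice centres
  mask <- array(FALSE, dim = c(ns, n, n))
  if (roi$kind == "polygon") {
    for (s in seq_along(roi$vertices)) {
      v <- roi$vertices[[s]]
      if (is.null(v)) next
      if (s > ns) stop("polygon slice index exceeds the number of slices")
      if (any(v[, 1] < 0 | v[, 1] > fovmm | v[, 2] < 0 | v[, 2] > fovmm))
        stop("polygon extends outside the field of view")
      ## points in column-major (row fastest) order: row = y, col = x
      inc <- .points_in_polygon(rep(cx, each = n), rep(cy, n), v)
      mask[s, , ] <- matrix(inc, nrow = n)   # rows = cy index, cols = cx index
    }
  } else {
    ctr <- roi$center
    rad <- roi$diameter / 2
    if (ctr[1] - rad < 0 || ctr[1] + rad > fovmm ||
        ctr[2] - rad < 0 || ctr[2] + rad > fovmm)
      stop("cylinder extends outside the field of view")
    d2 <- outer((cy - ctr[2])^2, (cx - ctr[1])^2, `+`)
    inplane <- d2 <= rad^2
    for (s in seq_len(ns)) {
      if (abs(zc[s] - ctr[3]) <= roi$height / 2) mask[s, , ] <- inplane
    }
  }
  if (!any(mask)) warning("ROI rasterized to an empty mask")
  mask
}

#' Summarize a kPL map and metabolite maps over an ROI
#'
#' @param mask Logical array `[slice, row, col]` (non-empty).
#' @param kpl_map A `kpl_map` from [fit_kpl_map()].
#' @param maps A `metabolite_maps` from [sum_time_maps()].
#' @param noise A single [noise_estimate()] applied to every map, a list
#'   with per-map estimates as returned by [estimate_noise_maps()], or
#'   `NULL` (noiseless data: SNR columns are `NA`).
#' @param label,patient_id Identifiers carried into the summary.
#' @return A one-row data frame (class `roi_summary`): voxel counts, median
#'   and range of kPL over fitted voxels, lactate-to-pyruvate ratio, and the
#'   per-metabolite SNRs of the ROI.
#' @export
summarize_roi <- function(mask, kpl_map, maps, noise,
                          label = "roi", patient_id = NA_character_) {
  stopifnot(is.logical(mask), inherits(kpl_map, "kpl_map"),
            inherits(maps, "metabolite_maps"))
  if (inherits(noise, "noise_estimate"))
    noise <- list(pyruvate = noise, lactate = noise, total_carbon = noise)
  if (!is.null(noise))
    stopifnot(all(c("pyruvate", "lactate", "total_carbon") %in% names(noise)))
  if (!any(mask)) stop("ROI mask is empty")
  kv <- kpl_map$k_pl[mask]
  kv <- kv[is.finite(kv)]
  if (length(kv) == 0) {
    warning(sprintf("ROI '%s': no fitted voxels; kPL summary is missing", label))
    kmed <- kmin <- kmax <- NA_real_
  } else {
    kmed <- stats::median(kv); kmin <- min(kv); kmax <- max(kv)
  }
  out <- data.frame(
    patient_id = patient_id, label = label,
    n_voxels = sum(mask), n_fitted = length(kv),
    kpl_median = kmed, kpl_min = kmin, kpl_max = kmax,
    lac_pyr = lac_pyr_ratio(maps, mask),
    snr_pyruvate = if (is.null(noise)) NA_real_ else
      compute_snr(maps$pyruvate[mask], noise$pyruvate),
    snr_lactate = if (is.null(noise)) NA_real_ else
      compute_snr(maps$lactate[mask], noise$lactate),
    snr_total_carbon = if (is.null(noise)) NA_real_ else
      compute_snr(maps$total_carbon[mask], noise$total_carbon),
    stringsAsFactors = FALSE)
  class(out) <- c("roi_summary", class(out))
  out
}

#' Patient-level table from biopsy-level measurements
#'
#' Applies the histological inclusion rule (viable tumor fraction of at
#' least 0.75; samples strictly below are excluded) and aggregates the
#' surviving biopsies of each patient by the median, compensating for
#' spatially heterogeneous marker expression.
#'
#' @param biopsy_table Data frame with columns `patient_id`,
#'   `viable_fraction`, and any of `kpl`, `mct1_pct`, `mct4_pct`,
#'   `cell_density` to aggregate.
#' @param viable_min Inclusion threshold on the viable fraction
#'   (default 0.75, inclusive).
#' @return Data frame with one row per patient: medians of the measurement
#'   columns over included biopsies, counts of included and excluded
#'   biopsies. Patients with no surviving biopsies get `NA` medians.
#' @export
patient_level_table <- function(biopsy_table, viable_min = 0.75) {
  stopifnot(is.data.frame(biopsy_table),
            all(c("patient_id", "viable_fraction") %in% names(biopsy_table)))
  meas <- intersect(c("kpl", "lac_pyr", "mct1_pct", "mct4_pct", "cell_density",
                      "grade"),
                    names(biopsy_table))
  keep <- biopsy_table$viable_fraction >= viable_min
  pts <- unique(biopsy_table$patient_id)
  rows <- lapply(pts, function(p) {
    sel <- biopsy_table$patient_id == p
    inc <- sel & keep
    r <- data.frame(patient_id = p,
                    n_biopsies = sum(sel),
                    n_included = sum(inc),
                    n_excluded = sum(sel) - sum(inc))
    for (m in meas) {
      r[[paste0(m, "_median")]] <-
        if (any(inc)) stats::median(biopsy_table[[m]][inc]) else NA_real_
    }
    if (!any(inc))
      warning(sprintf("patient %s: no biopsies with viable fraction >= %g",
                      p, viable_min))
    r
  })
  do.call(rbind, rows)
}
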