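#' @title Kinetic fit results
#' @description Container returned by the kPL estimators: the estimated
#'   exchange rate `k_pl_hat` (1/s), the estimated (or assumed) apparent decay
#'   rate of lactate `inv_t1_eff_hat` (1/s), the least-squares residual norm,
#'   the number of frames used, the estimator tag and any diagnostic flags.
#'   Negative estimates are reported as-is and flagged, never clipped.
#' @param k_pl_hat,inv_t1_eff_hat,residual_norm,n_frames_used,method,flags
#'   Fields; see description.
#' @return An object of class `kpl_fit`.
#' @keywords internal
kpl_fit_result <- function(k_pl_hat, inv_t1_eff_hat, residual_norm,
                           n_frames_used, method, flags = character()) {
  if (is.finite(k_pl_hat) && k_pl_hat < 0) flags <- union(flags, "negative_kpl")
  if (is.finite(inv_t1_eff_hat) && inv_t1_eff_hat < 0)
    flags <- union(flags, "negative_decay")
  structure(list(k_pl_hat = k_pl_hat, inv_t1_eff_hat = inv_t1_eff_hat,
                 residual_norm = residual_norm, n_frames_used = n_frames_used,
                 method = method, flags = flags),
            class = "kpl_fit")
}

#' @export
print.kpl_fit <- function(x, ...) {
  cat(sprintf("kPL fit [%s]: k_pl = %.5g /s, 1/t1_eff = %.5g /s (t1_eff = %.3g s)\n",
              x$method, x$k_pl_hat, x$inv_t1_eff_hat,
              ifelse(x$inv_t1_eff_hat > 0, 1 / x$inv_t1_eff_hat, NA)))
  cat(sprintf("  residual norm %.4g over %d frames%s\n", x$residual_norm,
              x$n_frames_used,
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

## First-order-hold gains of the lactate equation over one frame interval:
## exact integral of exp(-r(dt - s)) against a linearly interpolated input.
## L_{k+1} = a L_k + k_pl (g0 P_k + g1 P_{k+1}), a = exp(-r dt).
.foh_gains <- function(r, dt) {
  if (r < 1e-12) return(list(a = 1, g0 = dt / 2, g1 = dt / 2))
  a <- exp(-r * dt)
  g1 <- 1 / r - (1 - a) / (r^2 * dt)
  g0 <- (1 - a) / r - g1
  list(a = a, g0 = g0, g1 = g1)
}

## DFT design pieces shared by the joint and fixed-decay solvers. The
## difference equations of the exchange model are posed per frequency bin:
## after final-value detrending and zero-padding, a one-sample delay is the
## exact multiplication by zbar = exp(-2*pi*i*m/N), and the two record
## boundary rows plus the detrending constant are absorbed by three exact
## nuisance regressors (DFTs of an all-ones column, of the record-row
## indicator, and of the row-n indicator).
.freq_system <- function(pyr, lac, pad) {
  n <- length(pyr)
  pyr <- pyr - pyr[n]
  lac <- lac - lac[n]
  N <- pad * n
  padfft <- function(x) stats::fft(c(x, rep(0, N - n)))
  Ph <- padfft(pyr)
  Lh <- padfft(lac)
  m <- 0:(N - 1)
  zbar <- exp(-2i * pi * m / N)
  Ind <- padfft(c(0, rep(1, n - 1)))      # dynamic-equation rows 1..n-1
  ones <- rep(1 + 0i, N)
  ## nuisance coefficients are complex (the boundary values and detrending
  ## constants carry the data's phase); each complex coefficient is two real
  ## ones, hence the 1i-duplicated columns
  nuis <- cbind(Ind, 1i * Ind, ones, 1i * ones, zbar^n, 1i * zbar^n)
  list(n = n, N = N, Ph = Ph, Lh = Lh, zbar = zbar, nuis = nuis)
}

.stack_solve <- function(A, b) {
  fit <- stats::lm.fit(rbind(Re(A), Im(A)), c(Re(b), Im(b)))
  coef <- unname(fit$coefficients)
  coef[is.na(coef)] <- 0
  list(coef = coef, rss = sum(fit$residuals^2))
}

#' Frequency-domain linear least-squares kPL fit
#'
#' Estimates the apparent pyruvate-to-lactate exchange rate constant from
#' sampled metabolite time courses under the two-site exchange model
#' `dL/dt = k_pl * P - L / t1_eff`. Both courses are detrended by their final
#' value, zero-padded fourfold and transformed by the discrete Fourier
#' transform; the model is imposed per frequency bin through the exact
#' first-order-hold discretization symbol (a one-frame delay is the exact
#' per-bin factor `exp(-i omega frame_spacing)` for the padded record), and
#' the resulting overdetermined complex linear system is solved by ordinary
#' least squares over stacked real and imaginary parts. Exact boundary
#' nuisance regressors account for the record edges and the detrending
#' constant.
#'
#' With `t1_eff = NULL` (default) the lactate decay rate is estimated jointly
#' with `k_pl`; this is accurate on noiseless or high-SNR (e.g. ROI-averaged)
#' courses but unstable when the per-frame lactate SNR is low. Supplying a
#' fixed `t1_eff` (optionally pre-adjusted for RF depletion via
#' [effective_decay_rate()]) reduces the problem to a single linear
#' coefficient and is the configuration used for voxel-wise mapping of noisy
#' data.
#'
#' Courses may be real magnitudes (noiseless or high-SNR data) or complex
#' (post coil-combination dynamics, where the noise is zero-mean and the
#' magnitude noise floor is avoided).
#'
#' @param pyr_course,lac_course Numeric or complex vectors of equal length
#'   (>= 4): pyruvate and lactate signal per frame.
#' @param frame_spacing Frame interval in seconds.
#' @param t1_eff `NULL` to fit the lactate decay rate jointly, or a fixed
#'   apparent decay time in seconds whose reciprocal is used as the decay
#'   rate of the sampled data.
#' @param pad Zero-padding factor for the DFT (default 4).
#' @return A `kpl_fit` object with `method = "frequency_domain"`. Negative
#'   estimates are returned as-is and flagged.
#' @seealso [fit_kpl_time_domain_oracle()], [fit_kpl_map()]
#' @examples
#' g <- acq_geometry()
#' s <- simulate_two_site_exchange(kinetic_params(0.0065, 30),
#'                                 gamma_variate_bolus(), g,
#'                                 rf_depletion = FALSE)
#' fit_kpl_frequency_domain(s$pyruvate, s$lactate, g$frame_spacing)
#' @export
fit_kpl_frequency_domain <- function(pyr_course, lac_course, frame_spacing,
                                     t1_eff = NULL, pad = 4) {
  n <- length(pyr_course)
  if (length(lac_course) != n)
    stop("pyruvate and lactate courses must have the same length")
  if (n < 4) stop("need at least 4 frames")
  stopifnot(frame_spacing > 0, pad >= 1)
  if (all(Mod(pyr_course) == 0))
    stop("pyruvate course is identically zero: k_pl is unidentifiable")
  dt <- frame_spacing
  flags <- character()

  if (all(Mod(lac_course) == 0)) {
    return(kpl_fit_result(0, if (is.null(t1_eff)) 0 else 1 / t1_eff, 0, n,
                          "frequency_domain", flags = "zero_lactate"))
  }

  if (is.null(t1_eff)) {
    ## joint solve: L = a * delay(L) + c0 * delay(P) + c1 * P + nuisances
    sys <- .freq_system(pyr_course, lac_course, pad)
    A <- cbind(sys$zbar * sys$Lh, sys$zbar * sys$Ph, sys$Ph, sys$nuis)
    sol <- .stack_solve(A, sys$Lh)
    a <- sol$coef[1]
    csum <- sol$coef[2] + sol$coef[3]
    if (a <= 0) {
      return(kpl_fit_result(NA_real_, NA_real_, sqrt(sol$rss), n,
                            "frequency_domain", flags = "degenerate_decay"))
    }
    r <- -log(a) / dt
    kpl <- if (abs(1 - a) < 1e-12) csum / dt else csum * r / (1 - a)
    kpl_fit_result(kpl, r, sqrt(sol$rss), n, "frequency_domain", flags)
  } else {
    ## fixed decay rate: the model is linear in k_pl alone. The regressor is
    ## the first-order-hold convolution of the measured pyruvate course with
    ## the decay kernel (built by the exact one-frame recursion), plus an
    ## initial-condition decay column and an intercept. The DFT of these
    ## equations is unitary, so the per-bin least-squares solution equals the
    ## stacked solve performed here.
    stopifnot(is.finite(t1_eff), t1_eff > 0)
    r <- 1 / t1_eff
    gn <- .foh_gains(r, dt)
    B <- rep(0 + 0i, n)
    for (k in 2:n)
      B[k] <- gn$a * B[k - 1] + gn$g0 * pyr_course[k - 1] +
        gn$g1 * pyr_course[k]
    I0 <- exp(-r * (seq_len(n) - 1) * dt)
    ones <- rep(1 + 0i, n)
    A <- cbind(B, I0, 1i * I0, ones, 1i * ones)
    sol <- .stack_solve(A, as.complex(lac_course))
    kpl_fit_result(sol$coef[1], r, sqrt(sol$rss), n, "frequency_domain",
                   flags = "fixed_t1_eff")
  }
}

#' Time-domain nonlinear least-squares oracle for kPL
#'
#' Independent verification fit for [fit_kpl_frequency_domain()]. Models the
#' lactate course as the convolution of the measured pyruvate course with an
#' exponential kernel,
#' \deqn{L(t) = L(t_1) e^{-(t-t_1)/T_{1,\mathrm{eff}}} + k_{PL}
#'   \int_{t_1}^{t} P(\tau) e^{-(t-\tau)/T_{1,\mathrm{eff}}} d\tau,}
#' with pyruvate linearly interpolated between frames and the integral
#' evaluated by trapezoidal quadrature on a fine grid. The decay term for the
#' lactate already present at the first frame (the record starts well after
#' the injection) uses the observed initial value. The decay rate is profiled
#' out by bounded one-dimensional optimization from four starting points
#' (bounds: `k_pl` in [0, 0.1] 1/s, decay rate in [1/120, 1] 1/s), with the
#' amplitude solved in closed form at each candidate rate.
#'
#' @inheritParams fit_kpl_frequency_domain
#' @param fine_dt Quadrature step in seconds.
#' @return A `kpl_fit` object with `method = "time_domain_oracle"`.
#' @export
fit_kpl_time_domain_oracle <- function(pyr_course, lac_course, frame_spacing,
                                       fine_dt = 0.02) {
  n <- length(pyr_course)
  if (length(lac_course) != n)
    stop("pyruvate and lactate courses must have the same length")
  if (n < 4) stop("need at least 4 frames")
  stopifnot(is.numeric(pyr_course), is.numeric(lac_course), frame_spacing > 0)
  if (all(pyr_course == 0))
    stop("pyruvate course is identically zero: k_pl is unidentifiable")
  if (all(lac_course == 0))
    return(kpl_fit_result(0, 0, 0, n, "time_domain_oracle",
                          flags = "zero_lactate"))
  t <- (seq_len(n) - 1) * frame_spacing
  tf <- seq(0, t[n], by = fine_dt)
  Pf <- stats::approx(t, pyr_course, tf)$y
  idx <- vapply(t, function(ti) which.min(abs(tf - ti)), integer(1))

  eval_at <- function(r) {
    w <- Pf * exp(tf * r)
    C <- c(0, cumsum((w[-1] + w[-length(w)]) / 2)) * fine_dt
    conv <- exp(-t * r) * C[idx]
    y <- lac_course - lac_course[1] * exp(-t * r)
    k <- sum(y * conv) / sum(conv^2)
    k <- min(max(k, 0), 0.1)
    list(k = k, rss = sum((y - k * conv)^2))
  }
  best <- NULL
  for (r0 in c(1 / 120, 1 / 60, 1 / 20, 1 / 5)) {
    o <- tryCatch(
      stats::optim(r0, function(r) eval_at(r)$rss, method = "L-BFGS-B",
                   lower = 1 / 120, upper = 1),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("time-domain optimizer failed from every starting point: ",
         "objective non-finite over the decay-rate bounds")
  ## bracketed polish around the best start's solution
  pol <- stats::optimize(function(r) eval_at(r)$rss,
                         lower = max(1 / 120, best$par / 2),
                         upper = min(1, best$par * 2), tol = 1e-10)
  r <- if (pol$objective < best$value) pol$minimum else best$par
  ev <- eval_at(r)
  kpl_fit_result(ev$k, r, sqrt(ev$rss), n, "time_domain_oracle")
}

#' Voxel-wise kPL map from a combined dynamic image
#'
#' Applies the frequency-domain estimator with a fixed apparent lactate decay
#' rate to every voxel selected by `mask`, using the complex post-combination
#' time courses. The assumed tissue relaxation time is adjusted for the known
#' per-frame RF depletion of the acquisition (see [effective_decay_rate()]).
#' Unmasked voxels carry `NA`; per-voxel failures are converted to `NA` with
#' a count reported in the result.
#'
#' @param combined A combined dynamic image as returned by
#'   [apply_coil_weights()].
#' @param mask Logical array (slice, row, col), typically from
#'   [build_fit_mask()].
#' @param t1_eff Assumed tissue-level lactate relaxation time in seconds.
#' @param rf_correction Add the geometry's RF depletion rate to the assumed
#'   decay rate (default `TRUE`).
#' @return A list of class `kpl_map` with arrays `k_pl` and `residual_norm`
#'   (NA outside the mask), the scalar `inv_t1_eff` used, the mask, and
#'   `n_failed`.
#' @export
fit_kpl_map <- function(combined, mask, t1_eff = 30, rf_correction = TRUE) {
  stopifnot(inherits(combined, "combined_dynamic_image"), is.logical(mask))
  dm <- dim(combined$data)   # metabolite, frame, slice, row, col
  if (!identical(dim(mask), dm[3:5]))
    stop("mask dimensions do not match the image grid")
  geom <- combined$geometry
  r <- effective_decay_rate(t1_eff, if (rf_correction) geom else NULL)
  kmap <- array(NA_real_, dim = dm[3:5])
  resmap <- array(NA_real_, dim = dm[3:5])
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0) {
    warning("empty mask: returning all-missing kPL map")
    return(structure(list(k_pl = kmap, residual_norm = resmap,
                          inv_t1_eff = r, mask = mask, n_failed = 0L),
                     class = "kpl_map"))
  }
  n_failed <- 0L
  for (i in seq_len(nrow(vox))) {
    s <- vox[i, 1]; rr <- vox[i, 2]; cc <- vox[i, 3]
    pyr <- combined$data[1, , s, rr, cc]
    lac <- combined$data[2, , s, rr, cc]
    fit <- tryCatch(
      fit_kpl_frequency_domain(pyr, lac, geom$frame_spacing,
                               t1_eff = 1 / r),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$k_pl_hat)) {
      n_failed <- n_failed + 1L
    } else {
      kmap[s, rr, cc] <- fit$k_pl_hat
      resmap[s, rr, cc] <- fit$residual_norm
    }
  }
  if (n_failed > 0)
    message(sprintf("fit_kpl_map: %d voxel fit(s) failed and are missing",
                    n_failed))
  structure(list(k_pl = kmap, residual_norm = resmap, inv_t1_eff = r,
                 mask = mask, n_failed = n_failed),
            class = "kpl_map")
}

#' Lactate-to-pyruvate ratio over a region of interest
#'
#' Model-free metabolic index: the sum of the time-summed lactate map over
#' the ROI divided by the sum of the time-summed pyruvate map over the ROI.
#'
#' @param maps A `metabolite_maps` object from [sum_time_maps()].
#' @param mask Logical array (slice, row, col) selecting the ROI.
#' @return Scalar ratio.
#' @export
lac_pyr_ratio <- function(maps, mask) {
  stopifnot(inherits(maps, "metabolite_maps"), is.logical(mask))
  if (!any(mask)) stop("ROI mask is empty")
  psum <- sum(maps$pyruvate[mask])
  if (psum <= 0) stop("pyruvate signal in ROI is zero: ratio undefined")
  sum(maps$lactate[mask]) / psum
}
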