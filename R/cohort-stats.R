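#' Statistical test result container
#'
#' @param statistic Name of the statistic (`spearman_rho`, `pearson_r`,
#'   `wilcoxon_rank_sum`, `wilcoxon_signed_rank`, `blocked_permutation_F`).
#' @param estimate Point estimate (correlation or test statistic).
#' @param p_value Two-sided p-value in [0, 1].
#' @param n Sample size.
#' @param notes Method notes (tie handling, exact vs asymptotic branch,
#'   permutation count and seed).
#' @return An object of class `stat_result`.
#' @keywords internal
stat_result <- function(statistic, estimate, p_value, n, notes = "") {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, estimate = estimate,
                 p_value = p_value, n = as.integer(n), notes = notes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (n = %d)%s\n", x$statistic, x$estimate,
              x$p_value, x$n,
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

## all permutations of 1..n (n <= 8 in practice)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

.pearson_r <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Spearman rank correlation
#'
#' Rank-transforms both variables with mid-ranks for ties, then computes the
#' product-moment correlation of the ranks. The two-sided p-value is exact
#' (full enumeration of all permutations, counting `|rho| >= |rho_obs|`) for
#' n at most 8, and uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return A `stat_result` with `statistic = "spearman_rho"`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant input: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- .pearson_r(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) .pearson_r(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    notes <- sprintf("exact permutation (%d)", nrow(perms))
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    notes <- "t approximation"
  }
  stat_result("spearman_rho", rho, p, n, paste0("mid-ranks; ", notes))
}

#' Pearson correlation
#'
#' Product-moment correlation with the standard two-sided t-based p-value on
#' n - 2 degrees of freedom.
#'
#' @inheritParams spearman_cor
#' @return A `stat_result` with `statistic = "pearson_r"`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- .pearson_r(x, y)
  tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
  stat_result("pearson_r", r, p, n, "t-based p")
}

## two-sided doubling convention on a discrete null distribution
.doubled_p <- function(null_vals, obs) {
  lo <- mean(null_vals <= obs + 1e-12)
  hi <- mean(null_vals >= obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon rank-sum test (unpaired)
#'
#' Mid-ranks for ties. The null distribution of the rank sum of the first
#' group is enumerated exactly over all group assignments when the combined
#' sample size is at most 10; otherwise the normal approximation with tie
#' correction and continuity correction is used. Two-sided p-values use the
#' doubling convention.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return A `stat_result` with `statistic = "wilcoxon_rank_sum"` whose
#'   estimate is the rank sum of `a`.
#' @export
rank_sum_test <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  stopifnot(na >= 2, nb >= 2)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  if (n <= 10) {
    combs <- utils::combn(n, na)
    null_w <- colSums(matrix(r[combs], nrow = na))
    p <- .doubled_p(null_w, W)
    notes <- sprintf("exact enumeration (%d assignments)", ncol(combs))
  } else {
    ties <- table(r)
    EW <- na * (n + 1) / 2
    VW <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(W - EW) - 0.5) / sqrt(VW)
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
    notes <- "normal approximation, tie-corrected"
  }
  stat_result("wilcoxon_rank_sum", W, p, n, paste0("mid-ranks; ", notes))
}

#' Wilcoxon signed-rank test (paired differences)
#'
#' Zero differences are dropped (their count is noted); the remaining
#' absolute differences are mid-ranked and the statistic is the rank sum of
#' the positive differences. Exact sign enumeration for at most 10 nonzero
#' differences, tie-corrected normal approximation otherwise; two-sided
#' doubling convention.
#'
#' @param diffs Numeric vector of paired differences with at least one
#'   nonzero value.
#' @return A `stat_result` with `statistic = "wilcoxon_signed_rank"`.
#' @export
signed_rank_test <- function(diffs) {
  nz <- diffs[diffs != 0]
  n0 <- length(diffs) - length(nz)
  m <- length(nz)
  if (m == 0) stop("all differences are zero: test degenerate")
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  if (m <= 10) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    null_v <- as.numeric(signs %*% r)
    p <- .doubled_p(null_v, V)
    notes <- sprintf("exact enumeration (%d sign patterns)", nrow(signs))
  } else {
    EV <- m * (m + 1) / 4
    VV <- sum(r^2) / 4
    z <- (abs(V - EV) - 0.5) / sqrt(VV)
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
    notes <- "normal approximation, tie-corrected"
  }
  stat_result("wilcoxon_signed_rank", V, p, m,
              sprintf("mid-ranks; %s; %d zero diff(s) dropped", notes, n0))
}

#' Patient-blocked permutation test of the biopsy-level grade effect
#'
#' Tests whether biopsy-level kPL depends on biopsy grade after accounting
#' for the strong patient dependence of kPL. The observed statistic is the
#' partial F for (numeric-ordinal) grade in the least-squares model
#' `kpl ~ patient + grade`; the null distribution is generated by permuting
#' the grade labels within each patient block, which preserves the patient
#' structure while breaking any within-patient grade-kPL link. The p-value
#' is `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param biopsy_table Data frame with columns `patient_id`, `grade`, `kpl`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed (mandatory).
#' @return A `stat_result` with `statistic = "blocked_permutation_F"`.
#' @export
blocked_grade_test <- function(biopsy_table, n_perm = 9999, seed) {
  stopifnot(is.data.frame(biopsy_table),
            all(c("patient_id", "grade", "kpl") %in% names(biopsy_table)),
            n_perm >= 1)
  if (missing(seed)) stop("seed is mandatory for the permutation test")
  ## block order follows first appearance so the permutation stream, and
  ## hence the p-value, is invariant to relabeling patients
  pid0 <- as.character(biopsy_table$patient_id)
  pid <- factor(pid0, levels = unique(pid0))
  g <- as.numeric(biopsy_table$grade)
  y <- as.numeric(biopsy_table$kpl)
  n <- length(y)
  if (length(unique(g)) < 2) stop("grade is constant: test undefined")
  blocks <- split(seq_len(n), pid)
  ## residualize against patient blocks (block-mean centering)
  ry <- y; rg <- g
  for (b in blocks) {
    ry[b] <- y[b] - mean(y[b])
    rg[b] <- g[b] - mean(g[b])
  }
  Sxx <- sum(rg^2)
  if (Sxx == 0)
    stop("grade is constant within every patient: test undefined")
  Syy <- sum(ry^2)
  df2 <- n - nlevels(pid) - 1
  if (df2 < 1) stop("not enough residual degrees of freedom")
  f_of <- function(sxy) {
    ess <- sxy^2 / Sxx
    (ess / 1) / ((Syy - ess) / df2)
  }
  F_obs <- f_of(sum(ry * rg))
  count <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      gp <- rg
      for (b in blocks) if (length(b) > 1) gp[b] <- gp[sample(b)]
      if (f_of(sum(ry * gp)) >= F_obs - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  p <- (1 + count) / (1 + n_perm)
  stat_result("blocked_permutation_F", F_obs, p, n,
              sprintf("within-patient permutation; n_perm = %d; seed = %d",
                      n_perm, as.integer(seed)))
}
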