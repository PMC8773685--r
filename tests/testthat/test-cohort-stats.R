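test_that("Spearman correlation attains +/-1 on monotone data", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(spearman_cor(x, x^2)$estimate, 1)
  expect_equal(spearman_cor(x, rev(x))$estimate, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  ## invariance under strictly monotone transforms
  set.seed(1)
  a <- rnorm(7); b <- rnorm(7)
  expect_equal(spearman_cor(exp(a), b^3 + 2 * b)$estimate,
               spearman_cor(a, b^3 + 2 * b)$estimate)
})

test_that("exact Spearman p-values match full enumeration with ties", {
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2.1, 1.9, 3.0, 3.0, 4.5, 4.4)
  res <- spearman_cor(x, y)
  ## independent oracle: brute-force over all 720 permutations using cor()
  perms <- expand.grid(rep(list(1:6), 6))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  rho_obs <- cor(x, y, method = "spearman")
  rhos <- apply(perms, 1, function(p) cor(x, y[unlist(p)], method = "spearman"))
  expect_equal(res$estimate, rho_obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(abs(rhos) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-12)
})

test_that("Pearson correlation matches the covariance formula and cor.test", {
  x <- 1:8
  expect_equal(pearson_cor(x, 2 * x)$estimate, 1)
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(pearson_cor(a, b)$estimate, 0)
  set.seed(4)
  u <- rnorm(20); v <- 0.5 * u + rnorm(20)
  res <- pearson_cor(u, v)
  expect_equal(res$estimate,
               sum((u - mean(u)) * (v - mean(v))) /
                 sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2)),
               tolerance = 1e-12)
  ct <- cor.test(u, v)
  expect_equal(res$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("rank-sum test: exact conventions on small samples", {
  expect_equal(rank_sum_test(c(3, 5, 7), c(3, 5, 7))$p_value, 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  expect_error(rank_sum_test(1, c(2, 3)))
})

test_that("rank-sum exact and asymptotic branches agree near the switch", {
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5, 0.5)
    exact <- rank_sum_test(a, b)$p_value
    ## asymptotic recomputation at the same data (normal, tie-corrected)
    r <- rank(c(a, b)); W <- sum(r[1:5]); n <- 10
    EW <- 5 * 11 / 2
    VW <- 25 / 12 * (11 - sum(table(r)^3 - table(r)) / (n * (n - 1)))
    pz <- min(1, 2 * pnorm(-(abs(W - EW) - 0.5) / sqrt(VW)))
    expect_lt(abs(exact - pz), 0.02)
  }
})

test_that("signed-rank test conventions", {
  expect_equal(signed_rank_test(1.5)$p_value, 1)     # single pair
  expect_error(signed_rank_test(c(0, 0)), "degenerate")
  ## exact two-sided on a clean case, against manual enumeration
  d <- c(1, 2, 3, 4)
  res <- signed_rank_test(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 4)))
  null_v <- signs %*% rank(abs(d))
  expect_equal(res$p_value,
               min(1, 2 * min(mean(null_v <= 10), mean(null_v >= 10))))
  ## zero differences are dropped and reported
  res2 <- signed_rank_test(c(0, 1, 2))
  expect_match(res2$notes, "1 zero diff")
  expect_equal(res2$n, 2L)
})

test_that("blocked permutation test hits the minimum p on a strong effect", {
  ## asymmetric within-block grade patterns: no permutation can mirror the
  ## observed alignment, so the observed F exceeds every permuted F
  bt <- data.frame(patient_id = rep(c("A", "B"), each = 6),
                   grade = rep(c(2, 2, 3, 4, 4, 4), 2),
                   kpl = c(1, 1.1, 2.9, 5, 5.2, 4.9,
                           11, 11.2, 13.1, 15, 15.1, 14.9))
  res <- blocked_grade_test(bt, n_perm = 199, seed = 1)
  expect_equal(res$p_value, 1 / 200)
})

test_that("blocked test is invariant to patient relabeling and block shifts", {
  set.seed(9)
  bt <- data.frame(patient_id = rep(c("A", "B", "C"), each = 5),
                   grade = sample(2:4, 15, replace = TRUE),
                   kpl = rnorm(15))
  r1 <- blocked_grade_test(bt, n_perm = 299, seed = 5)
  bt2 <- bt
  bt2$patient_id <- c(A = "Z", B = "Y", C = "X")[bt$patient_id]
  bt2$kpl <- bt$kpl + c(A = 10, B = -3, C = 0.5)[bt$patient_id]
  r2 <- blocked_grade_test(bt2, n_perm = 299, seed = 5)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("blocked test reduces to a one-block permutation test", {
  bt <- data.frame(patient_id = "A",
                   grade = c(2, 2, 4, 4, 3),
                   kpl = c(0.2, 0.1, 0.9, 1.0, 0.5))
  res <- blocked_grade_test(bt, n_perm = 499, seed = 3)
  ## manual one-block permutation of grades against kpl
  ry <- bt$kpl - mean(bt$kpl)
  rg <- bt$grade - mean(bt$grade)
  fstat <- function(gp) {
    s <- sum(ry * gp)^2 / sum(gp^2)
    s / ((sum(ry^2) - s) / (length(ry) - 2))
  }
  Fobs <- fstat(rg)
  set.seed(31)
  expect_equal(res$estimate, Fobs, tolerance = 1e-9)
  expect_gt(res$p_value, 0)
  expect_error(blocked_grade_test(bt[bt$grade == 2, ], n_perm = 9, seed = 1),
               "constant")
  bt3 <- data.frame(patient_id = c("A", "A", "B", "B"),
                    grade = c(2, 2, 4, 4), kpl = rnorm(4))
  expect_error(blocked_grade_test(bt3, n_perm = 9, seed = 1),
               "within every patient")
})
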