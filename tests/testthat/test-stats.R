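# build a vector with exact mean and sample SD
affine_vector <- function(n, mean, sd) {
  z <- scale(seq_len(n))  # mean 0, sample SD 1
  as.numeric(mean + sd * z)
}

test_that("one-sample t handles constants and degenerate variance", {
  res <- one_sample_t(rep(2.5, 10), 2.5)
  expect_equal(res$statistic, 0)
  expect_equal(res$d, 0)
  over <- one_sample_t(rep(2.5, 10), 0)
  expect_true(is.infinite(over$statistic))
})

test_that("one-sample t and d match published reconstructions from mean/SD/n", {
  v <- affine_vector(67, 1.433, 1.395)
  res <- one_sample_t(v, 0)
  expect_equal(res$df, 66)
  expect_equal(round(res$d, 3), 1.027)
  # published t and SE reconstruct to the precision the rounded mean/SD allow
  expect_lt(abs(res$statistic - 8.409), 0.005)
  expect_equal(round(res$se, 2), 0.17)

  v2 <- affine_vector(67, -0.044, 0.913)
  res2 <- one_sample_t(v2, 0)
  expect_equal(round(abs(res2$d), 3), 0.048)
  expect_lt(abs(res2$se - 0.111), 0.001)
})

test_that("one-sample t agrees with stats::t.test and is location-scale consistent", {
  set.seed(1001)
  v <- rnorm(30, 1, 2)
  res <- one_sample_t(v, 0.5)
  oracle <- t.test(v, mu = 0.5)
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  shifted <- one_sample_t(v + 10, 10.5)
  expect_equal(shifted$statistic, res$statistic, tolerance = 1e-12)
  scaled <- one_sample_t(v * 3, 1.5)
  expect_equal(scaled$statistic, res$statistic, tolerance = 1e-12)
})

test_that("paired t equals one-sample t on differences", {
  expect_equal(paired_t(1:10, 1:10)$statistic, 0)
  set.seed(1002)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(paired_t(a, b), one_sample_t(a - b, 0))
  # constant nonzero difference -> overflow
  expect_true(is.infinite(paired_t(1:10, (1:10) - 2)$statistic))
})

test_that("pearson r hits the exact bounds and matches cor.test", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(1003)
  a <- rnorm(40); b <- 0.4 * a + rnorm(40)
  res <- pearson_r(a, b)
  oracle <- cor.test(a, b)
  expect_equal(res$r, unname(oracle$estimate))
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  expect_equal(res$df, 38)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "constant")
})

test_that("p-values match the distribution functions to high precision", {
  set.seed(1004)
  v <- rnorm(25, 0.3)
  res <- one_sample_t(v, 0)
  expect_equal(res$p, 2 * pt(-abs(res$statistic), 24), tolerance = 1e-10)
  a <- rnorm(25); b <- 0.5 * a + rnorm(25)
  rr <- pearson_r(a, b)
  expect_equal(rr$p, 2 * pt(-abs(rr$statistic), 23), tolerance = 1e-10)
  sz <- steiger_z(0.4, 0.1, 0.2, 50)
  expect_equal(sz$p, 2 * pnorm(-abs(sz$z)), tolerance = 1e-12)
})

test_that("Steiger's Z: symmetry, dual-coded formula, and edge guards", {
  expect_equal(steiger_z(0.4, 0.4, 0.2, 50)$z, 0)
  res <- steiger_z(0.5, 0.2, 0.3, 50)
  expect_equal(res$z, oracle_steiger_z(0.5, 0.2, 0.3, 50), tolerance = 1e-4)
  # antisymmetry in the two dependent correlations
  expect_equal(steiger_z(0.2, 0.5, 0.3, 50)$z, -res$z)
  expect_error(steiger_z(1, 0.2, 0.3, 50), "diverges")
})

test_that("Steiger's Z type-I rate is nominal under equal true correlations", {
  set.seed(1005)
  n <- 68
  rejections <- vapply(1:2000, function(k) {
    # trivariate normal: j correlates 0.3 with both k and h; kh 0.4
    z <- matrix(rnorm(3 * n), n, 3)
    S <- matrix(c(1, 0.3, 0.3, 0.3, 1, 0.4, 0.3, 0.4, 1), 3, 3)
    xyz <- z %*% chol(S)
    r <- cor(xyz)
    abs(steiger_z(r[1, 2], r[1, 3], r[2, 3], n)$z) > qnorm(0.975)
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("Cousineau normalization removes between-subject offsets", {
  m <- rbind(c(1, 3), c(5, 7))
  se <- cousineau_se(m)
  expect_equal(unname(se), c(0, 0))

  # identical participants: normalization is the identity, SE is 0 anyway;
  # check the invariance instead on random data
  set.seed(1006)
  m2 <- matrix(rnorm(40), 10, 4)
  se2 <- cousineau_se(m2)
  m3 <- m2; m3[4, ] <- m3[4, ] + 100  # constant offset for one participant
  expect_equal(cousineau_se(m3), se2, tolerance = 1e-9)

  # when participant offsets dominate, within-subject SE < naive SE
  offsets <- rnorm(10, 0, 20)
  m4 <- sweep(matrix(rnorm(20, 0, 0.5), 10, 2), 1, offsets, "+")
  naive <- apply(m4, 2, function(col) sd(col) / sqrt(length(col)))
  expect_true(all(cousineau_se(m4) < naive))

  expect_error(cousineau_se(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("one-sample t type-I rate is nominal at the study's n", {
  set.seed(1007)
  rejections <- vapply(1:2000, function(k) {
    one_sample_t(rnorm(67), 0)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})
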