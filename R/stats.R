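#' One-sample t test with Cohen's d
#'
#' Two-tailed one-sample t test of `values` against `mu0`, wrapping
#' [stats::t.test()], with the standardized effect size
#' d = (mean - mu0) / SD (sample SD, n - 1 denominator).
#'
#' @param values numeric vector, n >= 2.
#' @param mu0 null value (default 0).
#' @return list with `statistic`, `df`, `p`, `d`, `mean`, `sd`, `se`, `n`.
#'   Zero variance with mean equal to `mu0` yields t = 0, d = 0; zero
#'   variance otherwise reports infinite t (overflow).
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  stopifnot(n >= 2)
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    stat <- if (m == mu0) 0 else Inf * sign(m - mu0)
    return(list(statistic = stat, df = n - 1,
                p = if (m == mu0) 1 else 0,
                d = if (m == mu0) 0 else Inf * sign(m - mu0),
                mean = m, sd = s, se = 0, n = n))
  }
  tt <- stats::t.test(values, mu = mu0, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (m - mu0) / s, mean = m, sd = s,
       se = s / sqrt(n), n = n)
}

#' Paired t test with Cohen's d
#'
#' Equivalent to a one-sample t test on the within-pair differences
#' `a - b`; d = mean(diff) / sd(diff).
#'
#' @param a,b paired numeric vectors of equal length.
#' @return As [one_sample_t()] (on the differences).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  one_sample_t(a[keep] - b[keep], 0)
}

#' Pearson correlation with t test
#'
#' Product-moment correlation with the usual two-tailed t test on
#' df = n - 2, wrapping [stats::cor.test()].  Pairs with missing values are
#' dropped (complete-case), so the reported df reflects the contributing n.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs,
#'   both nonconstant.
#' @return list with `r`, `statistic` (t), `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("pearson_r: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r: constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), statistic = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n = n)
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests whether the correlation of j with k differs from the correlation
#' of j with h, measured on the same n cases, given the correlation between
#' k and h.  Uses the pooled-correlation Z1* form: the two correlations are
#' Fisher-transformed, their covariance is estimated with the pooled
#' r-bar = (r_jk + r_jh)/2,
#' \deqn{\bar\psi = r_{kh}(1 - 2\bar r^2) - \tfrac12 \bar r^2
#'   (1 - 2\bar r^2 - r_{kh}^2), \quad
#'   \bar s = \bar\psi / (1 - \bar r^2)^2,}
#' and
#' \deqn{Z = (z_{jk} - z_{jh}) \sqrt{\frac{n - 3}{2 - 2\bar s}}.}
#' Two-tailed p from the standard normal.
#'
#' @param r_jk,r_jh the two dependent correlations sharing variable j.
#' @param r_kh correlation between the two non-shared variables.
#' @param n number of cases (> 3).
#' @return list with `z`, `p`, `r_jk`, `r_jh`, `r_kh`, `n`.
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  stopifnot(n > 3, abs(r_kh) <= 1)
  if (abs(r_jk) >= 1 || abs(r_jh) >= 1)
    stop("steiger_z: |r| = 1 input; Fisher transform diverges")
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  sbar <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * sbar))
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n)
}

#' Cousineau within-subject standard errors
#'
#' Removes between-participant offsets before computing per-condition
#' standard errors, so error bars reflect the within-subject variability
#' that drives repeated-measures tests: each cell is normalized as
#' value - participant mean + grand mean, and the SE of the normalized
#' values is taken per condition.  (No further condition-count correction
#' is applied.)
#'
#' @param m numeric matrix, participants x conditions, no missing cells,
#'   at least 2 rows and 2 columns.
#' @return Named numeric vector of per-condition standard errors.
#' @export
cousineau_se <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  if (anyNA(m)) stop("cousineau_se: missing cells not allowed")
  norm <- m - rowMeans(m) + mean(m)
  apply(norm, 2, function(col) stats::sd(col) / sqrt(length(col)))
}
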