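#' Chi-squared goodness-of-fit test for normality
#'
#' Bins the sample into `k = ceiling(1 + 3.322 * log10(n))` equal-probability
#' bins under the fitted normal `N(mean(x), sd(x)^2)` and compares observed
#' with expected counts. Degrees of freedom are `k - 3` (two estimated
#' parameters).
#'
#' @param samples Numeric vector, at least 20 values, nonzero variance.
#' @param alpha Significance level (default 0.05).
#' @param k Number of bins; defaults to the Sturges rule above.
#' @return A `stat_test_result` list: `test`, `statistic`, `df`, `p_value`,
#'   `alpha`, `reject`.
#' @export
chi2_normality <- function(samples, alpha = 0.05, k = NULL) {
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 20) stop("chi-squared normality test requires n >= 20")
  s <- sd(x)
  if (s == 0) stop("chi-squared normality test undefined for zero variance")
  m <- mean(x)
  if (is.null(k)) k <- ceiling(1 + 3.322 * log10(n))
  breaks <- qnorm(seq(0, 1, length.out = k + 1), mean = m, sd = s)
  breaks[1] <- -Inf; breaks[k + 1] <- Inf
  obs <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               left.open = TRUE), nbins = k)
  exp_count <- n / k
  stat <- sum((obs - exp_count)^2 / exp_count)
  df <- k - 3
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  stat_test_result("chi2_normality", stat, p, alpha, df = df)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples' location. The U statistic uses
#' midranks for ties. The p-value is exact (null distribution of U over all
#' rank assignments) when both samples have at most 8 observations and there
#' are no ties; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Nonempty numeric samples.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`
#'   (alternatives about the location of `x` relative to `y`).
#' @param alpha Significance level.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   default `NULL` applies the rule above.
#' @return A `stat_test_result` with the U statistic of the first sample.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p_value  # exact: 1/3
mann_whitney <- function(x, y, alternative = c("two_sided", "less", "greater"),
                         alpha = 0.05, exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  ties <- any(duplicated(c(x, y)))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (is.null(exact)) exact <- max(nx, ny) <= 8 && !ties
  if (exact && ties) stop("exact Mann-Whitney p-value requires tie-free data")
  if (exact) {
    p_le <- pwilcox(U, nx, ny)
    p_ge <- 1 - pwilcox(U - 1, nx, ny)
    p <- switch(alternative,
                two_sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
    method <- "exact"
  } else {
    n_tot <- nx + ny
    mu <- nx * ny / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n_tot * (n_tot - 1))
    sigma <- sqrt(nx * ny / 12 * ((n_tot + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      cc <- switch(alternative, two_sided = sign(U - mu) * 0.5,
                   less = -0.5, greater = 0.5)
      z <- (U - mu - cc) / sigma
      p <- switch(alternative,
                  two_sided = min(1, 2 * pnorm(-abs(z))),
                  less = pnorm(z),
                  greater = pnorm(z, lower.tail = FALSE))
    }
    method <- "normal_approximation"
  }
  res <- stat_test_result("mann_whitney", U, p, alpha)
  res$method <- method
  res
}

stat_test_result <- function(test, statistic, p_value, alpha, df = NULL) {
  structure(list(test = test, statistic = as.numeric(statistic), df = df,
                 p_value = as.numeric(p_value), alpha = alpha,
                 reject = p_value < alpha),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.6g%s p=%.4g alpha=%g => %s H0\n",
              x$test, x$statistic,
              if (!is.null(x$df)) sprintf(" df=%d", x$df) else "",
              x$p_value, x$alpha, if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

# Per-eta, per-item best values of one family's tensor, flattened.
best_value_pool <- function(vr) {
  higher <- metric_higher_better(vr$metric)
  vals <- apply(vr$tensor, c(3, 4), function(slab) {
    if (all(is.na(slab))) NA_real_
    else if (higher) max(slab, na.rm = TRUE) else min(slab, na.rm = TRUE)
  })
  as.numeric(vals[!is.na(vals)])
}

#' Compare two datasets' wavelet responses per family
#'
#' The robustness protocol: for each wavelet family, pools the per-noise
#' -level per-item best metric values from two volumetric responses (e.g.
#' one computed on CT-like images, one on MR-like images), screens each pool
#' with the Chi-squared normality test, and compares the two pools with the
#' Mann-Whitney test of equal medians.
#'
#' @param vr_a,vr_b A `volumetric_response` or list of them (one per family;
#'   matching families, metric and schedule in both datasets).
#' @param alpha Significance level.
#' @return Data frame with one row per family: `family`, `metric`, sample
#'   sizes, normality p-values for both pools, the Mann-Whitney `statistic`,
#'   `p_value` and `reject`.
#' @export
compare_datasets <- function(vr_a, vr_b, alpha = 0.05) {
  la <- as_vr_list(vr_a); lb <- as_vr_list(vr_b)
  fams <- intersect(wavelet_families(), names(la))
  if (!setequal(names(la), names(lb))) stop("family sets differ between datasets")
  rows <- NULL
  for (fam in fams) {
    a <- la[[fam]]; b <- lb[[fam]]
    if (a$metric != b$metric) stop("metrics differ between datasets")
    if (!isTRUE(all.equal(a$schedule$levels, b$schedule$levels))) {
      stop("schedules differ between datasets")
    }
    pa <- best_value_pool(a); pb <- best_value_pool(b)
    chi_a <- tryCatch(chi2_normality(pa, alpha)$p_value, error = function(e) NA_real_)
    chi_b <- tryCatch(chi2_normality(pb, alpha)$p_value, error = function(e) NA_real_)
    mw <- mann_whitney(pa, pb, alpha = alpha)
    rows <- rbind(rows, data.frame(
      family = fam, metric = a$metric, n_a = length(pa), n_b = length(pb),
      chi2_p_a = chi_a, chi2_p_b = chi_b,
      statistic = mw$statistic, p_value = mw$p_value, reject = mw$reject))
  }
  rownames(rows) <- NULL
  rows
}
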