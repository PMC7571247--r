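#' Robust noise-scale estimate from the finest detail band
#'
#' The median-absolute-deviation estimator of the additive-noise standard
#' deviation: `sigma_hat = median(|finest detail coefficients|) / 0.6745`.
#' For images the level-1 diagonal band is used, where signal content is
#' weakest and the estimate is dominated by noise.
#'
#' @param pyramid A `coef_pyramid` from [wt_decompose()].
#' @return Nonnegative noise-scale estimate.
#' @export
estimate_sigma <- function(pyramid) {
  stopifnot(inherits(pyramid, "coef_pyramid"))
  if (length(pyramid$details) < 1) stop("pyramid has no detail level")
  finest <- pyramid$details[[1]]
  band <- if (pyramid$kind == "image") as.numeric(finest$d) else as.numeric(finest)
  if (length(band) == 0) stop("empty finest detail band")
  median(abs(band)) / 0.6745
}

#' Donoho's universal threshold
#'
#' `T = sigma_hat * sqrt(2 * ln(n_samples))` — the global threshold under
#' which i.i.d. Gaussian noise coefficients are removed with probability
#' approaching one as the sample count grows.
#'
#' @param sigma_hat Noise-scale estimate (>= 0).
#' @param n_samples Total element count of the record (>= 2).
#' @return Nonnegative threshold.
#' @export
universal_threshold <- function(sigma_hat, n_samples) {
  if (sigma_hat < 0) stop("sigma_hat must be >= 0")
  if (n_samples < 2) stop("n_samples must be >= 2")
  sigma_hat * sqrt(2 * log(n_samples))
}

soft_threshold <- function(c, T) sign(c) * pmax(abs(c) - T, 0)
hard_threshold <- function(c, T) c * (abs(c) > T)

#' Threshold the detail bands of a pyramid
#'
#' Applies soft or hard thresholding with a single global threshold `T` to
#' every detail coefficient at every level; the approximation band is left
#' untouched.
#'
#' @param pyramid A `coef_pyramid`.
#' @param T Threshold (>= 0).
#' @param rule `"universal_soft"` (shrink toward zero) or
#'   `"universal_hard"` (keep-or-kill).
#' @return A thresholded `coef_pyramid`.
#' @export
shrink <- function(pyramid, T, rule = c("universal_soft", "universal_hard")) {
  rule <- match.arg(rule)
  stopifnot(inherits(pyramid, "coef_pyramid"))
  if (T < 0) stop("threshold must be >= 0")
  fn <- if (rule == "universal_soft") soft_threshold else hard_threshold
  pyramid$details <- lapply(pyramid$details, function(det) {
    if (is.list(det)) lapply(det, fn, T = T) else fn(det, T = T)
  })
  pyramid
}

#' Wavelet shrinkage denoising
#'
#' The full pipeline of the sweep's inner loop: decompose, estimate the
#' noise scale from the finest detail band, form the universal threshold
#' from the record's total element count, threshold all detail bands, and
#' reconstruct.
#'
#' @param data Numeric vector, matrix, or [clean_record()].
#' @param config A [wavelet_config()] (its `threshold_rule` selects soft or
#'   hard shrinkage).
#' @param mode Boundary mode, see [wt_decompose()].
#' @return Denoised data with the input's shape (plain vector/matrix).
#' @export
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 512))
#' noisy <- x + rnorm(512, sd = 0.2)
#' den <- wt_denoise(noisy, wavelet_config("daubechies", 4, 3))
#' mean((den - x)^2) < mean((noisy - x)^2)
wt_denoise <- function(data, config, mode = "symmetric") {
  x <- record_data(data)
  pyr <- wt_decompose(x, config, mode)
  sigma_hat <- estimate_sigma(pyr)
  T <- universal_threshold(sigma_hat, length(x))
  pyr <- shrink(pyr, T, config$threshold_rule)
  wt_reconstruct(pyr)
}

#' Linear intensity adjustment
#'
#' Maps the intensity window `[low_in, high_in]` linearly onto `[0, 1]`,
#' clipping values outside the window. Used in the 2D pipeline to restore
#' contrast after denoising (the classical image-adjust step).
#'
#' @param image Numeric matrix or image [clean_record()] in `[0, 1]`.
#' @param low_in Lower input bound, in `[0, 1)`.
#' @param high_in Upper input bound, in `(low_in, 1]`.
#' @return Adjusted matrix.
#' @export
adjust_intensity <- function(image, low_in = 0, high_in = 1) {
  x <- record_data(image)
  if (!is.matrix(x)) stop("adjust_intensity expects a 2D image")
  if (low_in < 0 || low_in >= 1) stop("low_in must lie in [0, 1)")
  if (high_in <= low_in || high_in > 1) stop("high_in must lie in (low_in, 1]")
  clip_unit((x - low_in) / (high_in - low_in))
}

#' Recommended intensity-adjust lower bound per record class
#'
#' The empirically useful low-intensity cutoffs for the image-adjust step:
#' 0.45 for high-contrast piecewise (CT-like) content, 0.40 for smooth
#' textured (MR-like) content, and 0.50 otherwise.
#'
#' @param kind `"piecewise"`, `"smooth_textured"`, or anything else.
#' @return The suggested `low_in` value.
#' @export
recommended_low_in <- function(kind) {
  switch(as.character(kind),
         piecewise = , ct_like = 0.45,
         smooth_textured = , mr_like = 0.40,
         0.50)
}
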