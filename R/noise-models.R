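#' Additive white Gaussian noise at a prescribed SNR (1D)
#'
#' Adds zero-mean Gaussian noise whose power is set relative to the
#' *measured* power of the input signal: noise power equals
#' `P_signal / 10^(snr_db/10)` with `P_signal = mean(x^2)`.
#'
#' @param signal A 1D [clean_record()] or numeric vector; must not be
#'   identically zero (the SNR would be undefined).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer seed.
#' @return Degraded signal of the same type and length as the input.
#' @export
add_awgn_1d <- function(signal, snr_db, seed = 1) {
  x <- record_data(signal)
  if (is.matrix(x)) stop("add_awgn_1d expects a 1D signal")
  p_sig <- mean(x^2)
  if (p_sig == 0) stop("SNR undefined for the all-zero signal")
  sd_noise <- sqrt(p_sig / 10^(snr_db / 10))
  noisy <- with_seed(seed, x + rnorm(length(x), sd = sd_noise))
  record_like(noisy, signal)
}

#' Impulse noise with prescribed variance (1D)
#'
#' Sparse symmetric impulses: each sample independently receives an impulse
#' with probability `p`; impulse amplitudes are `+A` or `-A` with equal
#' probability, with `A = sqrt(variance / p)` so the marginal impulse process
#' has mean zero and variance exactly `variance`.
#'
#' @param signal 1D [clean_record()] or numeric vector.
#' @param variance Total impulse-process variance (>= 0).
#' @param seed Integer seed.
#' @param p Impulse occurrence probability per sample (default 0.05).
#' @return Degraded signal.
#' @export
add_impulse_1d <- function(signal, variance, seed = 1, p = 0.05) {
  x <- record_data(signal)
  if (is.matrix(x)) stop("add_impulse_1d expects a 1D signal")
  if (variance < 0) stop("impulse variance must be >= 0")
  if (variance == 0) return(record_like(x, signal))
  amp <- sqrt(variance / p)
  noisy <- with_seed(seed, {
    hit <- runif(length(x)) < p
    sgn <- sample(c(-1, 1), length(x), replace = TRUE)
    x + hit * sgn * amp
  })
  record_like(noisy, signal)
}

#' Additive Gaussian noise for images (2D)
#'
#' Adds Gaussian noise to a `[0, 1]` image and clips the result back to
#' `[0, 1]`. Following the sweep protocol, the iterated parameter
#' `gauss_param` is by default the noise *mean* with a fixed variance of
#' 0.01; set `interpret = "variance"` to treat it as the variance of
#' zero-mean noise instead.
#'
#' @param image 2D [clean_record()] or numeric matrix in `[0, 1]`.
#' @param gauss_param The swept noise parameter.
#' @param seed Integer seed.
#' @param variance Noise variance used when `interpret = "mean"`.
#' @param interpret `"mean"` (default) or `"variance"`.
#' @return Degraded image, clipped to `[0, 1]`.
#' @export
add_gaussian_2d <- function(image, gauss_param, seed = 1, variance = 0.01,
                            interpret = c("mean", "variance")) {
  interpret <- match.arg(interpret)
  x <- record_data(image)
  if (!is.matrix(x)) stop("add_gaussian_2d expects a 2D image")
  mu <- if (interpret == "mean") gauss_param else 0
  v <- if (interpret == "mean") variance else gauss_param
  if (v < 0) stop("gaussian variance must be >= 0")
  noisy <- with_seed(seed, x + rnorm(length(x), mean = mu, sd = sqrt(v)))
  record_like(clip_unit(matrix(noisy, nrow(x))), image)
}

#' Salt-and-pepper noise (2D)
#'
#' Each pixel is independently corrupted with probability `d`; corrupted
#' pixels are set to 0 (pepper) or 1 (salt) with equal probability.
#'
#' @param image 2D [clean_record()] or matrix.
#' @param d Noise density in `[0, 1]`.
#' @param seed Integer seed.
#' @return Degraded image.
#' @export
add_salt_pepper <- function(image, d, seed = 1) {
  if (!is_scalar_number(d) || d < 0 || d > 1) {
    stop("salt-and-pepper density d must lie in [0, 1]")
  }
  x <- record_data(image)
  if (!is.matrix(x)) stop("add_salt_pepper expects a 2D image")
  noisy <- with_seed(seed, {
    hit <- runif(length(x)) < d
    salt <- runif(length(x)) < 0.5
    out <- x
    out[hit & salt] <- 1
    out[hit & !salt] <- 0
    out
  })
  record_like(matrix(noisy, nrow(x)), image)
}

#' Multiplicative speckle noise (2D)
#'
#' Degrades an image with the multiplicative model `J = I + n * I`, where
#' the multiplier field `n` is i.i.d. uniform on
#' `[-sqrt(3 v), +sqrt(3 v)]` — zero mean, variance `v` (default 0.05).
#' The result is clipped to `[0, 1]`.
#'
#' @param image 2D [clean_record()] or matrix.
#' @param speckle_variance Variance `v` of the multiplier field (>= 0).
#' @param seed Integer seed.
#' @return Degraded image.
#' @export
add_speckle <- function(image, speckle_variance = 0.05, seed = 1) {
  if (speckle_variance < 0) stop("speckle variance must be >= 0")
  x <- record_data(image)
  if (!is.matrix(x)) stop("add_speckle expects a 2D image")
  half <- sqrt(3 * speckle_variance)
  noisy <- with_seed(seed, {
    n_field <- runif(length(x), min = -half, max = half)
    x + n_field * x
  })
  record_like(clip_unit(matrix(noisy, nrow(x))), image)
}

#' Composite noise at a schedule intensity
#'
#' Applies the full degradation used by the parameter sweep at noise
#' intensity `eta`:
#'
#' * 1D: AWGN at `snr_db = eta` followed by impulse noise with variance
#'   `1/eta` (so lower SNR also means stronger impulses). Requires
#'   `eta > 0`.
#' * 2D: Gaussian noise with swept parameter `eta`, then speckle at a
#'   constant variance, then salt-and-pepper with density `eta` (applied
#'   last so its extreme pixels reach the denoiser intact).
#'
#' @param record [clean_record()] or plain array.
#' @param eta Noise intensity from the active schedule.
#' @param seed Integer seed; component seeds are derived from it.
#' @param speckle_variance Constant speckle variance for the 2D composite.
#' @param impulse_p Impulse occurrence probability for the 1D composite.
#' @param gaussian_variance,gaussian_interpret Passed to [add_gaussian_2d()].
#' @return Degraded record of the same type as the input.
#' @export
composite_noise <- function(record, eta, seed = 1, speckle_variance = 0.05,
                            impulse_p = 0.05, gaussian_variance = 0.01,
                            gaussian_interpret = "mean") {
  x <- record_data(record)
  if (is.matrix(x)) {
    if (eta < 0 || eta > 1) stop("2D noise intensity eta must lie in [0, 1]")
    out <- add_gaussian_2d(x, eta, seed = derive_seed(seed, 11),
                           variance = gaussian_variance,
                           interpret = gaussian_interpret)
    out <- add_speckle(out, speckle_variance, seed = derive_seed(seed, 12))
    out <- add_salt_pepper(out, eta, seed = derive_seed(seed, 13))
    record_like(out, record)
  } else {
    if (eta <= 0) stop("1D noise intensity eta must be > 0 (impulse variance = 1/eta)")
    out <- add_awgn_1d(x, snr_db = eta, seed = derive_seed(seed, 21))
    out <- add_impulse_1d(out, variance = 1 / eta, seed = derive_seed(seed, 22),
                          p = impulse_p)
    record_like(out, record)
  }
}

#' Default noise-intensity schedules
#'
#' The canonical sweep schedules: for 1D, SNR values `0.05, 0.10, ..., 10`
#' dB (200 levels); for 2D, the 11 values `0, 0.1, ..., 1` driving the
#' Gaussian mean and salt-and-pepper density.
#'
#' @param kind `"schedule_1d"` or `"schedule_2d"`.
#' @return A `noise_schedule` object with fields `levels` and `kind`.
#' @export
default_schedule <- function(kind = c("schedule_1d", "schedule_2d")) {
  kind <- match.arg(kind)
  levels <- if (kind == "schedule_1d") seq(0.05, 10, by = 0.05) else seq(0, 1, by = 0.1)
  noise_schedule(levels, kind)
}

#' Construct a noise schedule
#'
#' @param levels Strictly increasing, nonempty numeric vector of noise
#'   intensities (the eta axis of the volumetric response).
#' @param kind `"schedule_1d"` or `"schedule_2d"`.
#' @return A `noise_schedule` object.
#' @export
noise_schedule <- function(levels, kind = c("schedule_1d", "schedule_2d")) {
  kind <- match.arg(kind)
  levels <- as.numeric(levels)
  if (length(levels) == 0) stop("schedule must be nonempty")
  if (any(diff(levels) <= 0)) stop("schedule levels must be strictly increasing")
  structure(list(levels = levels, kind = kind), class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> %s: %d levels in [%g, %g]\n",
              x$kind, length(x$levels), min(x$levels), max(x$levels)))
  invisible(x)
}
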