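#' Mean squared error
#'
#' Mean of squared elementwise differences between two same-shape arrays.
#'
#' @param X,Y Numeric arrays of identical shape with at least one element.
#' @return Nonnegative scalar.
#' @export
mse <- function(X, Y) {
  X <- record_data(X); Y <- record_data(Y)
  check_same_shape(X, Y)
  mean((X - Y)^2)
}

#' 2D (flattened) Pearson correlation
#'
#' Pearson correlation over all elements with both means removed. Undefined
#' for constant arrays: the result is `NA` (recorded as a missing cell by the
#' sweep drivers, never silently zero).
#'
#' @param X,Y Numeric arrays of identical shape.
#' @param warn Emit a warning when the correlation is undefined.
#' @return Scalar in `[-1, 1]`, or `NA` if either array is constant.
#' @export
corr2d <- function(X, Y, warn = TRUE) {
  X <- record_data(X); Y <- record_data(Y)
  check_same_shape(X, Y)
  if (sd(X) == 0 || sd(Y) == 0) {
    if (warn) warning("correlation undefined for constant input; returning NA")
    return(NA_real_)
  }
  cor(as.numeric(X), as.numeric(Y))
}

#' Euclidean distance
#'
#' Square root of the sum of squared elementwise differences; satisfies
#' `ED^2 = m * n * MSE`.
#'
#' @param X,Y Numeric arrays of identical shape.
#' @return Nonnegative scalar.
#' @export
euclidean_distance <- function(X, Y) {
  X <- record_data(X); Y <- record_data(Y)
  check_same_shape(X, Y)
  sqrt(sum((X - Y)^2))
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(peak^2 / MSE)` in decibels; `+Inf` for a zero MSE.
#' For images normalised to `[0, 1]` the peak is 1.
#'
#' @param mse_value Mean squared error (>= 0).
#' @param peak Peak signal value (> 0), default 1.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(mse_value, peak = 1) {
  if (mse_value < 0) stop("mse_value must be >= 0")
  if (peak <= 0) stop("peak must be > 0")
  if (mse_value == 0) return(Inf)
  10 * log10(peak^2 / mse_value)
}

check_same_shape <- function(X, Y) {
  if (length(X) == 0) stop("metrics require at least one element")
  dx <- dim(X) %||% length(X)
  dy <- dim(Y) %||% length(Y)
  if (!identical(as.integer(dx), as.integer(dy))) {
    stop("shape mismatch: ", paste(dx, collapse = "x"), " vs ",
         paste(dy, collapse = "x"))
  }
  invisible(TRUE)
}

#' All four evaluation metrics at once
#'
#' @param X,Y Numeric arrays of identical shape (e.g. denoised vs gold
#'   standard).
#' @param peak Peak value for PSNR.
#' @return A one-row data frame with columns `mse`, `corr`,
#'   `euclidean_distance`, `psnr_db`.
#' @export
metric_report <- function(X, Y, peak = 1) {
  m <- mse(X, Y)
  data.frame(mse = m,
             corr = corr2d(X, Y, warn = FALSE),
             euclidean_distance = euclidean_distance(X, Y),
             psnr_db = psnr(m, peak))
}

#' Metric names supported by the response mapping
#'
#' @return Character vector of metric identifiers.
#' @export
metric_names <- function() c("corr", "mse", "ed", "psnr")

# Direction of optimality per metric.
metric_higher_better <- function(metric) {
  metric <- match.arg(metric, metric_names())
  metric %in% c("corr", "psnr")
}

evaluate_metric <- function(metric, denoised, clean, peak = 1) {
  switch(metric,
         corr = corr2d(denoised, clean, warn = FALSE),
         mse = mse(denoised, clean),
         ed = euclidean_distance(denoised, clean),
         psnr = psnr(mse(denoised, clean), peak),
         stop("unknown metric: ", metric))
}
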