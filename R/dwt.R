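# Discrete wavelet transform: two boundary modes.
#
# "symmetric": half-sample symmetric extension by (F-1) samples on each side,
# valid convolution, even-phase downsampling. Coefficient bands have length
# floor((n + F - 1) / 2); the mild redundancy is what makes the decimated
# transform perfectly invertible under non-periodic extension.
#
# "periodic": circular convolution with even-phase downsampling; band length
# n/2 (n must be even at every level). The periodized analysis operator of an
# orthonormal filter pair is orthogonal, so synthesis is its adjoint and
# coefficient energy equals signal energy exactly.

# ---- single-level steps (1D on rows of a matrix; vectors are 1-row) -------

# Filter every row of X along its columns, symmetric extension.
dwt_rows_sym <- function(X, lo, hi) {
  F <- length(lo); n <- ncol(X)
  if (n < F) stop_infeasible(n, F)
  ext <- cbind(X[, (F - 1):1, drop = FALSE], X, X[, n:(n - F + 2), drop = FALSE])
  m <- n + F - 1
  zlo <- matrix(0, nrow(X), m)
  zhi <- matrix(0, nrow(X), m)
  for (k in seq_len(F)) {
    seg <- ext[, (1:m) + (F - k), drop = FALSE]
    zlo <- zlo + lo[k] * seg
    zhi <- zhi + hi[k] * seg
  }
  idx <- seq(2, m, by = 2)
  list(lo = zlo[, idx, drop = FALSE], hi = zhi[, idx, drop = FALSE], n = n)
}

# Inverse along columns: upsample, convolve with synthesis filters, trim.
idwt_rows_sym <- function(L, H, lo, hi, n) {
  F <- length(lo); Lc <- ncol(L)
  u <- matrix(0, nrow(L), 2 * Lc); u[, seq(2, 2 * Lc, by = 2)] <- L
  v <- matrix(0, nrow(H), 2 * Lc); v[, seq(2, 2 * Lc, by = 2)] <- H
  rlo <- rev(lo); rhi <- rev(hi)   # synthesis = time-reversed analysis
  r <- matrix(0, nrow(L), 2 * Lc + F - 1)
  for (k in seq_len(F)) {
    cols <- (1:(2 * Lc)) + (k - 1)
    r[, cols] <- r[, cols] + rlo[k] * u + rhi[k] * v
  }
  r[, F:(F + n - 1), drop = FALSE]
}

dwt_rows_per <- function(X, lo, hi) {
  F <- length(lo); n <- ncol(X)
  if (n < F || n %% 2 != 0) stop_infeasible(n, F)
  L <- n / 2
  zlo <- matrix(0, nrow(X), L)
  zhi <- matrix(0, nrow(X), L)
  base <- 2 * seq_len(L) - 1
  for (k in seq_len(F)) {
    idx <- (base + k - 2) %% n + 1
    seg <- X[, idx, drop = FALSE]
    zlo <- zlo + lo[k] * seg
    zhi <- zhi + hi[k] * seg
  }
  list(lo = zlo, hi = zhi, n = n)
}

idwt_rows_per <- function(L, H, lo, hi, n) {
  F <- length(lo); Lc <- ncol(L)
  out <- matrix(0, nrow(L), n)
  base <- 2 * seq_len(Lc) - 1
  for (k in seq_len(F)) {
    idx <- (base + k - 2) %% n + 1
    out[, idx] <- out[, idx] + lo[k] * L + hi[k] * H
  }
  out
}

dwt_step_1d <- function(x, fb, mode) {
  f <- if (mode == "periodic") dwt_rows_per else dwt_rows_sym
  r <- f(matrix(x, nrow = 1), fb$dec_lo, fb$dec_hi)
  list(cA = as.numeric(r$lo), cD = as.numeric(r$hi), n = r$n)
}

idwt_step_1d <- function(cA, cD, fb, mode, n) {
  f <- if (mode == "periodic") idwt_rows_per else idwt_rows_sym
  as.numeric(f(matrix(cA, nrow = 1), matrix(cD, nrow = 1),
               fb$dec_lo, fb$dec_hi, n))
}

# Separable 2D step: filter along columns of each row, then along rows of
# each column (via transposition). Sub-band naming: h = horizontal detail
# (lowpass rows / highpass columns), v = vertical detail, d = diagonal.
dwt_step_2d <- function(X, fb, mode) {
  rows <- if (mode == "periodic") dwt_rows_per else dwt_rows_sym
  r1 <- rows(X, fb$dec_lo, fb$dec_hi)
  cl <- rows(t(r1$lo), fb$dec_lo, fb$dec_hi)
  ch <- rows(t(r1$hi), fb$dec_lo, fb$dec_hi)
  list(cA = t(cl$lo), h = t(cl$hi), v = t(ch$lo), d = t(ch$hi),
       dims = dim(X))
}

idwt_step_2d <- function(cA, h, v, d, fb, mode, dims) {
  irows <- if (mode == "periodic") idwt_rows_per else idwt_rows_sym
  lo_cols <- t(irows(t(cA), t(h), fb$dec_lo, fb$dec_hi, dims[1]))
  hi_cols <- t(irows(t(v), t(d), fb$dec_lo, fb$dec_hi, dims[1]))
  irows(lo_cols, hi_cols, fb$dec_lo, fb$dec_hi, dims[2])
}

stop_infeasible <- function(n, F) {
  stop(structure(class = c("wavemap_infeasible", "error", "condition"),
                 list(message = sprintf(
                   "decomposition infeasible: band length %d below filter length %d",
                   n, F), call = sys.call(-1))))
}

# ---- multi-level decomposition -------------------------------------------

#' Check feasibility of a decomposition
#'
#' A `(family, order, level)` setting is feasible for a record when every
#' decomposition stage keeps the approximation band at least as long as the
#' filter (and, in periodic mode, of even length).
#'
#' @param data Numeric vector, matrix, or [clean_record()].
#' @param config A [wavelet_config()].
#' @param mode `"symmetric"` or `"periodic"`.
#' @return `TRUE` or `FALSE`.
#' @export
feasible_level <- function(data, config, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  x <- record_data(data)
  F <- filter_bank(config$family, config$order)$length
  sizes <- if (is.matrix(x)) dim(x) else length(x)
  for (j in seq_len(config$level)) {
    if (any(sizes < F)) return(FALSE)
    if (mode == "periodic") {
      if (any(sizes %% 2 != 0)) return(FALSE)
      sizes <- sizes / 2
    } else {
      sizes <- floor((sizes + F - 1) / 2)
    }
  }
  TRUE
}

#' Multi-level discrete wavelet decomposition
#'
#' Decomposes a 1D signal or 2D image into a coefficient pyramid with
#' `config$level` detail levels plus a final approximation band. Detail
#' levels are stored finest first: `details[[1]]` holds the level-1 (finest)
#' coefficients — a numeric vector for signals or a list with elements
#' `h`, `v`, `d` for images.
#'
#' @param data Numeric vector, matrix, or [clean_record()].
#' @param config A [wavelet_config()].
#' @param mode Boundary handling: `"symmetric"` (default; half-sample
#'   symmetric extension) or `"periodic"` (circular; orthonormal, exact
#'   energy conservation, even sizes required).
#' @return A `coef_pyramid` object. Infeasible settings raise a condition of
#'   class `wavemap_infeasible` which sweep drivers record as a missing cell.
#' @seealso [wt_reconstruct()]
#' @export
wt_decompose <- function(data, config, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  x <- record_data(data)
  fb <- filter_bank(config$family, config$order)
  if (!feasible_level(x, config, mode)) {
    stop_infeasible(if (is.matrix(x)) min(dim(x)) else length(x), fb$length)
  }
  two_d <- is.matrix(x)
  details <- vector("list", config$level)
  sizes <- vector("list", config$level)
  cur <- x
  for (j in seq_len(config$level)) {
    if (two_d) {
      st <- dwt_step_2d(cur, fb, mode)
      details[[j]] <- st[c("h", "v", "d")]
      sizes[[j]] <- st$dims
      cur <- st$cA
    } else {
      st <- dwt_step_1d(cur, fb, mode)
      details[[j]] <- st$cD
      sizes[[j]] <- st$n
      cur <- st$cA
    }
  }
  structure(list(approximation = cur, details = details, sizes = sizes,
                 level = config$level, family = fb$family, order = fb$order,
                 mode = mode, kind = if (two_d) "image" else "signal"),
            class = "coef_pyramid")
}

#' Reconstruct from a coefficient pyramid
#'
#' Inverts [wt_decompose()]. Without coefficient modification the round trip
#' reproduces the input to near machine precision.
#'
#' @param pyramid A `coef_pyramid`.
#' @return Numeric vector or matrix with the original shape.
#' @export
wt_reconstruct <- function(pyramid) {
  stopifnot(inherits(pyramid, "coef_pyramid"))
  fb <- filter_bank(pyramid$family, pyramid$order)
  cur <- pyramid$approximation
  for (j in rev(seq_len(pyramid$level))) {
    if (pyramid$kind == "image") {
      det <- pyramid$details[[j]]
      cur <- idwt_step_2d(cur, det$h, det$v, det$d, fb, pyramid$mode,
                          pyramid$sizes[[j]])
    } else {
      cur <- idwt_step_1d(cur, pyramid$details[[j]], fb, pyramid$mode,
                          pyramid$sizes[[j]])
    }
  }
  cur
}

#' @export
print.coef_pyramid <- function(x, ...) {
  cat(sprintf("<coef_pyramid> %s %s-%d, %d level(s), mode=%s\n",
              x$kind, x$family, x$order, x$level, x$mode))
  invisible(x)
}
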