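#' Synthetic gold-standard phantom image
#'
#' Generates a clean 2D phantom with the structural character of the two
#' image classes the sweep is designed for:
#'
#' * `"piecewise"` — a low background plus 3 to 8 constant-intensity
#'   ellipses whose intensities differ from the background by at least 0.2.
#'   This emulates high-contrast, piecewise-constant CT content (e.g.
#'   calcifications, bone against soft tissue).
#' * `"smooth_textured"` — a low-frequency intensity gradient plus
#'   band-limited sinusoidal texture of amplitude at most 0.2, emulating
#'   smooth MR soft-tissue content with mild anatomical texture.
#'
#' Output is deterministic given `seed`.
#'
#' @param size Side length in pixels (square image), at least 32.
#' @param kind `"piecewise"` or `"smooth_textured"`.
#' @param seed Integer seed.
#' @return A [clean_record()] of kind `"image"` with values in `[0, 1]`.
#' @export
#' @examples
#' img <- make_phantom_image(64, "piecewise", seed = 1)
#' range(img$data)
make_phantom_image <- function(size, kind = c("piecewise", "smooth_textured"),
                               seed = 1) {
  kind <- match.arg(kind)
  if (!is_scalar_number(size) || size < 32) {
    stop("phantom size must be a single number >= 32")
  }
  size <- as.integer(size)
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size)  # row index
  img <- with_seed(seed, {
    if (kind == "piecewise") {
      background <- 0.1
      out <- matrix(background, size, size)
      n_ell <- sample(3:8, 1)
      # intensities at least 0.2 away from background and from each other's
      # floor; drawn from a coarse grid above background + 0.2
      levels_avail <- seq(background + 0.2, 0.95, by = 0.05)
      for (e in seq_len(n_ell)) {
        cx <- runif(1, 0.2, 0.8) * size
        cy <- runif(1, 0.2, 0.8) * size
        rx <- runif(1, 0.08, 0.30) * size
        ry <- runif(1, 0.08, 0.30) * size
        th <- runif(1, 0, pi)
        val <- sample(levels_avail, 1)
        xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
        yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
        inside <- (xr / rx)^2 + (yr / ry)^2 <= 1
        out[inside] <- val
      }
      out
    } else {
      u <- (xs - 1) / (size - 1)
      v <- (ys - 1) / (size - 1)
      # low-frequency gradient: oriented ramp plus a half-cycle bulge
      ang <- runif(1, 0, 2 * pi)
      ramp <- (u * cos(ang) + v * sin(ang) + 1) / 2
      bulge <- 0.25 * sin(pi * u) * sin(pi * v)
      base <- 0.3 + 0.4 * ramp + bulge
      # band-limited texture: a few mid-frequency sinusoids, amplitude <= 0.2
      tex <- matrix(0, size, size)
      n_comp <- 4L
      for (i in seq_len(n_comp)) {
        f <- runif(1, 2, 6)          # cycles across the field: low-mid band
        phi <- runif(1, 0, 2 * pi)
        th <- runif(1, 0, pi)
        tex <- tex + sin(2 * pi * f * (u * cos(th) + v * sin(th)) + phi)
      }
      tex <- tex / n_comp * 0.15
      base + tex
    }
  })
  clean_record(clip_unit(img), kind = "image",
               label = paste0(if (kind == "piecewise") "ct_like" else "mr_like",
                              "_", size),
               provenance = "synthetic")
}

#' Synthetic EMG-like burst signal
#'
#' A zero-mean broadband Gaussian carrier multiplied by a burst envelope:
#' quiet baseline interrupted by `n_bursts` active windows with raised-cosine
#' (Hann) onsets and offsets. This mimics surface-EMG recordings of
#' intermittent muscle activations. Deterministic given `seed`.
#'
#' @param n Signal length in samples, at least 64.
#' @param n_bursts Number of activation bursts, at least 1. Each burst needs
#'   a window of at least 32 samples, so `n >= 32 * n_bursts` is required.
#' @param seed Integer seed.
#' @param baseline Envelope amplitude between bursts (relative to the burst
#'   peak amplitude of 1).
#' @return A [clean_record()] of kind `"signal"`.
#' @export
make_emg_like_signal <- function(n, n_bursts = 2, seed = 1, baseline = 0.05) {
  if (!is_scalar_number(n) || n < 64) stop("signal length must be >= 64")
  if (!is_scalar_number(n_bursts) || n_bursts < 1) stop("n_bursts must be >= 1")
  n <- as.integer(n); n_bursts <- as.integer(n_bursts)
  min_window <- 32L
  if (n < min_window * n_bursts) {
    stop(n_bursts, " burst windows of ", min_window,
         " samples cannot fit in ", n, " samples")
  }
  with_seed(seed, {
    carrier <- rnorm(n)
    env <- rep(baseline, n)
    seg <- n / n_bursts
    for (b in seq_len(n_bursts)) {
      lo <- (b - 1) * seg
      width <- max(min_window, round(0.5 * seg))
      start <- round(lo + (seg - width) / 2) + 1
      idx <- start:(start + width - 1)
      # raised-cosine (Hann) burst envelope: smooth and bandlimited
      env[idx] <- pmax(env[idx],
                       0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = width))))
    }
    clean_record(carrier * env, kind = "signal", label = "emg_like",
                 provenance = "synthetic")
  })
}

#' Build a bank of synthetic gold standards
#'
#' Creates `n_images` phantom images (alternating piecewise / smooth
#' textured) followed by `n_signals` EMG-like signals. Child seeds are
#' derived deterministically from `seed` and the record index, so banks are
#' reproducible and records within a bank are distinct.
#'
#' @param n_images Number of images (>= 0).
#' @param n_signals Number of signals (>= 0).
#' @param seed Master seed.
#' @param image_size Side length of each phantom.
#' @param signal_length Length of each signal.
#' @return A list of [clean_record()] objects (images first).
#' @export
make_bank <- function(n_images, n_signals = 0, seed = 1,
                      image_size = 64, signal_length = 1024) {
  if (n_images < 0 || n_signals < 0) stop("record counts must be >= 0")
  bank <- vector("list", n_images + n_signals)
  for (i in seq_len(n_images)) {
    kind <- if (i %% 2 == 1) "piecewise" else "smooth_textured"
    bank[[i]] <- make_phantom_image(image_size, kind,
                                    seed = derive_seed(seed, 1, i))
  }
  for (i in seq_len(n_signals)) {
    bank[[n_images + i]] <- make_emg_like_signal(
      signal_length, n_bursts = 1 + (i %% 3),
      seed = derive_seed(seed, 2, i))
  }
  bank
}
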