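# Filter-bank construction for the three orthonormal wavelet families.
# Lowpass decomposition coefficients are loaded from the bundled plain-text
# table; highpass and synthesis filters follow from the quadrature-mirror
# relations of an orthogonal filter bank.

.wavemap_env <- new.env(parent = emptyenv())

filter_table <- function() {
  if (is.null(.wavemap_env$filters)) {
    path <- system.file("extdata", "wavelet_filters.txt", package = "wavemap")
    if (path == "") path <- file.path("inst", "extdata", "wavelet_filters.txt")
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    tab <- list()
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      h <- as.numeric(parts[-(1:2)])
      # minimal-norm polish: published tables satisfy sum(h) = sqrt(2) and
      # H(Nyquist) = 0 only to ~1e-12; project onto both constraints so
      # detail bands of smooth signals vanish to machine precision
      F <- length(h)
      s <- (-1)^seq_len(F)
      h <- h + (sqrt(2) - sum(h)) / F - s * sum(s * h) / F
      tab[[paste(parts[1], parts[2])]] <- h
    }
    .wavemap_env$filters <- tab
  }
  .wavemap_env$filters
}

#' Wavelet family names
#'
#' @return The three supported mother-wavelet families, in their canonical
#'   enumeration order (used for tie-breaking in recommendations).
#' @export
wavelet_families <- function() c("daubechies", "symlet", "coiflet")

#' Orthonormal analysis/synthesis filter quadruple
#'
#' Returns the four finite impulse responses of the two-channel orthogonal
#' filter bank for a given mother-wavelet family and order: decomposition
#' lowpass/highpass and reconstruction lowpass/highpass. Filters satisfy
#' `sum(dec_lo) = sqrt(2)` and `sum(dec_lo^2) = 1`; the highpass is the
#' quadrature mirror of the lowpass and the synthesis filters are the
#' time-reversed analysis filters. Filter lengths: Daubechies/Symlet order
#' `k` has `2k` taps, Coiflet order `k` has `6k` taps.
#'
#' @param family One of `"daubechies"`, `"symlet"`, `"coiflet"` (partial
#'   matching of the common abbreviations db/sym/coif is accepted).
#' @param order Integer order, 1 to 5. Orders above 5 are rejected for every
#'   family so the sweep grid stays square: 5 is the highest order available
#'   for the Coiflet family.
#' @return A list with elements `family`, `order`, `length`, `dec_lo`,
#'   `dec_hi`, `rec_lo`, `rec_hi`.
#' @export
#' @examples
#' fb <- filter_bank("daubechies", 1)
#' fb$dec_lo  # the Haar filter: c(1, 1) / sqrt(2)
filter_bank <- function(family, order) {
  family <- normalize_family(family)
  if (!is_scalar_number(order) || order != round(order) || order < 1) {
    stop("wavelet order must be a positive integer")
  }
  if (order > 5) {
    stop("order ", order, " not supported: orders are capped at 5 ",
         "(the highest available Coiflet order)")
  }
  lo <- filter_table()[[paste(family, order)]]
  if (is.null(lo)) stop("no filter for ", family, " order ", order)
  len <- length(lo)
  hi <- (-1)^(seq_len(len)) * rev(lo)   # quadrature mirror
  list(family = family, order = as.integer(order), length = len,
       dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi))
}

normalize_family <- function(family) {
  fam <- tolower(family)
  full <- wavelet_families()
  hit <- full[pmatch(fam, full)]
  if (is.na(hit)) {
    hit <- switch(fam, db = "daubechies", sym = "symlet", coif = "coiflet",
                  stop("unknown wavelet family: ", family))
  }
  hit
}

#' Wavelet sweep configuration
#'
#' Bundles one point of the sweep grid: mother-wavelet family, filter order,
#' decomposition level, and thresholding rule.
#'
#' @param family Wavelet family, see [wavelet_families()].
#' @param order Filter order, 1..5.
#' @param level Decomposition level, 1..5 by convention (any positive level
#'   is accepted; infeasible levels surface when decomposing).
#' @param threshold_rule `"universal_soft"` (default) or `"universal_hard"`.
#' @return A `wavelet_config` object.
#' @export
wavelet_config <- function(family, order, level,
                           threshold_rule = c("universal_soft", "universal_hard")) {
  threshold_rule <- match.arg(threshold_rule)
  fb <- filter_bank(family, order)   # validates family/order
  if (!is_scalar_number(level) || level != round(level) || level < 1) {
    stop("decomposition level must be a positive integer")
  }
  structure(list(family = fb$family, order = fb$order, level = as.integer(level),
                 threshold_rule = threshold_rule),
            class = "wavelet_config")
}
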