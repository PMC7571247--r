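#' Gold-standard record container
#'
#' A `clean_record` holds one gold-standard input: either a 1D signal
#' (numeric vector) or a 2D grayscale image (numeric matrix with intensities
#' in `[0, 1]`). Every downstream operation — noise injection, denoising,
#' response mapping — scores its output against such a record.
#'
#' @param data Numeric vector (signal) or matrix (image). Image values must
#'   lie in `[0, 1]`; all values must be finite. Signals must have at least
#'   64 samples, images at least 32 pixels along each side.
#' @param kind `"signal"` or `"image"`. Inferred from `data` if omitted.
#' @param label Free-text label (e.g. `"ct_like"`, `"emg_like"`).
#' @param provenance `"synthetic"` or `"file"`.
#'
#' @return An object of class `clean_record` with fields `data`, `kind`,
#'   `label` and `provenance`.
#' @export
#' @examples
#' r <- clean_record(matrix(0.5, 32, 32), label = "flat")
#' r$kind
clean_record <- function(data, kind = NULL, label = "", provenance = "synthetic") {
  if (is.null(kind)) kind <- if (is.matrix(data)) "image" else "signal"
  kind <- match.arg(kind, c("signal", "image"))
  provenance <- match.arg(provenance, c("synthetic", "file"))
  if (!is.numeric(data)) stop("record data must be numeric")
  if (!all(is.finite(data))) stop("record data must be finite")
  if (kind == "image") {
    if (!is.matrix(data)) stop("image records require a matrix")
    if (min(dim(data)) < 32) stop("image records require min(m, n) >= 32")
    if (min(data) < 0 || max(data) > 1) stop("image intensities must lie in [0, 1]")
  } else {
    data <- as.numeric(data)
    if (length(data) < 64) stop("signal records require n >= 64 samples")
  }
  structure(list(data = data, kind = kind, label = label, provenance = provenance),
            class = "clean_record")
}

#' @export
print.clean_record <- function(x, ...) {
  dims <- if (x$kind == "image") paste(dim(x$data), collapse = " x ") else length(x$data)
  cat(sprintf("<clean_record> %s [%s] label='%s' provenance=%s range=[%.4g, %.4g]\n",
              x$kind, dims, x$label, x$provenance, min(x$data), max(x$data)))
  invisible(x)
}

is_clean_record <- function(x) inherits(x, "clean_record")

# Extract the raw array from a record or pass a plain array through.
record_data <- function(x) if (is_clean_record(x)) x$data else x

# Rebuild an object of the same flavour as `template` around new data.
record_like <- function(data, template) {
  if (is_clean_record(template)) {
    out <- template
    out$data <- data
    out
  } else {
    data
  }
}

#' Read a gold-standard record from disk
#'
#' Images are read from PNG or TIFF (8/16-bit integer or 32-bit float
#' grayscale; values rescaled to `[0, 1]` by the readers). Signals are read
#' from CSV with one numeric value per row and no header.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.csv` file.
#' @param kind `"image"` or `"signal"`. Inferred from the file extension if
#'   omitted.
#' @return A [clean_record()] with `provenance = "file"`.
#' @export
load_record <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("cannot read record: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (is.null(kind)) {
    kind <- switch(ext, png = , tif = , tiff = "image", csv = "signal",
                   stop("cannot infer record kind from extension of ", path))
  }
  kind <- match.arg(kind, c("signal", "image"))
  if (kind == "image") {
    img <- switch(ext,
                  png = png::readPNG(path),
                  tif = , tiff = tiff::readTIFF(path),
                  stop("unsupported image format for ", path))
    if (length(dim(img)) == 3) {
      ch <- dim(img)[3]
      rgb <- img[, , seq_len(min(ch, 3)), drop = FALSE]
      spread <- apply(rgb, c(1, 2), function(v) diff(range(v)))
      if (max(spread) > 1e-8) stop("non-grayscale image rejected: ", path)
      img <- rgb[, , 1]
    }
    clean_record(clip_unit(img), kind = "image",
                 label = basename(path), provenance = "file")
  } else {
    lines <- readLines(path)
    if (any(!nzchar(trimws(lines)))) stop("blank line in signal CSV: ", path)
    vals <- suppressWarnings(as.numeric(lines))
    if (any(is.na(vals))) stop("non-numeric value in signal CSV: ", path)
    clean_record(vals, kind = "signal", label = basename(path), provenance = "file")
  }
}

#' Write a gold-standard record to disk
#'
#' Images go to PNG (8-bit) or TIFF (8/16-bit integer or 32-bit float; the
#' float variant is lossless for values in `[0, 1]`); signals go to CSV with
#' one value per row.
#'
#' @param record A [clean_record()] or plain array.
#' @param path Output path; the extension selects the format.
#' @param bits TIFF bit depth: 8, 16 or 32 (32 = IEEE float; ignored for
#'   PNG/CSV).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, bits = 32) {
  data <- record_data(record)
  ext <- tolower(tools::file_ext(path))
  if (is.matrix(data)) {
    switch(ext,
           png = png::writePNG(data, target = path),
           tif = , tiff = {
             if (!bits %in% c(8, 16, 32)) stop("TIFF bit depth must be 8, 16 or 32")
             tiff::writeTIFF(data, path, bits.per.sample = bits, reduce = FALSE)
           },
           stop("unsupported image output format: ", ext))
  } else {
    if (ext != "csv") stop("signals are written as CSV, got: ", ext)
    writeLines(formatC(data, digits = 17, format = "g"), path)
  }
  invisible(path)
}
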