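#' Spatial response map (level x order) for one degraded record
#'
#' Denoises `degraded` at every cell of the decomposition-level x
#' wavelet-order grid for one family, scores each result against `clean`,
#' and returns the K x N matrix of metric values — one spatial response map.
#' Settings that are infeasible for the record size (deep levels with long
#' filters) yield `NA` cells, as do cells where the metric is undefined.
#'
#' @param clean Gold-standard [clean_record()] or plain array.
#' @param degraded Degraded data of the same shape.
#' @param family Wavelet family.
#' @param metric One of [metric_names()].
#' @param K Number of decomposition levels (rows), default 5.
#' @param N Number of wavelet orders (columns), default 5.
#' @param threshold_rule Shrinkage rule, see [wavelet_config()].
#' @param adjust_low_in,adjust_high_in Intensity-adjust window applied to the
#'   denoised image before scoring (2D only). The default `(0, 1)` is the
#'   identity.
#' @param mode Boundary mode for the transform.
#' @param eta,item_id Optional annotations stored on the result.
#' @return A `spatial_response_map`: K x N numeric matrix with attributes
#'   `metric`, `family`, `eta`, `item_id`.
#' @export
spatial_map <- function(clean, degraded, family, metric = "corr", K = 5, N = 5,
                        threshold_rule = "universal_soft",
                        adjust_low_in = 0, adjust_high_in = 1,
                        mode = "symmetric", eta = NA_real_, item_id = NA) {
  metric <- match.arg(metric, metric_names())
  x_clean <- record_data(clean)
  x_deg <- record_data(degraded)
  check_same_shape(x_clean, x_deg)
  two_d <- is.matrix(x_clean)
  vals <- matrix(NA_real_, K, N,
                 dimnames = list(level = seq_len(K), order = seq_len(N)))
  for (n in seq_len(N)) {
    for (k in seq_len(K)) {
      cfg <- wavelet_config(family, n, k, threshold_rule)
      den <- tryCatch(wt_denoise(x_deg, cfg, mode),
                      wavemap_infeasible = function(e) NULL)
      if (is.null(den)) next
      if (two_d) {
        den <- clip_unit(den)
        if (adjust_low_in > 0 || adjust_high_in < 1) {
          den <- adjust_intensity(den, adjust_low_in, adjust_high_in)
        }
      }
      vals[k, n] <- evaluate_metric(metric, den, x_clean)
    }
  }
  structure(vals, class = c("spatial_response_map", "matrix"),
            metric = metric, family = normalize_family(family),
            eta = eta, item_id = item_id)
}

#' @export
print.spatial_response_map <- function(x, ...) {
  cat(sprintf("<spatial_response_map> metric=%s family=%s eta=%s\n",
              attr(x, "metric"), attr(x, "family"),
              format(attr(x, "eta"))))
  print(unclass(x)[, ])
  invisible(x)
}

# Shared sweep core: degrade each bank item at each schedule level once,
# denoise each grid cell once, and score with every requested metric.
sweep_tensors <- function(bank, family, schedule, metrics, master_seed,
                          K = 5, N = 5, threshold_rule = "universal_soft",
                          adjust = FALSE, mode = "symmetric",
                          speckle_variance = 0.05, impulse_p = 0.05,
                          gaussian_variance = 0.01, gaussian_interpret = "mean") {
  stopifnot(length(bank) >= 1)
  metrics <- vapply(metrics, function(m) match.arg(m, metric_names()), "")
  family <- normalize_family(family)
  H <- length(schedule$levels)
  J <- length(bank)
  dn <- list(level = as.character(seq_len(K)), order = as.character(seq_len(N)),
             eta = as.character(schedule$levels),
             item = as.character(seq_len(J)))
  tensors <- lapply(metrics, function(m) array(NA_real_, c(K, N, H, J),
                                               dimnames = dn))
  names(tensors) <- metrics
  for (j in seq_len(J)) {
    rec <- bank[[j]]
    x_clean <- record_data(rec)
    two_d <- is.matrix(x_clean)
    low_in <- if (adjust && two_d) {
      recommended_low_in(sub("_[0-9]+$", "", if (is_clean_record(rec)) rec$label else ""))
    } else 0
    for (i in seq_len(H)) {
      eta <- schedule$levels[i]
      deg <- record_data(composite_noise(
        x_clean, eta, seed = derive_seed(master_seed, i, j),
        speckle_variance = speckle_variance, impulse_p = impulse_p,
        gaussian_variance = gaussian_variance,
        gaussian_interpret = gaussian_interpret))
      for (n in seq_len(N)) {
        for (k in seq_len(K)) {
          cfg <- wavelet_config(family, n, k, threshold_rule)
          den <- tryCatch(wt_denoise(deg, cfg, mode),
                          wavemap_infeasible = function(e) NULL)
          if (is.null(den)) next
          if (two_d) {
            den <- clip_unit(den)
            if (low_in > 0) den <- adjust_intensity(den, low_in, 1)
          }
          for (m in metrics) {
            tensors[[m]][k, n, i, j] <- evaluate_metric(m, den, x_clean)
          }
        }
      }
    }
  }
  lapply(metrics, function(m) {
    structure(list(tensor = tensors[[m]], metric = m, family = family,
                   schedule = schedule, master_seed = master_seed,
                   item_ids = vapply(bank, function(r) {
                     if (is_clean_record(r) && nzchar(r$label)) r$label else ""
                   }, "")),
              class = "volumetric_response")
  }) |> stats::setNames(metrics)
}

#' Volumetric (4D) response tensor
#'
#' Runs the full nested sweep for one wavelet family and one metric: each
#' bank item is degraded with [composite_noise()] at every schedule
#' intensity, denoised at every (level, order) cell, and scored against its
#' gold standard. The result is the 4D response tensor with axes
#' (decomposition level, wavelet order, noise index, item index). Noise
#' seeds are derived deterministically from `(master_seed, noise index,
#' item index)`, so tensors are exactly reproducible.
#'
#' @param bank List of [clean_record()] objects (or plain arrays).
#' @param family Wavelet family.
#' @param schedule A [noise_schedule()]; defaults to the canonical schedule
#'   for the bank's record kind.
#' @param metric One of [metric_names()].
#' @param master_seed Master seed for all noise draws.
#' @param ... Further sweep options passed to the core driver:
#'   `K`, `N`, `threshold_rule`, `adjust`, `mode`, `speckle_variance`,
#'   `impulse_p`, `gaussian_variance`, `gaussian_interpret`.
#' @return A `volumetric_response` object with fields `tensor` (4D array),
#'   `metric`, `family`, `schedule`, `master_seed`, `item_ids`.
#' @export
volumetric_response <- function(bank, family, schedule = NULL, metric = "corr",
                                master_seed = 1, ...) {
  if (is.null(schedule)) {
    two_d <- is.matrix(record_data(bank[[1]]))
    schedule <- default_schedule(if (two_d) "schedule_2d" else "schedule_1d")
  }
  sweep_tensors(bank, family, schedule, metric, master_seed, ...)[[metric]]
}

#' @export
print.volumetric_response <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf(
    "<volumetric_response> metric=%s family=%s dims=[%s] (%d missing cells)\n",
    x$metric, x$family, paste(d, collapse = ", "), sum(is.na(x$tensor))))
  invisible(x)
}

as_vr_list <- function(vr) {
  if (inherits(vr, "volumetric_response")) {
    out <- list(vr); names(out) <- vr$family; return(out)
  }
  stopifnot(all(vapply(vr, inherits, TRUE, "volumetric_response")))
  names(vr) <- vapply(vr, function(v) v$family, "")
  vr
}

check_aligned <- function(vrs) {
  s0 <- vrs[[1]]$schedule$levels
  m0 <- vrs[[1]]$metric
  for (v in vrs) {
    if (!isTRUE(all.equal(v$schedule$levels, s0)) || v$metric != m0) {
      stop("volumetric responses are misaligned (schedule or metric differ)")
    }
    if (!identical(dim(v$tensor), dim(vrs[[1]]$tensor))) {
      stop("volumetric responses are misaligned (tensor shapes differ)")
    }
  }
  invisible(TRUE)
}

#' Optimal wavelet settings per noise level
#'
#' For each noise intensity, averages the response over bank items and
#' reports the best (family, order, level) cell: the maximum for `corr` /
#' `psnr`, the minimum for `mse` / `ed`. Ties are broken by lowest
#' decomposition level, then lowest order, then family enumeration order.
#'
#' @param vr A `volumetric_response`, or a list of them (one per family,
#'   aligned schedules) to recommend across families.
#' @return A `wavelet_recommendation`: data frame with one row per noise
#'   level (`eta`, `family`, `order`, `level`, `value`, `n_cells`) and the
#'   full per-eta ranking in `attr(, "ranking")`.
#' @export
best_settings <- function(vr) {
  vrs <- as_vr_list(vr)
  check_aligned(vrs)
  metric <- vrs[[1]]$metric
  higher <- metric_higher_better(metric)
  etas <- vrs[[1]]$schedule$levels
  fam_order <- intersect(wavelet_families(), names(vrs))
  rank_all <- NULL
  rows <- NULL
  for (i in seq_along(etas)) {
    cells <- NULL
    for (fam in fam_order) {
      ten <- vrs[[fam]]$tensor
      slab <- ten[, , i, , drop = FALSE]
      mean_kn <- apply(slab, c(1, 2), function(v) {
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      })
      K <- nrow(mean_kn); N <- ncol(mean_kn)
      cells <- rbind(cells, data.frame(
        eta = etas[i],
        family = fam,
        level = rep(seq_len(K), times = N),
        order = rep(seq_len(N), each = K),
        value = as.numeric(mean_kn)))
    }
    cells <- cells[!is.na(cells$value), , drop = FALSE]
    if (nrow(cells) == 0) stop("all cells missing at eta = ", etas[i])
    fam_idx <- match(cells$family, fam_order)
    ord <- order(if (higher) -cells$value else cells$value,
                 cells$level, cells$order, fam_idx)
    ranked <- cells[ord, , drop = FALSE]
    ranked$rank <- seq_len(nrow(ranked))
    rank_all <- rbind(rank_all, ranked)
    best <- ranked[1, c("eta", "family", "order", "level", "value")]
    best$n_cells <- nrow(cells)
    rows <- rbind(rows, best)
  }
  rownames(rows) <- NULL
  rownames(rank_all) <- NULL
  structure(rows, ranking = rank_all, metric = metric,
            class = c("wavelet_recommendation", "data.frame"))
}

#' Maximum-achievable-quality curve over noise intensity
#'
#' For each noise intensity, takes the best metric value over all (level,
#' order) cells *per bank item*, then aggregates over items. For `corr` this
#' is the maximum achievable correlation curve.
#'
#' @param vr A `volumetric_response`.
#' @param aggregate `"mean"` (default) or `"median"` over items.
#' @return Data frame with columns `eta` and `value` (one row per schedule
#'   level).
#' @export
max_achievable_curve <- function(vr, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(vr, "volumetric_response"))
  higher <- metric_higher_better(vr$metric)
  agg <- if (aggregate == "mean") mean else median
  etas <- vr$schedule$levels
  vals <- vapply(seq_along(etas), function(i) {
    per_item <- apply(vr$tensor[, , i, , drop = FALSE], 4, function(slab) {
      if (all(is.na(slab))) NA_real_
      else if (higher) max(slab, na.rm = TRUE) else min(slab, na.rm = TRUE)
    })
    agg(per_item, na.rm = TRUE)
  }, 0.0)
  data.frame(eta = etas, value = vals)
}

#' Per-family summary of achievable denoising quality
#'
#' Computes, for each wavelet family, the mean of the per-noise-level,
#' per-item best metric values, and each family's difference from the best
#' family mean (0 for the winning family; negative for the others when
#' higher is better, positive when lower is better).
#'
#' @param vrs List of `volumetric_response` objects, one per family, with
#'   aligned schedules, banks and metric.
#' @param aggregate Item aggregation for the underlying curve.
#' @return Data frame with one row per family: `family`, `metric`,
#'   `mean_best`, `diff_from_best`, `n_values`.
#' @export
family_summary <- function(vrs, aggregate = "mean") {
  vrs <- as_vr_list(vrs)
  check_aligned(vrs)
  metric <- vrs[[1]]$metric
  higher <- metric_higher_better(metric)
  fams <- intersect(wavelet_families(), names(vrs))
  per_family <- vapply(fams, function(fam) {
    v <- vrs[[fam]]
    vals <- apply(v$tensor, c(3, 4), function(slab) {
      if (all(is.na(slab))) NA_real_
      else if (higher) max(slab, na.rm = TRUE) else min(slab, na.rm = TRUE)
    })
    mean(vals, na.rm = TRUE)
  }, 0.0)
  best <- if (higher) max(per_family) else min(per_family)
  n_vals <- prod(dim(vrs[[1]]$tensor)[3:4])
  data.frame(family = fams, metric = metric,
             mean_best = as.numeric(per_family),
             diff_from_best = as.numeric(per_family - best),
             n_values = n_vals, row.names = NULL)
}
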