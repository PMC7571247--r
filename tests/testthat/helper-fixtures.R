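# Shared test fixtures: constructed volumetric responses and small records.

fake_vr <- function(tensor, metric = "corr", family = "daubechies",
                    levels = NULL, kind = "schedule_2d") {
  d <- dim(tensor)
  if (is.null(levels)) levels <- seq(0, 1, length.out = d[3])
  structure(list(tensor = tensor, metric = metric, family = family,
                 schedule = noise_schedule(levels, kind),
                 master_seed = 0L, item_ids = rep("", d[4])),
            class = "volumetric_response")
}

# A smooth deterministic test image (no RNG involvement).
grad_image <- function(size = 64) {
  u <- matrix(seq(0, 1, length.out = size), size, size)
  0.2 + 0.5 * u + 0.2 * t(u)
}

# Brute-force two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled observations to the two groups (independent oracle).
enumerate_mw_p <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  obs_u <- sum(rank(pool)[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) {
    sum(rank(pool)[idx]) - nx * (nx + 1) / 2
  })
  p_le <- mean(us <= obs_u)
  p_ge <- mean(us >= obs_u)
  min(1, 2 * min(p_le, p_ge))
}
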