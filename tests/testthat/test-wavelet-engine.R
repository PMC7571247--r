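test_that("filter banks are orthonormal with the standard lengths", {
  expect_equal(filter_bank("daubechies", 1)$dec_lo, c(1, 1) / sqrt(2))
  expect_length(filter_bank("coiflet", 2)$dec_lo, 12)
  for (fam in wavelet_families()) for (k in 1:5) {
    fb <- filter_bank(fam, k)
    exp_len <- if (fam == "coiflet") 6 * k else 2 * k
    expect_length(fb$dec_lo, exp_len)
    expect_lt(abs(sum(fb$dec_lo) - sqrt(2)), 1e-10)
    expect_lt(abs(sum(fb$dec_lo^2) - 1), 1e-10)
    # even-shift orthogonality and quadrature-mirror cross-orthogonality
    F <- fb$length
    if (F > 2) for (m in 1:(F / 2 - 1)) {
      expect_lt(abs(sum(fb$dec_lo[1:(F - 2 * m)] * fb$dec_lo[(1 + 2 * m):F])),
                1e-10)
    }
    expect_lt(abs(sum(fb$dec_lo * fb$dec_hi)), 1e-10)
  }
  expect_error(filter_bank("coiflet", 6), "capped at 5")
  expect_error(filter_bank("symlet", 6), "capped at 5")
})

test_that("haar details are scaled pairwise differences", {
  set.seed(1)
  x <- rnorm(64)
  p <- wt_decompose(x, wavelet_config("daubechies", 1, 1))
  expect_equal(p$details[[1]],
               (x[seq(1, 63, 2)] - x[seq(2, 64, 2)]) / sqrt(2))
})

test_that("constant signals have vanishing detail coefficients", {
  const <- rep(3.7, 256)
  for (fam in wavelet_families()) {
    p <- wt_decompose(const, wavelet_config(fam, 3, 3))
    expect_lt(max(abs(unlist(p$details))), 1e-12)
  }
})

test_that("decompose/reconstruct round-trips to machine precision", {
  set.seed(7)
  for (i in 1:10) {
    fam <- sample(wavelet_families(), 1)
    o <- sample(1:5, 1)
    x <- rnorm(sample(100:400, 1))
    cfg <- wavelet_config(fam, o, sample(1:4, 1))
    if (!feasible_level(x, cfg)) next
    expect_lt(max(abs(wt_reconstruct(wt_decompose(x, cfg)) - x)), 1e-10)
    m <- matrix(rnorm(48 * 40), 48, 40)
    cfg2 <- wavelet_config(fam, o, 2)
    if (feasible_level(m, cfg2)) {
      expect_lt(max(abs(wt_reconstruct(wt_decompose(m, cfg2)) - m)), 1e-10)
    }
  }
})

test_that("periodic-mode decomposition conserves energy", {
  set.seed(8)
  x <- rnorm(512)
  for (fam in wavelet_families()) {
    p <- wt_decompose(x, wavelet_config(fam, 5, 3), mode = "periodic")
    energy <- sum(p$approximation^2) + sum(unlist(p$details)^2)
    expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-8)
    expect_lt(max(abs(wt_reconstruct(p) - x)), 1e-10)
  }
})

test_that("infeasible levels are signalled as a typed condition", {
  x <- rnorm(32)
  # 30-tap filter: bands go 32 -> 30 -> 29, below the filter at level 3
  cfg <- wavelet_config("coiflet", 5, 3)
  expect_true(feasible_level(x, wavelet_config("coiflet", 5, 2)))
  expect_false(feasible_level(x, cfg))
  expect_error(wt_decompose(x, cfg), class = "wavemap_infeasible")
})

test_that("sigma estimation follows the MAD rule", {
  fake <- structure(list(details = list(c(-1, 1, 1, -1)), kind = "signal"),
                    class = "coef_pyramid")
  expect_equal(estimate_sigma(fake), 1 / 0.6745)
  zero <- structure(list(details = list(rep(0, 8)), kind = "signal"),
                    class = "coef_pyramid")
  expect_equal(estimate_sigma(zero), 0)
  # consistency on pure gaussian noise
  set.seed(3)
  reps <- vapply(1:20, function(i) {
    p <- wt_decompose(rnorm(4096, sd = 0.3), wavelet_config("daubechies", 4, 1))
    estimate_sigma(p) / 0.3
  }, 0.0)
  expect_gt(mean(reps), 0.95)
  expect_lt(mean(reps), 1.05)
})

test_that("universal threshold has the Donoho closed form", {
  expect_equal(universal_threshold(0, 100), 0)
  expect_lt(abs(universal_threshold(1, 2981) - 3.99997), 1e-4)
  expect_equal(universal_threshold(2.5, 500), 2.5 * universal_threshold(1, 500))
  expect_error(universal_threshold(1, 1), ">= 2")
})

test_that("shrinkage follows soft/hard rules and contracts", {
  expect_equal(soft <- sign(5) * max(abs(5) - 3, 0), 2)
  pyr <- wt_decompose(rnorm(128), wavelet_config("daubechies", 2, 2))
  s <- shrink(pyr, 3, "universal_soft")
  expect_equal(unlist(s$details),
               {d <- unlist(pyr$details); sign(d) * pmax(abs(d) - 3, 0)},
               ignore_attr = TRUE)
  h <- shrink(pyr, 3, "universal_hard")
  expect_equal(unlist(h$details),
               {d <- unlist(pyr$details); d * (abs(d) > 3)},
               ignore_attr = TRUE)
  # contraction property and T=0 identity
  expect_true(all(abs(unlist(s$details)) <= abs(unlist(pyr$details))))
  expect_identical(shrink(pyr, 0, "universal_soft")$details, pyr$details)
  expect_identical(s$approximation, pyr$approximation)
})

test_that("denoising a clean constant image is the identity", {
  img <- matrix(0.5, 64, 64)
  den <- wt_denoise(img, wavelet_config("symlet", 3, 3))
  expect_lt(max(abs(den - img)), 1e-10)
})

test_that("denoising reduces MSE on a noisy step signal", {
  step_sig <- rep(c(0.2, 0.8, 0.4, 1.0), each = 256)
  cfg <- wavelet_config("daubechies", 4, 3)
  set.seed(21)
  noisy <- step_sig + rnorm(1024, sd = 0.1)
  den <- wt_denoise(noisy, cfg)
  expect_lt(mse(den, step_sig), mse(noisy, step_sig))
  expect_identical(den, wt_denoise(noisy, cfg))
})

test_that("intensity adjustment maps the window linearly with clipping", {
  img <- matrix(c(0.45, 0.725, 1, 0.2), 2, 2)
  expect_equal(adjust_intensity(img, 0, 1), img)
  adj <- adjust_intensity(img, 0.45, 1)
  expect_equal(adj[1, 1], 0)
  expect_equal(adj[2, 1], (0.725 - 0.45) / 0.55)
  expect_equal(adj[1, 2], 1)
  expect_equal(adj[2, 2], 0)   # below the window clips to 0
  expect_error(adjust_intensity(img, 0.8, 0.5), "high_in")
  expect_equal(recommended_low_in("piecewise"), 0.45)
  expect_equal(recommended_low_in("smooth_textured"), 0.40)
  expect_equal(recommended_low_in("other"), 0.50)
})
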