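test_that("spatial map is near-perfect in the zero-noise limit", {
  # piecewise-constant gold standard: detail medians vanish, so the
  # universal threshold is 0 and denoising any cell is the identity
  sig <- rep(c(0.2, 0.7, 0.4, 0.9), each = 1024)
  for (fam in wavelet_families()) {
    sm <- spatial_map(sig, sig, fam, "mse")
    expect_true(all(!is.na(sm)))        # every cell feasible at n = 4096
    expect_true(all(sm <= 1e-6))
  }
  sm1 <- spatial_map(sig, sig, "daubechies", "mse", K = 5, N = 1)
  expect_equal(dim(unclass(sm1)), c(5, 1))
})

test_that("spatial maps are deterministic and flag infeasible cells", {
  img <- make_phantom_image(32, "piecewise", seed = 4)
  deg <- composite_noise(img, 0.2, seed = 6)
  a <- spatial_map(img, deg, "coiflet", "corr")
  b <- spatial_map(img, deg, "coiflet", "corr")
  expect_identical(unclass(a), unclass(b))
  # coif5 = 30 taps: on a 32px image levels >= 2 shrink below the filter
  expect_true(is.na(a[5, 5]))
  expect_false(is.na(a[1, 1]))
})

test_that("volumetric response has the documented axes and reproducibility", {
  bank <- make_bank(2, 0, seed = 11, image_size = 32)
  sched <- noise_schedule(c(0, 0.5, 1), "schedule_2d")
  vr <- volumetric_response(bank, "symlet", sched, "corr", master_seed = 5)
  expect_equal(dim(vr$tensor), c(5, 5, 3, 2))
  vr2 <- volumetric_response(bank, "symlet", sched, "corr", master_seed = 5)
  expect_identical(vr$tensor, vr2$tensor)
  expect_false(identical(
    vr$tensor,
    volumetric_response(bank, "symlet", sched, "corr", master_seed = 6)$tensor))
  # corr cells never exceed 1
  expect_true(all(vr$tensor[!is.na(vr$tensor)] <= 1 + 1e-12))
  # degradation: mean response at eta = 0 exceeds mean at eta = 1
  expect_gt(mean(vr$tensor[, , 1, ], na.rm = TRUE),
            mean(vr$tensor[, , 3, ], na.rm = TRUE))
})

test_that("best settings recover planted optima exhaustively", {
  base <- array(0.5, c(5, 5, 1, 1))
  for (k in 1:5) for (n in 1:5) {
    t <- base
    t[k, n, 1, 1] <- 0.9
    bs <- best_settings(fake_vr(t, levels = 0))
    expect_equal(bs$level, k)
    expect_equal(bs$order, n)
    expect_equal(bs$value, 0.9)
  }
  # |k-3|, |n-2| construction: optimum at level 3, order 2
  t <- base
  for (k in 1:5) for (n in 1:5) t[k, n, 1, 1] <- 1 - 0.01 * abs(k - 3) - 0.02 * abs(n - 2)
  bs <- best_settings(fake_vr(t, levels = 0))
  expect_equal(bs$level, 3)
  expect_equal(bs$order, 2)
  expect_equal(bs$value, 1)
})

test_that("best settings break ties toward low level then low order", {
  t <- array(0.1, c(5, 5, 1, 1))
  t[2, 3, 1, 1] <- 0.8
  t[4, 1, 1, 1] <- 0.8
  bs <- best_settings(fake_vr(t, levels = 0))
  expect_equal(bs$level, 2)
  t2 <- array(0.1, c(5, 5, 1, 1))
  t2[3, 4, 1, 1] <- 0.8
  t2[3, 2, 1, 1] <- 0.8
  expect_equal(best_settings(fake_vr(t2, levels = 0))$order, 2)
  # family order breaks remaining ties; minimisation flips the direction
  tm <- array(0.3, c(5, 5, 1, 1)); tm[4, 4, 1, 1] <- 0.01
  bs_m <- best_settings(fake_vr(tm, metric = "mse", levels = 0))
  expect_equal(c(bs_m$level, bs_m$order), c(4, 4))
})

test_that("recommendation values re-read from the tensor at their index", {
  set.seed(9)
  t <- array(runif(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  vr <- fake_vr(t, levels = c(0, 0.5, 1))
  bs <- best_settings(vr)
  for (r in seq_len(nrow(bs))) {
    i <- which(vr$schedule$levels == bs$eta[r])
    expect_equal(mean(t[bs$level[r], bs$order[r], i, ]), bs$value[r])
  }
  # single remaining cell is returned
  t_na <- array(NA_real_, c(5, 5, 1, 1))
  t_na[2, 4, 1, 1] <- 0.42
  expect_equal(best_settings(fake_vr(t_na, levels = 0))$value, 0.42)
  expect_error(best_settings(fake_vr(array(NA_real_, c(5, 5, 1, 1)), levels = 0)),
               "missing")
})

test_that("max achievable curve takes per-item optima then aggregates", {
  t <- array(NA_real_, c(2, 2, 2, 2))
  t[, , 1, 1] <- c(0.1, 0.9, 0.2, 0.3)
  t[, , 1, 2] <- c(0.5, 0.6, 0.1, 0.2)
  t[, , 2, 1] <- c(0.3, 0.2, 0.1, 0.0)
  t[, , 2, 2] <- c(0.4, 0.1, 0.1, 0.1)
  cur <- max_achievable_curve(fake_vr(t, levels = c(0, 1)))
  expect_equal(nrow(cur), 2)
  expect_equal(cur$value, c((0.9 + 0.6) / 2, (0.3 + 0.4) / 2))
  one <- fake_vr(array(0.7, c(1, 1, 1, 1)), levels = 0)
  expect_equal(max_achievable_curve(one)$value, 0.7)
  # mse flips to per-item minima
  cur_m <- max_achievable_curve(fake_vr(t, metric = "mse", levels = c(0, 1)))
  expect_equal(cur_m$value[1], (0.1 + 0.1) / 2)
})

test_that("family summaries report differences from the best family", {
  t <- array(0.8, c(5, 5, 2, 2))
  vrs <- list(fake_vr(t, family = "daubechies"),
              fake_vr(t, family = "symlet"),
              fake_vr(t + 0.01, family = "coiflet"))
  fs <- family_summary(vrs)
  expect_equal(nrow(fs), 3)
  expect_equal(fs$diff_from_best[fs$family == "coiflet"], 0)
  expect_equal(fs$diff_from_best[fs$family != "coiflet"], c(-0.01, -0.01))
  same <- family_summary(list(fake_vr(t, family = "daubechies"),
                              fake_vr(t, family = "symlet")))
  expect_true(all(same$diff_from_best == 0))
  # misaligned schedules are rejected
  bad <- fake_vr(array(0.5, c(5, 5, 3, 2)), family = "symlet")
  expect_error(family_summary(list(fake_vr(t, family = "daubechies"), bad)),
               "misaligned")
})
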