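test_that("image records round-trip through PNG and TIFF", {
  img <- make_phantom_image(48, "smooth_textured", seed = 13)
  d <- withr::local_tempdir()
  p8 <- file.path(d, "a.png")
  write_record(img, p8)
  expect_lte(max(abs(load_record(p8)$data - img$data)), 2^-8)
  p16 <- file.path(d, "a16.tif")
  write_record(img, p16, bits = 16)
  expect_lte(max(abs(load_record(p16)$data - img$data)), 2^-16)
  p32 <- file.path(d, "a32.tif")
  write_record(img, p32, bits = 32)
  expect_lte(max(abs(load_record(p32)$data - img$data)), 1e-7)
  expect_equal(load_record(p32)$provenance, "file")
})

test_that("signal CSVs round-trip and malformed inputs are rejected", {
  sig <- make_emg_like_signal(256, 2, seed = 14)
  d <- withr::local_tempdir()
  p <- file.path(d, "s.csv")
  write_record(sig, p)
  expect_equal(load_record(p)$data, sig$data, tolerance = 1e-15)
  writeLines(c("1.0", "", "2.0"), file.path(d, "blank.csv"))
  expect_error(load_record(file.path(d, "blank.csv")), "blank")
  writeLines(c("1.0", "abc"), file.path(d, "bad.csv"))
  expect_error(load_record(file.path(d, "bad.csv")), "non-numeric")
  expect_error(load_record(file.path(d, "missing.csv")), "no such file")
})

test_that("run configurations validate eagerly and round-trip as JSON", {
  cfg <- run_config(n_images = 1, metrics = c("corr", "mse"), master_seed = 4)
  d <- withr::local_tempdir()
  p <- file.path(d, "cfg.json")
  write_run_config(cfg, p)
  cfg2 <- read_run_config(p)
  expect_setequal(names(cfg2), names(cfg))
  for (f in names(cfg)) {
    if (is.numeric(cfg[[f]])) expect_equal(as.numeric(cfg2[[f]]),
                                           as.numeric(cfg[[f]]))
    else expect_equal(cfg2[[f]], cfg[[f]])
  }
  # invalid settings rejected before any computation
  expect_error(run_config(families = "nosuch"), "family")
  expect_error(run_config(N = 6), "capped at 5")
  expect_error(run_config(n_images = 0, n_signals = 0), "empty bank")
  expect_error(run_config(impulse_p = 0), "impulse_p")
})

test_that("volumetric responses persist as CSV + JSON and reload intact", {
  bank <- make_bank(1, 0, seed = 3, image_size = 32)
  vr <- volumetric_response(bank, "daubechies",
                            noise_schedule(c(0, 1), "schedule_2d"),
                            "corr", master_seed = 2)
  d <- withr::local_tempdir()
  p <- file.path(d, "t.csv")
  save_volumetric_response(vr, p)
  vr2 <- load_volumetric_response(p)
  expect_equal(vr2$tensor, vr$tensor)
  expect_equal(vr2$metric, vr$metric)
  expect_equal(vr2$schedule$levels, vr$schedule$levels)
})

test_that("sweeps persist tensors and summaries deterministically", {
  d <- withr::local_tempdir()
  cfg <- run_config(families = c("daubechies", "symlet"), metrics = "corr",
                    schedule_levels = c(0, 0.4, 0.8),
                    n_images = 1, image_size = 32, bank_seed = 7,
                    master_seed = 5, output_dir = file.path(d, "run1"))
  res <- run_sweep(cfg)
  expect_equal(dim(res$responses$daubechies$corr$tensor), c(5, 5, 3, 1))
  f1 <- file.path(d, "run1", "tensor_daubechies_corr.csv")
  expect_true(file.exists(f1))
  expect_true(file.exists(file.path(d, "run1", "recommendations.csv")))
  # rerun into a second directory: summary CSVs byte-identical
  cfg2 <- run_config(families = c("daubechies", "symlet"), metrics = "corr",
                     schedule_levels = c(0, 0.4, 0.8),
                     n_images = 1, image_size = 32, bank_seed = 7,
                     master_seed = 5, output_dir = file.path(d, "run2"))
  run_sweep(cfg2)
  for (f in c("recommendations.csv", "family_summary.csv",
              "tensor_symlet_corr.csv")) {
    expect_identical(readBin(file.path(d, "run1", f), "raw", 1e6),
                     readBin(file.path(d, "run2", f), "raw", 1e6))
  }
})

test_that("recommendation and plot layers accept sweep output", {
  bank <- make_bank(1, 0, seed = 3, image_size = 32)
  vr <- volumetric_response(bank, "daubechies",
                            noise_schedule(c(0, 0.6), "schedule_2d"),
                            "corr", master_seed = 2)
  sm <- spatial_map(bank[[1]], composite_noise(bank[[1]], 0.3, seed = 1),
                    "daubechies", "corr")
  expect_s3_class(plot_spatial_map(sm), "ggplot")
  expect_s3_class(plot_max_achievable_curve(vr), "ggplot")
})
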