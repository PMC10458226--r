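test_that("peak profiles attain half maximum at center +- fwhm/2", {
  for (shape in c("lorentzian", "gaussian")) {
    pk <- peak_model(1000, 24, 3.5, shape)
    expect_equal(eval_peak(pk, 1000), 3.5)
    expect_equal(eval_peak(pk, 1000 + 12), 3.5 / 2, tolerance = 1e-9)
    expect_equal(eval_peak(pk, 1000 - 12), 3.5 / 2, tolerance = 1e-9)
    # symmetry about the center
    x <- seq(0, 60, by = 0.7)
    expect_equal(eval_peak(pk, 1000 + x), eval_peak(pk, 1000 - x),
                 tolerance = 1e-12)
  }
  expect_error(peak_model(1000, -1, 1), "fwhm")
  expect_error(peak_model(1000, 1, -2), "amplitude")
})

test_that("class profile tables have the documented structure", {
  ch <- class_profile_table("cheese16")
  co <- class_profile_table("coffee7")
  expect_length(ch, 16)
  expect_length(co, 7)
  for (p in ch) {
    expect_length(p$libs_peaks, 5)
    expect_length(p$raman_peaks, 4)
  }
  expect_length(co[[1]]$raman_peaks, 3)
  # shared positions: classes differ only in amplitude multipliers
  centers <- function(pk) vapply(pk, `[[`, numeric(1), "center")
  expect_equal(centers(ch[[1]]$libs_peaks), centers(ch[[16]]$libs_peaks))
  expect_equal(centers(ch[[1]]$libs_peaks),
               c(388.2, 393.4, 422.7, 516.2, 588.9))
  expect_equal(centers(co[[3]]$raman_peaks), c(1440, 1570, 1650))
  expect_equal(centers(ch[[2]]$raman_peaks), c(890, 1287, 1432, 1670))
  # frozen multipliers: same seed gives identical draws
  again <- class_profile_table("cheese16")
  expect_identical(ch[[5]]$multipliers, again[[5]]$multipliers)
  expect_error(class_profile_table("custom"), "profiles")
  expect_error(sim_config("custom"), "profiles")
})

test_that("generate_dataset emits aligned, reproducible paired datasets", {
  cfg <- tiny_sim_config(replicates = 5, seed = 33)
  ds <- generate_dataset(cfg)
  expect_s3_class(ds$libs, "spectral_dataset")
  expect_equal(nrow(ds$libs$matrix), 15)
  expect_equal(nrow(ds$raman$matrix), 15)
  expect_identical(as.character(ds$libs$labels), as.character(ds$raman$labels))
  expect_equal(ncol(ds$libs$matrix), 160)
  expect_equal(ncol(ds$raman$matrix), 120)

  # pure function of the seed
  ds2 <- generate_dataset(tiny_sim_config(replicates = 5, seed = 33))
  expect_identical(ds$libs$matrix, ds2$libs$matrix)
  expect_identical(ds$raman$matrix, ds2$raman$matrix)
  ds3 <- generate_dataset(tiny_sim_config(replicates = 5, seed = 34))
  expect_false(identical(ds$libs$matrix, ds3$libs$matrix))

  # zero replicates: empty matrices with intact axes
  e <- generate_dataset(tiny_sim_config(replicates = 0))
  expect_equal(nrow(e$libs$matrix), 0)
  expect_equal(ncol(e$libs$matrix), 160)
  expect_equal(ncol(e$raman$matrix), 120)
})

test_that("noise-free spectra equal baseline plus summed peak profiles", {
  cfg <- tiny_sim_config(replicates = 1, noise_sd = 0, fluctuation_sd = 0)
  ds <- generate_dataset(cfg)
  pr <- cfg$profiles[[2]]
  manual <- Reduce(`+`, lapply(pr$libs_peaks, eval_peak,
                               x = cfg$libs_axis$values)) +
    cfg$baseline$libs_offset
  expect_equal(ds$libs$matrix[2, ], manual, tolerance = 1e-12)

  t <- (cfg$raman_axis$values - 800) / (2000 - 800)
  bl <- drop(outer(t, 0:3, `^`) %*% cfg$baseline$raman_coef)
  manual_r <- Reduce(`+`, lapply(pr$raman_peaks, eval_peak,
                                 x = cfg$raman_axis$values)) + bl
  expect_equal(ds$raman$matrix[2, ], manual_r, tolerance = 1e-12)
})

test_that("class means converge to the noise-free template", {
  cfg <- tiny_sim_config(replicates = 400, noise_sd = 0.02,
                         fluctuation_sd = 0.05, seed = 5, n_classes = 2)
  ds <- generate_dataset(cfg)
  clean <- generate_dataset(tiny_sim_config(replicates = 1, noise_sd = 0,
                                            fluctuation_sd = 0,
                                            n_classes = 2))
  sel <- ds$libs$labels == "T1"
  m <- colMeans(ds$libs$matrix[sel, ])
  tpl <- clean$libs$matrix[1, ]
  # lognormal(0, sd) has mean exp(sd^2/2); fold that into the template
  tpl_mean <- tpl * exp(0.05^2 / 2)
  se <- apply(ds$libs$matrix[sel, ], 2, sd) / sqrt(sum(sel))
  expect_true(all(abs(m - tpl_mean) < 3 * se + 1e-3 * max(tpl)))
})

test_that("multiplicative fluctuation preserves peak positions", {
  cfg <- tiny_sim_config(replicates = 6, noise_sd = 0, fluctuation_sd = 0.3,
                         seed = 9, n_classes = 2)
  ds <- generate_dataset(cfg)
  idx <- which(ds$libs$labels == "T1")
  peaks <- apply(ds$libs$matrix[idx, ], 1, which.max)
  expect_length(unique(peaks), 1)
})

test_that("simultaneous mode injects exactly the Na line into Raman", {
  base <- tiny_sim_config(replicates = 2, noise_sd = 0, fluctuation_sd = 0,
                          seed = 4)
  seq_ds <- generate_dataset(base)
  sim_cfg <- tiny_sim_config(replicates = 2, noise_sd = 0,
                             fluctuation_sd = 0, seed = 4,
                             mode = "simultaneous")
  sim_ds <- generate_dataset(sim_cfg)
  # LIBS block identical in both modes
  expect_equal(sim_ds$libs$matrix, seq_ds$libs$matrix, tolerance = 1e-12)
  diffm <- sim_ds$raman$matrix - seq_ds$raman$matrix
  pr <- base$profiles[[1]]
  na_amp <- pr$libs_peaks[[3]]$amplitude
  wl <- shift_to_wavelength(base$raman_axis$values, 532)
  expected <- eval_peak(peak_model(588.9, 0.7, na_amp, "lorentzian"), wl)
  expect_equal(diffm[1, ], expected, tolerance = 1e-12)
})

test_that("polystyrene fixture shows the canonical bands and lines", {
  fx <- ps_fixture("sequential")
  # exactly three interior local maxima on the Raman fixture
  y <- fx$raman$intensities
  lm <- which(diff(sign(diff(y))) < 0) + 1
  expect_length(lm, 3)
  expect_equal(fx$raman$axis$values[lm], c(984, 1158, 1584), tolerance = 2)

  fx2 <- ps_fixture("simultaneous")
  extra <- detect_peaks(fx2$raman, min_prominence = 0.05)
  expect_length(extra, 4)
  expect_equal(extra[4], wavelength_to_shift(588.9, 532), tolerance = 4)
})
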