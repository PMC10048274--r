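test_that("zero-analyte, zero-noise spectrum is the pure baseline curve", {
  cfg <- clean_cfg()
  wn <- seq(cfg$grid_start, cfg$grid_end, length.out = cfg$n_points)
  # independent closed-form evaluation of the configured baseline bands
  b <- cfg$baseline_bands
  expected <- Reduce(`+`, lapply(seq_len(nrow(b)), function(i)
    b$height[i] * exp(-0.5 * ((wn - b$center[i]) / b$width[i])^2)))
  expect_equal(simulate_spectrum(0, 0, cfg, 0), expected, tolerance = 1e-12)
})

test_that("absorbance is affine in concentration when noise is off", {
  cfg <- clean_cfg()
  s0 <- simulate_spectrum(0, 0, cfg, 0)
  s1 <- simulate_spectrum(25, 0, cfg, 0)
  s2 <- simulate_spectrum(50, 0, cfg, 0)
  expect_equal(s2 - s1, s1 - s0, tolerance = 1e-12)
})

test_that("a single analyte band adds the closed-form Gaussian peak", {
  cfg <- sim_config(analyte_bands = data.frame(center = 1745, width = 15,
                                               height = 0.002),
                    sigma_day = 0, sigma_noise = 0, nuisance_on = FALSE)
  wn <- seq(cfg$grid_start, cfg$grid_end, length.out = cfg$n_points)
  added <- simulate_spectrum(50, 0, cfg, 0) - simulate_spectrum(0, 0, cfg, 0)
  oracle <- 50 * 0.002 * exp(-0.5 * ((wn - 1745) / 15)^2)
  expect_equal(added, oracle, tolerance = 1e-12)
  # peak height at the band centre: 50 * 0.002 = 0.1 AU (up to grid snap)
  expect_equal(max(added), 0.1, tolerance = 5e-3)
})

test_that("negative concentrations are rejected", {
  expect_error(simulate_spectrum(-1, 0, clean_cfg()), "non-negative")
})

test_that("calibration set follows the 7-level x 15-replicate design", {
  s <- simulate_calibration_set(coarse_cfg())
  expect_equal(nrow(s$absorbance), 105)
  expect_equal(as.integer(table(s$meta$la_conc)), rep(15L, 7))
  expect_setequal(unique(s$meta$la_conc), c(1, 5, 10, 20, 50, 70, 100))
  expect_true(all(s$meta$role == "calibration"))

  one <- simulate_calibration_set(coarse_cfg(), levels = 5, replicates = 1)
  expect_equal(nrow(one$absorbance), 1)
})

test_that("identical config and seed give bit-identical spectra", {
  a <- simulate_calibration_set(coarse_cfg(seed = 7))
  b <- simulate_calibration_set(coarse_cfg(seed = 7))
  expect_identical(a$absorbance, b$absorbance)
  d <- simulate_calibration_set(coarse_cfg(seed = 8))
  expect_false(identical(a$absorbance, d$absorbance))

  v1 <- simulate_validation_set(coarse_cfg(seed = 7))
  v2 <- simulate_validation_set(coarse_cfg(seed = 7))
  expect_identical(v1$absorbance, v2$absorbance)
})

test_that("validation set is a balanced replicates x levels x days factorial", {
  s <- simulate_validation_set(coarse_cfg())
  expect_equal(nrow(s$absorbance), 45)
  counts <- table(s$meta$la_conc, s$meta$day)
  expect_true(all(counts == 3))
  expect_setequal(unique(s$meta$la_conc), c(5, 10, 20, 50, 100))
})

test_that("a dominant day effect shows up as between-day excess variance", {
  # day offsets are shared within a day, so with sigma_day >> sigma_noise the
  # one-way ANOVA of the mean absorbance on day must show MSB > MSE
  hits <- vapply(1:10, function(i) {
    cfg <- coarse_cfg(seed = i)
    cfg$sigma_day <- 0.05
    cfg$sigma_noise <- 1e-3
    cfg$nuisance_on <- FALSE
    s <- simulate_validation_set(cfg)
    m <- rowMeans(s$absorbance)
    av <- anova(lm(m ~ factor(s$meta$day)))
    av$`Mean Sq`[1] > av$`Mean Sq`[2]
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("blanks are zero-concentration spectra and need n >= 2", {
  s <- simulate_blanks(10, coarse_cfg())
  expect_equal(nrow(s$absorbance), 10)
  expect_true(all(s$meta$la_conc == 0))
  expect_true(all(s$meta$role == "blank"))
  expect_error(simulate_blanks(1, coarse_cfg()), ">= 2")

  quiet <- simulate_blanks(3, clean_cfg())
  expect_equal(quiet$absorbance[1, ], quiet$absorbance[2, ], tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("spectra round-trip through the CSV writer and reader", {
  s <- simulate_calibration_set(coarse_cfg(), levels = c(5, 50), replicates = 2)
  d <- withr::local_tempdir()
  write_spectra(s, file.path(d, "sp.csv"), file.path(d, "meta.csv"))
  r <- read_spectra(file.path(d, "sp.csv"), file.path(d, "meta.csv"))
  expect_equal(r$wavenumbers, s$wavenumbers, tolerance = 1e-6)
  expect_equal(unname(r$absorbance), unname(s$absorbance), tolerance = 1e-12)
  expect_equal(r$meta$la_conc, s$meta$la_conc)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- coarse_cfg(seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  r <- read_config(f)
  expect_s3_class(r, "mir_sim_config")
  expect_equal(r$seed, cfg$seed)
  expect_equal(r$analyte_bands, cfg$analyte_bands)
  expect_identical(simulate_blanks(2, r)$absorbance,
                   simulate_blanks(2, cfg)$absorbance)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sigma_noise = -1), "sigma")
  expect_error(sim_config(analyte_bands = data.frame(center = 1, width = 0,
                                                     height = 1)), "width")
  bad_meta <- data.frame(sample_id = "a", la_conc = 0, day = 1,
                         replicate = 1, role = "blank")
  expect_error(spectra_set(c(2, 1), matrix(0, 1, 2), bad_meta), "increasing")
  expect_error(spectra_set(c(1, 2), matrix(0, 1, 2),
                           transform(bad_meta, la_conc = 5)), "blank")
})
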