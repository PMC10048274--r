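#' Simulation configuration for synthetic milk FT-MIR spectra
#'
#' Bundles every knob of the spectra generator.  The generator is a
#' Beer-Lambert stand-in for an FT-MIR milk analyser: a fixed baseline
#' (water, lactose, protein, residual fat bands), a set of analyte bands
#' whose height is linear in the analyte concentration, a set of
#' interferent bands driven by a per-sample nuisance covariate (residual
#' fat/protein proxy), an additive per-day baseline offset, and iid
#' per-point Gaussian noise.
#'
#' The default grid has 1060 uniformly spaced points over 926--5012 cm^-1
#' (step ~3.86 cm^-1), so that the water-masked region retains roughly 520
#' points.  Band shape is Gaussian in wavenumber; `width` is the Gaussian
#' SD in cm^-1.  Analyte band heights are absorbance units (AU) per
#' mg/100 mL; all default analyte bands sit inside the fatty-acid-
#' associated regions 940--1215, 1342--1489, 1720--1766 and
#' 2823--2935 cm^-1 so that band selection has a recoverable truth.
#'
#' @param grid_start,grid_end wavenumber range, cm^-1.
#' @param n_points number of uniformly spaced grid points.
#' @param baseline_bands data frame with columns `center`, `width`,
#'   `height` (cm^-1, cm^-1, AU): concentration-independent background.
#' @param analyte_bands data frame with columns `center`, `width`,
#'   `height`; `height` is the absorbance response in AU per mg/100 mL.
#' @param interferent_bands data frame like `analyte_bands` but scaled by
#'   the per-sample nuisance covariate instead of the analyte.
#' @param sigma_day SD of the per-day additive baseline offset, AU.
#' @param sigma_noise SD of the iid per-point noise, AU.
#' @param nuisance_sdlog log-scale SD of the lognormal per-sample nuisance
#'   covariate (meanlog 0); set `nuisance_on = FALSE` to disable it.
#' @param nuisance_on logical; draw the nuisance covariate per sample?
#' @param day_effect `"additive"` (default, constant offset) or
#'   `"multiplicative"` (per-day gain `1 + offset`).
#' @param n_acquisitions acquisitions averaged per sample (instrument
#'   protocol: acquire twice, average).
#' @param seed integer master seed; identical config + seed gives
#'   bit-identical output.
#' @return an object of class `mir_sim_config`.
#' @export
sim_config <- function(grid_start = 926, grid_end = 5012, n_points = 1060,
                       baseline_bands = default_baseline_bands(),
                       analyte_bands = default_analyte_bands(),
                       interferent_bands = default_interferent_bands(),
                       sigma_day = 0.004, sigma_noise = 0.02,
                       nuisance_sdlog = 0.25, nuisance_on = TRUE,
                       day_effect = c("additive", "multiplicative"),
                       n_acquisitions = 2, seed = 1L) {
  day_effect <- match.arg(day_effect)
  stopifnot(grid_end > grid_start, n_points >= 2)
  check_bands <- function(b, nm, allow_zero_height = FALSE) {
    if (!is.data.frame(b) || !all(c("center", "width", "height") %in% names(b)))
      stop(nm, " must be a data frame with columns center, width, height")
    if (any(b$width <= 0)) stop(nm, ": widths must be > 0")
    if (any(b$height < 0)) stop(nm, ": heights must be >= 0")
    b
  }
  check_bands(baseline_bands, "baseline_bands")
  check_bands(analyte_bands, "analyte_bands")
  check_bands(interferent_bands, "interferent_bands")
  if (sigma_day < 0 || sigma_noise < 0) stop("sigma_day and sigma_noise must be >= 0")
  cfg <- list(grid_start = grid_start, grid_end = grid_end, n_points = as.integer(n_points),
              baseline_bands = baseline_bands, analyte_bands = analyte_bands,
              interferent_bands = interferent_bands,
              sigma_day = sigma_day, sigma_noise = sigma_noise,
              nuisance_sdlog = nuisance_sdlog, nuisance_on = isTRUE(nuisance_on),
              day_effect = day_effect,
              n_acquisitions = as.integer(n_acquisitions), seed = as.integer(seed))
  class(cfg) <- "mir_sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_baseline_bands <- function() {
  data.frame(center = c(1045, 1550, 1640, 2520, 2925, 3350),
             width  = c(60, 80, 120, 2000, 60, 350),
             height = c(0.45, 0.25, 1.20, 0.30, 0.15, 1.50))
}

#' @rdname sim_config
#' @export
default_analyte_bands <- function() {
  # ester C-O-C, CH bend / C=O Fermi, carbonyl stretch, acyl C-H stretches
  data.frame(center = c(1165, 1445, 1745, 2855, 2925),
             width  = c(20, 18, 14, 22, 18),
             height = c(0.0018, 0.0012, 0.0020, 0.0011, 0.0014))
}

#' @rdname sim_config
#' @export
default_interferent_bands <- function() {
  data.frame(center = c(1240, 1390, 2960),
             width  = c(35, 30, 25),
             height = c(0.020, 0.015, 0.025))
}

sim_grid <- function(cfg) seq(cfg$grid_start, cfg$grid_end, length.out = cfg$n_points)

# sum of Gaussian bands evaluated on wavenumber grid wn
gauss_bands <- function(wn, bands) {
  out <- numeric(length(wn))
  for (i in seq_len(nrow(bands)))
    out <- out + bands$height[i] * exp(-0.5 * ((wn - bands$center[i]) / bands$width[i])^2)
  out
}

#' Simulate one absorbance spectrum
#'
#' Deterministic signal plus noise:
#' `baseline + conc * analyte + nuisance * interferent + day offset + noise`.
#' With noise, nuisance and day offset all zero the spectrum is an exact
#' affine function of `conc` at every grid point.  Uses the current RNG
#' state; the set-level simulators seed it.
#'
#' @param conc analyte concentration, mg/100 mL (must be >= 0).
#' @param day_offset additive AU offset (or gain - 1 when the config uses
#'   a multiplicative day effect).
#' @param cfg a [sim_config()].
#' @param nuisance per-sample nuisance covariate value.
#' @return numeric absorbance vector of length `cfg$n_points`.
#' @export
simulate_spectrum <- function(conc, day_offset = 0, cfg = sim_config(), nuisance = 0) {
  if (!is.finite(conc) || conc < 0) stop("conc must be a finite non-negative number")
  wn <- sim_grid(cfg)
  sig <- gauss_bands(wn, cfg$baseline_bands) +
    conc * gauss_bands(wn, cfg$analyte_bands) +
    nuisance * gauss_bands(wn, cfg$interferent_bands)
  if (cfg$day_effect == "additive") sig <- sig + day_offset
  else sig <- sig * (1 + day_offset)
  sig + rnorm(length(wn), 0, cfg$sigma_noise)
}

# one sample = mean of cfg$n_acquisitions acquisitions (same signal, fresh noise)
simulate_sample <- function(conc, day_offset, cfg, nuisance) {
  acq <- replicate(cfg$n_acquisitions,
                   simulate_spectrum(conc, day_offset, cfg, nuisance))
  rowMeans(acq)
}

#' Construct a spectra set
#'
#' The container used throughout the package: a wavenumber grid, a
#' samples-by-points absorbance matrix, and per-sample metadata.
#'
#' @param wavenumbers numeric vector, cm^-1, strictly increasing.
#' @param absorbance numeric matrix, one row per sample, `length(wavenumbers)`
#'   columns, AU.
#' @param meta data frame with one row per sample; must contain columns
#'   `sample_id`, `la_conc` (mg/100 mL), `day`, `replicate`, `role`
#'   (one of calibration/validation/blank).
#' @return object of class `mir_spectra`.
#' @export
spectra_set <- function(wavenumbers, absorbance, meta) {
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance must have one column per wavenumber")
  if (nrow(absorbance) != nrow(meta))
    stop("meta must have one row per spectrum")
  need <- c("sample_id", "la_conc", "day", "replicate", "role")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta is missing columns: ", paste(miss, collapse = ", "))
  if (any(diff(wavenumbers) <= 0)) stop("wavenumbers must be strictly increasing")
  if (any(meta$la_conc < 0)) stop("la_conc must be >= 0")
  if (any(meta$role == "blank" & meta$la_conc != 0))
    stop("blank samples must have la_conc == 0")
  colnames(absorbance) <- format_wn(wavenumbers)
  rownames(absorbance) <- meta$sample_id
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 absorbance = absorbance,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE)),
            class = "mir_spectra")
}

format_wn <- function(wn) sprintf("wn_%.2f", wn)

#' @export
print.mir_spectra <- function(x, ...) {
  cat(sprintf("<mir_spectra> %d spectra x %d points, %.1f-%.1f cm^-1\n",
              nrow(x$absorbance), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$meta$role)),
                              table(x$meta$role)), collapse = " "), "\n")
  invisible(x)
}

#' Subset a spectra set
#'
#' @param x a `mir_spectra` object.
#' @param i sample (row) index.
#' @param j point (column) index, applied to both the wavenumber grid and
#'   the absorbance matrix.
#' @param ... unused.
#' @export
`[.mir_spectra` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$absorbance))
  if (missing(j)) j <- seq_along(x$wavenumbers)
  spectra_set(x$wavenumbers[j], x$absorbance[i, j, drop = FALSE],
              x$meta[i, , drop = FALSE])
}

#' Simulate the standard-addition calibration set
#'
#' Seven analyte levels (1, 5, 10, 20, 50, 70, 100 mg/100 mL) with 15
#' replicate samples each: 105 spectra, all acquired in one session (no
#' day effect); each sample is the average of two acquisitions.
#'
#' @param cfg a [sim_config()]; `cfg$seed` drives all randomness.
#' @param levels analyte concentrations, mg/100 mL.
#' @param replicates samples per level.
#' @return a [spectra_set()] with role `"calibration"`.
#' @export
simulate_calibration_set <- function(cfg = sim_config(),
                                     levels = c(1, 5, 10, 20, 50, 70, 100),
                                     replicates = 15) {
  stopifnot(replicates >= 1, length(levels) >= 1)
  with_seed(sub_seed(cfg$seed, "simulate"), {
    conc <- rep(levels, each = replicates)
    rep_id <- rep(seq_len(replicates), times = length(levels))
    nuis <- if (cfg$nuisance_on) rlnorm(length(conc), 0, cfg$nuisance_sdlog) else rep(0, length(conc))
    X <- t(vapply(seq_along(conc),
                  function(s) simulate_sample(conc[s], 0, cfg, nuis[s]),
                  numeric(cfg$n_points)))
    meta <- data.frame(sample_id = sprintf("cal_L%03d_r%02d", round(conc), rep_id),
                       la_conc = conc, day = NA_integer_, replicate = rep_id,
                       role = "calibration", nuisance = nuis,
                       stringsAsFactors = FALSE)
    spectra_set(sim_grid(cfg), X, meta)
  })
}

#' Simulate the full-factorial validation set
#'
#' Three replicates x five levels (5, 10, 20, 50, 100 mg/100 mL) x three
#' days = 45 samples.  One day offset is drawn per day and shared by all
#' samples of that day.
#'
#' @inheritParams simulate_calibration_set
#' @param levels analyte concentrations, mg/100 mL.
#' @param replicates replicates per level per day.
#' @param days number of days (series).
#' @return a [spectra_set()] with role `"validation"`.
#' @export
simulate_validation_set <- function(cfg = sim_config(),
                                    levels = c(5, 10, 20, 50, 100),
                                    replicates = 3, days = 3) {
  stopifnot(replicates >= 1, days >= 1)
  with_seed(sub_seed(cfg$seed, "day"), {
    offsets <- rnorm(days, 0, cfg$sigma_day)
    grid <- expand.grid(replicate = seq_len(replicates), la_conc = levels,
                        day = seq_len(days))
    nuis <- if (cfg$nuisance_on) rlnorm(nrow(grid), 0, cfg$nuisance_sdlog) else rep(0, nrow(grid))
    X <- t(vapply(seq_len(nrow(grid)), function(s)
      simulate_sample(grid$la_conc[s], offsets[grid$day[s]], cfg, nuis[s]),
      numeric(cfg$n_points)))
    meta <- data.frame(sample_id = sprintf("val_d%d_L%03d_r%02d", grid$day,
                                           round(grid$la_conc), grid$replicate),
                       la_conc = grid$la_conc, day = grid$day,
                       replicate = grid$replicate, role = "validation",
                       nuisance = nuis, stringsAsFactors = FALSE)
    spectra_set(sim_grid(cfg), X, meta)
  })
}

#' Simulate blank (zero-analyte) spectra
#'
#' @inheritParams simulate_calibration_set
#' @param n number of blank samples (>= 2, so that an SD is defined).
#' @return a [spectra_set()] with role `"blank"` and `la_conc == 0`.
#' @export
simulate_blanks <- function(n = 10, cfg = sim_config()) {
  if (n < 2) stop("n must be >= 2 (the blank SD is undefined otherwise)")
  with_seed(sub_seed(cfg$seed, "blank"), {
    nuis <- if (cfg$nuisance_on) rlnorm(n, 0, cfg$nuisance_sdlog) else rep(0, n)
    X <- t(vapply(seq_len(n), function(s) simulate_sample(0, 0, cfg, nuis[s]),
                  numeric(cfg$n_points)))
    meta <- data.frame(sample_id = sprintf("blank_%02d", seq_len(n)),
                       la_conc = 0, day = NA_integer_, replicate = seq_len(n),
                       role = "blank", nuisance = nuis, stringsAsFactors = FALSE)
    spectra_set(sim_grid(cfg), X, meta)
  })
}
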