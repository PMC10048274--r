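# noiseless config: deterministic signal only
clean_cfg <- function(seed = 1, ...) {
  sim_config(sigma_day = 0, sigma_noise = 0, nuisance_on = FALSE, seed = seed, ...)
}

# coarse grid for fast structural tests
coarse_cfg <- function(seed = 1, ...) sim_config(n_points = 300, seed = seed, ...)

# the worked one-level validation dataset used by several hand oracles
worked_level <- function() {
  level_data(50, rbind(c(48, 50, 52), c(47, 49, 51), c(50, 52, 54)))
}

# toy spectra set built directly (no simulator) for masking/preprocessing tests
toy_set <- function(wn = seq(900, 4500, by = 400), n = 2, seed = 1) {
  X <- with_toy_seed(seed, matrix(rnorm(n * length(wn)), n, length(wn)))
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                     la_conc = seq_len(n), day = NA_integer_,
                     replicate = seq_len(n), role = "calibration")
  spectra_set(wn, X, meta)
}

rmse_of <- function(obs, pred) sqrt(mean((obs - pred)^2))

with_toy_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
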