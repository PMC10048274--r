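#' Configuration for an end-to-end run
#'
#' Bundles the sub-configurations of every stage.  A single master seed
#' fans out to named sub-seeds (simulate / split / cv / rf / ann), so
#' each stage is independently reproducible.
#'
#' @param seed master seed.
#' @param sim a [sim_config()] (its own seed is overridden by `seed`).
#' @param algorithms,methods,grids candidate set for [grid_search()].
#' @param k,frac cross-validation folds and training fraction.
#' @param band_selection list: `enabled`, `B` (permutations), `n_trees`,
#'   `alpha`.
#' @param profile list: `beta`, `gamma`, `acceptance`.
#' @param n_blanks blank spectra used for the LOD.
#' @return object of class `mir_run_config`.
#' @export
run_config <- function(seed = 1L, sim = sim_config(),
                       algorithms = c("plsr", "pcr"),
                       methods = list_methods(), grids = default_grids(),
                       k = 10, frac = 0.8,
                       band_selection = list(enabled = TRUE, B = 200,
                                             n_trees = 500, alpha = 0.05),
                       profile = list(beta = 0.667, gamma = 0.9, acceptance = 20),
                       n_blanks = 10) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, algorithms = algorithms,
                 methods = methods, grids = grids, k = k, frac = frac,
                 band_selection = band_selection, profile = profile,
                 n_blanks = n_blanks),
            class = "mir_run_config")
}

#' Predict concentrations for a spectra set with a tuned pipeline
#'
#' Applies the winning preprocessing method, the band-selection mask (if
#' any) and the fitted model of a [grid_search()] leaderboard.
#'
#' @param object a `mir_leaderboard`.
#' @param s a [spectra_set()] on the same grid the leaderboard was tuned
#'   on.
#' @param ... unused.
#' @return numeric vector of predicted concentrations, mg/100 mL.
#' @export
predict.mir_leaderboard <- function(object, s, ...) {
  X <- apply_method(s, object$best$method)$absorbance
  if (!is.null(object$mask)) X <- X[, object$mask, drop = FALSE]
  predict(object$model, X)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline: simulate, preprocess, train, select bands,
#' validate
#'
#' Stages: (1) simulate calibration, validation and blank spectra;
#' (2) mask water regions; (3) full-spectrum cross-validated grid
#' search; (4) random-forest permutation band selection on the training
#' portion and model rebuilding on the selected points; (5) predict the
#' validation set and blanks with the selected-band winner and compute
#' the LOD, the linear profile and the accuracy profile.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory; when given, [write_report()] is
#'   called on the results.
#' @return a list of class `mir_run` with every stage's artifact.
#' @export
run_all <- function(cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "mir_run_config"))
  msg <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))

  msg("simulate", "calibration 7x15, validation 3x5x3, %d blanks (seed %d)",
      cfg$n_blanks, cfg$seed)
  cal <- stage("simulate", simulate_calibration_set(cfg$sim))
  val <- stage("simulate", simulate_validation_set(cfg$sim))
  blanks <- stage("simulate", simulate_blanks(cfg$n_blanks, cfg$sim))

  cal_m <- stage("preprocess", mask_water_regions(cal))
  val_m <- stage("preprocess", mask_water_regions(val))
  blk_m <- stage("preprocess", mask_water_regions(blanks))
  msg("preprocess", "retained %d of %d points after water masking",
      length(cal_m$wavenumbers), length(cal$wavenumbers))

  msg("train", "full-spectrum grid search: %s x %s",
      paste(cfg$algorithms, collapse = "/"), paste(cfg$methods, collapse = "/"))
  lb_full <- stage("train", grid_search(cal_m, algorithms = cfg$algorithms,
                                        methods = cfg$methods, grids = cfg$grids,
                                        k = cfg$k, frac = cfg$frac, seed = cfg$seed))

  importance <- sel <- lb_sel <- NULL
  final <- lb_full
  if (isTRUE(cfg$band_selection$enabled)) {
    bs <- cfg$band_selection
    split <- train_test_split(cal_m, cfg$frac, seed = sub_seed(cfg$seed, "split"))
    msg("select-bands", "RF permutation test: B=%d, %d trees, alpha=%g",
        bs$B, bs$n_trees, bs$alpha)
    importance <- stage("select-bands",
                        permutation_pvalues(split$train$absorbance,
                                            split$train$meta$la_conc,
                                            B = bs$B, n_trees = bs$n_trees,
                                            seed = sub_seed(cfg$seed, "rf"),
                                            alpha = bs$alpha))
    sel <- select_bands(importance, alpha = bs$alpha)
    msg("select-bands", "%d of %d points selected (%d regions)",
        sum(sel$mask), length(sel$mask), nrow(sel$regions))
    if (any(sel$mask)) {
      lb_sel <- stage("train", refit_on_selection(cal_m, sel$mask,
                                                  algorithms = cfg$algorithms,
                                                  methods = cfg$methods,
                                                  grids = cfg$grids, k = cfg$k,
                                                  frac = cfg$frac, seed = cfg$seed))
      final <- lb_sel
    }
  }

  msg("validate", "predicting validation set and blanks with %s/%s",
      final$best$algorithm, final$best$method)
  pred_val <- stage("validate", predict(final, val_m))
  pred_blank <- stage("validate", predict(final, blk_m))
  lodres <- lod(pred_blank)
  lin <- linear_profile(pred_val, val_m$meta$la_conc)
  levels <- lapply(sort(unique(val_m$meta$la_conc)), function(lv) {
    sub <- val_m$meta$la_conc == lv
    d <- val_m$meta$day[sub]; r <- val_m$meta$replicate[sub]
    Y <- matrix(NA_real_, length(unique(d)), length(unique(r)))
    Y[cbind(match(d, sort(unique(d))), match(r, sort(unique(r))))] <- pred_val[sub]
    level_data(lv, Y)
  })
  prof <- stage("validate", build_profile(levels,
                                          acceptance = cfg$profile$acceptance,
                                          beta = cfg$profile$beta,
                                          gamma = cfg$profile$gamma))
  results <- structure(list(config = cfg, seed = cfg$seed,
                            config_hash = config_hash(cfg),
                            calibration = cal, validation = val, blanks = blanks,
                            leaderboard_full = lb_full, importance = importance,
                            selection = sel, leaderboard_selected = lb_sel,
                            final = final, pred_validation = pred_val,
                            pred_blanks = pred_blank, lod = lodres,
                            linear_profile = lin, profile = prof),
                       class = "mir_run")
  if (!is.null(out_dir)) write_report(results, out_dir)
  results
}

fmt_interval <- function(l, u) sprintf("[%.2f, %.2f]", l, u)

#' Write a report bundle for a pipeline run
#'
#' Writes, under `dir`: the full and selected-band leaderboards (CSV), a
#' per-band importance CSV and a selected-regions TSV, a per-level
#' validation table (CSV, eight columns: level, mean, relative bias,
#' recovery, repeatability, intermediate precision, relative and
#' absolute tolerance limits), the accuracy profile as JSON, the run
#' configuration as YAML, and a short markdown summary.  Every artifact
#' carries the seed and the config hash.
#'
#' @param results a `mir_run` from [run_all()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  stopifnot(inherits(results, "mir_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, file, fun) { p <- file.path(dir, file); fun(obj, p); paths <<- c(paths, p); p }

  wr(results$leaderboard_full$results, "leaderboard_full.csv",
     function(o, p) write.csv(o, p, row.names = FALSE))
  if (!is.null(results$leaderboard_selected))
    wr(results$leaderboard_selected$results, "leaderboard_selected.csv",
       function(o, p) write.csv(o, p, row.names = FALSE))
  if (!is.null(results$importance))
    wr(as.data.frame(results$importance), "band_importance.csv",
       function(o, p) write.csv(o, p, row.names = FALSE))
  if (!is.null(results$selection))
    wr(results$selection$regions, "selected_regions.tsv",
       function(o, p) write.table(o, p, sep = "\t", row.names = FALSE, quote = FALSE))

  tab <- results$profile$table
  val_tab <- data.frame(level_mg_per_100mL = tab$y_r,
                        mean_mg_per_100mL = tab$mean,
                        relative_bias_pct = tab$bias_pct,
                        recovery_pct = tab$recovery_pct,
                        repeatability_pct = tab$rsd_re_pct,
                        intermediate_precision_pct = tab$rsd_ip_pct,
                        relative_tolerance_limits_pct = fmt_interval(tab$l_pct, tab$u_pct),
                        tolerance_limits_mg_per_100mL = fmt_interval(tab$l_abs, tab$u_abs))
  wr(val_tab, "validation_stats.csv",
     function(o, p) write.csv(o, p, row.names = FALSE))

  prof <- results$profile
  profile_json <- list(seed = results$seed, config_hash = results$config_hash,
                       beta = prof$beta, gamma = prof$gamma,
                       acceptance_pct = prof$acceptance,
                       lloq = prof$lloq, uloq = prof$uloq,
                       lod = results$lod$lod, s0 = results$lod$s0,
                       linear_profile = results$linear_profile,
                       levels = prof$table)
  wr(profile_json, "profile.json",
     function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA,
                                         dataframe = "columns"))
  wr(results$config, "config.yaml", write_config)

  n_sel <- if (!is.null(results$selection)) sum(results$selection$mask) else NA
  md <- c(sprintf("# Pipeline run (seed %d, config %s)", results$seed,
                  results$config_hash),
          "",
          sprintf("- Water masking retained %d points.",
                  length(results$leaderboard_full$split$train$wavenumbers)),
          if (!is.null(results$selection)) {
            if (n_sel > 0)
              sprintf("- Band selection retained %d points in %d regions.",
                      n_sel, nrow(results$selection$regions))
            else "- Band selection: no bands selected."
          },
          sprintf("- Winner: %s / %s (RMSE_P %.3f, R2_P %.4f).",
                  results$final$best$algorithm, results$final$best$method,
                  results$final$rmse_p, results$final$r2_p),
          sprintf("- LOD %.3f mg/100 mL; linear profile y = %.4fx + %.4f (R2 %.4f).",
                  results$lod$lod, results$linear_profile$slope,
                  results$linear_profile$intercept, results$linear_profile$r2),
          sprintf("- LLOQ %s, ULOQ %s mg/100 mL.",
                  ifelse(is.na(prof$lloq), "undefined", sprintf("%.2f", prof$lloq)),
                  ifelse(is.na(prof$uloq), "undefined", sprintf("%.2f", prof$uloq))))
  p <- file.path(dir, "report.md")
  writeLines(md, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read back a profile JSON written by [write_report()]
#'
#' @param file path to `profile.json`.
#' @return the profile list, with `levels` as a data frame.
#' @export
read_profile_json <- function(file) {
  out <- jsonlite::fromJSON(file)
  out$levels <- as.data.frame(out$levels)
  out
}
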