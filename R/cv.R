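#' Model specification for cross-validation
#'
#' @param algorithm `"plsr"`, `"pcr"` or `"ann"`.
#' @param n_lv latent variables / principal components (linear models).
#' @param size,decay hidden units and L2 penalty (ANN).
#' @param method preprocessing method id (see [preprocess_method()]).
#' @param seed seed used for ANN weight initialisation.
#' @return object of class `mir_spec`.
#' @export
model_spec <- function(algorithm = c("plsr", "pcr", "ann"), n_lv = NULL,
                       size = NULL, decay = NULL, method = "RAW", seed = 1) {
  algorithm <- match.arg(algorithm)
  if (algorithm %in% c("plsr", "pcr") && is.null(n_lv))
    stop("n_lv is required for ", algorithm)
  if (algorithm == "ann" && (is.null(size) || is.null(decay)))
    stop("size and decay are required for ann")
  structure(list(algorithm = algorithm, n_lv = n_lv, size = size,
                 decay = decay, method = method, seed = seed),
            class = "mir_spec")
}

fit_spec <- function(spec, X, y) {
  switch(spec$algorithm,
         plsr = fit_plsr(X, y, spec$n_lv),
         pcr = fit_pcr(X, y, spec$n_lv),
         ann = fit_ann(X, y, spec$size, spec$decay, seed = spec$seed))
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
rsq <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Random training / test split
#'
#' Test size is `round(n * (1 - frac))`, so 105 samples at `frac = 0.8`
#' give an 84 / 21 split.  Deterministic given `seed`.
#'
#' @param s a [spectra_set()].
#' @param frac training fraction, in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test` (disjoint, union = input).
#' @export
train_test_split <- function(s, frac = 0.8, seed = 1) {
  stopifnot(frac > 0, frac < 1)
  n <- nrow(s$absorbance)
  n_test <- round(n * (1 - frac))
  if (n < 2 || n_test < 1 || n_test >= n)
    stop("too few samples to split at this fraction")
  idx_test <- with_seed(seed, sort(sample.int(n, n_test)))
  list(train = s[setdiff(seq_len(n), idx_test), ], test = s[idx_test, ])
}

make_folds <- function(n, k, seed) {
  if (k > n) stop("k must not exceed the number of samples")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' k-fold cross-validation of one model specification
#'
#' Folds are drawn once from `seed`.  `rmse_cv` is the mean over folds of
#' the per-fold RMSE, `rmse_cv_sd` its SD over folds, and `r2_cv` is
#' `1 - SS_res/SS_tot` pooled over all held-out predictions.
#'
#' @param X numeric matrix, samples x points.
#' @param y response, mg/100 mL.
#' @param spec a [model_spec()].
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return object of class `mir_cv` with fields `rmse_cv`, `rmse_cv_sd`,
#'   `r2_cv`, `pred` (held-out predictions) and `spec`.
#' @export
kfold_cv <- function(X, y, spec, k = 10, seed = 1) {
  X <- as.matrix(X)
  folds <- make_folds(nrow(X), k, seed)
  pred <- numeric(length(y))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- suppressWarnings(fit_spec(spec, X[tr, , drop = FALSE], y[tr]))
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
    per_fold[f] <- rmse(y[!tr], pred[!tr])
  }
  structure(list(rmse_cv = mean(per_fold), rmse_cv_sd = sd(per_fold),
                 r2_cv = rsq(y, pred), pred = pred, spec = spec),
            class = "mir_cv")
}

# efficient CV over a whole component grid for plsr/pcr: one fit per fold
# at the maximum order, evaluated at every truncation
cv_components <- function(X, y, algorithm, comps, folds) {
  k <- max(folds)
  maxc <- max(comps)
  pred <- matrix(NA_real_, nrow(X), maxc)
  for (f in seq_len(k)) {
    tr <- folds != f
    cap <- min(maxc, sum(tr) - 1, ncol(X))
    m <- suppressWarnings(
      if (algorithm == "plsr") fit_plsr(X[tr, , drop = FALSE], y[tr], cap)
      else fit_pcr(X[tr, , drop = FALSE], y[tr], cap))
    for (a in seq_len(maxc))
      pred[!tr, a] <- predict(m, X[!tr, , drop = FALSE], n_comp = min(a, m$n_lv))
  }
  res <- lapply(comps, function(a) {
    pf <- vapply(seq_len(k), function(f) rmse(y[folds == f], pred[folds == f, a]),
                 numeric(1))
    c(rmse_cv = mean(pf), rmse_cv_sd = sd(pf), r2_cv = rsq(y, pred[, a]))
  })
  data.frame(n_lv = comps, do.call(rbind, res))
}

#' Default hyperparameter grids
#'
#' Latent variables 1..25 for PLSR and PCR; hidden-layer sizes 1..6 and
#' the decay set {0, 1e-4, 1e-3, 1e-2, 0.1, 0.2, 0.3, 0.4, 0.5} for the
#' ANN.
#' @export
default_grids <- function() {
  list(plsr = 1:25, pcr = 1:25,
       ann = expand.grid(size = 1:6,
                         decay = c(0, 1e-4, 1e-3, 1e-2, 0.1, 0.2, 0.3, 0.4, 0.5)))
}

#' Cross-validated grid search over preprocessing and model candidates
#'
#' Evaluates every (preprocessing method, algorithm, hyperparameter) cell
#' with the same fold assignment, ranks the cells by `rmse_cv`
#' (ascending), refits the winner on the full training portion and scores
#' it on the held-out test portion (`rmse_p`, `r2_p`).
#'
#' @param s a [spectra_set()] (typically the masked calibration set).
#' @param algorithms subset of `c("plsr", "pcr", "ann")`.
#' @param methods preprocessing method ids (see [list_methods()]).
#' @param grids list as in [default_grids()].
#' @param k folds.
#' @param frac training fraction for the outer split.
#' @param seed master seed (fans out to split / folds / ANN).
#' @param mask optional logical vector over grid points: preprocessing is
#'   applied on the full grid first, then only masked-in columns are used
#'   for modelling (band-selection refits).
#' @return object of class `mir_leaderboard`: `results` (ranked data
#'   frame), `best` (winning [model_spec()]), `model` (refit winner),
#'   `rmse_p`, `r2_p`, and the split.
#' @export
grid_search <- function(s, algorithms = c("plsr", "pcr"),
                        methods = list_methods(), grids = default_grids(),
                        k = 10, frac = 0.8, seed = 1, mask = NULL) {
  stopifnot(length(algorithms) >= 1, length(methods) >= 1)
  split <- train_test_split(s, frac, seed = sub_seed(seed, "split"))
  y <- split$train$meta$la_conc
  folds <- make_folds(length(y), k, sub_seed(seed, "cv"))
  rows <- list()
  for (meth in methods) {
    pre_tr <- apply_method(split$train, meth)$absorbance
    if (!is.null(mask)) pre_tr <- pre_tr[, mask, drop = FALSE]
    for (alg in algorithms) {
      if (alg %in% c("plsr", "pcr")) {
        comps <- grids[[alg]]
        comps <- comps[comps <= min(length(y) - 1, ncol(pre_tr))]
        cvres <- cv_components(pre_tr, y, alg, comps, folds)
        rows[[length(rows) + 1L]] <-
          data.frame(algorithm = alg, method = meth, n_lv = cvres$n_lv,
                     size = NA_real_, decay = NA_real_,
                     rmse_cv = cvres$rmse_cv, rmse_cv_sd = cvres$rmse_cv_sd,
                     r2_cv = cvres$r2_cv)
      } else {
        g <- grids$ann
        for (i in seq_len(nrow(g))) {
          spec <- model_spec("ann", size = g$size[i], decay = g$decay[i],
                             method = meth, seed = sub_seed(seed, "ann"))
          cvr <- kfold_cv(pre_tr, y, spec, k = k, seed = sub_seed(seed, "cv"))
          rows[[length(rows) + 1L]] <-
            data.frame(algorithm = "ann", method = meth, n_lv = NA_real_,
                       size = g$size[i], decay = g$decay[i],
                       rmse_cv = cvr$rmse_cv, rmse_cv_sd = cvr$rmse_cv_sd,
                       r2_cv = cvr$r2_cv)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$rmse_cv), ]
  rownames(results) <- NULL
  top <- results[1, ]
  best <- if (top$algorithm == "ann")
    model_spec("ann", size = top$size, decay = top$decay, method = top$method,
               seed = sub_seed(seed, "ann"))
  else model_spec(top$algorithm, n_lv = top$n_lv, method = top$method)
  pre_tr <- apply_method(split$train, best$method)$absorbance
  pre_te <- apply_method(split$test, best$method)$absorbance
  if (!is.null(mask)) {
    pre_tr <- pre_tr[, mask, drop = FALSE]
    pre_te <- pre_te[, mask, drop = FALSE]
  }
  model <- suppressWarnings(fit_spec(best, pre_tr, y))
  pred_te <- predict(model, pre_te)
  structure(list(results = results, best = best, model = model,
                 rmse_p = rmse(split$test$meta$la_conc, pred_te),
                 r2_p = rsq(split$test$meta$la_conc, pred_te),
                 pred_test = pred_te, split = split, mask = mask,
                 n_points = ncol(pre_tr), seed = seed),
            class = "mir_leaderboard")
}

#' @export
print.mir_leaderboard <- function(x, n = 5, ...) {
  cat(sprintf("<mir_leaderboard> %d candidates, winner: %s/%s (rmse_p=%.3f, r2_p=%.4f)\n",
              nrow(x$results), x$best$algorithm, x$best$method, x$rmse_p, x$r2_p))
  print(head(x$results, n))
  invisible(x)
}

#' Linear profile of predictions against reference values
#'
#' Ordinary least squares of predicted on true concentration; slope near
#' 1 and intercept near 0 indicate agreement.
#'
#' @param pred predicted concentrations.
#' @param truth reference concentrations.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
linear_profile <- function(pred, truth) {
  if (length(pred) < 3) stop("need at least 3 points")
  if (sd(truth) == 0) stop("reference concentrations are constant")
  fit <- lm(pred ~ truth)
  r2 <- if (sd(pred) == 0) 0 else cor(pred, truth)^2
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]), r2 = r2)
}
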