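#' Random-forest permutation importance of spectral points
#'
#' Fits a regression random forest (500 trees by default) and returns the
#' out-of-bag permutation importance of every grid point: the mean
#' increase in OOB mean squared error when that predictor is permuted.
#'
#' @param X numeric matrix, samples x points (>= 10 samples).
#' @param y response, mg/100 mL (must not be constant).
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return named numeric importance vector, one value per column.
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("need at least 10 samples")
  if (sd(y) == 0) stop("response is constant")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  fit <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = n_trees,
                        importance = "permutation", scale.permutation.importance = FALSE,
                        seed = seed, num.threads = 1)
  fit$variable.importance
}

#' Response-permutation p-values for band importance
#'
#' The observed importance of each point is compared against its null
#' distribution obtained by refitting the forest `B` times with the
#' response randomly permuted.  The p-value uses the add-one estimator
#' `p = (1 + #{null >= observed}) / (B + 1)`, so `p` is never zero.
#'
#' @inheritParams rf_importance
#' @param B number of response permutations (>= 20).
#' @param alpha significance level used to flag `selected`.
#' @return data frame of class `mir_importance` with columns
#'   `wavenumber` (parsed from the column names when possible, otherwise
#'   the column index), `observed_importance`, `p_value`, `selected`;
#'   attributes `n_permutations`, `n_trees`, `seed`, `alpha`.
#' @export
permutation_pvalues <- function(X, y, B = 1000, n_trees = 500, seed = 1,
                                alpha = 0.05) {
  if (B < 20) stop("B must be >= 20")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  obs <- rf_importance(X, y, n_trees, seed)
  exceed <- integer(ncol(X))
  perm_seed <- sub_seed(seed, "perm")
  perms <- with_seed(perm_seed,
                     replicate(B, sample.int(length(y)), simplify = FALSE))
  for (b in seq_len(B)) {
    null_imp <- rf_importance(X, y[perms[[b]]], n_trees,
                              seed = as.numeric(perm_seed) + b)
    exceed <- exceed + (null_imp >= obs)
  }
  p <- (1 + exceed) / (B + 1)
  wn <- suppressWarnings(as.numeric(sub("^wn_", "", colnames(X))))
  if (anyNA(wn)) wn <- seq_len(ncol(X))
  res <- data.frame(wavenumber = wn, observed_importance = unname(obs),
                    p_value = unname(p), selected = unname(p <= alpha))
  attr(res, "n_permutations") <- B
  attr(res, "n_trees") <- n_trees
  attr(res, "seed") <- seed
  attr(res, "alpha") <- alpha
  class(res) <- c("mir_importance", "data.frame")
  res
}

#' Select significant bands and merge them into regions
#'
#' Points with `p <= alpha` are selected; runs of adjacent selected grid
#' points are merged into contiguous wavenumber regions.
#'
#' @param res a [permutation_pvalues()] result.
#' @param alpha significance level.
#' @return list with `mask` (logical over points) and `regions` (data
#'   frame `start_cm1`, `end_cm1`, `n_points`).
#' @export
select_bands <- function(res, alpha = 0.05) {
  mask <- res$p_value <= alpha
  if (!any(mask)) {
    warning("no bands selected at alpha = ", alpha)
    return(list(mask = mask,
                regions = data.frame(start_cm1 = numeric(0), end_cm1 = numeric(0),
                                     n_points = integer(0))))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  regions <- data.frame(start_cm1 = res$wavenumber[starts[sel]],
                        end_cm1 = res$wavenumber[ends[sel]],
                        n_points = r$lengths[sel])
  list(mask = mask, regions = regions)
}

#' Rebuild calibration models on the selected sub-spectrum
#'
#' Reruns [grid_search()] restricted to the selected grid points.
#' Preprocessing is applied on the full grid first, then the selected
#' columns are extracted, so derivative filters never straddle the gaps
#' between selected regions.
#'
#' @param s a [spectra_set()] on the same grid the mask refers to.
#' @param mask logical vector over grid points (nonempty selection).
#' @param ... passed to [grid_search()].
#' @return a `mir_leaderboard`; its `n_points` field reports the
#'   selected-point count.
#' @export
refit_on_selection <- function(s, mask, ...) {
  if (!any(mask)) stop("mask selects no points")
  if (length(mask) != length(s$wavenumbers))
    stop("mask length does not match the grid")
  message(sprintf("refit_on_selection: %d of %d points retained",
                  sum(mask), length(mask)))
  grid_search(s, mask = mask, ...)
}
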