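#' Partial least squares regression (NIPALS)
#'
#' Single-response NIPALS PLS: components successively maximise the
#' covariance between the centred spectra and the centred response, with
#' X and y deflated after each component.  Regression coefficients for
#' every truncation 1..`n_lv` are stored, so one fit serves a whole
#' latent-variable grid.
#'
#' If `n_lv` exceeds the effective rank of the centred data the extracted
#' components are truncated with a warning.  At full rank the fitted
#' model is equivalent to ordinary least squares on the centred data.
#'
#' @param X numeric matrix, samples x points.
#' @param y numeric response, mg/100 mL.
#' @param n_lv number of latent variables to extract.
#' @return object of classes `mir_plsr`, `mir_linmod`: contains the
#'   centring vectors, weight/loading matrices and a `coefficients`
#'   matrix (points x components, cumulative).
#' @export
fit_plsr <- function(X, y, n_lv) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_lv >= 1)
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean); f <- y - y_mean
  p <- ncol(X)
  W <- P <- R <- matrix(0, p, n_lv)
  qv <- numeric(n_lv)
  B <- matrix(0, p, n_lv)
  tt1 <- NULL
  a <- 0L
  for (cmp in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tvec <- drop(E %*% w)
    tt <- sum(tvec^2)
    if (is.null(tt1)) tt1 <- tt
    if (tt < 1e-10 * tt1) break
    pv <- drop(crossprod(E, tvec)) / tt
    q <- sum(f * tvec) / tt
    E <- E - tcrossprod(tvec, pv)
    f <- f - q * tvec
    a <- cmp
    W[, a] <- w; P[, a] <- pv; qv[a] <- q
    # projection weights: r_a = w_a - sum_{b<a} (p_b' w_a) r_b
    r <- w
    if (a > 1L) for (b in seq_len(a - 1L)) r <- r - sum(P[, b] * w) * R[, b]
    R[, a] <- r
    B[, a] <- if (a == 1L) q * r else B[, a - 1L] + q * r
  }
  if (a < n_lv) {
    warning(sprintf("n_lv truncated from %d to %d (rank deficiency)", n_lv, a))
    if (a == 0L) stop("no usable latent variable: X has no variance")
    W <- W[, 1:a, drop = FALSE]; P <- P[, 1:a, drop = FALSE]
    R <- R[, 1:a, drop = FALSE]; B <- B[, 1:a, drop = FALSE]
    qv <- qv[1:a]
  }
  structure(list(algorithm = "plsr", n_lv = a, x_mean = x_mean, y_mean = y_mean,
                 weights = W, loadings = P, proj = R, yloadings = qv,
                 coefficients = B, colnames = colnames(X)),
            class = c("mir_plsr", "mir_linmod"))
}

#' Principal component regression
#'
#' PCA (mean-centred, unscaled) of the spectra followed by ordinary least
#' squares of the response on the leading `n_pc` scores.  Because scores
#' are orthogonal, coefficients for every truncation 1..`n_pc` come from
#' one decomposition.  Also reports `n_pc_95`, the smallest number of
#' components explaining at least 95 percent of the spectral variance.
#'
#' @inheritParams fit_plsr
#' @param n_pc number of principal components.
#' @return object of classes `mir_pcr`, `mir_linmod`.
#' @export
fit_pcr <- function(X, y, n_pc) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_pc >= 1)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  pos <- which(pc$sdev > 1e-10 * pc$sdev[1])
  rank <- length(pos)
  a <- min(n_pc, rank)
  if (a < n_pc) warning(sprintf("n_pc truncated from %d to %d (rank deficiency)", n_pc, a))
  Tm <- pc$x[, 1:a, drop = FALSE]
  yc <- y - mean(y)
  gam <- colSums(Tm * yc) / colSums(Tm^2)
  V <- pc$rotation[, 1:a, drop = FALSE]
  B <- V %*% (diag(a) * gam)            # per-component contribution
  B <- t(apply(B, 1, cumsum))           # cumulative coefficients
  if (a == 1L) B <- matrix(B, ncol = 1)
  varexp <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  structure(list(algorithm = "pcr", n_lv = a, x_mean = pc$center, y_mean = mean(y),
                 rotation = V, score_coef = gam, coefficients = B,
                 n_pc_95 = which(varexp >= 0.95)[1], colnames = colnames(X)),
            class = c("mir_pcr", "mir_linmod"))
}

#' Single-hidden-layer neural network calibration
#'
#' Thin wrapper around [nnet::nnet()]: inputs are standardised, the
#' response is rescaled to `[0, 1]`, the hidden layer is sigmoidal, the
#' output linear, and `decay` is the L2 weight penalty.  Training is
#' deterministic given `seed`.
#'
#' @inheritParams fit_plsr
#' @param size hidden units.
#' @param decay L2 weight penalty.
#' @param seed integer seed for the random initial weights.
#' @param maxit optimiser iteration cap.
#' @return object of class `mir_ann`.
#' @export
fit_ann <- function(X, y, size = 3, decay = 0, seed = 1, maxit = 500) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), size >= 1, decay >= 0)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd); x_sd[x_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_min <- min(y); y_rng <- max(y) - y_min
  if (y_rng == 0) y_rng <- 1
  ys <- (y - y_min) / y_rng
  fit <- with_seed(seed, nnet::nnet(Xs, ys, size = size, decay = decay,
                                    linout = TRUE, trace = FALSE, maxit = maxit,
                                    MaxNWts = (ncol(X) + 1) * size + size + 1))
  structure(list(algorithm = "ann", fit = fit, x_mean = x_mean, x_sd = x_sd,
                 y_min = y_min, y_rng = y_rng, size = size, decay = decay,
                 seed = seed, colnames = colnames(X)),
            class = "mir_ann")
}

check_grid <- function(m, X) {
  if (!is.null(m$colnames) && !is.null(colnames(X)) &&
      !identical(colnames(X), m$colnames))
    stop("prediction grid does not match the training grid/preprocessing")
  if (ncol(X) != length(m$x_mean))
    stop("prediction grid does not match the training grid/preprocessing")
}

#' Predict concentrations from a calibration model
#'
#' Predictions are not clipped; negative concentrations are reported
#' as-is.
#'
#' @param object a fitted `mir_plsr`, `mir_pcr` or `mir_ann` model.
#' @param newdata matrix on the same wavenumber grid and preprocessing as
#'   the training spectra.
#' @param n_comp number of latent variables / components to use (linear
#'   models only; default: all extracted).
#' @param ... unused.
#' @return numeric vector of concentrations, mg/100 mL.
#' @export
predict.mir_linmod <- function(object, newdata, n_comp = NULL, ...) {
  newdata <- as.matrix(newdata)
  check_grid(object, newdata)
  a <- n_comp %||% object$n_lv
  if (a < 1 || a > object$n_lv) stop("n_comp out of range")
  drop(sweep(newdata, 2, object$x_mean) %*% object$coefficients[, a]) + object$y_mean
}

#' @rdname predict.mir_linmod
#' @export
predict.mir_ann <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  check_grid(object, newdata)
  Xs <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_sd, "/")
  drop(predict(object$fit, Xs)) * object$y_rng + object$y_min
}
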