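#' Preprocessing method descriptors
#'
#' The seven standard transforms used for milk FT-MIR calibration, plus
#' the identity:
#'
#' | id      | transform                                        |
#' |---------|--------------------------------------------------|
#' | `RAW`   | none                                             |
#' | `SNV`   | standard normal variate                          |
#' | `SG`    | 11-point Savitzky--Golay smoothing               |
#' | `SG1`   | Savitzky--Golay first derivative                 |
#' | `SG2`   | Savitzky--Golay second derivative                |
#' | `S_SG`  | SNV then SG smoothing                            |
#' | `S_SG1` | SNV then SG first derivative                     |
#' | `S_SG2` | SNV then SG second derivative                    |
#'
#' When SNV and a Savitzky--Golay step are combined, SNV is applied first.
#'
#' @param id method id, one of the table above.
#' @param sg_window Savitzky--Golay window length in points (odd).
#' @param sg_polyorder local polynomial order (default 2).
#' @return an object of class `mir_method` with fields `id`, `snv`,
#'   `sg`, `deriv`, `sg_window`, `sg_polyorder`.
#' @export
preprocess_method <- function(id = c("RAW", "SNV", "SG", "SG1", "SG2",
                                     "S_SG", "S_SG1", "S_SG2"),
                              sg_window = 11, sg_polyorder = 2) {
  id <- match.arg(id)
  deriv <- c(RAW = 0, SNV = 0, SG = 0, SG1 = 1, SG2 = 2,
             S_SG = 0, S_SG1 = 1, S_SG2 = 2)[[id]]
  m <- list(id = id,
            snv = id %in% c("SNV", "S_SG", "S_SG1", "S_SG2"),
            sg = id %in% c("SG", "SG1", "SG2", "S_SG", "S_SG1", "S_SG2"),
            deriv = deriv, sg_window = as.integer(sg_window),
            sg_polyorder = as.integer(sg_polyorder))
  if (m$sg_window %% 2 == 0 || m$sg_window <= m$sg_polyorder)
    stop("sg_window must be odd and greater than sg_polyorder")
  if (m$deriv > m$sg_polyorder) stop("derivative order exceeds polynomial order")
  class(m) <- "mir_method"
  m
}

#' @rdname preprocess_method
#' @export
list_methods <- function() c("RAW", "SNV", "SG", "SG1", "SG2", "S_SG", "S_SG1", "S_SG2")

#' Mask water-dominated spectral regions
#'
#' Drops every grid point lying strictly inside any of the `omit`
#' intervals.  With the defaults (O-H bending 1618--1705 cm^-1 and O-H
#' stretching above 3025 cm^-1) the retained grid spans
#' `[926, 1618] U [1705, 3025]` cm^-1.  Sample count and metadata are
#' unchanged.
#'
#' @param s a [spectra_set()].
#' @param omit list of `c(lo, hi)` wavenumber intervals (open: points
#'   strictly between `lo` and `hi` are removed).
#' @return the masked `mir_spectra`.
#' @export
mask_water_regions <- function(s, omit = list(c(1618, 1705), c(3025, Inf))) {
  keep <- rep(TRUE, length(s$wavenumbers))
  for (iv in omit) {
    if (length(iv) != 2 || iv[2] <= iv[1]) stop("each omit interval must be c(lo, hi) with hi > lo")
    keep <- keep & !(s$wavenumbers > iv[1] & s$wavenumbers < iv[2])
  }
  if (!any(keep)) stop("masking removed every grid point")
  message(sprintf("mask_water_regions: retained %d of %d points",
                  sum(keep), length(keep)))
  s[, which(keep)]
}

#' Standard normal variate transform
#'
#' Centres and scales each spectrum to mean 0 and SD 1 (sample SD,
#' divisor n-1), removing additive offsets and multiplicative scatter:
#' `snv(a*x + b) == snv(x)` for any `a > 0`.
#'
#' @param x numeric vector (one spectrum) or matrix (one spectrum per row).
#' @return transformed vector or matrix.
#' @export
snv <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, snv)))
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("snv: zero variance spectrum")
  (x - mean(x)) / s
}

# Savitzky-Golay coefficient matrix for n points: row i holds the weights
# producing the deriv-th derivative of the local polynomial fit at point i.
# Interior points use the full centred window; points within half a window
# of either boundary use the truncated window (no padding), fitted
# off-centre at the point itself.
sg_coef_matrix <- function(n, window, polyorder, deriv, step) {
  h <- (window - 1L) %/% 2L
  C <- matrix(0, n, n)
  row_for <- function(idx, i) {
    A <- outer(idx - i, 0:polyorder, `^`)
    # derivative of the fitted polynomial at offset 0 = factorial(deriv) * coef
    (factorial(deriv) * solve(crossprod(A), t(A))[deriv + 1L, ]) / step^deriv
  }
  interior <- row_for((-h):h + (h + 1L), h + 1L)  # same weights for all interior points
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (hi - lo + 1L == window) C[i, lo:hi] <- interior
    else {
      if (hi - lo < polyorder) stop("segment too short for the polynomial order")
      C[i, lo:hi] <- row_for(lo:hi, i)
    }
  }
  C
}

#' Savitzky--Golay smoothing and derivatives
#'
#' Moving-window local least-squares polynomial filter.  Each point is
#' replaced by the order-`deriv` derivative of the polynomial fitted to
#' its window; derivatives are scaled by `1/step^deriv` so that a first
#' derivative of a straight line of slope m (in AU per cm^-1) returns m.
#' Boundary points are fitted on the truncated window rather than on
#' padded data.
#'
#' @param x numeric vector (or matrix, one spectrum per row).
#' @param window odd window length in points.
#' @param polyorder polynomial order (> deriv).
#' @param deriv derivative order 0, 1 or 2.
#' @param step grid spacing in cm^-1 used to scale derivatives.
#' @return filtered vector or matrix.
#' @export
savitzky_golay <- function(x, window = 11, polyorder = 2, deriv = 0, step = 1) {
  if (window %% 2 == 0) stop("window must be odd")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  if (window <= polyorder) stop("window must exceed polyorder")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < window) stop("input shorter than the filter window")
  C <- sg_coef_matrix(n, as.integer(window), as.integer(polyorder),
                      as.integer(deriv), step)
  if (is.matrix(x)) x %*% t(C) else drop(C %*% x)
}

# split a (possibly masked) grid into contiguous uniform-step segments
contiguous_segments <- function(wn) {
  if (length(wn) < 2) return(list(seq_along(wn)))
  step <- min(diff(wn))
  breaks <- which(diff(wn) > 1.5 * step)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(wn))
  mapply(seq, starts, ends, SIMPLIFY = FALSE)
}

#' Apply a preprocessing method to a spectra set
#'
#' Applies SNV first (when the method includes it), then the
#' Savitzky--Golay step.  On masked grids the SG filter is applied
#' separately to each contiguous segment so the window never spans a
#' masked gap.
#'
#' @param s a [spectra_set()].
#' @param m a [preprocess_method()] or a method id string.
#' @return the transformed `mir_spectra`.
#' @export
apply_method <- function(s, m) {
  if (is.character(m)) m <- preprocess_method(m)
  X <- s$absorbance
  if (m$snv) X <- snv(X)
  if (m$sg) {
    segs <- contiguous_segments(s$wavenumbers)
    for (idx in segs) {
      step <- if (length(idx) > 1) mean(diff(s$wavenumbers[idx])) else 1
      win <- m$sg_window
      if (length(idx) < win) {  # short segment: shrink the window, keep it odd
        win <- length(idx) - (1 - length(idx) %% 2)
        if (win <= m$sg_polyorder) stop("segment too short for Savitzky-Golay")
      }
      X[, idx] <- savitzky_golay(X[, idx, drop = FALSE], win, m$sg_polyorder,
                                 m$deriv, step)
    }
  }
  out <- s
  out$absorbance <- X
  out
}
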