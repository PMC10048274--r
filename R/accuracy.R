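#' Replicate-by-day measurements at one concentration level
#'
#' @param y_r theoretical (nominal) concentration, mg/100 mL (> 0).
#' @param measurements numeric matrix of back-predicted concentrations,
#'   one row per day (series), one column per within-day replicate.
#'   The design must be balanced; `m = nrow` days and `n = ncol`
#'   replicates, both >= 2.
#' @return object of class `mir_level`.
#' @export
level_data <- function(y_r, measurements) {
  measurements <- as.matrix(measurements)
  if (!is.finite(y_r) || y_r <= 0) stop("y_r must be > 0")
  if (nrow(measurements) < 2 || ncol(measurements) < 2)
    stop("need at least 2 days and 2 replicates per day")
  if (any(!is.finite(measurements))) stop("measurements must all be finite")
  structure(list(y_r = y_r, measurements = measurements,
                 m = nrow(measurements), n = ncol(measurements)),
            class = "mir_level")
}

#' Limit of detection from blank predictions
#'
#' `LOD = 3 * s0` where `s0` is the sample SD of the predicted
#' concentrations of blank samples.
#'
#' @param blank_predictions numeric vector (>= 2 values), mg/100 mL.
#' @return list with `s0` and `lod`.
#' @export
lod <- function(blank_predictions) {
  if (length(blank_predictions) < 2) stop("need at least 2 blank predictions")
  s0 <- sd(blank_predictions)
  list(s0 = s0, lod = 3 * s0)
}

#' Trueness: bias and recovery at one level
#'
#' `bias% = 100 (mean - y_r) / y_r`, `recovery% = 100 mean / y_r`; by
#' construction `recovery% - 100 == bias%`.
#'
#' @param d a [level_data()].
#' @return list with `mean`, `bias_pct`, `recovery_pct`.
#' @export
bias_recovery <- function(d) {
  ybar <- mean(d$measurements)
  list(mean = ybar, bias_pct = 100 * (ybar - d$y_r) / d$y_r,
       recovery_pct = 100 * ybar / d$y_r)
}

#' One-way variance components: between- and within-day mean squares
#'
#' Balanced one-way random-effects ANOVA with day as the grouping
#' factor: `MSB = n * sum((day mean - grand mean)^2) / (m - 1)`,
#' `MSE = sum((y - day mean)^2) / (m (n - 1))`.
#'
#' @param d a [level_data()].
#' @return list with `msb` and `mse` (squared mg/100 mL).
#' @export
anova_components <- function(d) {
  Y <- d$measurements
  di <- rowMeans(Y)
  g <- mean(Y)
  list(msb = d$n * sum((di - g)^2) / (d$m - 1),
       mse = sum((Y - di)^2) / (d$m * (d$n - 1)))
}

#' Repeatability and intermediate precision
#'
#' When `MSB > MSE`: repeatability variance is `MSE`, the between-day
#' component is `(MSB - MSE)/n`, and the intermediate-precision variance
#' is their sum (total within-laboratory variance), so `s_ip >= s_re`
#' always.  Otherwise both precisions collapse to the pooled SD of all
#' `m*n` values (divisor `mn - 1`).
#'
#' @param d a [level_data()].
#' @return list with `s_re`, `s_ip` (SDs, mg/100 mL), `sigma_b2`
#'   (between-day variance component), `msb`, `mse`.
#' @export
precision_components <- function(d) {
  av <- anova_components(d)
  if (av$msb > av$mse) {
    sb2 <- (av$msb - av$mse) / d$n
    s_re <- sqrt(av$mse)
    s_ip <- sqrt(av$mse + sb2)
  } else {
    sb2 <- 0
    s_re <- s_ip <- sqrt(sum((d$measurements - mean(d$measurements))^2) /
                           (d$m * d$n - 1))
  }
  list(s_re = s_re, s_ip = s_ip, sigma_b2 = sb2, msb = av$msb, mse = av$mse)
}

#' Shrunken between/within variance-ratio estimate
#'
#' `R' = max(0, (1/n) * (MSB / (MSE * F_q) - 1))` where `F_q` is the
#' 0.85 quantile of the F distribution with `m(n-1)` and `m-1` degrees
#' of freedom.  The ratio is set to zero unless the observed `MSB/MSE`
#' clears that quantile.
#'
#' @param msb,mse between- and within-day mean squares (`mse > 0`).
#' @param m,n days and replicates per day.
#' @return the ratio estimate `R'` (>= 0).
#' @export
r_prime <- function(msb, mse, m, n) {
  if (mse <= 0) stop("mse must be > 0")
  fq <- qf(0.85, m * (n - 1), m - 1)
  max(0, (msb / (mse * fq) - 1) / n)
}

#' Satterthwaite effective degrees of freedom
#'
#' `k = (R'+1)^2 / [ (R'+1/n)^2/(m-1) + (1-1/n)/(mn) ]`: the effective
#' degrees of freedom of the intermediate-precision variance estimate
#' `MSB/n + (1-1/n) MSE`.  Tends to `m - 1` as the between-day component
#' dominates.
#'
#' @param r_prime variance-ratio estimate (>= 0).
#' @param m,n days and replicates per day (both >= 2).
#' @return effective degrees of freedom `k > 0`.
#' @export
satterthwaite_k <- function(r_prime, m, n) {
  if (m < 2 || n < 2) stop("m and n must both be >= 2")
  if (r_prime < 0) stop("r_prime must be >= 0")
  (r_prime + 1)^2 / ((r_prime + 1 / n)^2 / (m - 1) + (1 - 1 / n) / (m * n))
}

#' Noncentrality parameter of the tolerance factor
#'
#' `lambda = sqrt((n R' + 1) / (m n (R' + 1)))`: the standardised
#' standard error of the grand mean, i.e. `lambda^2 = Var(mean) /
#' sigma_IP^2` under the one-way random-effects model.  Ranges from
#' `1/sqrt(mn)` (no day effect) to `1/sqrt(m)` (day-dominated).
#'
#' @inheritParams satterthwaite_k
#' @return `lambda > 0`.
#' @export
noncentrality_lambda <- function(r_prime, m, n) {
  if (r_prime < 0) stop("r_prime must be >= 0")
  sqrt((n * r_prime + 1) / (m * n * (r_prime + 1)))
}

#' Beta-content tolerance factor
#'
#' `chi_k = sqrt( k * Q_ncchisq(beta; df = 1, ncp = lambda^2) /
#' Q_chisq(1 - gamma; df = k) )`: the numerator is the beta quantile of
#' a noncentral chi-square with 1 degree of freedom and noncentrality
#' `lambda^2`; the denominator is the lower `(1 - gamma)` quantile of a
#' central chi-square with `k` degrees of freedom.  In the limit
#' `k -> Inf`, `lambda -> 0` the factor tends to the central normal
#' quantile `z_(1+beta)/2`.
#'
#' @param k effective degrees of freedom (> 0).
#' @param lambda noncentrality parameter.
#' @param beta content proportion, in (0, 1).
#' @param gamma confidence level, in (0, 1).
#' @return the tolerance factor `chi_k > 0`.
#' @export
tolerance_factor <- function(k, lambda, beta = 0.667, gamma = 0.9) {
  if (k <= 0) stop("k must be > 0")
  if (beta <= 0 || beta >= 1 || gamma <= 0 || gamma >= 1)
    stop("beta and gamma must lie in (0, 1)")
  sqrt(k * qchisq(beta, df = 1, ncp = lambda^2) / qchisq(1 - gamma, df = k))
}

#' Full per-level statistics
#'
#' Convenience wrapper combining trueness and precision at one level.
#'
#' @param d a [level_data()].
#' @return data frame row of class `mir_level_stats` with columns
#'   `y_r`, `mean`, `bias_pct`, `recovery_pct`, `msb`, `mse`, `s_re`,
#'   `s_ip`, `rsd_re_pct`, `rsd_ip_pct`.
#' @export
level_stats <- function(d) {
  tr <- bias_recovery(d)
  pr <- precision_components(d)
  out <- data.frame(y_r = d$y_r, mean = tr$mean, bias_pct = tr$bias_pct,
                    recovery_pct = tr$recovery_pct, msb = pr$msb, mse = pr$mse,
                    s_re = pr$s_re, s_ip = pr$s_ip,
                    rsd_re_pct = 100 * pr$s_re / d$y_r,
                    rsd_ip_pct = 100 * pr$s_ip / d$y_r)
  class(out) <- c("mir_level_stats", "data.frame")
  out
}

#' Beta-content tolerance interval at one level
#'
#' Relative limits `[L%, U%] = bias% -/+ chi_k * RSD_IP%` with
#' `RSD_IP% = 100 s_ip / y_r`; absolute limits are
#' `y_r * (1 + limit/100)`.  The interval always contains the bias and
#' degenerates to `[bias, bias]` when `s_ip = 0`.
#'
#' @param d a [level_data()].
#' @param beta content proportion.
#' @param gamma confidence level.
#' @return data frame row of class `mir_tolerance` with the level
#'   statistics plus `r_prime`, `k`, `lambda`, `chi_k`, `l_pct`,
#'   `u_pct`, `l_abs`, `u_abs`.
#' @export
tolerance_interval <- function(d, beta = 0.667, gamma = 0.9) {
  st <- level_stats(d)
  # mse == 0 (all replicate values identical within days) degenerates the
  # ratio; the interval then collapses to the bias anyway when s_ip == 0
  rp <- if (st$mse > 0) r_prime(st$msb, st$mse, d$m, d$n) else 0
  k <- satterthwaite_k(rp, d$m, d$n)
  lam <- noncentrality_lambda(rp, d$m, d$n)
  chik <- tolerance_factor(k, lam, beta, gamma)
  l_pct <- st$bias_pct - chik * st$rsd_ip_pct
  u_pct <- st$bias_pct + chik * st$rsd_ip_pct
  out <- cbind(st, data.frame(r_prime = rp, k = k, lambda = lam, chi_k = chik,
                              l_pct = l_pct, u_pct = u_pct,
                              l_abs = d$y_r * (1 + l_pct / 100),
                              u_abs = d$y_r * (1 + u_pct / 100)))
  class(out) <- c("mir_tolerance", "data.frame")
  out
}

#' Interpolated limits of quantification
#'
#' A level is valid when its relative tolerance interval lies entirely
#' inside `[-acceptance, +acceptance]`.  The LLOQ is the lowest
#' concentration at which the limits enter the acceptance band, found by
#' piecewise-linear interpolation of `L(c)` and `U(c)` between the last
#' invalid level and the first valid level of the validated run that
#' reaches the top; when the lowest level is already valid the LLOQ is
#' that level.  The ULOQ is the highest valid concentration.
#'
#' @param conc level concentrations, mg/100 mL (>= 2 distinct values).
#' @param l_pct,u_pct relative tolerance limits per level, percent.
#' @param acceptance acceptance half-width, percent.
#' @return list with `lloq`, `uloq` (NA with a warning when no level is
#'   valid) and the per-level `valid` flags.
#' @export
quantification_limits <- function(conc, l_pct, u_pct, acceptance = 20) {
  stopifnot(length(conc) >= 2, length(l_pct) == length(conc),
            length(u_pct) == length(conc))
  if (anyDuplicated(conc)) stop("level concentrations must be distinct")
  ord <- order(conc)
  conc <- conc[ord]; l_pct <- l_pct[ord]; u_pct <- u_pct[ord]
  valid <- l_pct >= -acceptance & u_pct <= acceptance
  if (!any(valid)) {
    warning("no level has its tolerance interval inside the acceptance limits")
    return(list(lloq = NA_real_, uloq = NA_real_, valid = valid[order(ord)]))
  }
  uloq <- max(conc[valid])
  # first level of the contiguous valid run ending at the ULOQ
  i_top <- max(which(valid))
  i_lo <- i_top
  while (i_lo > 1 && valid[i_lo - 1]) i_lo <- i_lo - 1
  if (i_lo == 1) lloq <- conc[1]
  else {
    c0 <- conc[i_lo - 1]; c1 <- conc[i_lo]
    cross <- numeric(0)
    if (u_pct[i_lo - 1] > acceptance)
      cross <- c(cross, c0 + (u_pct[i_lo - 1] - acceptance) /
                   (u_pct[i_lo - 1] - u_pct[i_lo]) * (c1 - c0))
    if (l_pct[i_lo - 1] < -acceptance)
      cross <- c(cross, c0 + (l_pct[i_lo - 1] + acceptance) /
                   (l_pct[i_lo - 1] - l_pct[i_lo]) * (c1 - c0))
    lloq <- if (length(cross)) max(cross) else conc[i_lo]
  }
  list(lloq = lloq, uloq = uloq, valid = valid[order(ord)])
}

#' Build the accuracy profile
#'
#' Computes the beta-content tolerance interval at every level, flags
#' levels whose interval lies inside the acceptance band and levels
#' whose intermediate-precision CV exceeds 20 percent, and interpolates
#' the LLOQ / ULOQ.
#'
#' @param levels list of [level_data()] objects with distinct `y_r`.
#' @param acceptance acceptance half-width, percent.
#' @param beta content proportion.
#' @param gamma confidence level.
#' @return object of class `mir_profile`: `table` (per-level statistics
#'   and limits, ordered by concentration), `lloq`, `uloq`, `beta`,
#'   `gamma`, `acceptance`.
#' @export
build_profile <- function(levels, acceptance = 20, beta = 0.667, gamma = 0.9) {
  if (length(levels) < 2) stop("need at least 2 levels")
  tab <- do.call(rbind, lapply(levels, tolerance_interval, beta = beta, gamma = gamma))
  if (anyDuplicated(tab$y_r)) stop("levels must have distinct y_r")
  tab <- tab[order(tab$y_r), ]
  rownames(tab) <- NULL
  ql <- quantification_limits(tab$y_r, tab$l_pct, tab$u_pct, acceptance)
  tab$valid <- ql$valid
  tab$cv_flag <- tab$rsd_ip_pct > 20
  structure(list(table = tab, lloq = ql$lloq, uloq = ql$uloq,
                 beta = beta, gamma = gamma, acceptance = acceptance),
            class = "mir_profile")
}

#' @export
print.mir_profile <- function(x, ...) {
  cat(sprintf("<mir_profile> beta=%.3f gamma=%.2f acceptance=+/-%g%%  LLOQ=%s ULOQ=%s\n",
              x$beta, x$gamma, x$acceptance,
              ifelse(is.na(x$lloq), "NA", sprintf("%.2f", x$lloq)),
              ifelse(is.na(x$uloq), "NA", sprintf("%.2f", x$uloq))))
  print(x$table[, c("y_r", "mean", "bias_pct", "recovery_pct", "rsd_re_pct",
                    "rsd_ip_pct", "l_pct", "u_pct", "valid")], digits = 4)
  invisible(x)
}

#' Monte-Carlo check of the tolerance-interval confidence
#'
#' Simulates balanced one-way random-effects datasets
#' (`Y_ij = mu + B_i + E_ij`), builds the beta-content tolerance
#' interval for each, computes the true content (the mass of
#' `N(mu, sigma_b^2 + sigma_e^2)` inside the absolute interval) and
#' returns the fraction of datasets whose content reaches `beta` - the
#' empirical confidence, to be compared with the nominal `gamma`.
#'
#' @param m,n days and replicates per day.
#' @param sigma_b,sigma_e between-day and within-day SDs.
#' @param mu true mean (used as the nominal value).
#' @param beta,gamma tolerance-interval parameters.
#' @param n_sims number of simulated datasets (>= 200).
#' @param seed integer seed.
#' @return list with `confidence` (empirical) and `content` (per-dataset
#'   vector).
#' @export
coverage_simulation <- function(m = 3, n = 3, sigma_b = 1, sigma_e = 1,
                                mu = 50, beta = 0.667, gamma = 0.9,
                                n_sims = 2000, seed = 1) {
  if (n_sims < 200) stop("n_sims must be >= 200")
  sigma_tot <- sqrt(sigma_b^2 + sigma_e^2)
  content <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
    if (sigma_tot == 0) return(1)  # degenerate model: every value equals mu
    Y <- matrix(mu + rep(rnorm(m, 0, sigma_b), each = n) + rnorm(m * n, 0, sigma_e),
                nrow = m, byrow = TRUE)
    ti <- tolerance_interval(level_data(mu, Y), beta, gamma)
    pnorm((ti$u_abs - mu) / sigma_tot) - pnorm((ti$l_abs - mu) / sigma_tot)
  }, numeric(1)))
  list(confidence = mean(content >= beta), content = content)
}
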