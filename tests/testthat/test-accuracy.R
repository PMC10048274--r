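test_that("limit of detection is three blank SDs", {
  expect_equal(lod(rep(2, 5))$lod, 0)
  r <- lod(c(0, 1, 2, 3, 4))
  expect_equal(r$s0, sd(c(0, 1, 2, 3, 4)))          # hand: sqrt(10/4) = 1.5811
  expect_equal(r$lod, 3 * sqrt(2.5), tolerance = 1e-12)
  expect_equal(lod(2 * c(0, 1, 2, 3, 4))$lod, 2 * r$lod, tolerance = 1e-12)
  expect_error(lod(1), "at least 2")
})

test_that("bias and recovery are consistent percentages of the nominal value", {
  d <- level_data(20, matrix(20.43, 3, 3))
  br <- bias_recovery(d)
  expect_equal(br$bias_pct, 2.15, tolerance = 1e-10)
  expect_equal(br$recovery_pct, 102.15, tolerance = 1e-10)
  exact <- bias_recovery(level_data(50, matrix(50, 2, 2)))
  expect_equal(exact$bias_pct, 0)
  expect_equal(exact$recovery_pct, 100)
  # recovery - 100 == bias at machine precision on random data
  for (i in 1:5) {
    d <- level_data(7, matrix(with_toy_seed(i, rnorm(9, 7, 2)), 3, 3))
    br <- bias_recovery(d)
    expect_equal(br$recovery_pct - 100, br$bias_pct, tolerance = 1e-12)
  }
  expect_error(level_data(0, matrix(1, 2, 2)), "y_r")
})

test_that("one-way mean squares match hand ANOVA and the SS identity", {
  d <- level_data(4, rbind(c(1, 3), c(5, 7)))
  av <- anova_components(d)
  expect_equal(av$mse, 2)
  expect_equal(av$msb, 16)
  zero <- anova_components(level_data(5, matrix(5, 3, 3)))
  expect_equal(zero$msb, 0)
  expect_equal(zero$mse, 0)
  # SSB + SSE equals the total sum of squares
  Y <- matrix(with_toy_seed(1, rnorm(9, 10, 2)), 3, 3)
  d <- level_data(10, Y)
  av <- anova_components(d)
  ssb <- av$msb * (d$m - 1); sse <- av$mse * d$m * (d$n - 1)
  expect_equal(ssb + sse, sum((Y - mean(Y))^2), tolerance = 1e-10)
})

test_that("precision components follow the two-branch variance decomposition", {
  # MSB = 16, MSE = 2, n = 2: s_re = sqrt(2), sigma_b2 = 7, s_ip = 3
  pr <- precision_components(level_data(4, rbind(c(1, 3), c(5, 7))))
  expect_equal(pr$s_re, sqrt(2), tolerance = 1e-12)
  expect_equal(pr$sigma_b2, 7, tolerance = 1e-12)
  expect_equal(pr$s_ip, 3, tolerance = 1e-12)
  # MSB <= MSE collapses both to the pooled SD
  Y <- rbind(c(1, 9), c(4, 6))                       # day means equal -> MSB = 0
  pr2 <- precision_components(level_data(5, Y))
  expect_equal(pr2$s_re, pr2$s_ip)
  expect_equal(pr2$s_ip, sd(as.vector(Y)), tolerance = 1e-12)
  # s_ip >= s_re by construction, random cases
  for (i in 1:10) {
    pr3 <- precision_components(
      level_data(10, matrix(with_toy_seed(i, rnorm(12, 10)), 3, 4)))
    expect_gte(pr3$s_ip, pr3$s_re)
  }
})

test_that("with no true day effect the two precisions converge", {
  Y <- matrix(with_toy_seed(42, rnorm(400, 50, 2)), 20, 20)
  pr <- precision_components(level_data(50, Y))
  expect_lt(pr$s_ip / pr$s_re, 1.1)
})

test_that("the variance-ratio estimate truncates at zero", {
  expect_equal(r_prime(2, 4, 3, 3), 0)               # MSB <= MSE
  fq <- qf(0.85, 6, 2)
  expect_equal(r_prime(0.9 * fq, 1, 3, 3), 0)        # MSB/MSE below the quantile
  # hand formula at MSB/MSE = 20
  expect_equal(r_prime(20, 1, 3, 3), (20 / fq - 1) / 3, tolerance = 1e-12)
  expect_error(r_prime(1, 0, 3, 3), "mse")
})

test_that("the effective df formula is the generic Satterthwaite df", {
  expect_equal(satterthwaite_k(0, 3, 3), 1 / ((1 / 9) / 2 + (2 / 3) / 9),
               tolerance = 1e-12)                    # 7.7142857
  # R' -> Inf limit is m - 1
  expect_equal(satterthwaite_k(1e9, 4, 3), 3, tolerance = 1e-6)
  # random triples against the generic two-mean-squares Satterthwaite formula
  for (i in 1:20) {
    r <- with_toy_seed(i, runif(1, 0, 5))
    m <- with_toy_seed(i + 100, sample(2:8, 1))
    n <- with_toy_seed(i + 200, sample(2:8, 1))
    msb <- n * r + 1; mse <- 1                        # expected mean squares
    sip2 <- msb / n + (1 - 1 / n) * mse
    generic <- sip2^2 / ((msb / n)^2 / (m - 1) +
                           ((1 - 1 / n) * mse)^2 / (m * (n - 1)))
    expect_equal(satterthwaite_k(r, m, n), generic, tolerance = 1e-10)
  }
})

test_that("the noncentrality parameter is the standardised SE of the mean", {
  expect_equal(noncentrality_lambda(0, 3, 3), 1 / 3, tolerance = 1e-12)
  expect_equal(noncentrality_lambda(1e12, 5, 3), 1 / sqrt(5), tolerance = 1e-6)
  # analytic identity: lambda^2 = Var(mean)/sigma_IP^2 at ratio R
  for (r in c(0.3, 1, 4)) for (m in 2:4) for (n in 2:4) {
    var_mean <- r / m + 1 / (m * n)                  # sigma_e^2 = 1
    expect_equal(noncentrality_lambda(r, m, n)^2, var_mean / (r + 1),
                 tolerance = 1e-12)
  }
})

test_that("the tolerance factor approaches the normal quantile in the limit", {
  expect_equal(tolerance_factor(1e8, 1e-9, 0.667, 0.9), qnorm((1 + 0.667) / 2),
               tolerance = 1e-3)
  # gamma = 0.5 at large k: denominator quantile ~ k
  expect_equal(tolerance_factor(1e6, 0.2, 0.667, 0.5),
               sqrt(qchisq(0.667, 1, ncp = 0.04)), tolerance = 1e-3)
  expect_error(tolerance_factor(-1, 0.1), "k must")
  expect_error(tolerance_factor(5, 0.1, beta = 1.2), "beta")
})

test_that("the tolerance factor is monotone in gamma and lambda, antitone in k", {
  ks <- c(2, 5, 10, 30, 100)
  lams <- seq(0.05, 0.6, length.out = 5)
  gams <- seq(0.5, 0.95, length.out = 5)
  for (k in ks) for (l in lams)
    expect_true(all(diff(sapply(gams, function(g) tolerance_factor(k, l, 0.667, g))) > 0))
  for (k in ks) for (g in gams)
    expect_true(all(diff(sapply(lams, function(l) tolerance_factor(k, l, 0.667, g))) > 0))
  for (l in lams) for (g in gams)
    expect_true(all(diff(sapply(ks, function(k) tolerance_factor(k, l, 0.667, g))) < 0))
})

test_that("the full tolerance-interval chain matches a step-by-step hand oracle", {
  ti <- tolerance_interval(worked_level())
  # independent arithmetic: day means 50, 49, 52; grand mean 50.333
  msb <- 3 * sum((c(50, 49, 52) - 151 / 3)^2) / 2    # 7
  mse <- (8 + 8 + 8) / 6                             # 4
  expect_equal(ti$msb, msb, tolerance = 1e-12)
  expect_equal(ti$mse, mse, tolerance = 1e-12)
  sip <- sqrt(mse + (msb - mse) / 3)                 # sqrt(5)
  rp <- max(0, (msb / (mse * qf(0.85, 6, 2)) - 1) / 3)   # 0: ratio below Fq
  expect_equal(ti$r_prime, rp)
  k <- (rp + 1)^2 / ((rp + 1 / 3)^2 / 2 + (2 / 3) / 9)
  lam <- sqrt((3 * rp + 1) / (9 * (rp + 1)))
  chik <- sqrt(k * qchisq(0.667, 1, ncp = lam^2) / qchisq(0.1, k))
  bias <- 100 * (151 / 3 - 50) / 50
  rsd <- 100 * sip / 50
  expect_equal(ti$chi_k, chik, tolerance = 1e-12)
  expect_equal(ti$l_pct, bias - chik * rsd, tolerance = 1e-12)
  expect_equal(ti$u_pct, bias + chik * rsd, tolerance = 1e-12)
  expect_equal(ti$l_abs, 50 * (1 + ti$l_pct / 100), tolerance = 1e-12)
})

test_that("tolerance intervals contain the bias and degenerate when s_ip = 0", {
  same <- tolerance_interval(level_data(10, matrix(11, 3, 3)))
  expect_equal(same$l_pct, same$bias_pct)
  expect_equal(same$u_pct, same$bias_pct)
  for (i in 1:5) {
    ti <- tolerance_interval(level_data(20, matrix(with_toy_seed(i, rnorm(9, 20, 2)), 3, 3)))
    expect_lte(ti$l_pct, ti$bias_pct)
    expect_gte(ti$u_pct, ti$bias_pct)
  }
})

test_that("interval width grows with the confidence level", {
  d <- worked_level()
  w <- sapply(c(0.5, 0.8, 0.9, 0.99), function(g) {
    ti <- tolerance_interval(d, gamma = g)
    ti$u_pct - ti$l_pct
  })
  expect_true(all(diff(w) > 0))
})

test_that("quantification limits interpolate the acceptance crossings", {
  # all levels valid: LLOQ is the lowest, ULOQ the highest level
  ql <- quantification_limits(c(5, 10, 20), c(-5, -3, -2), c(5, 3, 2))
  expect_equal(ql$lloq, 5)
  expect_equal(ql$uloq, 20)
  # constructed crossing: U(c) linear from 30 at c=10 to 10 at c=20 crosses
  # +20 exactly at c = 15
  ql2 <- quantification_limits(c(10, 20), c(-5, -5), c(30, 10))
  expect_equal(ql2$lloq, 15, tolerance = 1e-12)
  # lower limit can set the crossing too
  ql3 <- quantification_limits(c(10, 20), c(-40, -10), c(5, 5))
  expect_equal(ql3$lloq, 10 + 20 / 30 * 10, tolerance = 1e-12)
  expect_warning(none <- quantification_limits(c(5, 10), c(-50, -40), c(50, 40)),
                 "no level")
  expect_true(is.na(none$lloq) && is.na(none$uloq))
  expect_error(quantification_limits(c(5, 5), c(0, 0), c(0, 0)), "distinct")
})

test_that("build_profile flags levels and reports the validated range", {
  mk <- function(y_r, spread) level_data(y_r, matrix(
    y_r + spread * c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE))
  prof <- build_profile(list(mk(5, 3), mk(20, 0.5), mk(100, 2)))
  expect_s3_class(prof, "mir_profile")
  expect_false(prof$table$valid[1])                  # 60% spread blows the band
  expect_true(all(prof$table$valid[2:3]))
  expect_equal(prof$uloq, 100)
  expect_gt(prof$lloq, 5)
  expect_lt(prof$lloq, 20)
  expect_true(prof$table$cv_flag[1])
  expect_false(any(prof$table$cv_flag[2:3]))
})

test_that("coverage simulation handles the degenerate model and grows with days", {
  degen <- coverage_simulation(sigma_b = 0, sigma_e = 0, n_sims = 200, seed = 1)
  expect_equal(degen$confidence, 1)
  expect_true(all(degen$content == 1))
  c3 <- coverage_simulation(m = 3, n = 3, n_sims = 1000, seed = 2)
  c6 <- coverage_simulation(m = 6, n = 3, n_sims = 1000, seed = 2)
  expect_gt(c6$confidence, c3$confidence)
  expect_true(all(c3$content >= 0 & c3$content <= 1))
})

test_that("coverage is near nominal when day effects are small", {
  cov <- coverage_simulation(m = 3, n = 3, sigma_b = 0.1, sigma_e = 1,
                             n_sims = 1000, seed = 3)
  expect_gte(cov$confidence, 0.85)
})
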