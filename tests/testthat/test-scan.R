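test_that("scan statistics reproduce simple-regression t statistics", {
  set.seed(33)
  n <- 50
  Z <- matrix(sample(0:2, n * 20, replace = TRUE), n, 20)
  r <- rnorm(n)
  scan <- residual_scan(r, geno_matrix(Z))
  ols <- oracle_ols_scan(r, Z)
  expect_equal(scan$effect_a, unname(ols[, "a"]), tolerance = 1e-8)
  expect_equal(scan$chi2, unname(ols[, "chi2"]), tolerance = 1e-8)
  expect_equal(scan$chi2, scan$U^2, tolerance = 1e-12)
})

test_that("constant genotype columns are flagged, not fatal", {
  Z <- cbind(rep(1, 30), sample(0:2, 30, replace = TRUE))
  scan <- residual_scan(rnorm(30), geno_matrix(Z))
  expect_equal(scan$flag, c("constant_genotype", ""))
  expect_true(is.na(scan$chi2[1]))
  expect_error(residual_scan(rnorm(2), geno_matrix(Z[1:2, ])), "at least 3")
})

test_that("uncorrected residual-scan statistics are deflated under a polygenic null", {
  dat <- quick_sim(777, n_snps = 800, fams = rep(c(23, 22), c(4, 5)))
  fit <- fit_null_reml(dat$phenotypes$length, compute_grm(dat$geno))
  scan <- residual_scan(fit$residuals, dat$geno)
  expect_lt(mean(scan$chi2, na.rm = TRUE), 1)
})

test_that("lambda estimation: constant input, homogeneity, median scaling", {
  x <- rep(1, 200)
  expect_equal(estimate_lambda(x)$lambda_hat, 1)
  set.seed(12)
  y <- rchisq(500, df = 1)
  for (m in c("mean", "median")) {
    l1 <- estimate_lambda(y, method = m)$lambda_hat
    l2 <- estimate_lambda(3 * y, method = m)$lambda_hat
    expect_equal(l2, 3 * l1, tolerance = 1e-12)
  }
  set.seed(13)
  big <- rchisq(1e5, df = 1)
  lam <- estimate_lambda(big, method = "median")$lambda_hat
  expect_lt(abs(lam - 1), 0.02)
  expect_error(estimate_lambda(rchisq(50, 1)), "at least 100")
})

test_that("genomic-control correction rescales and recalibrates", {
  set.seed(44)
  Z <- matrix(sample(0:2, 200 * 150, replace = TRUE), 200, 150)
  scan <- residual_scan(rnorm(200), geno_matrix(Z))
  gc1 <- structure(list(lambda_hat = 1, method = "mean", n_snps_used = 150),
                   class = "genomic_control")
  s1 <- correct_statistics(scan, gc1)
  expect_equal(s1$chi2_corrected, s1$chi2)
  gc <- estimate_lambda(scan$chi2, min_snps = 100)
  s2 <- correct_statistics(scan, gc)
  expect_equal(mean(s2$chi2_corrected, na.rm = TRUE), 1, tolerance = 1e-12)
  # 1-df chi-squared tail oracle
  s3 <- scan[1, ]
  s3$chi2 <- 6.634897
  s3 <- correct_statistics(s3, 1)
  expect_equal(s3$p_value, 0.01, tolerance = 1e-6)
})

test_that("p-values decrease strictly in the corrected statistic", {
  chi <- sort(runif(100, 0, 30))
  p <- pchisq(chi, 1, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
  # and correction by lambda < 1 can only gain power
  scan <- data.frame(chi2 = rchisq(200, 1), flag = "")
  a <- correct_statistics(scan, 1)
  b <- correct_statistics(scan, 0.7)
  expect_true(all(b$p_value <= a$p_value))
})

test_that("QTN calling applies the Bonferroni rule exactly", {
  scan <- data.frame(snp_id = sprintf("s%02d", 1:10), chr = "1",
                     bp = 1:10 * 1000,
                     effect_a = rnorm(10), se = 1, U = 0, chi2 = 0,
                     chi2_corrected = 0,
                     p_value = c(1e-8, 0.5, 3e-7, 1e-6, 0.9, 2e-9, 0.04,
                                 5e-6, 1e-5, 0.2),
                     neg_log10_p = 0, flag = "", stringsAsFactors = FALSE)
  m <- 1e5
  calls <- call_qtns(scan, alpha = 0.05, m_total = m)
  brute <- scan$snp_id[scan$p_value <= 0.05 / m]
  expect_setequal(calls$snp_id, brute)
  expect_equal(calls$p_value, sort(calls$p_value))
  null_scan <- scan
  null_scan$p_value <- rep(0.5, 10)
  expect_equal(nrow(call_qtns(null_scan, m_total = m)), 0L)
})

test_that("variance explained follows R2 = a2 var(z) / var(y)", {
  z <- rep(c(0, 1, 2, 1), 25)
  y <- rnorm(100)
  expect_equal(qtl_variance_explained(0, z, y), 0)
  # hand arithmetic: 0.5^2 * 0.24 / 1.2 = 0.05
  z2 <- c(rep(0, 3), rep(1, 4), rep(2, 3))
  y2 <- rnorm(10)
  r2 <- 0.5^2 * var(z2) / var(y2)
  expect_equal(qtl_variance_explained(0.5, z2, y2), min(r2, 1))
  expect_equal(0.5^2 * 0.24 / 1.2, 0.05)
  expect_error(qtl_variance_explained(1, z, rep(2, 100)), "positive")
})

test_that("R2 estimates recover a QTN explaining ~5% of variance", {
  # divergent-only markers: var(z) = 1/4 and K diagonal = 2/3 exactly, so
  # the generating R2 is known in closed form
  h2 <- 0.3
  a <- sqrt(0.05 / 0.95 * (2 / 3 * h2 + (1 - h2)) / 0.25)
  r2_true <- a^2 * 0.25 / (a^2 * 0.25 + 2 / 3 * h2 + (1 - h2))
  # E[a_hat^2] = a^2 + Var(a_hat): remove the exact squared-estimate bias
  # before comparing, using the regression's own standard error
  est <- vapply(1:200, function(s) {
    dat <- quick_sim(2500 + s, n_snps = 120, fams = rep(25, 4), h2 = h2,
                     qtn = qtn_spec(30, a = a), divergent_snp_fraction = 1)
    z <- dat$geno$X[, 30]
    y <- dat$phenotypes$length
    cf <- summary(lm(y ~ z))$coefficients
    (cf[2, 1]^2 - cf[2, 2]^2) * var(z) / var(y)
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - r2_true), 2 * mc_se)
})
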