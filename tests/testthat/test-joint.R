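# build a corrected scan + residuals with planted signal for joint tests
joint_fixture <- function(seed, qtn = qtn_spec(c(150, 650), a = 2),
                          n_snps = 1000, fams = rep(c(34, 33), c(3, 6))) {
  dat <- quick_sim(seed, n_snps = n_snps, fams = fams, qtn = qtn)
  y <- dat$phenotypes$length
  fit <- fit_null_reml(y, compute_grm(dat$geno))
  scan <- residual_scan(fit$residuals, dat$geno)
  gc <- estimate_lambda(scan$chi2)
  scan <- correct_statistics(scan, gc)
  list(dat = dat, fit = fit, scan = scan, gc = gc,
       m = sum(scan$flag == ""))
}

test_that("candidate selection thresholds and prunes like brute force", {
  fx <- joint_fixture(2024)
  sug <- 1e-4
  cand <- select_candidates(fx$scan, fx$dat$geno, suggestive_p = sug)
  # brute force: threshold then greedy prune by marginal p
  idx <- which(fx$scan$p_value <= sug & fx$scan$flag == "")
  Z <- impute_genotype_means(fx$dat$geno)
  idx <- idx[order(fx$scan$p_value[idx], idx)]
  kept <- integer(0)
  for (j in idx) {
    if (all(vapply(kept, function(k) cor(Z[, j], Z[, k])^2 <= 0.99,
                   logical(1)))) kept <- c(kept, j)
  }
  expect_setequal(cand$index, kept)

  none <- select_candidates(fx$scan, fx$dat$geno, suggestive_p = 1e-300)
  expect_equal(nrow(none), 0L)
})

test_that("perfectly collinear significant SNPs collapse to the better one", {
  fx <- joint_fixture(2025, qtn = qtn_spec(150, a = 2))
  g <- fx$dat$geno
  dup <- g
  dup$X <- cbind(g$X, g$X[, 150])
  dup$map <- rbind(g$map, data.frame(snp_id = "DUP", chr = "99", bp = 1L))
  dup <- geno_matrix(dup$X, dup$map, ids = g$ids)
  scan2 <- residual_scan(fx$fit$residuals, dup)
  scan2 <- correct_statistics(scan2, estimate_lambda(scan2$chi2))
  cand <- select_candidates(scan2, dup)
  expect_equal(sum(cand$index %in% c(150, 1001)), 1L)
  hits <- which(scan2$p_value[c(150, 1001)] ==
                  min(scan2$p_value[c(150, 1001)]))
  expect_true(cand$index[cand$index %in% c(150, 1001)] %in% c(150, 1001)[hits])
})

test_that("a single candidate reduces to the marginal corrected decision", {
  fx <- joint_fixture(2026, qtn = qtn_spec(400, a = 2))
  cand <- data.frame(snp_id = fx$scan$snp_id[400], index = 400L,
                     p_value = fx$scan$p_value[400])
  jm <- backward_joint(fx$fit$residuals, fx$dat$geno, cand, fx$gc,
                       m_total = fx$m)
  marginal_hit <- fx$scan$p_value[400] <= 0.05 / fx$m
  expect_equal(nrow(jm$selected) == 1, marginal_hit)
  if (nrow(jm$selected) == 1) {
    # same statistic up to the simple- vs multiple-regression df (n-2 vs n-2)
    expect_equal(jm$selected$chi2_corrected,
                 fx$scan$chi2_corrected[400], tolerance = 1e-8)
  }
})

test_that("backward elimination replays an independent lm()-based route", {
  fx <- joint_fixture(2027, qtn = qtn_spec(c(100, 500, 900), a = 1.5))
  cand <- select_candidates(fx$scan, fx$dat$geno)
  expect_gte(nrow(cand), 3)
  jm <- backward_joint(fx$fit$residuals, fx$dat$geno, cand, fx$gc,
                       m_total = fx$m)
  Zc <- impute_genotype_means(subset_snps(fx$dat$geno, cand$index))
  keep <- oracle_backward(fx$fit$residuals, Zc, fx$gc$lambda_hat,
                          0.05 / fx$m)
  expect_setequal(jm$selected$index, cand$index[keep])
  # and equals the best Bonferroni-feasible subset by exhaustive search
  best <- oracle_best_subset(fx$fit$residuals, Zc, fx$gc$lambda_hat,
                             0.05 / fx$m)
  expect_setequal(jm$selected$index, cand$index[best])
})

test_that("selection is invariant to candidate ordering", {
  fx <- joint_fixture(2028, qtn = qtn_spec(c(200, 700), a = 1.5))
  cand <- select_candidates(fx$scan, fx$dat$geno)
  jm1 <- backward_joint(fx$fit$residuals, fx$dat$geno, cand, fx$gc,
                        m_total = fx$m)
  set.seed(1)
  cand2 <- cand[sample(nrow(cand)), ]
  jm2 <- backward_joint(fx$fit$residuals, fx$dat$geno, cand2, fx$gc,
                        m_total = fx$m)
  expect_setequal(jm1$selected$index, jm2$selected$index)
  expect_identical(sort(jm1$trace$index), sort(jm2$trace$index))
})

test_that("empty candidate pools and singular designs are handled", {
  fx <- joint_fixture(2029, qtn = NULL, n_snps = 400,
                      fams = rep(c(23, 22), c(4, 5)))
  jm <- backward_joint(fx$fit$residuals, fx$dat$geno,
                       data.frame(snp_id = character(0), index = integer(0),
                                  p_value = numeric(0)),
                       fx$gc, m_total = fx$m)
  expect_equal(nrow(jm$selected), 0L)
  # duplicated columns passed directly (bypassing pruning) must error
  g <- fx$dat$geno
  g$X <- cbind(g$X, g$X[, 1])
  g$map <- rbind(g$map, data.frame(snp_id = "DUP", chr = "1", bp = 2L))
  g2 <- geno_matrix(g$X, g$map, ids = g$ids)
  expect_error(
    backward_joint(fx$fit$residuals, g2, c(1L, 401L), fx$gc, m_total = fx$m),
    "singular")
})

test_that("the merged report never loses marginal calls", {
  for (s in 1:10) {
    fx <- joint_fixture(2100 + s, qtn = qtn_spec(c(150, 650), a = 2))
    calls <- call_qtns(fx$scan, genotypes = fx$dat$geno,
                       phenotype = fx$dat$phenotypes$length)
    cand <- select_candidates(fx$scan, fx$dat$geno)
    jm <- backward_joint(fx$fit$residuals, fx$dat$geno, cand, fx$gc,
                         m_total = fx$m)
    merged <- merge_qtn_calls(calls, jm, fx$scan)
    expect_true(all(calls$snp_id %in% merged$snp_id))
    expect_gte(nrow(merged), nrow(calls))
    expect_setequal(unique(merged$source[merged$snp_id %in% calls$snp_id]),
                    if (nrow(calls)) "marginal" else character(0))
  }
})
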