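make_geno <- function(X) geno_matrix(X)

test_that("variance rule removes all-heterozygous SNPs that MAF keeps", {
  X <- cbind(rep(1, 40),                     # all het: MAF 0.5, variance 0
             rep(0, 40),                     # monomorphic: MAF 0
             rep(c(0, 1, 2, 1), 10))         # healthy SNP
  out <- filter_snps(make_geno(X))
  expect_false(out$report$pass[1])
  expect_match(out$report$reason[1], "variance")
  expect_equal(out$report$maf[1], 0.5)       # MAF alone would keep it
  expect_false(out$report$pass[2])
  expect_match(out$report$reason[2], "maf")
  expect_true(out$report$pass[3])
  expect_equal(ncol(out$geno$X), 1L)
})

test_that("QC matches a rule-by-rule brute-force evaluation", {
  set.seed(14)
  n <- 60
  X <- sapply(1:10, function(j) sample(0:2, n, replace = TRUE,
                                       prob = c(0.5, 0.3, 0.2)))
  X[, 2] <- 0                                  # monomorphic
  X[, 4] <- 1                                  # all het
  X[sample(n, 10), 5] <- NA                    # low call rate
  X[, 7] <- c(rep(0, 58), 1, 1)                # low MAF
  X[, 9] <- NA                                 # all missing
  g <- make_geno(X)
  out <- filter_snps(g)
  expect_identical(out$report$pass, oracle_qc_pass(X))
  expect_false(out$report$pass[9])             # all-missing: fails, no error
  expect_match(out$report$reason[9], "call_rate")
})

test_that("QC is order-invariant because rules are marginal", {
  set.seed(8)
  X <- matrix(sample(c(0:2, NA), 300, replace = TRUE,
                     prob = c(.4, .3, .25, .05)), 30, 10)
  g <- make_geno(X)
  perm <- sample(10)
  direct <- filter_snps(g)$report$pass
  permuted <- filter_snps(subset_snps(g, perm))$report$pass
  expect_identical(direct[perm], permuted)
})

test_that("empty genotype matrix is an error", {
  expect_error(filter_snps(make_geno(matrix(0, 5, 0))), "empty")
})

test_that("Mendelian rule removes impossible offspring genotypes", {
  # dam coded 0 cannot transmit the reference allele: offspring code 2 is
  # impossible; SNP 1 violates in family A, SNP 2 is consistent
  off <- geno_matrix(rbind(c(2, 1), c(1, 1), c(0, 2)))
  off$family <- c("A", "A", "B")
  par_ids <- c("A_dam", "A_sire", "B_dam", "B_sire")
  P <- geno_matrix(rbind(c(0, 1), c(1, 2), c(1, 2), c(1, 1)), ids = par_ids)
  out <- filter_snps(off, maf_min = 0, call_rate_min = 0, var_min = -1,
                     parental_genotypes = P)
  expect_equal(out$report$mendel_error_count, c(1L, 0L))
  expect_identical(out$report$pass, c(FALSE, TRUE))
})

test_that("within-family adjustment satisfies the normal equations", {
  set.seed(21)
  fam <- rep(c("f1", "f2", "f3"), c(20, 15, 25))
  bw <- exp(rnorm(60, log(400), 0.3))
  y <- 2 + 0.5 * bw^(1/3) + rnorm(60)
  adj <- adjust_phenotype(y, bw, fam)
  x <- bw^(1/3)
  for (f in unique(fam)) {
    i <- fam == f
    expect_lt(abs(sum(adj$residual[i])), 1e-8 * sum(abs(y[i])))
    expect_lt(abs(sum(adj$residual[i] * x[i])), 1e-8 * sum(abs(y[i] * x[i])))
    # normal-equations oracle
    beta <- solve(crossprod(cbind(1, x[i])), crossprod(cbind(1, x[i]), y[i]))
    expect_equal(adj$residual[i], unname(y[i] - cbind(1, x[i]) %*% beta)[, 1],
                 tolerance = 1e-10)
  }
})

test_that("degenerate families fall back to mean centering", {
  y <- c(5, 7, 9, 4)
  bw <- c(8, 8, 8, 27)
  fam <- c("a", "a", "a", "b")
  w <- capture_warnings(adj <- adjust_phenotype(y, bw, fam))
  expect_length(w, 2)                        # one per degenerate family
  expect_match(w, "mean centering", all = TRUE)
  expect_equal(adj$residual[1:3], y[1:3] - mean(y[1:3]))
  expect_equal(adj$residual[4], 0)             # family of size 1
})

test_that("adjustment removes pure family stratification", {
  set.seed(4)
  fam <- rep(sprintf("f%d", 1:6), each = 30)
  shift <- rnorm(6, 0, 3)[as.integer(factor(fam))]
  y <- shift + rnorm(180, 0, 0.1)
  bw <- exp(rnorm(180, 6, 0.2))
  adj <- adjust_phenotype(y, bw, fam)
  fmeans <- tapply(adj$residual, fam, mean)
  expect_lt(var(fmeans), 1e-20)
})

test_that("phenotype mean imputation fills with the observed mean", {
  expect_equal(impute_missing_phenotypes(c(1, 2, 3, NA)), c(1, 2, 3, 2))
  v <- c(0.3, -1, 2.2)
  expect_identical(impute_missing_phenotypes(v), v)
  set.seed(2)
  y <- rnorm(50)
  y[sample(50, 8)] <- NA
  filled <- impute_missing_phenotypes(y)
  expect_equal(mean(filled), mean(y, na.rm = TRUE))
  expect_error(impute_missing_phenotypes(c(NA_real_, NA)), "all phenotype")
})

test_that("imputation log records fills on adjusted phenotypes", {
  fam <- rep("f1", 6)
  bw <- c(10, 20, 30, 40, 50, 60)
  y <- c(1.2, NA, 0.8, 1.5, NA, 1.1)
  adj <- impute_missing_phenotypes(adjust_phenotype(y, bw, fam))
  expect_equal(adj$imputation_log$index, c(2L, 5L))
  expect_false(anyNA(adj$residual))
})
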