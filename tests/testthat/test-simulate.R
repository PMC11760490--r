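test_that("generator handles empty marker sets and is seed-deterministic", {
  cfg <- sim_config(n_families = 2, family_sizes = c(5, 5), n_snps = 0,
                    heritability_h2 = 0, seed = 7)
  g <- simulate_backcross_genotypes(cfg)
  expect_equal(dim(g), c(10L, 0L))

  cfg2 <- sim_config(n_families = 3, family_sizes = c(10, 10, 10),
                     n_snps = 40, seed = 42, missing_geno_rate = 0.05,
                     missing_pheno_rate = 0.05)
  d1 <- simulate_dataset(cfg2)
  d2 <- simulate_dataset(cfg2)
  expect_identical(d1$geno$X, d2$geno$X)
  expect_identical(d1$phenotypes, d2$phenotypes)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_families = 2, family_sizes = c(-1, 5)),
               "negative")
  expect_error(sim_config(heritability_h2 = 1), "heritability")
  expect_error(sim_config(n_snps = 10, qtn_spec = qtn_spec(11, a = 1)),
               "indices")
  expect_error(sim_config(missing_pheno_rate = 1.5), "rates")
})

test_that("divergent SNPs follow the AA x AB backcross law", {
  # enumeration oracle: dam AA always transmits A, sire AB transmits A or B
  # with probability 1/2, so offspring codes are {2, 1} each w.p. 1/2
  n <- 2000
  cfg <- sim_config(n_families = 8, family_sizes = rep(250, 8), n_snps = 40,
                    divergent_snp_fraction = 1, heritability_h2 = 0,
                    seed = 99)
  g <- simulate_backcross_genotypes(cfg)
  expect_true(all(g$X %in% c(1, 2)))
  freq1 <- colMeans(g$X == 1)
  se3 <- 3 * sqrt(0.25 / n)
  expect_true(all(abs(freq1 - 0.5) <= se3))
})

test_that("non-divergent genotype frequencies match the family law", {
  # with shared parents per family, pooled code frequencies at n >= 1000
  # stay within binomial error of the law's marginal mean 2p
  cfg <- sim_config(n_families = 10, family_sizes = rep(150, 10),
                    n_snps = 60, divergent_snp_fraction = 0,
                    line_maf_distribution = c(0.3, 0.3),
                    heritability_h2 = 0, seed = 5)
  g <- simulate_backcross_genotypes(cfg)
  expect_true(all(g$X %in% 0:2))
  # family-shared parents inflate the variance of the pooled mean: each
  # family mean is centered on (dam+sire)/2 copies; use the family-level SE
  fam_means <- apply(g$X, 2, function(z) tapply(z, g$family, mean))
  grand <- colMeans(fam_means)
  se3 <- 3 * sqrt(2 * 0.3 * 0.7 / (2 * 10))  # var of parental mean over 10 fams
  expect_true(mean(abs(grand - 2 * 0.3) <= se3) > 0.9)
})

test_that("pure-noise limit reproduces the residual variance", {
  cfg <- sim_config(n_snps = 200, heritability_h2 = 0, family_effect_sd = 0,
                    bw_effect_beta = 0, seed = 31)
  dat <- simulate_dataset(cfg)
  n <- nrow(dat$phenotypes)
  se3 <- 3 * sqrt(2 / (n - 1))  # MC SE of a sample variance at sigma2 = 1
  for (tr in c("length", "width", "depth")) {
    expect_lt(abs(var(dat$phenotypes[[tr]]) - dat$truth$sigma2_e), se3)
  }
})

test_that("ordinary least squares recovers a planted QTN effect", {
  a_true <- 0.3
  est <- vapply(1:200, function(s) {
    dat <- quick_sim(800 + s, n_snps = 150, fams = rep(c(17, 16), c(2, 2)),
                     h2 = 0.3, qtn = qtn_spec(40, a = a_true))
    z <- dat$geno$X[, 40]
    if (var(z) == 0) return(NA_real_)   # uninformative draw: no contrast
    coef(lm(dat$phenotypes$length ~ z))[2]
  }, numeric(1))
  est <- est[!is.na(est)]
  expect_gte(length(est), 150)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - a_true), 2 * mc_se)
})

test_that("phenotypic variance decomposes into QTN, polygenic and residual parts", {
  dat <- quick_sim(123, n_snps = 400, fams = rep(139, 4), h2 = 0.4,
                   qtn = qtn_spec(100, a = 0.5))
  K <- compute_grm(dat$geno)
  z <- dat$geno$X[, 100]
  expected <- 0.5^2 * var(z) + dat$truth$sigma2_g * mean(diag(K$K)) +
    dat$truth$sigma2_e
  n <- nrow(dat$phenotypes)
  vy <- var(dat$phenotypes$length)
  # sampling error of a variance, inflated for the correlated polygenic part
  se3 <- 3 * sqrt(2 / (n - 1)) * expected * 2
  expect_lt(abs(vy - expected), se3)
})

test_that("generating truth is carried separately from observables", {
  dat <- quick_sim(3, n_snps = 50, fams = c(10, 10))
  expect_named(dat, c("geno", "phenotypes", "truth"))
  expect_false("truth" %in% names(dat$geno))
  expect_false(any(grepl("truth|qtn|sigma", names(dat$phenotypes))))
  # analysis entry points take observables only, never the truth record
  for (f in list(filter_snps, compute_grm, residual_scan, fit_null_reml)) {
    expect_false("truth" %in% names(formals(f)))
  }
})
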