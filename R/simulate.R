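#' Simulation configuration for backcross-family GWAS data
#'
#' Defines the generating model for a backcross design: each family is the
#' offspring of one purebred (channel-line) dam and one shared F1 hybrid
#' (channel x blue) sire. Genotype codes count copies of the channel-line
#' reference allele. Phenotypes follow
#' \deqn{y_t = family + \beta\,bw^{1/3} + \sum_q z_q a_{qt} + g + e}
#' with polygenic values \eqn{g \sim N(0, K\sigma^2_g)} (K the realized
#' genomic relationship matrix of the simulated genotypes) and residuals with
#' a configurable 3x3 correlation across the three head traits. Variance
#' components are scaled so that \eqn{\sigma^2_g + \sigma^2_e = 1} and
#' \eqn{\sigma^2_g/(\sigma^2_g + \sigma^2_e)} equals `heritability_h2`.
#'
#' Defaults mirror the study design the simulator emulates: nine backcross
#' families totalling 556 individuals with three correlated head-size traits
#' confounded with body weight and family.
#'
#' @param n_families number of backcross families.
#' @param family_sizes integer vector of offspring per family; default splits
#'   556 individuals across 9 families.
#' @param n_snps number of SNPs.
#' @param n_chromosomes chromosomes; SNPs are assigned in contiguous blocks.
#' @param divergent_snp_fraction fraction of SNPs fixed for alternative
#'   alleles in the two parental lines (channel AA, blue BB), so that
#'   backcross offspring are AA or AB with probability 1/2 each.
#' @param line_maf_distribution length-2 uniform bounds for the channel-line
#'   reference-allele frequency at non-divergent SNPs.
#' @param qtn_spec `NULL` or a data.frame as returned by [qtn_spec()] giving
#'   causal SNP indices and per-trait additive effects.
#' @param heritability_h2 polygenic heritability in `[0, 1)`.
#' @param family_effect_sd standard deviation of between-family phenotype
#'   shifts (drawn independently per trait), in phenotype units.
#' @param bw_effect_beta regression of each trait on cube-root body weight,
#'   phenotype units per cube-root gram.
#' @param bw_meanlog,bw_sdlog log-normal body-weight parameters (grams).
#' @param bw_polygenic_cor correlation between log body weight and the mean
#'   polygenic value, to stress-test the covariate adjustment (default 0:
#'   body weight independent of genotype).
#' @param trait_correlation 3x3 correlation matrix of the residual components
#'   of (length, width, depth).
#' @param missing_pheno_rate,missing_geno_rate completely-at-random missing
#'   rates applied to phenotype entries and genotype calls.
#' @param seed integer seed; identical configurations reproduce bit-identical
#'   datasets.
#'
#' @return a list of class `sim_config`.
#' @seealso [simulate_backcross_genotypes()], [simulate_phenotypes()],
#'   [simulate_dataset()]
#' @export
sim_config <- function(n_families = 9,
                       family_sizes = NULL,
                       n_snps = 5000,
                       n_chromosomes = 29,
                       divergent_snp_fraction = 0.3,
                       line_maf_distribution = c(0.1, 0.5),
                       qtn_spec = NULL,
                       heritability_h2 = 0.5,
                       family_effect_sd = 0.5,
                       bw_effect_beta = 0.2,
                       bw_meanlog = log(400),
                       bw_sdlog = 0.25,
                       bw_polygenic_cor = 0,
                       trait_correlation = default_trait_correlation(),
                       missing_pheno_rate = 0,
                       missing_geno_rate = 0,
                       seed = 1L) {
  if (is.null(family_sizes)) {
    base <- 556 %/% n_families
    extra <- 556 %% n_families
    family_sizes <- rep(base, n_families) + c(rep(1, extra),
                                              rep(0, n_families - extra))
  }
  family_sizes <- as.integer(family_sizes)
  if (length(family_sizes) != n_families) {
    stop("family_sizes must have one entry per family")
  }
  if (any(family_sizes < 0) || n_snps < 0 || n_chromosomes < 1) {
    stop("invalid configuration: negative sizes")
  }
  if (heritability_h2 < 0 || heritability_h2 >= 1) {
    stop("heritability_h2 must lie in [0, 1)")
  }
  rates <- c(divergent_snp_fraction, missing_pheno_rate, missing_geno_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(length(line_maf_distribution) == 2,
            line_maf_distribution[1] <= line_maf_distribution[2],
            all(line_maf_distribution >= 0 & line_maf_distribution <= 1))
  if (!is.null(qtn_spec)) {
    stopifnot(is.data.frame(qtn_spec),
              all(c("snp", "a_length", "a_width", "a_depth") %in%
                    names(qtn_spec)))
    if (any(qtn_spec$snp < 1 | qtn_spec$snp > n_snps)) {
      stop("qtn_spec SNP indices must lie in 1..n_snps")
    }
  }
  trait_correlation <- as.matrix(trait_correlation)
  stopifnot(all(dim(trait_correlation) == c(3, 3)),
            isTRUE(all.equal(trait_correlation, t(trait_correlation))),
            all(diag(trait_correlation) == 1))
  structure(list(
    n_families = as.integer(n_families),
    family_sizes = family_sizes,
    n_total = sum(family_sizes),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    divergent_snp_fraction = divergent_snp_fraction,
    line_maf_distribution = line_maf_distribution,
    qtn_spec = qtn_spec,
    heritability_h2 = heritability_h2,
    family_effect_sd = family_effect_sd,
    bw_effect_beta = bw_effect_beta,
    bw_meanlog = bw_meanlog,
    bw_sdlog = bw_sdlog,
    bw_polygenic_cor = bw_polygenic_cor,
    trait_correlation = trait_correlation,
    missing_pheno_rate = missing_pheno_rate,
    missing_geno_rate = missing_geno_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default residual correlation of the three head traits
#'
#' Head length, width and depth are strongly correlated morphometric traits;
#' 0.5 is a realistic residual correlation for such measures.
#' @return 3x3 correlation matrix.
#' @export
default_trait_correlation <- function() {
  r <- matrix(0.5, 3, 3)
  diag(r) <- 1
  dimnames(r) <- list(c("length", "width", "depth"),
                      c("length", "width", "depth"))
  r
}

#' Specify causal QTNs for the simulator
#'
#' @param snp integer SNP indices.
#' @param a additive effect shared by all three traits, or
#' @param a_length,a_width,a_depth per-trait effects (override `a`).
#' @return data.frame with columns `snp`, `a_length`, `a_width`, `a_depth`.
#' @export
qtn_spec <- function(snp, a = 0, a_length = a, a_width = a, a_depth = a) {
  data.frame(snp = as.integer(snp),
             a_length = rep_len(a_length, length(snp)),
             a_width = rep_len(a_width, length(snp)),
             a_depth = rep_len(a_depth, length(snp)))
}

#' Simulate backcross-family genotypes
#'
#' Genotype law: at a line-divergent SNP the dam (channel line) is AA and the
#' F1 sire is AB, so each offspring is AA or AB with probability 1/2 (codes 2
#' and 1, counting the channel allele A). At non-divergent SNPs the four
#' parental alleles of each family (two dam, two sire) are drawn independently
#' as Bernoulli(p) with p the channel-line reference-allele frequency of that
#' SNP, and each offspring receives one allele from each parent uniformly.
#' Parents are shared within a family, inducing the family relatedness the
#' downstream mixed model must absorb. SNPs are independent given parental
#' genotypes (no recombination map).
#'
#' @param config a [sim_config()].
#' @return a [geno_matrix()] with complete (no missing) codes and a map
#'   assigning SNPs to `n_chromosomes` contiguous blocks with increasing bp.
#' @export
simulate_backcross_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_total
  m <- config$n_snps
  fam <- rep(seq_len(config$n_families), config$family_sizes)

  X <- matrix(0, n, m)
  if (m > 0) {
    divergent <- stats::runif(m) < config$divergent_snp_fraction
    md <- sum(divergent)
    if (md > 0) {
      # dam transmits A; sire AB transmits A or B equiprobably
      X[, divergent] <- 1 + matrix(stats::rbinom(n * md, 1, 0.5), n, md)
    }
    mn <- m - md
    if (mn > 0) {
      p <- stats::runif(mn, config$line_maf_distribution[1],
                        config$line_maf_distribution[2])
      Xn <- matrix(0, n, mn)
      for (f in seq_len(config$n_families)) {
        rows <- which(fam == f)
        nf <- length(rows)
        if (nf == 0) next
        d1 <- stats::rbinom(mn, 1, p); d2 <- stats::rbinom(mn, 1, p)
        s1 <- stats::rbinom(mn, 1, p); s2 <- stats::rbinom(mn, 1, p)
        pick_d <- matrix(stats::rbinom(nf * mn, 1, 0.5), nf, mn)
        pick_s <- matrix(stats::rbinom(nf * mn, 1, 0.5), nf, mn)
        D1 <- matrix(d1, nf, mn, byrow = TRUE)
        D2 <- matrix(d2, nf, mn, byrow = TRUE)
        S1 <- matrix(s1, nf, mn, byrow = TRUE)
        S2 <- matrix(s2, nf, mn, byrow = TRUE)
        Xn[rows, ] <- (pick_d * D1 + (1 - pick_d) * D2) +
          (pick_s * S1 + (1 - pick_s) * S2)
      }
      X[, !divergent] <- Xn
    }
  }

  map <- make_snp_map(m, config$n_chromosomes)
  ids <- sprintf("F%02d_%04d", fam, seq_len(n))
  g <- geno_matrix(X, map, ids = ids)
  g$family <- sprintf("fam%02d", fam)
  g
}

# contiguous chromosome blocks, strictly increasing bp within each
make_snp_map <- function(m, n_chr) {
  if (m == 0) {
    return(data.frame(snp_id = character(0), chr = character(0),
                      bp = integer(0), stringsAsFactors = FALSE))
  }
  chr_of <- sort(rep_len(seq_len(min(n_chr, m)), m))
  bp <- integer(m)
  for (cc in unique(chr_of)) {
    idx <- which(chr_of == cc)
    bp[idx] <- cumsum(sample.int(50000, length(idx), replace = TRUE))
  }
  data.frame(snp_id = sprintf("SNP%06d", seq_len(m)),
             chr = as.character(chr_of), bp = bp, stringsAsFactors = FALSE)
}

#' Simulate phenotypes over simulated genotypes
#'
#' Builds the three head traits as family effect + cube-root body-weight
#' regression + planted QTN effects + polygenic value + correlated residual,
#' then injects completely-at-random missingness. The polygenic values are
#' drawn with covariance \eqn{K\sigma^2_g}, K computed from the supplied
#' genotypes, with \eqn{\sigma^2_g = h^2} and \eqn{\sigma^2_e = 1 - h^2}.
#' The generating truth (QTN effects, variance components, family effects)
#' is stored in a `truth` element that analysis stages never read.
#'
#' @param genotypes a complete [geno_matrix()] from
#'   [simulate_backcross_genotypes()].
#' @param config the same [sim_config()].
#' @return a list of class `sim_dataset`: `geno` (with genotype missingness
#'   injected), `phenotypes` (data.frame iid, family, length, width, depth,
#'   body_weight), and `truth`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(genotypes$X)
  h2 <- config$heritability_h2
  sigma2_g <- h2
  sigma2_e <- 1 - h2
  if (ncol(genotypes$X) == 0 && h2 > 0) {
    stop("cannot simulate polygenic values (h2 > 0) without SNPs")
  }

  fam <- genotypes$family
  if (is.null(fam)) fam <- rep("fam01", n)
  fam_levels <- unique(fam)

  # polygenic values: g_t = U sqrt(D sigma2_g) z, independent across traits
  G <- matrix(0, n, 3)
  eigK <- NULL
  if (h2 > 0) {
    K <- compute_grm(genotypes)
    eigK <- eigen(K$K, symmetric = TRUE)
    d <- pmax(eigK$values, 0)
    if (sum(d) < 1e-12) stop("degenerate (zero-variance) GRM; cannot scale h2")
    for (t in 1:3) {
      G[, t] <- eigK$vectors %*% (sqrt(d * sigma2_g) * stats::rnorm(n))
    }
  }

  # body weight, optionally correlated with the mean polygenic value
  zbw <- stats::rnorm(n)
  rho <- config$bw_polygenic_cor
  if (rho != 0 && h2 > 0) {
    gm <- rowMeans(G)
    gm <- (gm - mean(gm)) / stats::sd(gm)
    zbw <- rho * gm + sqrt(1 - rho^2) * zbw
  }
  bw <- exp(config$bw_meanlog + config$bw_sdlog * zbw)

  fe <- matrix(stats::rnorm(length(fam_levels) * 3, 0,
                            config$family_effect_sd),
               length(fam_levels), 3,
               dimnames = list(fam_levels, NULL))
  E <- matrix(stats::rnorm(n * 3), n, 3) %*%
    chol(config$trait_correlation) * sqrt(sigma2_e)

  Y <- fe[fam, , drop = FALSE] + config$bw_effect_beta * bw^(1 / 3) + G + E
  if (!is.null(config$qtn_spec) && nrow(config$qtn_spec) > 0) {
    Zq <- genotypes$X[, config$qtn_spec$snp, drop = FALSE]
    A <- as.matrix(config$qtn_spec[, c("a_length", "a_width", "a_depth")])
    Y <- Y + Zq %*% A
  }
  colnames(Y) <- c("length", "width", "depth")

  # completely-at-random missingness
  if (config$missing_pheno_rate > 0) {
    Y[matrix(stats::runif(n * 3) < config$missing_pheno_rate, n, 3)] <- NA
  }
  geno_out <- genotypes
  if (config$missing_geno_rate > 0 && ncol(geno_out$X) > 0) {
    mask <- stats::runif(length(geno_out$X)) < config$missing_geno_rate
    geno_out$X[matrix(mask, nrow(geno_out$X))] <- NA
  }

  phen <- data.frame(iid = genotypes$ids, family = fam,
                     length = Y[, 1], width = Y[, 2], depth = Y[, 3],
                     body_weight = bw, stringsAsFactors = FALSE)
  structure(list(
    geno = geno_out,
    phenotypes = phen,
    truth = list(qtn_spec = config$qtn_spec,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 heritability_h2 = h2,
                 family_effects = fe,
                 bw_effect_beta = config$bw_effect_beta)
  ), class = "sim_dataset")
}

#' Simulate a complete backcross dataset
#'
#' Convenience wrapper: genotypes then phenotypes from one configuration.
#' @param config a [sim_config()].
#' @return a `sim_dataset` (see [simulate_phenotypes()]).
#' @export
simulate_dataset <- function(config) {
  simulate_phenotypes(simulate_backcross_genotypes(config), config)
}
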