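#' Genome-wide simple-regression scan of null-model residuals
#'
#' Second stage of the two-stage (GRAMMAR-type) association analysis: each
#' SNP is tested by ordinary least squares of the GBLUP residuals on its
#' mean-imputed genotype codes, \eqn{y - \hat g = z a + e}. Per SNP the slope
#' \eqn{\hat a = \mathrm{cov}(z, r)/\mathrm{var}(z)}, its standard error
#' \eqn{se = \sqrt{\hat\sigma^2_{resid}/(n\,\mathrm{var}(z))}} (with
#' \eqn{\hat\sigma^2_{resid}} the simple regression's residual variance on
#' n - 2 degrees of freedom), the normal statistic \eqn{U = \hat a/se} and
#' \eqn{\chi^2 = U^2} are reported. Because breeding values absorb part of
#' every QTN effect, these raw statistics are systematically deflated; see
#' [estimate_lambda()] and [correct_statistics()].
#'
#' Constant (zero-variance) genotype columns yield a flagged record with `NA`
#' statistics rather than an error.
#'
#' @param residuals numeric vector of null-model residuals.
#' @param genotypes a [geno_matrix()]; missing codes are mean-imputed.
#' @return data.frame of class `scan_result`: `snp_id`, `chr`, `bp`,
#'   `effect_a`, `se`, `U`, `chi2`, `chi2_corrected` (NA until corrected),
#'   `p_value`, `neg_log10_p`, `flag`.
#' @export
residual_scan <- function(residuals, genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  n <- length(residuals)
  if (n < 3) stop("residual scan needs at least 3 individuals")
  stopifnot(nrow(genotypes$X) == n, all(is.finite(residuals)))
  Z <- impute_genotype_means(genotypes)

  rc <- residuals - mean(residuals)
  zm <- colMeans(Z)
  szz <- colSums(Z^2) - n * zm^2            # sum of squared centered codes
  szr <- drop(crossprod(Z, rc))             # = sum(zc * rc) since sum(rc)=0
  srr <- sum(rc^2)

  const <- szz <= n * 1e-12
  a <- ifelse(const, NA_real_, szr / szz)
  sse <- pmax(srr - a^2 * szz, 0)
  sigma2 <- sse / (n - 2)
  se <- sqrt(sigma2 / szz)
  U <- a / se
  chi2 <- U^2
  a[const] <- NA; se[const] <- NA; U[const] <- NA; chi2[const] <- NA

  out <- data.frame(
    snp_id = genotypes$map$snp_id, chr = genotypes$map$chr,
    bp = genotypes$map$bp,
    effect_a = a, se = se, U = U, chi2 = chi2,
    chi2_corrected = NA_real_,
    p_value = NA_real_, neg_log10_p = NA_real_,
    flag = ifelse(const, "constant_genotype", ""),
    stringsAsFactors = FALSE
  )
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Genomic-control deflation factor
#'
#' Estimates the variance deflation factor of the residual-scan statistics as
#' the mean of the genome-wide 1-df chi-squared statistics, or as their
#' median divided by 0.4549364 (the 1-df chi-squared median). Dividing every
#' statistic by this factor restores the null 1-df chi-squared calibration;
#' with the mean method the corrected statistics average exactly 1.
#'
#' @param chi2 numeric vector of per-SNP chi-squared statistics (NAs from
#'   flagged SNPs are dropped).
#' @param method `"mean"` (default) or `"median"`.
#' @param min_snps minimum number of finite statistics required.
#' @return list of class `genomic_control`: `lambda_hat`, `method`,
#'   `n_snps_used`.
#' @export
estimate_lambda <- function(chi2, method = c("mean", "median"),
                            min_snps = 100) {
  method <- match.arg(method)
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) < min_snps) {
    stop(sprintf("need at least %d finite chi-squared values, got %d",
                 min_snps, length(chi2)))
  }
  lambda <- switch(method,
    mean = mean(chi2),
    median = stats::median(chi2) / stats::qchisq(0.5, df = 1)
  )
  if (!is.finite(lambda) || lambda <= 0) stop("lambda estimate not positive")
  structure(list(lambda_hat = lambda, method = method,
                 n_snps_used = length(chi2)),
            class = "genomic_control")
}

#' Apply the genomic-control correction to a scan
#'
#' Divides each chi-squared statistic by the deflation factor and converts
#' the corrected statistic to an upper-tail p-value of the 1-df chi-squared
#' distribution.
#'
#' @param scan a [residual_scan()] result.
#' @param gc a [estimate_lambda()] result (or positive scalar lambda).
#' @return the scan with `chi2_corrected`, `p_value` and `neg_log10_p`
#'   filled in, and the genomic control attached as attribute
#'   `genomic_control`.
#' @export
correct_statistics <- function(scan, gc) {
  lambda <- if (inherits(gc, "genomic_control")) gc$lambda_hat else gc
  stopifnot(is.numeric(lambda), lambda > 0)
  scan$chi2_corrected <- scan$chi2 / lambda
  scan$p_value <- stats::pchisq(scan$chi2_corrected, df = 1,
                                lower.tail = FALSE)
  scan$neg_log10_p <- -stats::pchisq(scan$chi2_corrected, df = 1,
                                     lower.tail = FALSE, log.p = TRUE) /
    log(10)
  attr(scan, "genomic_control") <- if (inherits(gc, "genomic_control")) gc
  else structure(list(lambda_hat = lambda, method = "fixed",
                      n_snps_used = NA_integer_),
                 class = "genomic_control")
  scan
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error level.
#' @param m number of tested SNPs.
#' @return list with `threshold` (= alpha / m) and `neg_log10_threshold`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  th <- alpha / m
  list(threshold = th, neg_log10_threshold = -log10(th))
}

#' Call significant QTNs from a corrected scan
#'
#' Declares a SNP a quantitative trait nucleotide when its genomic-control
#' corrected p-value passes the Bonferroni threshold `alpha / M`, M being the
#' number of tested SNPs (defaults to the number of non-flagged scan rows).
#' Each call carries the fraction of phenotypic variance it explains,
#' \eqn{R^2 = \hat a^2 \mathrm{var}(z) / \mathrm{var}(y)}, when the adjusted
#' phenotype and genotypes are supplied.
#'
#' @param scan a corrected [residual_scan()] result.
#' @param alpha family-wise significance level.
#' @param m_total Bonferroni denominator; default `sum(scan$flag == "")`.
#' @param genotypes,phenotype optional [geno_matrix()] and adjusted phenotype
#'   vector used to compute `r2_explained`.
#' @return data.frame of class `qtn_calls` sorted by p-value: `snp_id`,
#'   `chr`, `position_bp`, `effect`, `r2_explained`, `p_value`,
#'   `neg_log10_p`, `source = "marginal"`; attribute `threshold`.
#' @export
call_qtns <- function(scan, alpha = 0.05, m_total = NULL,
                      genotypes = NULL, phenotype = NULL) {
  if (all(is.na(scan$p_value))) {
    stop("scan has no p-values: run correct_statistics() first")
  }
  if (is.null(m_total)) m_total <- sum(scan$flag == "")
  bt <- bonferroni_threshold(alpha, m_total)
  hit <- which(!is.na(scan$p_value) & scan$p_value <= bt$threshold)
  hit <- hit[order(scan$p_value[hit])]
  r2 <- rep(NA_real_, length(hit))
  if (!is.null(genotypes) && !is.null(phenotype) && length(hit) > 0) {
    Z <- impute_genotype_means(genotypes)
    cols <- match(scan$snp_id[hit], genotypes$map$snp_id)
    r2 <- vapply(seq_along(hit), function(i) {
      qtl_variance_explained(scan$effect_a[hit[i]], Z[, cols[i]], phenotype)
    }, numeric(1))
  }
  out <- data.frame(snp_id = scan$snp_id[hit], chr = scan$chr[hit],
                    position_bp = scan$bp[hit], effect = scan$effect_a[hit],
                    r2_explained = r2, p_value = scan$p_value[hit],
                    neg_log10_p = scan$neg_log10_p[hit],
                    source = rep("marginal", length(hit)),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- bt$threshold
  attr(out, "neg_log10_threshold") <- bt$neg_log10_threshold
  class(out) <- c("qtn_calls", "data.frame")
  out
}

#' Phenotypic variance explained by one QTL
#'
#' \deqn{R^2 = \sigma^2_{QTL} / \sigma^2_P = \hat a^2 \mathrm{var}(z) /
#' \mathrm{var}(y)} with `y` the adjusted phenotype the scan analysed;
#' clamped to `[0, 1]`.
#'
#' @param effect_a estimated additive effect.
#' @param genotype_column numeric genotype codes (mean-imputed).
#' @param phenotype adjusted phenotype vector.
#' @return scalar proportion in `[0, 1]`.
#' @export
qtl_variance_explained <- function(effect_a, genotype_column, phenotype) {
  vy <- stats::var(phenotype, na.rm = TRUE)
  if (!is.finite(vy) || vy <= 0) stop("phenotype variance must be positive")
  r2 <- effect_a^2 * stats::var(genotype_column, na.rm = TRUE) / vy
  min(max(r2, 0), 1)
}
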