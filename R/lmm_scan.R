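#' Exact single-SNP mixed-model scan (test oracle)
#'
#' Brute-force generalized-least-squares Wald scan of \eqn{y = 1\mu + za + g +
#' e}, the model class that one-step mixed-model GWAS programs compute. Each
#' SNP enters the mean structure and is tested with the polygenic covariance
#' \eqn{V = \sigma^2_g K + \sigma^2_e I}, either with variance components
#' fixed at the null-model estimates (default; the standard approximation) or
#' refitted per SNP by REML (`refit = TRUE`, exact but O(M) optimisations).
#' Intended as an internal cross-check of the residual-scan pipeline on small
#' problems, hence the hard cap on n.
#'
#' @param y adjusted phenotype vector.
#' @param K a [compute_grm()] result or plain matrix.
#' @param genotypes a [geno_matrix()].
#' @param refit refit variance components for every SNP.
#' @param null_fit optional [fit_null_reml()] result to reuse.
#' @param n_cap refuse problems larger than this many individuals.
#' @return data.frame: `snp_id`, `effect_a`, `se`, `chi2`, `p_value`.
#' @export
exact_lmm_scan <- function(y, K, genotypes, refit = FALSE, null_fit = NULL,
                           n_cap = 1000) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  n <- length(y)
  if (n > n_cap) {
    stop(sprintf(
      "exact_lmm_scan is a small-problem oracle (n = %d > cap %d); use residual_scan",
      n, n_cap))
  }
  if (is.null(null_fit)) null_fit <- fit_null_reml(y, K)
  eig <- null_fit$eig
  d <- pmax(eig$values, 0)
  yt <- drop(crossprod(eig$vectors, y))
  xt <- drop(crossprod(eig$vectors, rep(1, n)))
  Zt <- crossprod(eig$vectors, impute_genotype_means(genotypes))
  m <- ncol(Zt)

  if (!refit) {
    w <- 1 / (null_fit$delta * d + 1)
    a11 <- sum(w * xt^2)
    a12 <- drop(crossprod(Zt, w * xt))
    a22 <- drop(crossprod(Zt^2, w))
    b1 <- sum(w * xt * yt)
    b2 <- drop(crossprod(Zt, w * yt))
    det <- a11 * a22 - a12^2
    const <- det <= max(a11 * a22, 1) * 1e-12
    ahat <- (a11 * b2 - a12 * b1) / det
    muhat <- (b1 - a12 * ahat) / a11
    syy <- sum(w * yt^2)
    rss <- pmax(syy - muhat * b1 - ahat * b2, 0)
    sigma2 <- rss / (n - 2)
    va <- sigma2 * a11 / det
    chi2 <- ahat^2 / va
    se <- sqrt(va)
    ahat[const] <- NA; se[const] <- NA; chi2[const] <- NA
  } else {
    ahat <- se <- chi2 <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      zt <- Zt[, j]
      if (stats::var(zt) <= 1e-12) next
      nll <- function(ld) {
        -reml_profile_loglik2(exp(ld), d, yt, cbind(xt, zt))
      }
      opt <- stats::optimize(nll, interval = log(c(1e-6, 1e6)), tol = 1e-8)
      delta <- exp(opt$minimum)
      if (-nll(log(1e-12)) >= -opt$objective) delta <- 0
      w <- 1 / (delta * d + 1)
      Xw <- cbind(xt, zt)
      XtWX <- crossprod(Xw, w * Xw)
      XtWy <- crossprod(Xw, w * yt)
      beta <- solve(XtWX, XtWy)
      rss <- sum(w * yt^2) - sum(beta * XtWy)
      sigma2 <- rss / (n - 2)
      vb <- sigma2 * solve(XtWX)
      ahat[j] <- beta[2]
      se[j] <- sqrt(vb[2, 2])
      chi2[j] <- beta[2]^2 / vb[2, 2]
    }
  }
  data.frame(snp_id = genotypes$map$snp_id, effect_a = ahat, se = se,
             chi2 = chi2,
             p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# profiled REML log-likelihood with a general rotated fixed-effect matrix
reml_profile_loglik2 <- function(delta, d, yt, Xt) {
  n <- length(yt)
  p <- ncol(Xt)
  v <- delta * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xt, w * Xt)
  XtWy <- crossprod(Xt, w * yt)
  beta <- solve(XtWX, XtWy)
  rss <- sum(w * yt^2) - sum(beta * XtWy)
  sigma2 <- rss / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + sum(log(v)) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}
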