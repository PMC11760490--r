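# Independent oracle routes used across tests. These never call the package's
# eigendecomposition/REML/scan internals: dense matrix algebra, lm(), and
# explicit loops only.

# dense-matrix restricted log-likelihood of y = 1 mu + g + e at variance
# ratio delta = sigma2_g / sigma2_e, sigma2_e profiled out
oracle_reml_loglik <- function(delta, y, K) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- delta * K + diag(n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  rss <- drop(crossprod(r, Vi %*% r))
  sigma2_e <- rss / (n - 1)
  as.numeric(-0.5 * ((n - 1) * (log(2 * pi * sigma2_e) + 1) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus))
}

# grid search over h2 for the null model; returns best log-likelihood
oracle_reml_grid <- function(y, K, h2_grid = seq(0, 0.999, by = 0.001)) {
  ll <- vapply(h2_grid, function(h2) {
    oracle_reml_loglik(h2 / (1 - h2), y, K)
  }, numeric(1))
  list(h2 = h2_grid[which.max(ll)], loglik = max(ll))
}

# Henderson's mixed-model equations for y = 1 mu + g + e with g ~ N(0, K sg2)
oracle_mme_gbv <- function(y, K, sigma2_g, sigma2_e) {
  n <- length(y)
  X <- matrix(1, n, 1)
  lhs <- rbind(
    cbind(crossprod(X), t(X)),
    cbind(X, diag(n) + solve(K) * sigma2_e / sigma2_g)
  )
  sol <- solve(lhs, c(crossprod(X, y), y))
  list(mu = unname(sol[1]), gbv = unname(sol[-1]))
}

# brute-force SNP QC: explicit per-SNP loop over the three marginal rules
oracle_qc_pass <- function(X, maf_min = 0.05, call_rate_min = 0.95,
                           var_min = 0.09) {
  vapply(seq_len(ncol(X)), function(j) {
    z <- X[, j]
    obs <- z[!is.na(z)]
    cr <- length(obs) / length(z)
    if (length(obs) == 0) return(FALSE)
    f <- mean(obs) / 2
    maf <- min(f, 1 - f)
    v <- if (length(obs) < 2) 0 else var(obs)
    maf >= maf_min && cr >= call_rate_min && v > var_min
  }, logical(1))
}

# per-SNP simple regression via lm(): slope, squared t, p
oracle_ols_scan <- function(r, Z) {
  t(vapply(seq_len(ncol(Z)), function(j) {
    fit <- summary(lm(r ~ Z[, j]))$coefficients
    c(a = fit[2, 1], chi2 = fit[2, 3]^2, p = fit[2, 4])
  }, numeric(3)))
}

# brute-force closed-window interval overlap
oracle_window_overlap <- function(annotation, chr, pos, flank) {
  hits <- logical(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    hits[i] <- annotation$chromosome[i] == chr &&
      annotation$start_bp[i] <= pos + flank &&
      annotation$end_bp[i] >= pos - flank
  }
  annotation$gene_id[hits]
}

# independent backward elimination on lm(): drop largest corrected partial p
# (ties: larger column index) until all pass, returning the kept columns
oracle_backward <- function(r, Zc, lambda, threshold) {
  active <- seq_len(ncol(Zc))
  repeat {
    if (length(active) == 0) return(integer(0))
    df <- as.data.frame(Zc[, active, drop = FALSE])
    names(df) <- paste0("z", active)
    fit <- summary(lm(r ~ ., data = df))$coefficients
    chi2c <- fit[-1, 3]^2 / lambda
    p <- pchisq(chi2c, df = 1, lower.tail = FALSE)
    if (all(p <= threshold)) return(active)
    worst <- which(p == max(p))
    worst <- worst[which.max(active[worst])]
    active <- active[-worst]
  }
}

# all-subsets search: largest candidate subset in which every member's
# corrected partial p passes the threshold (ties: larger total chi2)
oracle_best_subset <- function(r, Zc, lambda, threshold) {
  k <- ncol(Zc)
  best <- integer(0)
  best_chi <- -Inf
  for (code in seq_len(2^k) - 1) {
    sub <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    if (length(sub) == 0) next
    df <- as.data.frame(Zc[, sub, drop = FALSE])
    names(df) <- paste0("z", sub)
    fit <- summary(lm(r ~ ., data = df))$coefficients
    chi2c <- fit[-1, 3]^2 / lambda
    p <- pchisq(chi2c, df = 1, lower.tail = FALSE)
    if (all(p <= threshold)) {
      tot <- sum(chi2c)
      if (length(sub) > length(best) ||
          (length(sub) == length(best) && tot > best_chi)) {
        best <- sub
        best_chi <- tot
      }
    }
  }
  best
}

# small-scale simulated dataset shared by several tests
quick_sim <- function(seed, n_snps = 300, fams = rep(c(23, 22), c(4, 5)),
                      h2 = 0.5, qtn = NULL, ...) {
  cfg <- sim_config(n_families = length(fams), family_sizes = fams,
                    n_snps = n_snps, heritability_h2 = h2,
                    family_effect_sd = 0, bw_effect_beta = 0,
                    qtn_spec = qtn, seed = seed, ...)
  simulate_dataset(cfg)
}
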