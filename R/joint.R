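#' Select QTN candidates for the joint analysis
#'
#' Pools every SNP whose corrected marginal p-value reaches a suggestive
#' level, then greedily prunes near-collinear pairs: candidates are visited
#' in order of increasing marginal p (ties broken by genome index) and a SNP
#' is kept only if its squared genotype correlation with every SNP already
#' kept is at most `r2_prune`.
#'
#' @param scan a corrected [residual_scan()] result.
#' @param genotypes the scanned [geno_matrix()].
#' @param suggestive_p inclusion threshold on the corrected p-value.
#' @param r2_prune maximum allowed squared pairwise genotype correlation.
#' @return data.frame: `snp_id`, `index` (column in `genotypes`), `p_value`.
#' @export
select_candidates <- function(scan, genotypes, suggestive_p = 1e-4,
                              r2_prune = 0.99) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  idx <- which(!is.na(scan$p_value) & scan$p_value <= suggestive_p &
                 scan$flag == "")
  empty <- data.frame(snp_id = character(0), index = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  if (length(idx) == 0) return(empty)
  idx <- idx[order(scan$p_value[idx], idx)]
  Z <- impute_genotype_means(subset_snps(genotypes, idx))
  keep <- integer(0)
  for (j in seq_along(idx)) {
    ok <- TRUE
    for (k in keep) {
      r <- suppressWarnings(stats::cor(Z[, j], Z[, k]))
      if (is.finite(r) && r^2 > r2_prune) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, j)
  }
  sel <- idx[keep]
  sel <- sel[order(sel)]
  data.frame(snp_id = scan$snp_id[sel], index = sel,
             p_value = scan$p_value[sel], stringsAsFactors = FALSE)
}

#' Backward-regression joint QTN analysis
#'
#' Third stage of the pipeline: the null-model residuals are regressed
#' jointly on all candidate SNP columns, \eqn{y - \hat g = Z_c a_c + e}, and
#' candidates are eliminated stepwise. At each iteration every candidate's
#' partial Wald chi-squared statistic is divided by the same genomic-control
#' factor as the marginal scan; if every corrected partial p-value meets the
#' Bonferroni level `alpha / m_total` the model is final, otherwise the
#' candidate with the largest partial p is dropped (ties broken by larger
#' genome index) and the model refitted. The elimination order is recorded so
#' a run replays deterministically and independently of candidate ordering.
#'
#' @param residuals null-model residual vector.
#' @param genotypes the scanned [geno_matrix()].
#' @param candidates a [select_candidates()] result (or integer indices).
#' @param gc the marginal scan's [estimate_lambda()] result (or scalar).
#' @param alpha family-wise significance level.
#' @param m_total Bonferroni denominator: the genome-wide SNP count.
#' @return list of class `joint_model`: `selected` (data.frame `snp_id`,
#'   `index`, `effect`, `chi2_corrected`, `p_value`), `trace` (one row per
#'   dropped candidate), `lambda`, `threshold`, `candidates`.
#' @export
backward_joint <- function(residuals, genotypes, candidates, gc,
                           alpha = 0.05, m_total) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  lambda <- if (inherits(gc, "genomic_control")) gc$lambda_hat else gc
  stopifnot(lambda > 0, m_total >= 1)
  if (is.data.frame(candidates)) {
    cand_idx <- candidates$index
    cand_p <- candidates$p_value
  } else {
    cand_idx <- as.integer(candidates)
    cand_p <- rep(NA_real_, length(cand_idx))
  }
  n <- length(residuals)
  threshold <- alpha / m_total
  empty <- data.frame(snp_id = character(0), index = integer(0),
                      effect = numeric(0), chi2_corrected = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  trace <- data.frame(iteration = integer(0), snp_id = character(0),
                      index = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  out <- function(sel_df) {
    structure(list(selected = sel_df, trace = trace, lambda = lambda,
                   threshold = threshold,
                   candidates = genotypes$map$snp_id[cand_idx]),
              class = "joint_model")
  }
  if (length(cand_idx) == 0) return(out(empty))

  # keep the design comfortably overdetermined before elimination starts
  if (length(cand_idx) >= n / 2 && !all(is.na(cand_p))) {
    keep <- order(cand_p, cand_idx)[seq_len(floor(n / 2) - 1)]
    cand_idx <- sort(cand_idx[keep])
  }
  Z <- impute_genotype_means(subset_snps(genotypes, cand_idx))
  active <- seq_along(cand_idx)
  iter <- 0L
  repeat {
    Xd <- cbind(1, Z[, active, drop = FALSE])
    XtX <- crossprod(Xd)
    Xty <- crossprod(Xd, residuals)
    qrX <- qr(XtX)
    if (qrX$rank < ncol(Xd)) {
      stop(paste0("singular joint design; offending candidates: ",
                  paste(genotypes$map$snp_id[cand_idx[active]],
                        collapse = ", ")))
    }
    beta <- solve(qrX, Xty)
    rss <- sum(residuals^2) - sum(beta * Xty)
    df <- n - ncol(Xd)
    if (df <= 0) stop("joint design has no residual degrees of freedom")
    sigma2 <- max(rss, 0) / df
    vb <- sigma2 * diag(solve(qrX, diag(ncol(Xd))))
    chi2 <- (beta^2 / vb)[-1]               # drop intercept
    chi2_c <- chi2 / lambda
    p <- stats::pchisq(chi2_c, df = 1, lower.tail = FALSE)
    if (all(p <= threshold)) {
      sel <- data.frame(snp_id = genotypes$map$snp_id[cand_idx[active]],
                        index = cand_idx[active],
                        effect = beta[-1],
                        chi2_corrected = chi2_c, p_value = p,
                        stringsAsFactors = FALSE)
      return(out(sel))
    }
    iter <- iter + 1L
    worst <- which(p == max(p))
    worst <- worst[which.max(cand_idx[active][worst])]
    trace <- rbind(trace, data.frame(
      iteration = iter,
      snp_id = genotypes$map$snp_id[cand_idx[active][worst]],
      index = cand_idx[active][worst], p_value = max(p),
      stringsAsFactors = FALSE))
    active <- active[-worst]
    if (length(active) == 0) return(out(empty))
  }
}

#' Merge marginal and joint QTN calls into one report
#'
#' One row per distinct QTN; SNPs found by the marginal scan keep
#' `source = "marginal"`, SNPs retained only by the backward joint analysis
#' are added with `source = "joint"` (the joint effect and p-value).
#'
#' @param marginal a [call_qtns()] result.
#' @param joint a [backward_joint()] result.
#' @param scan the corrected scan (for map coordinates of joint-only SNPs).
#' @param genotypes,phenotype optional, to fill `r2_explained` for joint-only
#'   calls.
#' @return data.frame in the marginal-call layout with a `source` column.
#' @export
merge_qtn_calls <- function(marginal, joint, scan, genotypes = NULL,
                            phenotype = NULL) {
  extra <- joint$selected[!(joint$selected$snp_id %in% marginal$snp_id), ,
                          drop = FALSE]
  if (nrow(extra) == 0) return(marginal)
  at <- match(extra$snp_id, scan$snp_id)
  r2 <- rep(NA_real_, nrow(extra))
  if (!is.null(genotypes) && !is.null(phenotype)) {
    Z <- impute_genotype_means(genotypes)
    cols <- match(extra$snp_id, genotypes$map$snp_id)
    r2 <- vapply(seq_len(nrow(extra)), function(i) {
      qtl_variance_explained(extra$effect[i], Z[, cols[i]], phenotype)
    }, numeric(1))
  }
  add <- data.frame(snp_id = extra$snp_id, chr = scan$chr[at],
                    position_bp = scan$bp[at], effect = extra$effect,
                    r2_explained = r2, p_value = extra$p_value,
                    neg_log10_p = -log10(extra$p_value),
                    source = rep("joint", nrow(extra)),
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(marginal), add)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- attr(marginal, "threshold")
  class(out) <- c("qtn_calls", "data.frame")
  out
}
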