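#' Genomic relationship matrix (VanRaden method 1)
#'
#' \deqn{K = \frac{W W^\top}{2\sum_j p_j(1-p_j)}}
#' where `W[i,j] = z[i,j] - 2 p_j` and `p_j` is the sample frequency of the
#' reference allele at SNP j. Missing codes are mean-imputed per SNP first
#' (they then contribute zero to the centered cross-product). Monomorphic
#' SNPs contribute nothing; if all SNPs are monomorphic the scaling constant
#' is zero and an error is raised.
#'
#' @param genotypes a [geno_matrix()] with at least 2 individuals.
#' @return list of class `kinship_matrix`: `K` (n x n), `allele_frequencies`,
#'   `scaling` (the denominator \eqn{2\sum p(1-p)}).
#' @export
compute_grm <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  X <- impute_genotype_means(genotypes)
  n <- nrow(X)
  if (n < 2) stop("GRM needs at least 2 individuals")
  p <- colMeans(X) / 2
  scaling <- 2 * sum(p * (1 - p))
  if (scaling <= 0) stop("all SNPs monomorphic: GRM scaling constant is zero")
  W <- sweep(X, 2, 2 * p, "-")
  K <- tcrossprod(W) / scaling
  K <- (K + t(K)) / 2
  dimnames(K) <- list(genotypes$ids, genotypes$ids)
  structure(list(K = K, allele_frequencies = p, scaling = scaling),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d x %d, mean diagonal %.3f\n",
              nrow(x$K), ncol(x$K), mean(diag(x$K))))
  invisible(x)
}
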