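#' Genotype matrix with SNP map
#'
#' Container for additive genotype codes together with the marker map. Codes
#' count copies of the reference allele, so they lie in \{0, 1, 2\} with `NA`
#' for missing calls. The map carries one row per SNP with its identifier,
#' chromosome and base-pair position.
#'
#' @param X integer or numeric matrix, individuals in rows, SNPs in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param map data.frame with columns `snp_id`, `chr`, `bp`, one row per
#'   column of `X`. If `NULL`, a single-chromosome map with unit spacing is
#'   generated.
#' @param ids character vector of individual identifiers (defaults to
#'   rownames of `X` or `ind1..indN`).
#'
#' @return An object of class `geno_matrix`: a list with elements `X`
#'   (the code matrix), `map`, and `ids`.
#' @export
geno_matrix <- function(X, map = NULL, ids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) && !all(is.na(X))) {
    stop("genotype codes must be numeric")
  }
  storage.mode(X) <- "double"
  bad <- !is.na(X) & !(X %in% c(0, 1, 2))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  m <- ncol(X)
  if (is.null(map)) {
    map <- data.frame(
      snp_id = if (m > 0) sprintf("snp%06d", seq_len(m)) else character(0),
      chr = rep("1", m),
      bp = seq_len(m),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(map) != m) {
    stop(sprintf("map has %d rows but genotype matrix has %d SNPs",
                 nrow(map), m))
  }
  stopifnot(all(c("snp_id", "chr", "bp") %in% names(map)))
  map$chr <- as.character(map$chr)
  if (is.null(ids)) {
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(X)))
  }
  structure(list(X = X, map = map, ids = ids), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$map$chr))))
  miss <- mean(is.na(x$X))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$X)

#' Subset a genotype matrix by SNP index
#'
#' @param geno a [geno_matrix()].
#' @param snps integer or logical index over SNP columns.
#' @return a `geno_matrix` restricted to the selected SNPs.
#' @export
subset_snps <- function(geno, snps) {
  stopifnot(inherits(geno, "geno_matrix"))
  out <- geno_matrix(geno$X[, snps, drop = FALSE],
                     geno$map[snps, , drop = FALSE], ids = geno$ids)
  out$family <- geno$family
  out
}

#' Mean-impute missing genotype codes per SNP
#'
#' Replaces missing codes by the SNP's mean observed code, the standard
#' preparation for GRM construction and the residual scan: it preserves the
#' allele frequency and contributes zero to the centered cross-product.
#' All-missing columns are filled with 0.
#'
#' @param geno a [geno_matrix()].
#' @return numeric matrix of the same dimension with no missing values.
#' @export
impute_genotype_means <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  X <- geno$X
  if (ncol(X) == 0 || !anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X))
  X[idx] <- mu[(idx - 1) %/% nrow(X) + 1]
  X
}
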