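#' SNP quality control
#'
#' Applies the marker filters used for array genotypes in a backcross design:
#' minor allele frequency, call rate, genotype-code variance, and (when
#' parental genotypes are available) Mendelian consistency. The variance rule
#' removes SNPs that are mostly or entirely heterozygous: an all-heterozygous
#' SNP has MAF 0.5 and passes the frequency rule, yet carries no usable
#' additive contrast (variance 0). All rules are evaluated marginally on the
#' raw input, so the retained set does not depend on application order. MAF
#' and variance are computed on non-missing codes only; missingness itself is
#' judged by the call-rate rule.
#'
#' @param genotypes a [geno_matrix()].
#' @param maf_min retain SNPs with minor allele frequency `>= maf_min`.
#' @param call_rate_min retain SNPs with call rate `>= call_rate_min`.
#' @param var_min retain SNPs with genotype-code variance strictly
#'   `> var_min`.
#' @param parental_genotypes optional `geno_matrix` of family parents (rows
#'   named by family: `<family>_dam`, `<family>_sire`); when supplied, SNPs
#'   with any Mendelian-impossible offspring are removed. When absent the
#'   rule is skipped and noted in the report.
#' @param family optional family label per individual (needed for the
#'   Mendelian rule; defaults to the `family` element of `genotypes`).
#'
#' @return list with `geno` (the filtered [geno_matrix()]) and `report`, a
#'   data.frame with per-SNP `maf`, `call_rate`, `genotype_variance`,
#'   `mendel_error_count` (NA when not checked), `pass` and `reason`.
#' @export
filter_snps <- function(genotypes, maf_min = 0.05, call_rate_min = 0.95,
                        var_min = 0.09, parental_genotypes = NULL,
                        family = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  X <- genotypes$X
  if (ncol(X) == 0) stop("empty genotype matrix: no SNPs to filter")
  n <- nrow(X)

  n_obs <- colSums(!is.na(X))
  call_rate <- n_obs / n
  freq <- colMeans(X, na.rm = TRUE) / 2     # reference-allele frequency
  freq[is.nan(freq)] <- NA
  maf <- pmin(freq, 1 - freq)
  gvar <- apply(X, 2, stats::var, na.rm = TRUE)
  gvar[n_obs < 2] <- 0

  mendel <- rep(NA_integer_, ncol(X))
  if (!is.null(parental_genotypes)) {
    if (is.null(family)) family <- genotypes$family
    if (is.null(family)) stop("Mendelian rule needs family labels")
    mendel <- count_mendel_errors(X, parental_genotypes, family)
  }

  ok_maf <- !is.na(maf) & maf >= maf_min
  ok_cr <- call_rate >= call_rate_min
  ok_var <- !is.na(gvar) & gvar > var_min
  ok_mendel <- is.na(mendel) | mendel == 0
  pass <- ok_maf & ok_cr & ok_var & ok_mendel

  reason <- rep("", ncol(X))
  reason[!ok_mendel] <- paste0(reason[!ok_mendel], "mendel;")
  reason[!ok_maf] <- paste0(reason[!ok_maf], "maf;")
  reason[!ok_cr] <- paste0(reason[!ok_cr], "call_rate;")
  reason[!ok_var] <- paste0(reason[!ok_var], "variance;")

  report <- data.frame(snp_id = genotypes$map$snp_id,
                       maf = maf, call_rate = call_rate,
                       genotype_variance = gvar,
                       mendel_error_count = mendel,
                       pass = pass, reason = reason,
                       stringsAsFactors = FALSE)
  list(geno = subset_snps(genotypes, pass), report = report)
}

# offspring codes incompatible with the stated parental pair; codes count the
# reference allele, a parent coded 0 cannot transmit it and one coded 2 must
count_mendel_errors <- function(X, parental_genotypes, family) {
  P <- parental_genotypes$X
  pid <- parental_genotypes$ids
  errs <- integer(ncol(X))
  for (f in unique(family)) {
    dam <- P[match(paste0(f, "_dam"), pid), ]
    sire <- P[match(paste0(f, "_sire"), pid), ]
    rows <- which(family == f)
    lo <- (dam == 2) + (sire == 2)        # minimum transmissible ref copies
    hi <- 2 - ((dam == 0) + (sire == 0))  # maximum
    off <- X[rows, , drop = FALSE]
    bad <- sweep(off, 2, lo, "<") | sweep(off, 2, hi, ">")
    errs <- errs + colSums(bad, na.rm = TRUE)
  }
  errs
}

#' Adjust a phenotype for body weight within each family
#'
#' Regresses the raw trait on the cube root of body weight by ordinary least
#' squares separately within each family and returns the residuals, removing
#' both the allometric body-weight effect and between-family phenotypic
#' stratification in one step. Families with a single member or a constant
#' covariate get slope 0 (residual = deviation from the family mean, with a
#' warning). Individuals with a missing trait value keep a missing residual;
#' see [impute_missing_phenotypes()].
#'
#' @param raw numeric trait vector.
#' @param body_weight positive numeric vector, same length.
#' @param family_ids family label per individual.
#' @return list of class `adjusted_phenotype`: `residual` (same order as
#'   input), `fits` (per-family intercept/slope), `imputation_log` (empty
#'   until imputation).
#' @export
adjust_phenotype <- function(raw, body_weight, family_ids) {
  n <- length(raw)
  stopifnot(length(body_weight) == n, length(family_ids) == n)
  if (any(!is.na(body_weight) & body_weight <= 0)) {
    stop("body weights must be positive")
  }
  x <- body_weight^(1 / 3)
  res <- rep(NA_real_, n)
  fits <- data.frame(family = character(0), intercept = numeric(0),
                     slope = numeric(0), n_used = integer(0),
                     stringsAsFactors = FALSE)
  for (f in unique(family_ids)) {
    rows <- which(family_ids == f)
    use <- rows[!is.na(raw[rows]) & !is.na(x[rows])]
    b0 <- 0; b1 <- 0
    if (length(use) == 0) {
      # nothing observed in this family; residuals stay missing
    } else if (length(use) < 2 || stats::sd(x[use]) == 0) {
      warning(sprintf(
        "family %s: size-1 or constant covariate; using family-mean centering",
        f))
      b0 <- mean(raw[use]); b1 <- 0
      res[use] <- raw[use] - b0
    } else {
      fit <- stats::lm.fit(cbind(1, x[use]), raw[use])
      b0 <- fit$coefficients[1]; b1 <- fit$coefficients[2]
      res[use] <- fit$residuals
    }
    fits <- rbind(fits, data.frame(family = f, intercept = b0, slope = b1,
                                   n_used = length(use),
                                   stringsAsFactors = FALSE))
  }
  structure(list(residual = res, fits = fits,
                 imputation_log = data.frame(index = integer(0),
                                             fill = numeric(0))),
            class = "adjusted_phenotype")
}

#' Fill missing adjusted phenotypes with the observed mean
#'
#' @param adjusted an [adjust_phenotype()] result (or plain numeric vector).
#' @return the same object with missing residuals replaced by the mean of the
#'   observed residuals and `imputation_log` recording each fill.
#' @export
impute_missing_phenotypes <- function(adjusted) {
  plain <- !inherits(adjusted, "adjusted_phenotype")
  y <- if (plain) adjusted else adjusted$residual
  obs <- !is.na(y)
  if (!any(obs)) stop("all phenotype values missing; nothing to impute from")
  fill <- mean(y[obs])
  idx <- which(!obs)
  y[idx] <- fill
  if (plain) return(y)
  adjusted$residual <- y
  adjusted$imputation_log <- data.frame(index = idx,
                                        fill = rep(fill, length(idx)))
  adjusted
}
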