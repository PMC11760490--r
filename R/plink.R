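#' Write genotypes (and phenotypes) as a PLINK bed/bim/fam set
#'
#' SNP-major binary bed with the standard 2-bit encoding: per SNP, each
#' sample occupies 2 bits (4 samples per byte, low bits first) with
#' `00` = homozygous A1 (code 2), `10` = heterozygous (code 1),
#' `11` = homozygous A2 (code 0), `01` = missing. Codes count the A1 allele.
#' The map goes to `.bim` (chr, id, 0 cM, bp, A1 = A, A2 = B) and individual
#' records to `.fam` (family used as FID). When a `sim_dataset` is given, a
#' phenotype TSV (`<prefix>.pheno.tsv`: IID, family, length, width, depth,
#' body_weight) and a truth JSON sidecar (`<prefix>.truth.json`) are written
#' alongside.
#'
#' @param x a [geno_matrix()] or `sim_dataset`.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the vector of files written.
#' @export
write_plink <- function(x, prefix) {
  sim <- inherits(x, "sim_dataset")
  geno <- if (sim) x$geno else x
  stopifnot(inherits(geno, "geno_matrix"))
  n <- nrow(geno$X)
  fam_id <- geno$family %||% rep("fam01", n)

  files <- paste0(prefix, c(".bed", ".bim", ".fam"))
  con <- file(files[1], "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  two_bits <- c(`0` = 3L, `1` = 2L, `2` = 0L)     # NA -> 1L
  nb <- ceiling(n / 4)
  pad <- nb * 4 - n
  shift <- 4L^(0:3)
  for (j in seq_len(ncol(geno$X))) {
    v <- geno$X[, j]
    bits <- ifelse(is.na(v), 1L, two_bits[as.character(v)])
    bits <- c(bits, rep(0L, pad))
    bytes <- colSums(matrix(bits * shift, nrow = 4))
    writeBin(as.raw(bytes), con)
  }
  utils::write.table(
    data.frame(geno$map$chr, geno$map$snp_id, 0, geno$map$bp, "A", "B"),
    files[2], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(fam_id, geno$ids, 0, 0, 0, -9),
    files[3], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  if (sim) {
    pfile <- paste0(prefix, ".pheno.tsv")
    utils::write.table(x$phenotypes, pfile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tfile <- paste0(prefix, ".truth.json")
    truth <- x$truth
    truth$family_effects <- as.data.frame(truth$family_effects)
    jsonlite::write_json(truth, tfile, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    files <- c(files, pfile, tfile)
  }
  invisible(files)
}

#' Read a PLINK bed/bim/fam set
#'
#' Decodes the 2-bit SNP-major bed encoding into additive codes counting the
#' A1 allele (see [write_plink()]); the binary `01` pattern becomes `NA`.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return a [geno_matrix()] with `family` set from the FID column.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chr", "snp_id", "cm", "bp",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b) {
    stop("not a PLINK bed file (bad magic bytes)")
  }
  if (raw[3] != 0x01) stop("only SNP-major bed files are supported")
  body <- as.integer(raw[-(1:3)])
  nb <- ceiling(n / 4)
  if (length(body) != nb * m) {
    stop(sprintf("bed payload has %d bytes but %d samples x %d SNPs need %d",
                 length(body), n, m, nb * m))
  }
  # expand each byte into its four 2-bit fields, low bits first
  B <- matrix(body, nrow = nb, ncol = m)
  codes <- c(2, NA, 1, 0)                   # indexed by 2-bit value + 1
  X <- matrix(NA_real_, n, m)
  for (k in 0:3) {
    rows <- seq.int(k + 1, by = 4, length.out = nb)
    rows_ok <- rows <= n
    vals <- (B %/% (4L^k)) %% 4L
    X[rows[rows_ok], ] <- codes[vals[rows_ok, , drop = FALSE] + 1]
  }
  g <- geno_matrix(X, bim[, c("snp_id", "chr", "bp")], ids = fam[[2]])
  g$family <- fam[[1]]
  g
}

#' Read genotypes from a plain TSV matrix plus map file
#'
#' Fallback interchange for small fixtures: a tab-separated matrix of codes
#' (rows = individuals with an `iid` first column, columns = SNP ids) and a
#' map TSV with columns `snp_id`, `chr`, `bp`.
#'
#' @param geno_path,map_path file paths.
#' @return a [geno_matrix()].
#' @export
read_geno_tsv <- function(geno_path, map_path) {
  gm <- utils::read.delim(geno_path, check.names = FALSE)
  map <- utils::read.delim(map_path,
                           colClasses = c("character", "character",
                                          "integer"))
  ids <- as.character(gm[[1]])
  X <- as.matrix(gm[, -1, drop = FALSE])
  if (!identical(colnames(X), map$snp_id)) {
    stop("genotype columns do not match the map's snp_id order")
  }
  geno_matrix(X, map, ids = ids)
}

#' Read a phenotype table
#'
#' @param path TSV with columns `iid`, `family`, `length`, `width`, `depth`,
#'   `body_weight` (empty fields become `NA`).
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, na.strings = c("NA", ""))
  need <- c("iid", "family", "length", "width", "depth", "body_weight")
  miss <- setdiff(need, names(ph))
  if (length(miss) > 0) {
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  }
  ph
}
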