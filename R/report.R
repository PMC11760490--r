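#' Manhattan and QQ plot tables for a corrected scan
#'
#' Pure reshaping of a scan into plot-ready tables: the Manhattan table adds
#' a cumulative genome coordinate (chromosomes laid end to end in map order)
#' and an alternating chromosome parity key; the QQ table pairs the observed
#' \eqn{-\log_{10} p} order statistics with expected uniform quantiles
#' \eqn{-\log_{10}(i/(M+1))}. No statistic is recomputed.
#'
#' @param scan a corrected [residual_scan()] result.
#' @param alpha,m_total define the threshold line `-log10(alpha / m_total)`;
#'   `m_total` defaults to the number of non-flagged SNPs.
#' @return list with `manhattan` (snp_id, chr, bp, genome_bp, neg_log10_p,
#'   parity), `qq` (expected, observed), `threshold_neg_log10`, `lambda`.
#' @export
manhattan_qq_data <- function(scan, alpha = 0.05, m_total = NULL) {
  ok <- !is.na(scan$p_value)
  if (is.null(m_total)) m_total <- sum(scan$flag == "")
  chrs <- unique(scan$chr)
  offset <- stats::setNames(numeric(length(chrs)), chrs)
  run <- 0
  for (cc in chrs) {
    offset[cc] <- run
    run <- run + max(scan$bp[scan$chr == cc], 0)
  }
  man <- data.frame(
    snp_id = scan$snp_id[ok], chr = scan$chr[ok], bp = scan$bp[ok],
    genome_bp = scan$bp[ok] + offset[scan$chr[ok]],
    neg_log10_p = scan$neg_log10_p[ok],
    parity = (match(scan$chr[ok], chrs) %% 2 == 0),
    stringsAsFactors = FALSE
  )
  pv <- sort(scan$p_value[ok])
  mq <- length(pv)
  qq <- data.frame(expected = -log10(seq_len(mq) / (mq + 1)),
                   observed = -log10(pv))
  gc <- attr(scan, "genomic_control")
  list(manhattan = man, qq = qq,
       threshold_neg_log10 = -log10(alpha / m_total),
       lambda = if (!is.null(gc)) gc$lambda_hat else NA_real_)
}

#' Genomic-control summary table across methods and traits
#'
#' Tabulates the mean genome-wide chi-squared statistic of each supplied scan
#' — the genomic control value. For corrected scans (`chi2_corrected`
#' available) the corrected mean is reported, otherwise the raw mean.
#'
#' @param scans named list (entries `<method>.<trait>`) of scan data.frames
#'   with a `chi2` and optionally `chi2_corrected` column.
#' @return data.frame with `method`, `trait`, `genomic_control`.
#' @export
genomic_control_table <- function(scans) {
  stopifnot(length(scans) > 0, !is.null(names(scans)))
  rows <- lapply(names(scans), function(nm) {
    s <- scans[[nm]]
    x <- if ("chi2_corrected" %in% names(s) &&
             any(is.finite(s$chi2_corrected))) s$chi2_corrected else s$chi2
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(method = parts[1],
               trait = if (length(parts) > 1) parts[2] else NA_character_,
               genomic_control = mean(x, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
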