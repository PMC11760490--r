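#' Pipeline configuration
#'
#' Bundles every tunable of the association pipeline. Serialises losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param genotype_prefix PLINK bed/bim/fam prefix.
#' @param phenotype_path phenotype TSV (see [read_phenotypes()]).
#' @param annotation_path optional GFF3/BED gene annotation.
#' @param traits traits to analyse, subset of length/width/depth.
#' @param maf_min,call_rate_min,var_min SNP QC thresholds.
#' @param lambda_method `"mean"` or `"median"`.
#' @param alpha family-wise significance level.
#' @param suggestive_p candidate-pool threshold for the joint analysis.
#' @param flank_bp candidate-gene window half-width (bp).
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory (created if needed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype_prefix, phenotype_path,
                            annotation_path = NULL,
                            traits = c("length", "width", "depth"),
                            maf_min = 0.05, call_rate_min = 0.95,
                            var_min = 0.09,
                            lambda_method = "mean", alpha = 0.05,
                            suggestive_p = 1e-4, flank_bp = 150000,
                            seed = 1L, out_dir = "grlgwas_out") {
  cfg <- list(genotype_prefix = genotype_prefix,
              phenotype_path = phenotype_path,
              annotation_path = annotation_path,
              traits = traits, maf_min = maf_min,
              call_rate_min = call_rate_min, var_min = var_min,
              lambda_method = lambda_method, alpha = alpha,
              suggestive_p = suggestive_p, flank_bp = flank_bp,
              seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (length(cfg$traits) == 0) stop("config invalid: empty trait list")
  bad <- setdiff(cfg$traits, c("length", "width", "depth"))
  if (length(bad) > 0) stop("config invalid: unknown traits ",
                            paste(bad, collapse = ", "))
  rng <- c(cfg$maf_min, cfg$call_rate_min, cfg$alpha, cfg$suggestive_p)
  if (any(rng < 0 | rng > 1) || cfg$var_min < 0 || cfg$flank_bp < 0) {
    stop("config invalid: threshold out of range")
  }
  if (!cfg$lambda_method %in% c("mean", "median")) {
    stop("config invalid: lambda_method must be mean or median")
  }
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Run the full association pipeline
#'
#' Stage order: SNP QC, within-family cube-root body-weight adjustment,
#' phenotype mean imputation, GRM, REML null fit, residual scan,
#' genomic-control correction, marginal QTN calls, joint backward analysis,
#' optional gene-window annotation, report files. All statistical output is a
#' deterministic function of the input files and the configuration. A
#' manifest (config, seed, per-stage row counts, genomic controls) is written
#' to `manifest.json` for exact re-runs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return invisibly, the manifest list. Output files land in `cfg$out_dir`:
#'   `qc_report.tsv`, `adjusted_phenotypes.tsv`, per-trait `scan_*.tsv`,
#'   `qtn_calls.tsv`, `genomic_control.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "read"
  manifest <- list(config = unclass(cfg), stages = list())
  tryCatch({
    geno <- read_plink(cfg$genotype_prefix)
    phen <- read_phenotypes(cfg$phenotype_path)
    ord <- match(geno$ids, phen$iid)
    if (anyNA(ord)) stop("phenotype table is missing genotyped individuals")
    phen <- phen[ord, ]
    manifest$stages$read <- list(n = nrow(geno$X), m = ncol(geno$X))
    say("read: %d individuals, %d SNPs", nrow(geno$X), ncol(geno$X))

    stage <- "qc"
    qc <- filter_snps(geno, cfg$maf_min, cfg$call_rate_min, cfg$var_min)
    utils::write.table(qc$report, file.path(cfg$out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    geno <- qc$geno
    manifest$stages$qc <- list(m_retained = ncol(geno$X))
    say("qc: %d SNPs retained", ncol(geno$X))

    stage <- "adjust"
    adj <- lapply(cfg$traits, function(tr) {
      impute_missing_phenotypes(
        adjust_phenotype(phen[[tr]], phen$body_weight, phen$family))
    })
    names(adj) <- cfg$traits
    adj_df <- data.frame(iid = phen$iid,
                         lapply(adj, function(a) a$residual))
    utils::write.table(adj_df,
                       file.path(cfg$out_dir, "adjusted_phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$adjust <- list(
      n_imputed = vapply(adj, function(a) nrow(a$imputation_log),
                         integer(1)))

    stage <- "grm"
    K <- compute_grm(geno)
    eig <- eigen(K$K, symmetric = TRUE)
    manifest$stages$grm <- list(mean_diag = mean(diag(K$K)))

    all_calls <- list()
    gc_rows <- list()
    for (tr in cfg$traits) {
      stage <- paste0("null_fit:", tr)
      y <- adj[[tr]]$residual
      fit <- fit_null_reml(y, K, eig = eig)
      say("%s: h2_hat = %.3f", stage, fit$h2_hat)

      stage <- paste0("scan:", tr)
      scan <- residual_scan(fit$residuals, geno)
      gc <- estimate_lambda(scan$chi2, method = cfg$lambda_method)
      scan <- correct_statistics(scan, gc)
      utils::write.table(scan,
                         file.path(cfg$out_dir,
                                   sprintf("scan_%s.tsv", tr)),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      stage <- paste0("call:", tr)
      calls <- call_qtns(scan, alpha = cfg$alpha,
                         genotypes = geno, phenotype = y)
      cand <- select_candidates(scan, geno,
                                suggestive_p = cfg$suggestive_p)
      joint <- backward_joint(fit$residuals, geno, cand, gc,
                              alpha = cfg$alpha,
                              m_total = sum(scan$flag == ""))
      merged <- merge_qtn_calls(calls, joint, scan,
                                genotypes = geno, phenotype = y)
      merged$trait <- rep(tr, nrow(merged))
      stage <- paste0("annotate:", tr)
      if (!is.null(cfg$annotation_path)) {
        ann <- read_gene_annotation(cfg$annotation_path)
        merged <- annotate_qtns(merged, ann, cfg$flank_bp)
      }
      all_calls[[tr]] <- merged
      gc_rows[[tr]] <- data.frame(
        trait = tr, h2_hat = fit$h2_hat, lambda = gc$lambda_hat,
        gc_corrected = mean(scan$chi2_corrected, na.rm = TRUE),
        n_marginal = nrow(calls), n_joint = nrow(joint$selected),
        n_reported = nrow(merged), stringsAsFactors = FALSE)
      say("%s: lambda = %.3f, %d marginal + %d joint-only calls",
          tr, gc$lambda_hat, nrow(calls), nrow(merged) - nrow(calls))
    }

    stage <- "report"
    calls_out <- do.call(rbind, lapply(all_calls, as.data.frame))
    utils::write.table(calls_out,
                       file.path(cfg$out_dir, "qtn_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gc_out <- do.call(rbind, gc_rows)
    utils::write.table(gc_out,
                       file.path(cfg$out_dir, "genomic_control.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$report <- list(
      n_calls = nrow(calls_out),
      per_trait = gc_out)
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
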