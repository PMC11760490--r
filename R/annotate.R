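#' Read a gene annotation from GFF3 or BED
#'
#' Uses rtracklayer to parse the file, keeps `gene` features (GFF3; every BED
#' record is kept), and returns 1-based inclusive coordinates. BED's 0-based
#' half-open intervals are converted on import by rtracklayer.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return data.frame: `gene_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `strand`, `name`.
#' @export
read_gene_annotation <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df)) {
    df <- df[as.character(df$type) %in% feature_type, , drop = FALSE]
  }
  id <- if ("ID" %in% names(df)) as.character(df$ID)
  else if ("name" %in% names(df)) as.character(df$name)
  else sprintf("gene%05d", seq_len(nrow(df)))
  nm <- if ("Name" %in% names(df)) as.character(df$Name)
  else if ("name" %in% names(df)) as.character(df$name) else id
  out <- data.frame(gene_id = id,
                    chromosome = normalize_chr(as.character(df$seqnames)),
                    start_bp = df$start, end_bp = df$end,
                    strand = as.character(df$strand), name = nm,
                    stringsAsFactors = FALSE)
  stopifnot(all(out$start_bp <= out$end_bp))
  out[order(out$chromosome, out$start_bp), ]
}

# strip "chr" prefixes and leading zeros so map and annotation naming agree
normalize_chr <- function(x) {
  x <- sub("^[Cc]hr", "", as.character(x))
  sub("^0+(?=.)", "", x, perl = TRUE)
}

#' Candidate genes in a window around a QTN
#'
#' Collects every gene whose interval overlaps the closed window
#' `[position - flank_bp, position + flank_bp]` on the QTN's chromosome.
#' Boundaries are inclusive: a gene ending exactly `flank_bp` base pairs
#' before the QTN is in the window; one starting `flank_bp + 1` after it is
#' not. The default flank of 150 kb matches the reporting convention for
#' array QTNs.
#'
#' @param qtn one-row data.frame (or list) with `snp_id`, `chr`,
#'   `position_bp`.
#' @param annotation a [read_gene_annotation()] data.frame.
#' @param flank_bp half-width of the window in base pairs.
#' @return list of class `candidate_window`: `qtn`, `flank_bp`, `genes`
#'   (annotation rows overlapping the window, sorted by start).
#' @export
window_genes <- function(qtn, annotation, flank_bp = 150000) {
  chr <- normalize_chr(qtn$chr %||% qtn$chromosome)
  pos <- qtn$position_bp %||% qtn$bp
  stopifnot(length(chr) == 1, length(pos) == 1, flank_bp >= 0)
  if (!chr %in% unique(annotation$chromosome)) {
    stop(sprintf(
      "chromosome '%s' absent from annotation (known: %s)", chr,
      paste(sort(unique(annotation$chromosome)), collapse = ", ")))
  }
  lo <- pos - flank_bp
  hi <- pos + flank_bp
  hitrows <- annotation$chromosome == chr &
    annotation$start_bp <= hi & annotation$end_bp >= lo
  genes <- annotation[hitrows, , drop = FALSE]
  genes <- genes[order(genes$start_bp), ]
  rownames(genes) <- NULL
  structure(list(qtn = qtn, flank_bp = flank_bp, genes = genes),
            class = "candidate_window")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate a QTN call table with candidate-gene windows
#'
#' @param calls a [call_qtns()] / [merge_qtn_calls()] table.
#' @param annotation a [read_gene_annotation()] data.frame.
#' @param flank_bp window half-width.
#' @return `calls` with an added `genes` column (comma-separated gene names).
#' @export
annotate_qtns <- function(calls, annotation, flank_bp = 150000) {
  if (nrow(calls) == 0) {
    calls$genes <- character(0)
    return(calls)
  }
  calls$genes <- vapply(seq_len(nrow(calls)), function(i) {
    w <- window_genes(calls[i, ], annotation, flank_bp)
    paste(w$genes$name, collapse = ",")
  }, character(1))
  calls
}
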