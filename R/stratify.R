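# Expression integration and nascent-transcription strandedness.

#' Read a per-gene expression table
#'
#' The table has a gene-symbol first column and one or more replicate value
#' columns. Values are aggregated per gene (mean of replicates), rows below
#' the given quantile of the aggregated distribution are dropped, and gene
#' names occurring more than once (multi-locus symbols) are excluded, each
#' filter being logged.
#'
#' @param path TSV path with a header row.
#' @param aggregate Aggregation across replicate columns; only `"mean"`.
#' @param low_intensity_quantile Quantile in `[0, 1)` of the aggregated
#'   values below which rows are dropped (0 = no filter).
#' @return An `ExpressionTable`: list with `values` (named numeric vector),
#'   `replicates`, `filter_log`.
#' @export
read_expression <- function(path, aggregate = "mean",
                            low_intensity_quantile = 0) {
  .assert(identical(aggregate, "mean"), "only aggregate='mean' is supported")
  .assert(low_intensity_quantile >= 0 && low_intensity_quantile < 1,
          "low_intensity_quantile must be in [0, 1)")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2L, "expression table needs a gene column plus values")
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    .assert(length(bad) == 0L, "non-numeric expression value at row ",
            if (length(bad)) bad[1L] else 0L, ", column ", j + 1L)
    vals[[j]] <- v
  }
  gene <- as.character(df[[1L]])
  log <- sprintf("read %d rows x %d replicates from %s",
                 nrow(df), ncol(vals), path)
  dup <- gene %in% gene[duplicated(gene)]
  if (any(dup))
    log <- c(log, sprintf("dropped %d multi-locus rows (%s)", sum(dup),
                          paste(unique(gene[dup]), collapse = ",")))
  gene <- gene[!dup]
  agg <- rowMeans(as.matrix(vals)[!dup, , drop = FALSE])
  if (low_intensity_quantile > 0) {
    cut <- quantile(agg, low_intensity_quantile, names = FALSE)
    drop <- agg < cut
    log <- c(log, sprintf("low-intensity filter q=%g: dropped %d rows",
                          low_intensity_quantile, sum(drop)))
    gene <- gene[!drop]; agg <- agg[!drop]
  }
  structure(list(values = setNames(agg, gene),
                 replicates = ncol(vals), filter_log = log),
            class = "ExpressionTable")
}

#' Top expressed genes within a universe
#'
#' Deterministic ranking: descending value, ties broken lexicographically by
#' gene name, so `top-n` is always nested in `top-(n+1)`.
#'
#' @param et An `ExpressionTable`.
#' @param n Number of genes to return.
#' @param universe Optional `GeneSet` to intersect with first.
#' @return Character vector of `n` gene names, ranked.
#' @export
select_top_expressed <- function(et, n, universe = NULL) {
  v <- et$values
  if (!is.null(universe)) v <- v[names(v) %in% universe$genes$name]
  .assert(n <= length(v), "n exceeds the ", length(v),
          " genes with expression values in the universe")
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(n)]
}

#' Expression summaries per cluster
#'
#' @param cr A `ClusterResult`.
#' @param et An `ExpressionTable`.
#' @return Data frame per cluster: n (members with expression data), median,
#'   q1, q3, whisker_low/high (1.5 IQR rule, clamped to the data range).
#'   Clusters without expression data get `NA` summaries.
#' @export
cluster_expression_summary <- function(cr, et) {
  .assert(any(names(cr$assignments) %in% names(et$values)),
          "clusters and expression table share no genes")
  out <- data.frame(cluster = seq_len(cr$k), n = 0L, median = NA_real_,
                    q1 = NA_real_, q3 = NA_real_,
                    whisker_low = NA_real_, whisker_high = NA_real_)
  for (j in seq_len(cr$k)) {
    genes <- names(cr$assignments)[cr$assignments == j]
    v <- et$values[intersect(genes, names(et$values))]
    out$n[j] <- length(v)
    if (length(v) == 0L) next
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    out$median[j] <- q[2]; out$q1[j] <- q[1]; out$q3[j] <- q[3]
    out$whisker_low[j] <- min(v[v >= q[1] - 1.5 * iqr])
    out$whisker_high[j] <- max(v[v <= q[3] + 1.5 * iqr])
  }
  out
}

#' Antisense read fraction downstream of the EAG
#'
#' For each gene, the fraction of stranded reads overlapping the window
#' (offsets downstream of the EAG, in transcription orientation) that map
#' antisense to the gene. Genes with no overlapping reads are `NA`.
#'
#' @param reads Stranded alignment data frame (e.g. a nascent-transcription
#'   track).
#' @param gs A `GeneSet`.
#' @param window `c(from_bp, to_bp)` offsets downstream of the EAG point.
#' @return Data frame: gene, n_sense, n_antisense, antisense_fraction.
#' @export
antisense_fraction <- function(reads, gs, window = c(0, 4000)) {
  g <- gs$genes
  eagp <- .anchor_point(g, "EAG")
  out <- data.frame(gene = g$name, n_sense = 0L, n_antisense = 0L,
                    antisense_fraction = NA_real_)
  for (ch in unique(g$chrom)) {
    r <- reads[reads$chrom == ch, , drop = FALSE]
    gi <- which(g$chrom == ch)
    if (nrow(r) == 0L || length(gi) == 0L) next
    read_ir <- .ir(r$start, r$end)
    win_s <- ifelse(g$strand[gi] == "+", eagp[gi] + window[1],
                    eagp[gi] - window[2])
    win_e <- ifelse(g$strand[gi] == "+", eagp[gi] + window[2],
                    eagp[gi] - window[1])
    hits <- IRanges::findOverlaps(.ir(win_s, win_e), read_ir)
    qi <- S4Vectors::queryHits(hits)
    sense <- r$strand[S4Vectors::subjectHits(hits)] ==
      g$strand[gi][qi]
    out$n_sense[gi] <- tabulate(qi[sense], length(gi))
    out$n_antisense[gi] <- tabulate(qi[!sense], length(gi))
  }
  tot <- out$n_sense + out$n_antisense
  out$antisense_fraction <- ifelse(tot > 0, out$n_antisense / tot, NA_real_)
  out
}
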