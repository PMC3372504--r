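# Gene-model ingestion and filtering.
#
# A GeneSet holds one row per transcription unit with 0-based half-open
# coordinates, exon structure, strand-aware anchors and a class label.
# The two anchors of a unit are the TSS (5' boundary) and the EAG (end of
# annotated gene, the 3' boundary). Anchor *fields* follow the base
# convention (tss = start for +, end-1 for -); window extraction elsewhere
# anchors at the interval boundary so that mirroring the genome and flipping
# strands is an exact symmetry.

.GENE_CLASSES <- c("core_histone", "variant_histone", "other", "unknown")

.new_gene_set <- function(genes, provenance = character()) {
  rownames(genes) <- NULL
  structure(list(genes = genes, provenance = provenance), class = "GeneSet")
}

.gene_columns <- c(
  "chrom", "start", "end", "strand", "name", "transcript_id",
  "exon_starts", "exon_ends", "gene_class"
)

.finish_genes <- function(df) {
  .assert(all(df$strand %in% c("+", "-")),
          "unknown strand character in gene models")
  .assert(all(df$start < df$end), "gene models must satisfy start < end")
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    .assert(length(es) == length(ee) && length(es) >= 1L,
            "gene ", df$name[i], ": exon start/end lists must be parallel")
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    .assert(all(ee > es), "gene ", df$name[i], ": empty exon")
    .assert(all(es >= df$start[i]) && all(ee <= df$end[i]),
            "gene ", df$name[i], ": exon outside transcription unit")
    if (length(es) > 1L)
      .assert(all(es[-1L] >= ee[-length(ee)]),
              "gene ", df$name[i], ": overlapping exons")
    df$exon_starts[[i]] <- es
    df$exon_ends[[i]] <- ee
  }
  df$n_exons <- lengths(df$exon_starts)
  df$intronless <- df$n_exons == 1L
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$eag <- ifelse(df$strand == "+", df$end - 1L, df$start)
  df
}

# 3'/5' boundary coordinate used to center anchored windows. For a plus gene
# the EAG point is `end`, for a minus gene `start`; symmetric under the
# genome mirror x -> L - x.
.anchor_point <- function(genes, anchor = c("EAG", "TSS")) {
  anchor <- match.arg(anchor)
  if (anchor == "EAG") {
    ifelse(genes$strand == "+", genes$end, genes$start)
  } else {
    ifelse(genes$strand == "+", genes$start, genes$end)
  }
}

#' Read gene models from BED12, refFlat or GTF
#'
#' Parses transcript models into a `GeneSet` with one row per transcript.
#' Coordinates are converted to 0-based half-open internally; GTF input is
#' read as 1-based inclusive and converted. Exon structure is populated from
#' BED12 blocks, refFlat exon lists, or GTF `exon` records grouped by
#' `transcript_id`.
#'
#' @param path Path to the annotation file.
#' @param format One of `"bed12"`, `"refflat"` (UCSC column order) or
#'   `"gtf"`.
#' @return A `GeneSet`: a list with `genes` (data frame with columns `chrom`,
#'   `start`, `end`, `strand`, `name`, `transcript_id`, list columns
#'   `exon_starts`/`exon_ends`, `gene_class`, `n_exons`, `intronless`, and
#'   derived anchors `tss`, `eag`) and a `provenance` log.
#' @export
read_gene_models <- function(path, format = c("bed12", "refflat", "gtf")) {
  format <- match.arg(format)
  .assert(file.exists(path), "annotation file not found: ", path)
  df <- switch(format,
    bed12 = .read_bed12(path),
    refflat = .read_refflat(path),
    gtf = .read_gtf(path)
  )
  df$gene_class <- rep("unknown", nrow(df))
  df <- .finish_genes(df)
  .new_gene_set(df, provenance = sprintf("read %d transcripts from %s [%s]",
                                         nrow(df), path, format))
}

.read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  .assert(length(bad) == 0L,
          "malformed BED12 line ", if (length(bad)) bad[1L] else 0L,
          ": expected 12 fields, got ", if (length(bad)) nf[bad[1L]] else 0L)
  # normalise whitespace so the standard importer sees canonical BED
  tf <- tempfile(fileext = ".bed")
  on.exit(unlink(tf), add = TRUE)
  writeLines(vapply(fields, function(f) paste(f[1:12], collapse = "\t"), ""),
             tf)
  gr <- rtracklayer::import(tf, format = "bed")
  strands <- as.character(BiocGenerics::strand(gr))
  bad <- which(!strands %in% c("+", "-"))
  .assert(length(bad) == 0L, "unknown strand character on BED12 line ",
          if (length(bad)) bad[1L] else 0L)
  start0 <- BiocGenerics::start(gr) - 1L
  blocks <- gr$blocks  # exon ranges relative to the transcript, 1-based
  exon_starts <- exon_ends <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    bl <- blocks[[i]]
    exon_starts[[i]] <- start0[i] + (BiocGenerics::start(bl) - 1L)
    exon_ends[[i]] <- start0[i] + BiocGenerics::end(bl)
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = BiocGenerics::end(gr),
    strand = strands,
    name = gr$name,
    transcript_id = gr$name,
    exon_starts = I(exon_starts),
    exon_ends = I(exon_ends),
    stringsAsFactors = FALSE
  )
}

.read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  .assert(length(bad) == 0L,
          "malformed refFlat line ", if (length(bad)) bad[1L] else 0L,
          ": expected 11 fields, got ", if (length(bad)) nf[bad[1L]] else 0L)
  parse_list <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
  n <- length(fields)
  exon_starts <- exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    exon_starts[[i]] <- parse_list(fields[[i]][10L])
    exon_ends[[i]] <- parse_list(fields[[i]][11L])
    .assert(!anyNA(exon_starts[[i]]) && !anyNA(exon_ends[[i]]),
            "malformed refFlat line ", i, ": non-numeric exon list")
  }
  f <- function(k) vapply(fields, `[[`, "", k)
  start <- suppressWarnings(as.integer(f(5L)))
  end <- suppressWarnings(as.integer(f(6L)))
  bad <- which(is.na(start) | is.na(end))
  .assert(length(bad) == 0L, "malformed refFlat line ",
          if (length(bad)) bad[1L] else 0L, ": non-numeric coordinates")
  data.frame(
    chrom = f(3L), start = start, end = end, strand = f(4L),
    name = f(1L), transcript_id = f(2L),
    exon_starts = I(exon_starts), exon_ends = I(exon_ends),
    stringsAsFactors = FALSE
  )
}

.read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  .assert(length(ex) > 0L, "GTF contains no exon records: ", path)
  .assert(!is.null(ex$transcript_id) && !anyNA(ex$transcript_id),
          "GTF exons must carry transcript_id attributes")
  .assert(!is.null(ex$gene_id), "GTF exons must carry gene_id attributes")
  tx <- split(seq_along(ex), ex$transcript_id)
  start0 <- BiocGenerics::start(ex) - 1L  # GTF is 1-based inclusive
  end0 <- BiocGenerics::end(ex)
  strands <- as.character(BiocGenerics::strand(ex))
  chroms <- as.character(GenomicRanges::seqnames(ex))
  name <- if (!is.null(ex$gene_name)) ex$gene_name else ex$gene_id
  rows <- lapply(names(tx), function(t) {
    i <- tx[[t]]
    o <- order(start0[i])
    i <- i[o]
    data.frame(
      chrom = chroms[i[1L]], start = min(start0[i]), end = max(end0[i]),
      strand = strands[i[1L]], name = name[i[1L]], transcript_id = t,
      exon_starts = I(list(start0[i])), exon_ends = I(list(end0[i])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Collapse transcripts to one model per gene name
#'
#' @param gs A `GeneSet`.
#' @param rule `"longest"` keeps the longest transcript per gene name;
#'   `"union"` merges the transcription-unit extent and the exon intervals of
#'   all isoforms. Names occurring on more than one chromosome or strand are
#'   excluded and logged.
#' @return A collapsed `GeneSet` (unique gene names).
#' @export
collapse_transcripts <- function(gs, rule = c("longest", "union")) {
  rule <- match.arg(rule)
  g <- gs$genes
  by_name <- split(seq_len(nrow(g)), g$name)
  dropped <- character()
  rows <- list()
  for (nm in sort(names(by_name))) {
    i <- by_name[[nm]]
    if (length(unique(g$chrom[i])) > 1L || length(unique(g$strand[i])) > 1L) {
      dropped <- c(dropped, nm)
      next
    }
    if (rule == "longest") {
      len <- g$end[i] - g$start[i]
      pick <- i[order(-len, g$transcript_id[i])][1L]
      rows[[nm]] <- g[pick, , drop = FALSE]
    } else {
      merged <- IRanges::reduce(.ir(unlist(g$exon_starts[i]),
                                    unlist(g$exon_ends[i])))
      row <- g[i[1L], , drop = FALSE]
      row$start <- min(g$start[i]); row$end <- max(g$end[i])
      row$transcript_id <- paste(sort(g$transcript_id[i]), collapse = ",")
      row$exon_starts <- I(list(BiocGenerics::start(merged) - 1L))
      row$exon_ends <- I(list(BiocGenerics::end(merged)))
      rows[[nm]] <- row
    }
  }
  out <- if (length(rows) == 0L) {
    g[integer(0), , drop = FALSE]
  } else {
    .finish_genes(do.call(rbind, rows))
  }
  log <- c(gs$provenance,
           sprintf("collapse_transcripts rule=%s: %d -> %d genes", rule,
                   nrow(g), nrow(out)))
  if (length(dropped))
    log <- c(log, sprintf("excluded multi-locus gene names: %s",
                          paste(dropped, collapse = ",")))
  .new_gene_set(out, provenance = log)
}

#' Keep genes isolated from neighbouring transcription units
#'
#' A gene is kept when its transcription-unit interval lies at least
#' `min_distance_bp` away (end-to-start gap) from the nearest other unit on
#' the same chromosome, strand-blind. A gene with no neighbour on its
#' chromosome is kept. Overlapping units have distance 0.
#'
#' @param gs A collapsed `GeneSet`.
#' @param min_distance_bp Minimum gap in bp (default 4000).
#' @return The filtered `GeneSet`; the per-gene nearest-neighbour distances
#'   and kept flags are attached as attribute `"filter_log"`.
#' @export
filter_isolated <- function(gs, min_distance_bp = 4000) {
  .assert(min_distance_bp >= 0, "min_distance_bp must be >= 0")
  g <- gs$genes
  gr <- GenomicRanges::GRanges(g$chrom, .ir(g$start, g$end))
  hits <- GenomicRanges::distanceToNearest(gr, ignore.strand = TRUE)
  dist <- rep(NA_real_, nrow(g))
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  keep <- is.na(dist) | dist >= min_distance_bp
  log_df <- data.frame(gene = g$name, nearest_distance_bp = dist, kept = keep)
  out <- .new_gene_set(
    g[keep, , drop = FALSE],
    provenance = c(gs$provenance,
                   sprintf("filter_isolated D=%d: %d -> %d genes",
                           as.integer(min_distance_bp), nrow(g), sum(keep)))
  )
  attr(out, "filter_log") <- log_df
  out
}

#' Assign gene classes from curated lists and name patterns
#'
#' Classes are assigned from the explicit lists first (a name present in both
#' lists is an error), then from optional per-class regular expressions, and
#' default to `"other"`.
#'
#' @param gs A `GeneSet`.
#' @param core_list,variant_list Character vectors of gene symbols for
#'   core-histone and variant-histone genes.
#' @param name_patterns Optional named character vector of regular
#'   expressions, names in `c("core_histone", "variant_histone")`.
#' @return The `GeneSet` with `gene_class` filled in (`intronless` is an
#'   independent structural flag and is not touched).
#' @export
assign_gene_class <- function(gs, core_list = character(),
                              variant_list = character(),
                              name_patterns = NULL) {
  both <- intersect(core_list, variant_list)
  .assert(length(both) == 0L,
          "gene(s) in both core and variant lists: ",
          paste(both, collapse = ","))
  g <- gs$genes
  cls <- rep("other", nrow(g))
  if (!is.null(name_patterns)) {
    .assert(all(names(name_patterns) %in%
                  c("core_histone", "variant_histone")),
            "name_patterns must be named core_histone/variant_histone")
    for (k in names(name_patterns))
      cls[grepl(name_patterns[[k]], g$name)] <- k
  }
  cls[g$name %in% variant_list] <- "variant_histone"
  cls[g$name %in% core_list] <- "core_histone"
  g$gene_class <- cls
  .new_gene_set(g, provenance = c(gs$provenance, "assign_gene_class"))
}

#' Write kept genes as BED6 plus a filter log
#'
#' @param gs A `GeneSet` (typically the output of [filter_isolated()]).
#' @param bed_path Output BED6 path.
#' @param log_path Optional path for the filter-log TSV
#'   (gene, nearest-neighbour distance, kept flag).
#' @return Invisibly, `bed_path`.
#' @export
write_gene_bed <- function(gs, bed_path, log_path = NULL) {
  g <- gs$genes
  df <- data.frame(g$chrom, g$start, g$end, g$name, 0L, g$strand)
  write.table(df, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(log_path)) {
    log_df <- attr(gs, "filter_log")
    .assert(!is.null(log_df), "GeneSet carries no filter log")
    .write_tsv(log_df, log_path)
  }
  invisible(bed_path)
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  tab <- table(x$genes$gene_class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}
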