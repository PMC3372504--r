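# Read extension, per-base coverage and binned tracks.
#
# A CoverageTrack stores the exact per-base fragment depth per chromosome as
# run-length-encoded vectors (raw counts) together with the normalisation
# mode; binned summaries and anchored matrices are derived views, so that
# base-pair conservation (sum(bins) * bin_width == total covered bp) holds
# exactly and anchored windows need not align to a genome-wide grid.

#' Read aligned tags from a BED6 file
#'
#' @param path BED6 file of mapped tags (name and score columns ignored).
#' @return A data frame of alignments with 0-based half-open `start`/`end`,
#'   `chrom` and `strand`.
#' @export
read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strands <- as.character(BiocGenerics::strand(gr))
  .assert(all(strands %in% c("+", "-")),
          "alignments must be stranded (+/-): ", path)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strands,
    stringsAsFactors = FALSE
  )
}

#' Write alignments or fragments as BED6
#' @param reads Data frame with `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignments_bed <- function(reads, path) {
  n <- nrow(reads)
  df <- data.frame(reads$chrom, reads$start, reads$end,
                   sprintf("read_%d", seq_len(n)), 0L, reads$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extend tags directionally to fragment length
#'
#' Each tag is extended from its 5' end in the direction of the read to
#' `extension_length` bp (tags already at least that long keep their native
#' length), then clipped to the chromosome. This reconstructs the sequenced
#' fragment from the short tag, as is standard for single-end ChIP-seq.
#'
#' @param reads Alignment data frame (see [read_alignments_bed()]).
#' @param extension_length Target fragment length in bp (default 200).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A fragment data frame (`chrom`, `start`, `end`, `strand`,
#'   `source_read_id`).
#' @export
extend_reads <- function(reads, extension_length = 200, chrom_sizes) {
  .assert(all(reads$chrom %in% names(chrom_sizes)),
          "read on chromosome absent from chrom_sizes")
  sizes <- unname(chrom_sizes[reads$chrom])
  bad <- which(reads$start < 0 | reads$end > sizes)
  .assert(length(bad) == 0L, "read record ", if (length(bad)) bad[1L] else 0L,
          " extends beyond chromosome bounds")
  len <- pmax(extension_length, reads$end - reads$start)
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$end - len)
  end <- ifelse(plus, reads$start + len, reads$end)
  data.frame(
    chrom = reads$chrom,
    start = pmax(start, 0),
    end = pmin(end, sizes),
    strand = reads$strand,
    source_read_id = seq_len(nrow(reads)),
    stringsAsFactors = FALSE
  )
}

#' Build a binned coverage track from fragments
#'
#' Per-base fragment depth is computed exactly per chromosome; the bin value
#' exposed by [track_bins()] is the mean per-base depth within the bin, which
#' conserves covered base-pairs. `rpm` scales values by `1e6 /
#' total_fragments` so tracks of different depth are co-plottable.
#'
#' @param frags Fragment data frame (see [extend_reads()]).
#' @param bin_width Bin width in bp (default 50).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param strand_mode `"both"`, `"plus"` or `"minus"`: which fragment strands
#'   contribute.
#' @param normalization `"rpm"` (default) or `"raw"`.
#' @return A `CoverageTrack`.
#' @export
build_coverage <- function(frags, bin_width = 50, chrom_sizes,
                           strand_mode = c("both", "plus", "minus"),
                           normalization = c("rpm", "raw")) {
  strand_mode <- match.arg(strand_mode)
  normalization <- match.arg(normalization)
  .assert(bin_width >= 1, "bin_width must be >= 1")
  if (strand_mode != "both") {
    want <- if (strand_mode == "plus") "+" else "-"
    frags <- frags[frags$strand == want, , drop = FALSE]
  }
  n_frags <- nrow(frags)
  .assert(!(normalization == "rpm" && n_frags == 0L),
          "rpm normalization requires at least one fragment")
  cov <- lapply(names(chrom_sizes), function(ch) {
    f <- frags[frags$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0L)
      return(S4Vectors::Rle(0L, unname(chrom_sizes[ch])))
    IRanges::coverage(.ir(f$start, f$end), width = unname(chrom_sizes[ch]))
  })
  names(cov) <- names(chrom_sizes)
  structure(
    list(cov = cov, chrom_sizes = chrom_sizes, bin_width = bin_width,
         total_fragments = n_frags, strand_mode = strand_mode,
         normalization = normalization),
    class = "CoverageTrack"
  )
}

.track_scale <- function(track) {
  if (track$normalization == "rpm") 1e6 / track$total_fragments else 1
}

#' Binned values of a coverage track
#'
#' @param track A `CoverageTrack`.
#' @return Named list (per chromosome) of bin value vectors: mean per-base
#'   depth per `bin_width` window, on the track's normalisation scale.
#' @export
track_bins <- function(track) {
  w <- track$bin_width
  sc <- .track_scale(track)
  out <- lapply(names(track$cov), function(ch) {
    n <- unname(track$chrom_sizes[ch])
    starts <- seq(0L, n - 1L, by = w)
    ends <- pmin(starts + w, n)
    .window_sums(track$cov[[ch]], starts, ends) / w * sc
  })
  names(out) <- names(track$cov)
  out
}

#' Export a coverage track as bedGraph
#'
#' @param track A `CoverageTrack`.
#' @param path Output bedGraph path (binned values on the track's scale).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  bins <- track_bins(track)
  w <- track$bin_width
  rows <- lapply(names(bins), function(ch) {
    v <- bins[[ch]]
    starts <- seq(0L, by = w, length.out = length(v))
    keep <- v != 0
    data.frame(chrom = ch, start = starts[keep],
               end = pmin(starts[keep] + w, unname(track$chrom_sizes[ch])),
               value = v[keep])
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, .ir(df$start, df$end),
                               score = df$value)
  GenomeInfoDb::seqlengths(gr) <- track$chrom_sizes[
    GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf(
    "CoverageTrack: %d fragments, %d chromosome(s), bin %d bp, %s (%s)\n",
    x$total_fragments, length(x$cov), x$bin_width, x$normalization,
    x$strand_mode))
  invisible(x)
}

# ---- anchored matrices -----------------------------------------------------

.new_anchor_matrix <- function(values, anchor, flank_bp, bin_width,
                               n_body_bins = 0L, clipped = NULL) {
  structure(values, class = c("AnchorMatrix", "matrix"),
            anchor = anchor, flank_bp = flank_bp, bin_width = bin_width,
            n_body_bins = n_body_bins,
            clipped = clipped %||% rep(FALSE, nrow(values)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Offsets (bin midpoints, bp from the anchor) of matrix columns
#' @param m An `AnchorMatrix` from [anchor_matrix()].
#' @return Numeric vector of signed bin-midpoint offsets.
#' @export
anchor_offsets <- function(m) {
  f <- attr(m, "flank_bp"); w <- attr(m, "bin_width")
  .assert(attr(m, "n_body_bins") == 0L,
          "offsets are only defined for fixed-anchor matrices")
  seq(-f + w / 2, f - w / 2, by = w)
}

#' Occupancy matrix around a gene anchor, in transcription orientation
#'
#' One row per gene covering `[anchor - flank, anchor + flank)` in the
#' direction of transcription: columns always increase downstream, so
#' minus-strand windows read toward lower genomic coordinates. Windows are
#' centred on the annotation boundary (gene end for `+` EAG, gene start for
#' `-` EAG), which makes a genome mirror plus strand flip an exact symmetry.
#' Bins outside the chromosome are zero-filled and the row flagged.
#'
#' @param track A `CoverageTrack`.
#' @param gs A `GeneSet`.
#' @param anchor `"EAG"` or `"TSS"`.
#' @param flank_bp Flank on each side of the anchor; must be a multiple of
#'   the track's bin width.
#' @return An `AnchorMatrix` (genes x bins, values on the track scale) with
#'   attributes `anchor`, `flank_bp`, `bin_width` and per-row `clipped`
#'   flags. Genes on chromosomes absent from the track are dropped and
#'   recorded in attribute `"dropped"`.
#' @export
anchor_matrix <- function(track, gs, anchor = c("EAG", "TSS"),
                          flank_bp = 4000) {
  anchor <- match.arg(anchor)
  w <- track$bin_width
  .assert(flank_bp %% w == 0, "flank_bp must be a multiple of bin_width")
  g <- gs$genes
  present <- g$chrom %in% names(track$cov)
  dropped <- g$name[!present]
  g <- g[present, , drop = FALSE]
  n_bins <- as.integer(2 * flank_bp / w)
  p <- .anchor_point(g, anchor)
  vals <- matrix(0, nrow = nrow(g), ncol = n_bins,
                 dimnames = list(g$name, NULL))
  clipped <- logical(nrow(g))
  sc <- .track_scale(track)
  j <- seq_len(n_bins)
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") {
      starts <- p[i] - flank_bp + (j - 1L) * w
    } else {
      starts <- p[i] + flank_bp - j * w
    }
    ends <- starts + w
    rle <- track$cov[[g$chrom[i]]]
    vals[i, ] <- .window_sums(rle, starts, ends) / w * sc
    clipped[i] <- any(starts < 0) || any(ends > length(rle))
  }
  out <- .new_anchor_matrix(vals, anchor, flank_bp, w, clipped = clipped)
  attr(out, "dropped") <- dropped
  out
}

#' Scaled-gene ("metagene") occupancy matrix
#'
#' Gene bodies are split into `n_body_bins` equal proportional intervals
#' (mean per-base depth each); fixed-width flank bins are prepended and
#' appended, all in transcription orientation
#' (`upstream | scaled body | downstream`).
#'
#' @param track A `CoverageTrack`.
#' @param gs A `GeneSet`; genes shorter than `n_body_bins` bp are dropped and
#'   recorded in attribute `"dropped"`.
#' @param n_body_bins Number of proportional body bins (default 100).
#' @param flank_bp Fixed-width flank on each side.
#' @return An `AnchorMatrix` with `n_body_bins + 2 * flank_bp / bin_width`
#'   columns.
#' @export
scaled_gene_matrix <- function(track, gs, n_body_bins = 100,
                               flank_bp = 4000) {
  w <- track$bin_width
  .assert(flank_bp %% w == 0, "flank_bp must be a multiple of bin_width")
  g <- gs$genes
  len <- g$end - g$start
  keep <- g$chrom %in% names(track$cov) & len >= n_body_bins
  dropped <- g$name[!keep]
  g <- g[keep, , drop = FALSE]
  len <- len[keep]
  n_flank <- as.integer(flank_bp / w)
  n_cols <- 2L * n_flank + n_body_bins
  vals <- matrix(0, nrow = nrow(g), ncol = n_cols,
                 dimnames = list(g$name, NULL))
  sc <- .track_scale(track)
  for (i in seq_len(nrow(g))) {
    bounds <- g$start[i] + round(seq(0, n_body_bins) * len[i] / n_body_bins)
    body_s <- bounds[-length(bounds)]
    body_e <- bounds[-1L]
    up_s <- g$start[i] - flank_bp + (seq_len(n_flank) - 1L) * w
    dn_s <- g$end[i] + (seq_len(n_flank) - 1L) * w
    starts <- c(up_s, body_s, dn_s)
    ends <- c(up_s + w, body_e, dn_s + w)
    rle <- track$cov[[g$chrom[i]]]
    v <- .window_sums(rle, starts, ends) / pmax(ends - starts, 1) * sc
    if (g$strand[i] == "-") v <- rev(v)
    vals[i, ] <- v
  }
  out <- .new_anchor_matrix(vals, "scaled_body", flank_bp, w,
                            n_body_bins = as.integer(n_body_bins))
  attr(out, "dropped") <- dropped
  out
}

#' Column-wise mean profile of an anchored matrix
#'
#' @param m An `AnchorMatrix`.
#' @param gene_subset Optional character vector of row names to average over.
#' @return Numeric vector of per-bin mean densities.
#' @export
mean_profile <- function(m, gene_subset = NULL) {
  if (!is.null(gene_subset)) {
    .assert(all(gene_subset %in% rownames(m)),
            "gene_subset contains genes absent from the matrix")
    .assert(length(gene_subset) > 0L, "gene_subset is empty")
    m <- m[gene_subset, , drop = FALSE]
  }
  .assert(nrow(m) > 0L, "cannot average an empty matrix")
  colMeans(m)
}

#' Write an anchored matrix as TSV with a metadata sidecar
#'
#' @param m An `AnchorMatrix`.
#' @param path Output TSV path; header gives bin-midpoint offsets for
#'   fixed-anchor matrices. A `<path>.meta.yaml` sidecar records anchor,
#'   flank, bin width and body-bin count.
#' @param track Optional `CoverageTrack` whose fragment total is recorded.
#' @return Invisibly, `path`.
#' @export
write_anchor_matrix <- function(m, path, track = NULL) {
  hdr <- if (attr(m, "n_body_bins") == 0L) {
    sprintf("%+g", anchor_offsets(m))
  } else {
    paste0("col", seq_len(ncol(m)))
  }
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m)))
  names(df) <- c("gene", hdr)
  .write_tsv(df, path)
  meta <- list(anchor = attr(m, "anchor"), flank_bp = attr(m, "flank_bp"),
               bin_width = attr(m, "bin_width"),
               n_body_bins = attr(m, "n_body_bins"),
               n_genes = nrow(m),
               total_fragments = if (is.null(track)) NA
                                 else track$total_fragments)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
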