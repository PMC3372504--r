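# Shared fixtures and independent oracles, all built in code.

# GeneSet from a compact data frame; exons default to the full unit.
gs_from_df <- function(df) {
  if (is.null(df$transcript_id)) df$transcript_id <- paste0(df$name, ".1")
  if (is.null(df$exon_starts)) {
    df$exon_starts <- I(as.list(df$start))
    df$exon_ends <- I(as.list(df$end))
  }
  if (is.null(df$gene_class)) df$gene_class <- "other"
  polpause:::.new_gene_set(polpause:::.finish_genes(df))
}

frags_df <- function(chrom, start, end, strand = "+") {
  data.frame(chrom = rep_len(chrom, length(start)), start = start,
             end = end, strand = rep_len(strand, length(start)),
             source_read_id = seq_along(start), stringsAsFactors = FALSE)
}

# Uniform-coverage track: tile the chromosome with depth-1 fragments.
uniform_track <- function(len, w = 50, value = 1, normalization = "raw") {
  starts <- seq(0, len - w, by = w)
  fr <- frags_df("chr1", rep(starts, value), rep(starts + w, value))
  build_coverage(fr, w, c(chr1 = len), normalization = normalization)
}

# Brute-force per-base depth aggregated to bins (coverage oracle).
brute_bins <- function(frags, chrom_len, w) {
  depth <- numeric(chrom_len)
  for (i in seq_len(nrow(frags))) {
    s <- frags$start[i] + 1L
    e <- frags$end[i]
    if (e >= s) depth[s:e] <- depth[s:e] + 1
  }
  starts <- seq(1L, chrom_len, by = w)
  vapply(starts, function(s) sum(depth[s:min(s + w - 1L, chrom_len)]) / w,
         numeric(1))
}

# Brute-force nearest-neighbour gap between transcription units.
brute_isolated <- function(df, min_d) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    same <- which(df$chrom == df$chrom[i])
    same <- setdiff(same, i)
    if (length(same) == 0L) { keep[i] <- TRUE; next }
    gaps <- vapply(same, function(j) {
      g <- max(df$start[j] - df$end[i], df$start[i] - df$end[j])
      max(g, 0)
    }, numeric(1))
    keep[i] <- min(gaps) >= min_d
  }
  df$name[keep]
}

# Brute-force pair-counting adjusted Rand index.
brute_ari <- function(a, b) {
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ea <- a[i] == a[j]; eb <- b[i] == b[j]
    s_both <- s_both + (ea && eb)
    s_a <- s_a + ea; s_b <- s_b + eb
  }
  tot <- n * (n - 1) / 2
  expected <- s_a * s_b / tot
  maxi <- (s_a + s_b) / 2
  if (maxi == expected) return(1)
  (s_both - expected) / (maxi - expected)
}

# Point mirror of fragment/read intervals: [s, e) -> [L - e, L - s),
# strands flipped.
mirror_frags <- function(frags, len) {
  data.frame(chrom = frags$chrom,
             start = len - frags$end, end = len - frags$start,
             strand = ifelse(frags$strand == "+", "-", "+"),
             stringsAsFactors = FALSE)
}

mirror_gs <- function(gs, len) {
  g <- gs$genes
  out <- data.frame(
    chrom = g$chrom, start = len - g$end, end = len - g$start,
    strand = ifelse(g$strand == "+", "-", "+"),
    name = g$name, transcript_id = g$transcript_id,
    exon_starts = I(lapply(g$exon_ends, function(e) rev(len - e))),
    exon_ends = I(lapply(g$exon_starts, function(s) rev(len - s))),
    gene_class = g$gene_class, stringsAsFactors = FALSE
  )
  polpause:::.new_gene_set(polpause:::.finish_genes(out))
}

# EAG-anchored oriented bin means computed directly from an intensity
# vector (no reads): the noiseless expected-coverage path.
intensity_eag_row <- function(v, genomic_start, eag_point, strand,
                              flank = 4000, w = 50) {
  offs <- seq(-flank, flank - w, by = w)
  vapply(offs, function(o) {
    s <- if (strand == "+") eag_point + o else eag_point - o - w
    i <- s - genomic_start + 1L
    mean(v[i:(i + w - 1L)])
  }, numeric(1))
}
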