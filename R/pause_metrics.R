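# Per-gene quantification of the downstream-of-EAG pause: detection extent
# against a mock-derived threshold, exponential decay length, pausing
# indices, and narrow/broad shape classification.

#' Per-gene background from a mock anchor matrix
#'
#' @param mock_matrix Mock-track `AnchorMatrix`, congruent with the signal
#'   matrix (same genes and bins).
#' @param signal_matrix Optional signal matrix to check congruence against.
#' @return Data frame (gene, mean, sd, pooled flag). All-zero mock rows fall
#'   back to the pooled global mean/sd and are flagged.
#' @export
estimate_background <- function(mock_matrix, signal_matrix = NULL) {
  if (!is.null(signal_matrix)) {
    .assert(all(dim(mock_matrix) == dim(signal_matrix)) &&
              all(rownames(mock_matrix) == rownames(signal_matrix)),
            "mock and signal matrices are not congruent")
  }
  m <- unclass(mock_matrix)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  pooled_mean <- mean(m)
  pooled_sd <- sd(as.vector(m))
  zero <- mu == 0 & sdv == 0
  mu[zero] <- pooled_mean
  sdv[zero] <- pooled_sd
  data.frame(gene = rownames(m), mean = mu, sd = sdv, pooled = zero,
             row.names = NULL)
}

#' Pooled intergenic background of a coverage track
#'
#' Mean and sd of the per-base track value outside all gene bodies and their
#' flanks — the additive floor of the track itself, used when subtracting
#' background from the same track (the mock rpm level is a different track's
#' scale and is used only as a detection threshold).
#'
#' @param track A `CoverageTrack`.
#' @param gs A `GeneSet` whose neighbourhoods are excluded.
#' @param exclude_flank_bp Exclusion margin around each gene (default 9000,
#'   past the broadest modelled pause).
#' @return List with `mean` and `sd` (track scale).
#' @export
estimate_track_background <- function(track, gs, exclude_flank_bp = 9000) {
  sc <- .track_scale(track)
  tot <- 0; tot2 <- 0; n <- 0
  for (ch in names(track$cov)) {
    rle <- track$cov[[ch]]
    g <- gs$genes[gs$genes$chrom == ch, , drop = FALSE]
    excl <- IRanges::reduce(.ir(pmax(g$start - exclude_flank_bp, 0),
                                pmin(g$end + exclude_flank_bp, length(rle))))
    keep <- BiocGenerics::setdiff(IRanges::IRanges(1L, length(rle)), excl)
    if (length(keep) == 0L) next
    tot <- tot + sum(IRanges::viewSums(IRanges::Views(rle, keep)))
    tot2 <- tot2 + sum(IRanges::viewSums(IRanges::Views(rle * rle, keep)))
    n <- n + sum(BiocGenerics::width(keep))
  }
  .assert(n > 0, "no intergenic bases left to estimate background from")
  mu <- tot / n
  list(mean = mu * sc, sd = sqrt(pmax(tot2 / n - mu^2, 0)) * sc)
}

#' Downstream pause extent of one gene
#'
#' After centred running-mean smoothing, the extent is the distance from the
#' EAG to the start of the first downstream bin whose smoothed value falls
#' below `mean + 2 sd` of the background; 0 if the first downstream bin is
#' already below threshold, capped at the flank if no bin falls below.
#'
#' @param signal_row Density vector (one `AnchorMatrix` row, EAG-anchored).
#' @param eag_column Index (1-based) of the first downstream bin.
#' @param background List or row with `mean` and `sd`.
#' @param bin_width Bin width in bp.
#' @param smoothing_bins Running-mean window (default 3 bins).
#' @return Extent in bp.
#' @export
pause_extent <- function(signal_row, eag_column, background, bin_width = 50,
                         smoothing_bins = 3) {
  .assert(eag_column >= 1 && eag_column <= length(signal_row),
          "eag_column outside the row")
  smoothed <- .runmean(signal_row, smoothing_bins)
  thr <- background$mean + 2 * background$sd
  downstream <- smoothed[eag_column:length(signal_row)]
  below <- which(downstream < thr)
  if (length(below) == 0L)
    return((length(signal_row) - eag_column + 1L) * bin_width)
  (below[1L] - 1L) * bin_width
}

#' Exponential decay length of the downstream pause
#'
#' Least-squares slope of `log(signal - background_mean)` against distance
#' over downstream bins within the pause extent; `lambda = -1 / slope`.
#' Bins whose background-subtracted value is non-positive are unusable; with
#' fewer than 3 usable bins, or a non-negative slope, the result is
#' undefined (`NA`) rather than an error.
#'
#' @param signal_row Density vector (EAG-anchored row).
#' @param eag_column Index of the first downstream bin.
#' @param background List or row with `mean` (subtracted floor).
#' @param extent_bp Pause extent from [pause_extent()].
#' @param bin_width Bin width in bp.
#' @param fit_from_bp Exclude bins whose midpoint lies within this distance
#'   of the anchor (default 0). Coverage built from directionally extended
#'   fragments is a moving average over roughly twice the extension length,
#'   so pipelines fit from one extension length outward, where the convolved
#'   exponential tail keeps its decay constant exactly.
#' @return `lambda` in bp, or `NA` when undefined.
#' @export
decay_length <- function(signal_row, eag_column, background, extent_bp,
                         bin_width = 50, fit_from_bp = 0) {
  n_bins <- floor(extent_bp / bin_width)
  if (n_bins < 1L) return(NA_real_)
  idx <- eag_column + seq_len(min(n_bins, length(signal_row) - eag_column + 1L)) - 1L
  d <- (seq_along(idx) - 0.5) * bin_width
  resid <- signal_row[idx] - background$mean
  use <- resid > 0 & d > fit_from_bp
  if (sum(use) < 3L) return(NA_real_)
  fit <- lm(log(resid[use]) ~ d[use])
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  -1 / slope
}

#' TSS and downstream pausing indices for each gene
#'
#' `tss_index` is the mean density in `[TSS - 50, TSS + 300)` divided by the
#' mean body density (body = `[TSS + 300, EAG - 500)`, clipped to be
#' non-empty); `downstream_index` is the mean density in `(EAG, EAG + 4000]`
#' over the same body. A pseudocount is added to denominators. Genes too
#' short to host a body window get `NA` indices.
#'
#' @param track Signal `CoverageTrack` (rpm recommended).
#' @param gs A `GeneSet`.
#' @param tss_window,downstream_window Offsets (bp, downstream-positive)
#'   around the TSS / EAG anchor points.
#' @param body_trim `c(from_tss, from_eag)` bp trimmed off the body.
#' @param epsilon Pseudocount added to denominators (default 0.01).
#' @return Data frame: gene, tss_density, body_density, downstream_density,
#'   tss_index, downstream_index.
#' @export
pausing_indices <- function(track, gs, tss_window = c(-50, 300),
                            downstream_window = c(0, 4000),
                            body_trim = c(300, 500), epsilon = 0.01) {
  g <- gs$genes
  sc <- .track_scale(track)
  res <- data.frame(gene = g$name, tss_density = NA_real_,
                    body_density = NA_real_, downstream_density = NA_real_,
                    tss_index = NA_real_, downstream_index = NA_real_)
  tssp <- .anchor_point(g, "TSS")
  eagp <- .anchor_point(g, "EAG")
  window_mean <- function(rle, p, strand, o1, o2) {
    if (strand == "+") .window_means(rle, p + o1, p + o2) * sc
    else .window_means(rle, p - o2, p - o1) * sc
  }
  for (i in seq_len(nrow(g))) {
    rle <- track$cov[[g$chrom[i]]]
    if (is.null(rle)) next
    len <- g$end[i] - g$start[i]
    res$tss_density[i] <- window_mean(rle, tssp[i], g$strand[i],
                                      tss_window[1], tss_window[2])
    res$downstream_density[i] <- window_mean(rle, eagp[i], g$strand[i],
                                             downstream_window[1],
                                             downstream_window[2])
    if (len <= sum(body_trim)) next  # no body window for very short genes
    res$body_density[i] <- window_mean(rle, tssp[i], g$strand[i],
                                       body_trim[1], len - body_trim[2])
    res$tss_index[i] <- res$tss_density[i] / (res$body_density[i] + epsilon)
    res$downstream_index[i] <-
      res$downstream_density[i] / (res$body_density[i] + epsilon)
  }
  res
}

#' Classify a pause shape from its extent
#'
#' @param extent_bp Pause extent in bp (vectorised).
#' @param narrow_max_extent_bp Narrow/broad boundary (default 1000 bp,
#'   between the core-histone positive region at +0.1-0.3 kb and the
#'   poly(A)+ positive region starting +0.5-1 kb).
#' @return Character vector in `c("none", "narrow", "broad")`.
#' @export
classify_shape <- function(extent_bp, narrow_max_extent_bp = 1000) {
  out <- ifelse(extent_bp <= 0, "none",
                ifelse(extent_bp <= narrow_max_extent_bp, "narrow", "broad"))
  out
}

#' Per-gene pause metrics from signal and mock EAG matrices
#'
#' Combines [pause_extent()] (threshold from the per-gene mock background),
#' [decay_length()] (floor from `decay_background`, typically the signal
#' track's pooled intergenic level) and [classify_shape()].
#'
#' @param signal_matrix,mock_matrix Congruent EAG-anchored matrices.
#' @param decay_background List with `mean` (and optionally `sd`) subtracted
#'   before the log-linear decay fit; defaults to zero floor.
#' @param smoothing_bins,narrow_max_extent_bp,fit_from_bp See the underlying
#'   operations.
#' @return Data frame: gene, eag_peak, background_mean, background_sd,
#'   pause_extent_bp, decay_length_bp, shape_class.
#' @export
pause_metrics <- function(signal_matrix, mock_matrix,
                          decay_background = list(mean = 0),
                          smoothing_bins = 3, narrow_max_extent_bp = 1000,
                          fit_from_bp = 0) {
  bg <- estimate_background(mock_matrix, signal_matrix)
  w <- attr(signal_matrix, "bin_width")
  flank <- attr(signal_matrix, "flank_bp")
  eag_col <- as.integer(flank / w) + 1L
  m <- unclass(signal_matrix)
  n <- nrow(m)
  extent <- numeric(n)
  lambda <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    extent[i] <- pause_extent(m[i, ], eag_col, bg[i, ], bin_width = w,
                              smoothing_bins = smoothing_bins)
    lambda[i] <- decay_length(m[i, ], eag_col, decay_background, extent[i],
                              bin_width = w, fit_from_bp = fit_from_bp)
  }
  data.frame(
    gene = rownames(m),
    eag_peak = m[, eag_col],
    background_mean = bg$mean,
    background_sd = bg$sd,
    pause_extent_bp = extent,
    decay_length_bp = lambda,
    shape_class = classify_shape(extent, narrow_max_extent_bp),
    row.names = NULL
  )
}
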