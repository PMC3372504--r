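# The occupancy model, genome layout and tag sampler.

test_that("genome generation is deterministic and isolated by default", {
  g1 <- make_genome(n_genes = 12, seed = 5)
  g2 <- make_genome(n_genes = 12, seed = 5)
  expect_identical(g1$genes$genes, g2$genes$genes)
  expect_identical(g1$truth, g2$truth)
  # default spacing guarantees the isolated regime
  expect_equal(nrow(filter_isolated(g1$genes, 4000)$genes), 12L)
  # histone-cluster spacing defeats the isolation filter entirely
  gc <- make_genome(n_genes = 12, spacing_range = c(800, 1000),
                    n_chrom = 1, seed = 5)
  expect_equal(nrow(filter_isolated(gc$genes, 4000)$genes), 0L)
})

test_that("class mix controls layout and structure of planted genes", {
  g <- make_genome(n_genes = 30, class_mix = c(H = 1, PA = 0), seed = 2)
  expect_true(all(g$truth$pause_class == "H"))
  expect_true(all(g$genes$genes$intronless))
  expect_true(all(g$genes$genes$end - g$genes$genes$start <= 800))
  g2 <- make_genome(n_genes = 30, class_mix = c(H = 0, PA = 1), seed = 2)
  expect_true(all(g2$genes$genes$n_exons >= 2))
  expect_true(all(g2$genes$genes$end - g2$genes$genes$start >= 5000))
})

test_that("occupancy intensity components integrate to their closed forms", {
  gene <- data.frame(chrom = "chr1", start = 20000, end = 24000,
                     strand = "+", stringsAsFactors = FALSE)
  p <- occupancy_params("PA")
  v <- occupancy_intensity(gene, p, flank = 8000)
  len <- 4000
  closed <- p$background_rate * length(v) +
    p$tss_amplitude * p$tss_sd_bp * sqrt(2 * pi) +
    p$body_level * len +
    p$pause_amplitude * p$pause_decay_bp *
      (1 - exp(-p$pause_cap_bp / p$pause_decay_bp))
  expect_equal(sum(v), closed, tolerance = 1e-3)
  # at one decay length past the EAG the pause component is amp / e
  d_lambda <- v[attr(v, "genomic_start") * -1 + gene$end + p$pause_decay_bp]
  expect_equal(d_lambda - p$background_rate, p$pause_amplitude / exp(1),
               tolerance = 0.01)
  # mock parameterisation is pure background
  mock <- occupancy_params("PA", tss_amplitude = 0, body_level = 0,
                           pause_amplitude = 0)
  vm <- occupancy_intensity(gene, mock, flank = 8000)
  expect_true(all(vm == mock$background_rate))
})

test_that("intensity is mirror symmetric between strands", {
  p <- occupancy_params("H")
  plus <- data.frame(chrom = "c", start = 20000, end = 20600, strand = "+")
  L <- 60000
  minus <- data.frame(chrom = "c", start = L - 20600, end = L - 20000,
                      strand = "-")
  vp <- occupancy_intensity(plus, p, flank = 2000)
  vm <- occupancy_intensity(minus, p, flank = 2000)
  expect_equal(as.numeric(vp), rev(as.numeric(vm)))
})

test_that("tag sampling is seed-deterministic with Poisson-consistent depth", {
  gen <- make_genome(n_genes = 6, seed = 9)
  gi <- polpause:::.genome_intensity(gen, "chip")
  r1 <- sample_reads(gi$intensity, 10000, seed = 4)
  r2 <- sample_reads(gi$intensity, 10000, seed = 4)
  expect_identical(r1, r2)
  expect_false(identical(r1, sample_reads(gi$intensity, 10000, seed = 5)))
  # observed count within the Poisson 99.9% interval of the target depth
  expect_gt(nrow(r1), qpois(5e-4, 10000))
  expect_lt(nrow(r1), qpois(1 - 5e-4, 10000))
  expect_true(all(r1$end - r1$start <= 32))
  expect_error(sample_reads(list(chr1 = rep(0, 100)), 10), "zero total mass")
})

test_that("nascent tags are sense-stranded; zero background means none anti", {
  sc <- simulate_scenario(n_genes = 12, seed = 21, nascent_background = 0)
  af <- antisense_fraction(sc$reads$nascent, sc$genome$genes)
  defined <- af$antisense_fraction[!is.na(af$antisense_fraction)]
  expect_gt(length(defined), 0L)
  expect_true(all(defined == 0))
})

test_that("condition scaling touches only poly(A)+ parameters", {
  gen <- make_genome(n_genes = 20, seed = 3)
  tr <- apply_condition(gen$truth, gamma_downstream = 2, delta_tss = 0.5)
  pa <- gen$truth$pause_class == "PA"
  expect_equal(tr$pause_amplitude[pa], gen$truth$pause_amplitude[pa] * 2)
  expect_equal(tr$tss_amplitude[pa], gen$truth$tss_amplitude[pa] * 0.5)
  expect_equal(tr[!pa, ], gen$truth[!pa, ], ignore_attr = TRUE)
  # identity round trip
  expect_equal(apply_condition(gen$truth, 1, 1)$pause_amplitude,
               gen$truth$pause_amplitude)
})

test_that("planted extents on noiseless expected coverage match class truth", {
  gen <- make_genome(n_genes = 16, seed = 13)
  g <- gen$genes$genes
  for (i in seq_len(nrow(g))) {
    tr <- gen$truth[i, ]
    p <- as.list(tr[c("tss_amplitude", "tss_offset_bp", "tss_sd_bp",
                      "body_level", "pause_amplitude", "pause_decay_bp",
                      "pause_cap_bp", "background_rate")])
    v <- occupancy_intensity(g[i, , drop = FALSE], p, flank = 8000)
    pt <- if (g$strand[i] == "+") g$end[i] else g$start[i]
    row <- intensity_eag_row(v, attr(v, "genomic_start"), pt, g$strand[i])
    ext <- pause_extent(row, 81, list(mean = p$background_rate,
                                      sd = 0.005 * p$background_rate),
                        smoothing_bins = 1)
    if (tr$pause_class == "H") {
      expect_lte(ext, 1000)   # narrow: extinguished within the planted cap
      expect_gte(ext, 500)
    } else {
      expect_gte(ext, 2000)   # broad: detectable across the whole flank
    }
  }
})

test_that("sampled coverage converges to the extension-smoothed intensity", {
  sc <- simulate_scenario(n_genes = 10, seed = 17, depth_per_gene = 400)
  frags <- extend_reads(sc$reads$signal, 200, sc$genome$chrom_sizes)
  tr <- build_coverage(frags, 50, sc$genome$chrom_sizes,
                       normalization = "raw")
  gi <- polpause:::.genome_intensity(sc$genome, "chip")
  for (ch in names(sc$genome$chrom_sizes)) {
    v <- gi$intensity[[ch]]
    # expected coverage: half the 400-bp window integral at each bin centre
    cs <- cumsum(v)
    n_bins <- length(track_bins(tr)[[ch]])
    centre <- (seq_len(n_bins) - 0.5) * 50
    lo <- pmax(floor(centre - 200), 0)
    hi <- pmin(ceiling(centre + 200), length(v))
    expected <- (cs[hi] - ifelse(lo > 0, cs[pmax(lo, 1)], 0)) / 2
    expect_gt(cor(track_bins(tr)[[ch]], expected), 0.95)
  }
})

test_that("scenario files round-trip through the standard readers", {
  sc <- simulate_scenario(n_genes = 8, seed = 25)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  gs <- read_gene_models(file.path(dir, "genes.bed"), "bed12")
  expect_setequal(gs$genes$name, sc$genome$genes$genes$name)
  expect_equal(gs$genes[order(gs$genes$name), c("start", "end", "strand")],
               sc$genome$genes$genes[order(sc$genome$genes$genes$name),
                                     c("start", "end", "strand")],
               ignore_attr = TRUE)
  reads <- read_alignments_bed(file.path(dir, "signal.bed"))
  expect_equal(nrow(reads), nrow(sc$reads$signal))
  expect_equal(reads$start, sc$reads$signal$start)
})
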