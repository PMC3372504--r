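# Read extension, binned coverage, anchored matrices.

chrom1 <- c(chr1 = 100000L)

test_that("tags extend from their 5' end in read orientation, clipped", {
  reads <- data.frame(chrom = "chr1",
                      start = c(1000, 5000, 10), end = c(1032, 5032, 42),
                      strand = c("+", "-", "-"), stringsAsFactors = FALSE)
  fr <- extend_reads(reads, 200, chrom1)
  expect_equal(fr$start, c(1000, 4832, 0))
  expect_equal(fr$end, c(1200, 5032, 42))
  # reads already longer than the extension keep their native length
  long <- data.frame(chrom = "chr1", start = 0, end = 300, strand = "+")
  expect_equal(extend_reads(long, 200, chrom1)$end, 300)
  bad <- data.frame(chrom = "chr1", start = 99990, end = 100022,
                    strand = "+")
  expect_error(extend_reads(bad, 200, chrom1), "record 1")
})

test_that("bin values are mean per-base depth, including partial overlap", {
  tr <- build_coverage(frags_df("chr1", 1000, 1200), 50, chrom1,
                       normalization = "raw")
  b <- track_bins(tr)$chr1
  expect_equal(b[21:24], rep(1, 4))
  expect_equal(sum(b != 0), 4L)

  tr2 <- build_coverage(frags_df("chr1", 1025, 1225), 50, chrom1,
                        normalization = "raw")
  expect_equal(track_bins(tr2)$chr1[21:25], c(0.5, 1, 1, 1, 0.5))

  expect_error(build_coverage(frags_df("chr1", integer(0), integer(0)),
                              50, chrom1, normalization = "rpm"),
               "at least one fragment")
})

test_that("binned coverage equals the per-base oracle and conserves bp", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    s <- sample.int(9000, n)
    fr <- frags_df("chrS", s, s + sample(50:400, n, replace = TRUE),
                   sample(c("+", "-"), n, replace = TRUE))
    tr <- build_coverage(fr, 50, c(chrS = 10000L), normalization = "raw")
    expect_equal(track_bins(tr)$chrS, brute_bins(fr, 10000L, 50))
    expect_equal(sum(track_bins(tr)$chrS) * 50, sum(fr$end - fr$start))
  }
})

test_that("strand_mode restricts which fragments contribute", {
  fr <- frags_df("chr1", c(0, 0), c(100, 100), c("+", "-"))
  both <- build_coverage(fr, 50, chrom1, normalization = "raw")
  plus <- build_coverage(fr, 50, chrom1, strand_mode = "plus",
                         normalization = "raw")
  expect_equal(track_bins(both)$chr1[1], 2)
  expect_equal(track_bins(plus)$chr1[1], 1)
  expect_equal(plus$total_fragments, 1L)
})

test_that("rpm values are raw values scaled by 1e6 / total fragments", {
  fr <- frags_df("chr1", c(1000, 2000), c(1200, 2200))
  raw <- build_coverage(fr, 50, chrom1, normalization = "raw")
  rpm <- build_coverage(fr, 50, chrom1, normalization = "rpm")
  expect_equal(track_bins(rpm)$chr1, track_bins(raw)$chr1 * 1e6 / 2)
})

test_that("EAG windows anchor at the 3' boundary in both orientations", {
  gs <- gs_from_df(data.frame(
    chrom = "chr1", start = c(4000, 10000), end = c(10000, 16000),
    strand = c("+", "-"), name = c("plusg", "minusg"),
    stringsAsFactors = FALSE))
  # one fragment right at the plus gene's EAG boundary [10000, 10050)
  tr <- build_coverage(frags_df("chr1", 10000, 10050), 50, chrom1,
                       normalization = "raw")
  m <- anchor_matrix(tr, gs, "EAG", 4000)
  expect_equal(ncol(m), 160L)
  expect_equal(unname(m["plusg", 81]), 1)
  expect_equal(sum(m["plusg", ] != 0), 1L)
  # the minus gene's EAG point is its start (10000): its first downstream
  # bin covers [9950, 10000) and columns increase toward lower coordinates
  tr2 <- build_coverage(frags_df("chr1", 9950, 10000), 50, chrom1,
                        normalization = "raw")
  m2 <- anchor_matrix(tr2, gs, "EAG", 4000)
  expect_equal(unname(m2["minusg", 81]), 1)
  tr3 <- build_coverage(frags_df("chr1", 9900, 9950), 50, chrom1,
                        normalization = "raw")
  m3 <- anchor_matrix(tr3, gs, "EAG", 4000)
  expect_equal(unname(m3["minusg", 82]), 1)
})

test_that("a uniform track gives a constant matrix and flat mean profile", {
  tr <- uniform_track(20000, value = 1)
  gs <- gs_from_df(data.frame(chrom = "chr1", start = 8000, end = 12000,
                              strand = "+", name = "g",
                              stringsAsFactors = FALSE))
  m <- anchor_matrix(tr, gs, "EAG", 4000)
  expect_true(all(m == 1))
  expect_equal(mean_profile(m), rep(1, 160))
})

test_that("genome mirror plus strand flip leaves anchor matrices identical", {
  set.seed(11)
  L <- 60000L
  n <- 40
  s <- sample.int(L - 500L, n)
  fr <- frags_df("chr1", s, s + sample(50:300, n, replace = TRUE),
                 sample(c("+", "-"), n, replace = TRUE))
  gs <- gs_from_df(data.frame(
    chrom = "chr1", start = c(10000, 30000), end = c(15000, 36000),
    strand = c("+", "-"), name = c("gA", "gB"), stringsAsFactors = FALSE))
  tr <- build_coverage(fr, 50, c(chr1 = L), normalization = "raw")
  trM <- build_coverage(mirror_frags(fr, L), 50, c(chr1 = L),
                        normalization = "raw")
  for (anchor in c("EAG", "TSS")) {
    m <- anchor_matrix(tr, gs, anchor, 4000)
    mM <- anchor_matrix(trM, mirror_gs(gs, L), anchor, 4000)
    expect_identical(unclass(m)[rownames(m), ], unclass(mM)[rownames(m), ])
  }
})

test_that("scaled gene bodies match brute-force proportional means", {
  set.seed(3)
  n <- 30
  s <- sample.int(18000, n)
  fr <- frags_df("chr1", s, s + sample(50:400, n, replace = TRUE))
  tr <- build_coverage(fr, 50, c(chr1 = 20000L), normalization = "raw")
  gs <- gs_from_df(data.frame(chrom = "chr1", start = c(5000, 9000),
                              end = c(8017, 14000), strand = c("+", "-"),
                              name = c("gp", "gm"), stringsAsFactors = FALSE))
  m <- scaled_gene_matrix(tr, gs, n_body_bins = 10, flank_bp = 1000)
  expect_equal(ncol(m), 10 + 2 * 20)
  depth <- numeric(20000)
  for (i in seq_len(n)) depth[(fr$start[i] + 1):fr$end[i]] <-
      depth[(fr$start[i] + 1):fr$end[i]] + 1
  for (gn in c("gp", "gm")) {
    g <- gs$genes[gs$genes$name == gn, ]
    bounds <- g$start + round(seq(0, 10) * (g$end - g$start) / 10)
    body <- vapply(seq_len(10), function(k)
      mean(depth[(bounds[k] + 1):bounds[k + 1]]), numeric(1))
    if (g$strand == "-") body <- rev(body)
    expect_equal(unname(m[gn, 21:30]), body)
  }
  # uniform coverage stays flat through the proportional scaling
  mu <- scaled_gene_matrix(uniform_track(20000), gs, 10, 1000)
  expect_true(all(abs(mu - 1) < 1e-12))
})

test_that("mean profiles are column means with exact linearity", {
  m <- polpause:::.new_anchor_matrix(
    matrix(c(0, 2, 4, 0), 2, 2, byrow = TRUE,
           dimnames = list(c("a", "b"), NULL)), "EAG", 50, 50)
  expect_equal(mean_profile(m), c(2, 1))
  expect_equal(mean_profile(m, "a"), c(0, 2))
  expect_error(mean_profile(m, character(0)), "empty")
  # full mean equals the size-weighted mean of any partition
  expect_equal(mean_profile(m),
               (1 * mean_profile(m, "a") + 1 * mean_profile(m, "b")) / 2)
})
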