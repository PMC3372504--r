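# Pause extent, decay length, indices and shape classification.

mk_mat <- function(m, names, flank = 4000, w = 50) {
  polpause:::.new_anchor_matrix(
    `dimnames<-`(m, list(names, NULL)), "EAG", flank, w)
}

test_that("mock background is the per-gene row mean/sd with pooled fallback", {
  m <- mk_mat(rbind(rep(0.1, 160), rep(0, 160), runif(160)),
              c("flat", "zero", "rnd"))
  bg <- estimate_background(m)
  expect_equal(bg$mean[1], 0.1)
  expect_equal(bg$sd[1], 0)
  expect_true(bg$pooled[2])
  expect_equal(bg$mean[2], mean(m))  # pooled global fallback
  expect_equal(bg$mean[3], mean(m[3, ]))
  expect_equal(bg$sd[3], sd(m[3, ]))
  bad <- mk_mat(matrix(0, 2, 160), c("a", "b"))
  expect_error(estimate_background(m, bad), "congruent")
})

test_that("pause extent scans the smoothed downstream row to threshold", {
  w <- 50; flank <- 4000
  d <- seq(25, flank - 25, by = w)
  bg <- list(mean = 0.1, sd = 0.05)  # threshold 0.2
  # noiseless exponential over background, against a brute-force scan
  row <- c(rep(5, 80), 10 * exp(-d / 600) + 0.1)
  got <- pause_extent(row, 81, bg, bin_width = w)
  sm <- polpause:::.runmean(row, 3)
  brute <- (which(sm[81:160] < 0.2)[1] - 1) * w
  expect_equal(got, brute)
  expect_gt(got, 0)
  expect_lt(got, 4000)
  # everything below threshold from the first bin
  expect_equal(pause_extent(rep(0.05, 160), 81, bg), 0)
  # never drops below: capped at the flank
  expect_equal(pause_extent(rep(5, 160), 81, bg), 4000)
  # a slow decay that stays above threshold across the window is capped too
  expect_equal(pause_extent(c(rep(5, 80), 10 * exp(-d / 1500) + 0.1),
                            81, bg), 4000)
})

test_that("extent is scale invariant and monotone in the threshold", {
  d <- seq(25, 3975, by = 50)
  row <- c(rep(5, 80), 8 * exp(-d / 800) + 0.1)
  bg <- list(mean = 0.1, sd = 0.05)
  e1 <- pause_extent(row, 81, bg)
  e2 <- pause_extent(row * 7, 81, list(mean = 0.7, sd = 0.35))
  expect_equal(e1, e2)
  for (s in c(0.1, 0.3, 0.6)) {
    expect_lte(pause_extent(row, 81, list(mean = 0.1, sd = s)),
               pause_extent(row, 81, list(mean = 0.1, sd = s / 2)))
  }
})

test_that("noiseless exponentials give machine-precision decay lengths", {
  d <- seq(25, 3975, by = 50)
  for (lam in c(250, 1500)) {
    row <- c(rep(0, 80), 10 * exp(-d / lam) + 0.1)
    est <- decay_length(row, 81, list(mean = 0.1), extent_bp = 2000)
    expect_equal(est, lam, tolerance = 1e-9)
  }
  # scale invariance of the decay constant
  row <- c(rep(0, 80), 10 * exp(-d / 250) + 0.1)
  expect_equal(decay_length(row * 3, 81, list(mean = 0.3), 2000), 250,
               tolerance = 1e-9)
})

test_that("degenerate decay fits are undefined, not errors", {
  row <- c(rep(0, 80), rep(0.05, 80))
  expect_true(is.na(decay_length(row, 81, list(mean = 0.1), 4000)))
  expect_true(is.na(decay_length(row, 81, list(mean = 0), 100)))  # < 3 bins
  rising <- c(rep(0, 80), seq(1, 5, length.out = 80))
  expect_true(is.na(decay_length(rising, 81, list(mean = 0), 4000)))
})

test_that("fit_from_bp drops the kernel-contaminated bins near the anchor", {
  d <- seq(25, 3975, by = 50)
  pure <- 10 * exp(-d / 500)
  contaminated <- pure
  contaminated[d < 200] <- pure[d < 200] * 0.4  # extension transition
  row <- c(rep(0, 80), contaminated + 0.1)
  biased <- decay_length(row, 81, list(mean = 0.1), 3000)
  corrected <- decay_length(row, 81, list(mean = 0.1), 3000,
                            fit_from_bp = 200)
  expect_gt(abs(biased - 500), abs(corrected - 500))
  expect_equal(corrected, 500, tolerance = 1e-9)
})

test_that("pausing indices equal brute-force oriented window ratios", {
  flat <- uniform_track(30000, value = 2, normalization = "raw")
  gs <- gs_from_df(data.frame(chrom = "chr1", start = c(6000, 14000),
                              end = c(10000, 20000), strand = c("+", "-"),
                              name = c("gp", "gm"), stringsAsFactors = FALSE))
  pi_flat <- pausing_indices(flat, gs, epsilon = 0.01)
  expect_equal(pi_flat$tss_index, rep(2 / 2.01, 2))
  expect_equal(pi_flat$downstream_index, rep(2 / 2.01, 2))

  set.seed(19)
  n <- 80
  s <- sample.int(29000, n)
  fr <- frags_df("chr1", s, s + sample(100:400, n, replace = TRUE))
  tr <- build_coverage(fr, 50, c(chr1 = 30000L), normalization = "raw")
  res <- pausing_indices(tr, gs, epsilon = 0.01)
  depth <- numeric(30000)
  for (i in seq_len(n)) depth[(fr$start[i] + 1):fr$end[i]] <-
    depth[(fr$start[i] + 1):fr$end[i]] + 1
  wmean <- function(a, b) mean(depth[(a + 1):b])
  # plus gene: tss point 6000, eag point 10000
  expect_equal(res$tss_density[1], wmean(5950, 6300))
  expect_equal(res$body_density[1], wmean(6300, 9500))
  expect_equal(res$downstream_density[1], wmean(10000, 14000))
  expect_equal(res$tss_index[1],
               wmean(5950, 6300) / (wmean(6300, 9500) + 0.01))
  # minus gene: tss point 20000, eag point 14000
  expect_equal(res$tss_density[2], wmean(19700, 20050))
  expect_equal(res$downstream_density[2], wmean(10000, 14000))
})

test_that("genes without a body window get undefined indices", {
  tr <- uniform_track(10000, normalization = "raw")
  gs <- gs_from_df(data.frame(chrom = "chr1", start = 5000, end = 5500,
                              strand = "+", name = "tiny",
                              stringsAsFactors = FALSE))
  res <- pausing_indices(tr, gs)
  expect_true(is.na(res$tss_index))
  expect_true(is.na(res$body_density))
})

test_that("shapes classify by extent against the narrow/broad boundary", {
  expect_equal(classify_shape(c(300, 4500, 0, 1000, 1050)),
               c("narrow", "broad", "none", "narrow", "broad"))
})

test_that("the metrics wrapper combines extent, decay and shape per gene", {
  w <- 50; d <- seq(25, 3975, by = 50)
  sig <- rbind(c(rep(2, 80), 10 * exp(-d / 250) + 0.02),
               c(rep(2, 80), 10 * exp(-d / 1500) + 0.02))
  mock <- matrix(0.5, 2, 160)
  sm <- mk_mat(sig, c("narrowg", "broadg"))
  mm <- mk_mat(mock, c("narrowg", "broadg"))
  out <- pause_metrics(sm, mm, decay_background = list(mean = 0.02))
  expect_equal(out$shape_class, c("narrow", "broad"))
  expect_equal(out$decay_length_bp, c(250, 1500), tolerance = 1e-6)
  expect_equal(out$background_mean, c(0.5, 0.5))
})
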