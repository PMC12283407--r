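test_that("bin and profile validation rejects malformed inputs", {
  expect_error(cn_bins("chr1", 100, 100), "end > start")
  expect_error(cn_bins("chr1", c(0, 50), c(100, 150)), "overlap")
  g <- tiny_genome()
  expect_error(make_profile(g, "chr1", 0, 2e7, 2), "past chromosome end")
  expect_error(make_profile(g, "chr1", 0, 1e6, -1), ">= 0")
  expect_error(make_profile(g, c("chr1", "chr1"), c(0, 5e5), c(1e6, 1.5e6),
                            c(2, 3)), "overlap")
})

test_that("correct_counts flattens planted GC bias and masks low mappability", {
  n <- 500
  gc <- seq(0.3, 0.6, length.out = n)
  bias <- exp(-15 * (gc - 0.45)^2)  # planted quadratic-type GC curve
  bins <- cn_bins("chr1", (0:(n - 1)) * 5e4, (1:n) * 5e4, gc = gc,
                  mappability = 1, count = 100 * bias)
  out <- correct_counts(bins)
  # residual flatness: brute-force binning of corrected values by GC decile
  dec <- cut(out$gc, stats::quantile(out$gc, 0:10 / 10),
             include.lowest = TRUE)
  group_medians <- tapply(out$value, dec, stats::median)
  expect_lt(max(abs(group_medians - 1)), 0.05)
  expect_equal(stats::median(out$value), 1)

  # constant counts and covariates: all values exactly 1
  flat <- cn_bins("chr1", (0:99) * 5e4, (1:100) * 5e4, gc = 0.4,
                  mappability = 1, count = 80)
  expect_equal(unique(correct_counts(flat)$value), 1)

  # masked bin dropped
  flat$mappability[5] <- 0
  out2 <- correct_counts(flat)
  expect_equal(nrow(out2), 99)

  # degenerate inputs
  zero <- cn_bins("chr1", c(0, 5e4), c(5e4, 1e5), gc = 0.4, count = 0)
  expect_error(correct_counts(zero), "empty profile")
  noanno <- cn_bins("chr1", c(0, 5e4), c(5e4, 1e5), count = 10)
  expect_error(correct_counts(noanno), "annotation")
})

test_that("segment_profile recovers exact steps and matches the DP oracle", {
  g <- tiny_genome(1, 3e5)
  step <- cn_bins("chr1", (0:5) * 5e4, (1:6) * 5e4, gc = 0.4,
                  count = 1, value = c(1, 1, 1, 3, 3, 3))
  prof <- segment_profile(step, penalty = 0.01, genome = g)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$value, c(1, 3))
  expect_equal(prof$n_bins, c(3L, 3L))

  flat <- cn_bins("chr1", (0:5) * 5e4, (1:6) * 5e4, gc = 0.4,
                  count = 1, value = 2)
  expect_equal(nrow(segment_profile(flat, penalty = 0.01, genome = g)), 1)

  expect_error(segment_profile(step, penalty = 0), "positive")

  # planted changepoints with noise: within 1 bin of the truth, and the
  # PELT search agrees with the exhaustive DP oracle
  set.seed(11)
  truth_cp <- c(30, 65, 100, 140, 170)
  means <- c(2, 3, 1.5, 2.5, 4, 2)
  x <- rep(means, diff(c(0, truth_cp, 200))) + rnorm(200, 0, 0.05)
  g2 <- tiny_genome(1, 200 * 5e4)
  b <- cn_bins("chr1", (0:199) * 5e4, (1:200) * 5e4, gc = 0.4, count = 1,
               value = x)
  pen <- 2 * 0.05^2 * log(200)
  prof2 <- segment_profile(b, penalty = pen, genome = g2)
  found <- prof2$end[-nrow(prof2)] / 5e4
  expect_equal(length(found), 5)
  expect_true(all(abs(found - truth_cp) <= 1))
  expect_equal(found, op_changepoints_dp(x, pen))

  # PELT equals the exhaustive oracle across random penalties/signals
  for (s in 1:5) {
    set.seed(100 + s)
    y <- rep(sample(1:4, 4, replace = TRUE), each = 25) + rnorm(100, 0, 0.1)
    pen_s <- runif(1, 0.01, 0.5)
    expect_equal(cinresist:::pelt_mean(y, pen_s),
                 op_changepoints_dp(y, pen_s))
  }
})

test_that("smooth_merge follows the greedy running-mean rule", {
  g <- tiny_genome(1)
  p <- make_profile(g, "chr1", c(0, 1e6, 2e6), c(1e6, 2e6, 3e6),
                    c(2.0, 2.05, 2.09))
  out <- smooth_merge(p)
  expect_equal(nrow(out), 1)
  expect_equal(out$value, mean(c(2.0, 2.05, 2.09)))

  p2 <- make_profile(g, "chr1", c(0, 1e6), c(1e6, 2e6), c(2.0, 2.3))
  expect_equal(nrow(smooth_merge(p2)), 2)

  # chain 2.0, 2.09, 2.18: first two merge (running mean 2.045), third is
  # 0.135 away and stays separate
  p3 <- make_profile(g, "chr1", c(0, 1e6, 2e6), c(1e6, 2e6, 3e6),
                     c(2.0, 2.09, 2.18))
  out3 <- smooth_merge(p3)
  expect_equal(out3$value, c(2.045, 2.18))

  # post-condition: no adjacent pair within tol, total length conserved
  for (s in 1:10) {
    set.seed(s)
    n <- 20
    vals <- cumsum(rnorm(n, 0, 0.12)) + 2
    bounds <- sort(sample(seq(1e5, 9.9e6, by = 1e5), n - 1))
    p <- make_profile(g, "chr1", c(0, bounds), c(bounds, 1e7), abs(vals))
    out <- smooth_merge(p, tol = 0.1)
    if (nrow(out) > 1)
      expect_true(all(abs(diff(out$value)) > 0.1))
    expect_equal(sum(out$end - out$start), 1e7)
  }
})

test_that("resegment_30kb snaps to the grid, drops 30kb orphans, idempotent", {
  g <- tiny_genome(1, 9e6)
  cols <- c("chrom", "start", "end", "value")
  # single whole-chromosome segment: unchanged
  p <- make_profile(g, "chr1", 0, 9e6, 2)
  out <- resegment_30kb(p)
  expect_equal(as.data.frame(out)[cols], as.data.frame(p)[cols])

  # two 90kb segments: boundary already on the grid, no orphan created
  p2 <- make_profile(g, "chr1", c(0, 9e4), c(9e4, 1.8e5), c(2, 4))
  out2 <- resegment_30kb(p2)
  expect_equal(out2$start, c(0, 9e4))
  expect_equal(out2$end, c(9e4, 1.8e5))
  expect_equal(out2$value, c(2, 4))

  # off-grid boundary at 100kb: bin 90-120kb averages (2*10+4*20)/30 = 3.33,
  # becoming a 30kb orphan that is removed
  p3 <- make_profile(g, "chr1", c(0, 1e5), c(1e5, 1.8e5), c(2, 4))
  out3 <- resegment_30kb(p3)
  expect_equal(nrow(out3), 2)
  expect_equal(out3$value, c(2, 4))
  expect_equal(out3$end[1], 9e4)
  expect_equal(out3$start[2], 1.2e5)

  # exactly-30kb segment between two long segments differing by > 0.1
  p4 <- make_profile(g, "chr1", c(0, 3e6, 3e6 + 3e4), c(3e6, 3e6 + 3e4, 6e6),
                     c(2, 5, 3))
  out4 <- resegment_30kb(p4)
  expect_equal(out4$value, c(2, 3))

  # idempotence on grid-aligned output
  expect_equal(as.data.frame(resegment_30kb(out4))[cols],
               as.data.frame(out4)[cols])
})

test_that("wGII averages per-chromosome aberrant fractions", {
  g24 <- genome_table(paste0("chr", 1:24), rep(1e7, 24), rep(5e6, 24))
  flat <- make_profile(g24, paste0("chr", 1:24), rep(0, 24), rep(1e7, 24),
                       rep(2, 24))
  expect_equal(wgii(flat), 0)

  # genome at CN 3 except one whole chromosome at CN 2: wGII = 1/24
  vals <- c(rep(3, 23), 2)
  p <- make_profile(g24, paste0("chr", 1:24), rep(0, 24), rep(1e7, 24), vals)
  expect_equal(wgii(p), 1 / 24)

  # half of every chromosome aberrant: wGII = 0.5
  p2 <- make_profile(g24, rep(paste0("chr", 1:24), each = 2),
                     rep(c(0, 5e6), 24), rep(c(5e6, 1e7), 24),
                     rep(c(2, 3), 24))
  expect_equal(wgii(p2), 0.5)

  expect_error(wgii(flat[0, ]), "empty")
})

test_that("profile_difference measures discordant genome fraction", {
  g <- genome_table(paste0("chr", 1:10), rep(1e7, 10), rep(5e6, 10))
  p <- make_profile(g, paste0("chr", 1:10), rep(0, 10), rep(1e7, 10),
                    rep(2, 10))
  expect_equal(profile_difference(p, p), 0)

  # differ on exactly one of ten equal chromosomes: 10%
  q <- p
  vals <- q$value
  vals[1] <- 3
  q <- make_profile(g, q$chrom, q$start, q$end, vals)
  expect_equal(profile_difference(p, q), 10)
  expect_equal(profile_difference(q, p), 10)  # symmetric

  # all values shifted by +1: 100%
  r <- make_profile(g, p$chrom, p$start, p$end, p$value + 1)
  expect_equal(profile_difference(p, r), 100)

  disjoint <- make_profile(g, "chr1", 0, 1e6, 2)
  other <- make_profile(g, "chr2", 0, 1e6, 2)
  expect_error(profile_difference(disjoint, other), "disjoint")
})

test_that("segment and bin tables round-trip through disk", {
  g <- tiny_genome()
  p <- make_profile(g, c("chr1", "chr1", "chr2"), c(0, 4e6, 1e6),
                    c(4e6, 8e6, 5e6), c(2, 3.25, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(p, path)
  back <- read_segments(path, g, space = "absolute")
  expect_equal(as.data.frame(back), as.data.frame(p))
  # SEG convention on disk: 1-based inclusive start
  raw <- utils::read.delim(path)
  expect_equal(raw$start[1], 1)

  b <- cn_bins("chr1", c(0, 5e4), c(5e4, 1e5), gc = c(0.4, 0.5),
               mappability = c(1, 0.9), reptiming = c(0.1, -0.2),
               count = c(10, 20))
  bpath <- withr::local_tempfile(fileext = ".tsv")
  write_bins(b, bpath)
  expect_equal(as.data.frame(read_bins(bpath)), as.data.frame(b))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t300", "chr2\t0\t50"), bed)
  panel <- read_bed(bed)
  expect_equal(nrow(panel), 2)  # overlapping chr1 intervals merged
  expect_equal(panel$end[panel$chrom == "chr1"], 300)
})
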