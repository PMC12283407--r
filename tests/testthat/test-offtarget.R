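make_grid_bins <- function(n = 200, width = 5e4, count = 100) {
  cn_bins("chr1", (0:(n - 1)) * width, (1:n) * width, gc = 0.45,
          mappability = 1, reptiming = 0, count = count)
}

test_that("annotate_overlaps does the interval arithmetic", {
  bins <- make_grid_bins(3)
  panel <- panel_design(data.frame(
    chrom = "chr1",
    start = c(0, 60000, 75000, 90000),
    end = c(50000, 63000, 78000, 94000)))
  out <- annotate_overlaps(bins, panel)
  # bin 1 fully inside one target
  expect_equal(out$overlap_fraction[1], 1)
  expect_equal(out$overlap_count[1], 1)
  # bin 2 (50-100kb) overlapped 3+3+4 = 10 kb by 3 targets
  expect_equal(out$overlap_fraction[2], 0.2)
  expect_equal(out$overlap_count[2], 3)
  # bin 3 untouched
  expect_equal(out$overlap_fraction[3], 0)
  expect_equal(out$overlap_count[3], 0)
})

test_that("filter_bins applies strict/inclusive boundaries and PoN flags", {
  bins <- make_grid_bins(5)
  bins <- annotate_overlaps(bins, panel_design(
    data.frame(chrom = "chr1", start = 1, end = 2)))
  bins$overlap_fraction <- c(0.25, 0.249, 0, 0, 0)
  bins$overlap_count <- c(0L, 0L, 10L, 11L, 0L)
  pon <- build_pon(matrix(100, 5, 3), bins)
  pon$usable <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  out <- filter_bins(bins, pon)
  # fraction 0.25 removed (strict <), 0.249 kept; count 10 kept, 11 removed;
  # PoN-unusable removed even with zero overlap
  expect_equal(out$start / 5e4, c(1, 2))
  expect_equal(attr(out, "removed"),
               c(overlap_fraction = 1L, overlap_count = 1L,
                 pon_unusable = 1L))

  # monotone in the cutoffs: relaxing never removes more bins
  strict <- filter_bins(bins, pon, max_fraction = 0.2, max_count = 5)
  relaxed <- filter_bins(bins, pon, max_fraction = 0.3, max_count = 12)
  expect_true(all(strict$start %in% relaxed$start))

  expect_error(filter_bins(bins[1:3, ], pon), "grid")
})

test_that("fill_pseudocounts rescales the PoN mean to sample depth", {
  bins <- make_grid_bins(4, count = 60)  # sample median depth 60
  bins$overlap_fraction <- c(0, 0, 0.1, 0)
  bins$overlap_count <- c(0L, 0L, 2L, 0L)
  bins$count[3] <- 5
  pon <- build_pon(matrix(40, 4, 3), bins)  # PoN per-bin mean 40
  out <- fill_pseudocounts(bins, pon)
  # depth ratio 60/40 = 1.5, pseudocount = 40 * 1.5 = 60
  expect_equal(out$count[3], 60)
  expect_true(out$pseudocount[3])
  expect_equal(out$count[c(1, 2, 4)], rep(60, 3))  # untouched
  expect_false(any(out$pseudocount[c(1, 2, 4)]))

  allhit <- bins
  allhit$overlap_count <- rep(1L, 4)
  expect_error(fill_pseudocounts(allhit, pon), "overlap-free")
})

test_that("bias_correct removes a planted log-linear bias", {
  set.seed(21)
  n <- 400
  bins <- make_grid_bins(n)
  score <- rnorm(n)
  score <- (score - mean(score)) / sd(score)
  bins$bias_score <- score
  beta <- 0.5
  bins$count <- rpois(n, 100 * exp(beta * score))
  out <- bias_correct(bins)
  expect_equal(attr(out, "bias_slope"), beta, tolerance = 0.05)
  refit <- coef(lm(log(out$count[out$count > 0]) ~
                     out$bias_score[out$count > 0]))[2]
  expect_lt(abs(refit), 0.02)
  # genome-wide median approximately preserved
  expect_equal(median(out$count), 100, tolerance = 0.05)

  # all-zero score: identity
  flat <- make_grid_bins(50)
  flat$bias_score <- 0
  expect_warning(out2 <- bias_correct(flat), "degenerate")
  expect_equal(out2$count, flat$count)

  # two-bin input: no-op with warning
  two <- make_grid_bins(2)
  two$bias_score <- c(-1, 1)
  expect_warning(out3 <- bias_correct(two), "degenerate")
  expect_equal(out3$count, two$count)
})

test_that("loess_correct flattens planted GC bias and is near-identity on null", {
  set.seed(22)
  n <- 600
  bins <- make_grid_bins(n)
  bins$gc <- runif(n, 0.3, 0.6)
  bins$reptiming <- rnorm(n)
  bias <- sin(pi * (bins$gc - 0.3) / 0.6) * 0.4  # rising sine arc
  bins$count <- rpois(n, 100 * exp(bias))
  expect_gt(cor(bins$count, bins$gc, method = "spearman"), 0.3)
  out <- loess_correct(bins)
  expect_lt(abs(cor(out$count, bins$gc, method = "spearman")), 0.05)
  # genome-wide median preserved relative to the input
  expect_equal(median(out$count), median(bins$count), tolerance = 0.01)

  # unbiased counts: correction changes values by little
  null_bins <- make_grid_bins(n)
  null_bins$gc <- runif(n, 0.3, 0.6)
  null_bins$reptiming <- rnorm(n)
  null_bins$count <- rpois(n, 100)
  out_null <- loess_correct(null_bins)
  rel_change <- abs(out_null$count - null_bins$count) / null_bins$count
  expect_lt(median(rel_change), 0.02)

  # constant gc: the gc pass is the identity
  const <- make_grid_bins(n)
  const$count <- rpois(n, 100)
  before <- const$count
  out_const <- loess_correct(const)
  expect_equal(out_const$count, before)

  # too few bins: no-op with one warning per skipped pass
  small <- make_grid_bins(20)
  small$gc <- runif(20, 0.3, 0.6)
  warns <- capture_warnings(out_small <- loess_correct(small))
  expect_length(warns, 2)
  expect_match(warns, "100 usable", all = TRUE)
  expect_equal(out_small$count, small$count)
})

test_that("off-target pipeline recovers a synthetic tumor profile", {
  prof <- simulate_absolute_profile(ploidy = 3.0, seed = 31)
  sim <- simulate_panel(prof, purity = 0.6, beta = 0.4, gc_slope = 0.5,
                        rt_slope = 0.05, seed = 32)
  res <- offtarget_pipeline(sim$bins, sim$panel, sim$pon,
                            anchor = list(purity = 0.6, ploidy = 3.0),
                            genome = toy_genome())
  expect_lt(profile_difference(res$profile, prof), 10)
  expect_true(abs(res$fit$best$purity - 0.6) <= 0.05 + 1e-9)
  expect_true(abs(res$fit$best$ploidy - 3.0) <= 0.2 + 1e-9)

  # an empty panel reduces to the plain sWGS path
  empty_panel <- panel_design(data.frame(chrom = "chr1", start = 0,
                                         end = 1))[0, ]
  class(empty_panel) <- c("panel_design", "data.frame")
  sim0 <- simulate_panel(prof, purity = 0.6, n_targets = 0, beta = 0,
                         seed = 33)
  res0 <- offtarget_pipeline(sim0$bins, empty_panel, sim0$pon,
                             anchor = list(purity = 0.6, ploidy = 3.0),
                             genome = toy_genome())
  expect_lt(profile_difference(res0$profile, prof), 5)
  expect_false(any(res0$bins$pseudocount))
})

test_that("simulate_panel's planted similarity bias is recovered", {
  prof <- simulate_absolute_profile(ploidy = 2.0, seed = 41, n_segments = 8)
  sim <- simulate_panel(prof, purity = 1, beta = 0.4, seed = 42)
  b <- annotate_overlaps(sim$bins, sim$panel)
  b$bias_score <- similarity_bias_score(sim$pon)
  ok <- b$count > 0
  slope <- coef(lm(log(b$count[ok]) ~ b$bias_score[ok]))[2]
  # score is standardized, so the regression slope is beta * sd(z)
  expect_equal(unname(slope), 0.4 * sd(sim$truth$z), tolerance = 0.1)
})
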