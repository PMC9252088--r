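test_that("the binomial null matches the mean-of-nonzero-bins estimator", {
  m <- estimate_binomial_model(c(0, 0, 2, 4, 6), n = 12)
  expect_equal(m$p, 1 / 3)
  expect_equal(m$n, 12)

  # constant counts: p = c / n
  m <- estimate_binomial_model(rep(7, 5), n = 100)
  expect_equal(m$p, 7 / 100)

  expect_error(estimate_binomial_model(c(0, 0, 0), n = 10), "no signal")

  # real-valued scaled counts are rounded half-away-from-zero first
  m <- estimate_binomial_model(c(0, 1.5, 2.4), n = 10)
  expect_equal(m$p, mean(c(2, 2)) / 10)
})

test_that("upper-tail p-values are exact", {
  m <- list(n = 10, p = 0.5)
  expect_equal(binom_tail(0, m), 1)
  expect_equal(binom_tail(10, m), 0.5^10)
  m <- list(n = 20, p = 0.1)
  expect_equal(binom_tail(5, m), brute_binom_tail(5, 20, 0.1))
  expect_error(binom_tail(21, m), "exceeds")
})

test_that("BH adjustment is the standard step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(3)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_equal(bh_adjust(p), brute_bh(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("only bins strictly above minreads are tested, BH over that family", {
  bins <- iv("chr1", (0:3) * 100, (0:3) * 100 + 100)
  bins$count <- c(15, 16, 40, 2)
  bins$cpm <- bins$count
  out <- test_bins(bins, n = 100, minreads = 15)
  expect_equal(out$tested, c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(out$pvalue[!out$tested])))
  expect_false(any(out$significant[!out$tested]))
  # BH family is the 2 tested bins only
  expect_equal(
    out$padj[out$tested],
    brute_bh(out$pvalue[out$tested])
  )

  # vacuous family: nothing tested, nothing significant
  bins$count <- rep(3, 4)
  bins$cpm <- bins$count
  out <- test_bins(bins, n = 100)
  expect_equal(sum(out$tested), 0)
  expect_equal(nrow(merge_significant(out[out$significant, ])), 0)
})

test_that("significance uses adjusted p <= threshold", {
  bins <- iv("chr1", c(0, 100), c(100, 200))
  bins$count <- c(16, 30)
  bins$cpm <- bins$count
  out <- test_bins(bins, n = 60, minreads = 15, pthresh = 0.05)
  expect_equal(out$significant[out$tested], out$padj[out$tested] <= 0.05)
})

test_that("significant bins merge under the gap rule and width filter", {
  bins <- iv("chr1", c(0, 150), c(100, 250))
  pk <- merge_significant(bins, mdist = 150, minwidth = 150)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 0)
  expect_equal(pk$end, 250)
  expect_equal(pk$n_bins, 2L)

  # gap 200 > mdist: two candidates, both then dropped by minwidth
  bins <- iv("chr1", c(0, 300), c(100, 400))
  expect_equal(nrow(merge_significant(bins, mdist = 150, minwidth = 150)), 0)

  pk <- merge_significant(iv("chr1", 0, 200), mdist = 150, minwidth = 150)
  expect_equal(nrow(pk), 1)

  # chromosomes never merge, whatever the coordinates
  bins <- iv(c("chr1", "chr2"), c(0, 50), c(200, 250))
  expect_equal(nrow(merge_significant(bins, mdist = 1e6, minwidth = 0)), 2)
})

test_that("merging equals connected-components brute force on random instances", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    start <- sort(sample(0:500, n))
    bins <- iv(
      sample(c("c1", "c2"), n, replace = TRUE),
      start, start + sample(10:80, n, replace = TRUE)
    )
    mdist <- sample(c(0, 20, 50, 150), 1)
    got <- merge_significant(bins, mdist = mdist, minwidth = 0)
    want <- brute_merge(as.data.frame(bins), mdist)
    expect_equal(as.data.frame(got[, c("chrom", "start", "end")]), want)
  }
})

test_that("peak statistics aggregate min padj and max count over merged bins", {
  bins <- iv("chr1", c(0, 100, 400), c(150, 250, 600))
  bins$padj <- c(0.01, 0.001, 0.04)
  bins$test_count <- c(20L, 35L, 18L)
  pk <- merge_significant(bins, mdist = 150, minwidth = 100)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$min_padj, 0.001)
  expect_equal(pk$max_count, 35)
  expect_equal(pk$n_bins, 3L)
  expect_equal(pk$score, -log10(0.001))
})

test_that("a single simulated enriched region yields exactly one covering peak", {
  sizes <- tibble::tibble(chrom = "chrT", size = 500000L)
  cfg <- sim_config(sizes,
    truth = tibble::tibble(
      chrom = "chrT", start = 200000, end = 201000,
      shape = "narrow", fold = 20
    ),
    background_rate = 2, depth = 5e4
  )
  sim <- simulate_fragments(cfg, seed = 7)
  fit <- call_peaks(sim$sample, sizes)
  pk <- tidy(fit)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start < 201000 && pk$end > 200000)
  expect_gt(binpeaks:::overlap_coverage(sim$truth, pk) / 1000, 0.5)
})

test_that("uniform background alone yields no peaks at defaults", {
  sizes <- tibble::tibble(chrom = "chrT", size = 1000000L)
  cfg <- sim_config(sizes, background_rate = 2)
  sim <- simulate_fragments(cfg, seed = 5)
  fit <- call_peaks(sim$sample, sizes)
  expect_equal(nrow(tidy(fit)), 0)
})

test_that("a sample used as its own control calls no peaks", {
  sizes <- tibble::tibble(chrom = "chrT", size = 200000L)
  cfg <- sim_config(sizes,
    truth = tibble::tibble(
      chrom = "chrT", start = 100000, end = 101000,
      shape = "narrow", fold = 20
    ),
    background_rate = 2, depth = 2e4
  )
  sim <- simulate_fragments(cfg, seed = 2)
  fit <- call_peaks(sim$sample, sizes, control = sim$sample)
  expect_equal(nrow(tidy(fit)), 0)
})

test_that("adding fragments inside a called peak never removes it", {
  sizes <- tibble::tibble(chrom = "chrT", size = 500000L)
  cfg <- sim_config(sizes,
    truth = tibble::tibble(
      chrom = "chrT", start = 200000, end = 201000,
      shape = "narrow", fold = 20
    ),
    background_rate = 2, depth = 5e4
  )
  sim <- simulate_fragments(cfg, seed = 9)
  base_fit <- call_peaks(sim$sample, sizes)
  pk <- tidy(base_fit)
  expect_equal(nrow(pk), 1)
  extra <- iv(
    rep("chrT", 50),
    round(seq(pk$start[1], pk$end[1] - 120, length.out = 50))
  , NA)
  extra$end <- extra$start + 100
  boosted <- call_peaks(dplyr::bind_rows(sim$sample, extra), sizes)
  pk2 <- tidy(boosted)
  expect_true(any(pk2$start < pk$end[1] & pk2$end > pk$start[1]))
})

test_that("broad mode keeps a 20-kb domain as one peak", {
  cfg <- broad_scenario()
  sim <- simulate_fragments(cfg, seed = 21)
  fit <- call_peaks(sim$sample, cfg$chrom_sizes,
    control = sim$control, broad = TRUE, mdist = 3000
  )
  expect_equal(fit$params$step, 5000)
  expect_equal(fit$params$slide, 1000)
  pk <- tidy(fit)
  expect_equal(nrow(pk), 1)
  covered <- binpeaks:::overlap_coverage(sim$truth, pk) / 20000
  expect_gte(covered, 0.95)
})

test_that("glance reports the run summary and write_peaks emits sorted BED", {
  sizes <- tibble::tibble(chrom = "chrT", size = 500000L)
  cfg <- sim_config(sizes,
    truth = tibble::tibble(
      chrom = "chrT", start = c(100000, 300000), end = c(101000, 301000),
      shape = "narrow", fold = 20
    ),
    background_rate = 2, depth = 5e4
  )
  sim <- simulate_fragments(cfg, seed = 4)
  fit <- call_peaks(sim$sample, sizes)
  g <- glance(fit)
  expect_equal(g$n_peaks, nrow(tidy(fit)))
  expect_equal(g$n_fragments, nrow(sim$sample))
  expect_true(g$null_p > 0 && g$null_p < 1)
  tf <- withr::local_tempfile()
  write_peaks(fit, tf)
  lines <- readLines(tf)
  expect_equal(length(lines), g$n_peaks)
  starts <- as.numeric(vapply(strsplit(lines, "\t"), `[`, "", 2))
  expect_true(!is.unsorted(starts))
})
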