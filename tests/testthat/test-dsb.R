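test_that("sites are assigned to bins by their 5' coordinate", {
  b <- make_bins(c(chr1 = 10000), 5000)
  sites <- tibble::tibble(chrom = "chr1", start = c(0, 4999, 5000),
                          end = c(1, 5000, 5001))
  tr <- count_reads_per_bin(sites, b)
  expect_equal(tr$count, c(2, 1))

  empty <- count_reads_per_bin(sites[0, ], b)
  expect_equal(empty$count, c(0, 0))

  withr::with_seed(1, {
    s <- sample(0:9999, 10000, replace = TRUE)
    tr2 <- count_reads_per_bin(tibble::tibble(chrom = "chr1", start = s, end = s + 1), b)
    expect_equal(sum(tr2$count), 10000)
  })

  off <- tibble::tibble(chrom = c("chr1", "chrX"), start = c(20000, 5), end = c(20001, 6))
  expect_warning(tr3 <- count_reads_per_bin(off, b), "2 site")
  expect_equal(sum(tr3$count), 0)

  minus <- tibble::tibble(chrom = "chr1", start = 4000, end = 5001, strand = "-")
  expect_equal(count_reads_per_bin(minus, b)$count, c(0, 1)) # 5' end at 5000
})

test_that("dsb_ratio matches the CPM fold-change formula", {
  b <- make_bins(c(chr1 = 10000), 5000)
  mk <- function(counts) { t <- tibble::as_tibble(b); t$count <- counts; t }
  # identical samples give unit ratios
  r <- dsb_ratio(mk(c(3, 7)), mk(c(3, 7)))
  expect_equal(r$ratio, c(1, 1))

  # worked example with pseudocount 0
  r2 <- dsb_ratio(mk(c(10, 5)), mk(c(5, 5)), pseudocount = 0)
  expect_equal(r2$ratio[1], (10 / 15) / (5 / 10))

  # invariance to global library scaling (doubling every treated count)
  expect_equal(dsb_ratio(mk(c(20, 10)), mk(c(5, 5)))$ratio,
               dsb_ratio(mk(c(10, 5)), mk(c(5, 5)))$ratio)

  # monotone in the treated count for a fixed control
  r4 <- dsb_ratio(mk(c(11, 5)), mk(c(5, 5)), pseudocount = 0)
  expect_gt(r4$ratio[1], r2$ratio[1])

  b2 <- make_bins(c(chr1 = 15000), 5000)
  t2 <- tibble::as_tibble(b2); t2$count <- c(1, 1, 1)
  expect_error(dsb_ratio(t2, mk(c(1, 1))), "share one binning")
})

test_that("hypergeometric upper tail matches enumeration", {
  expect_equal(hypergeom_bin_test(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeom_bin_test(0, 4, 5, 10), 1)
  expect_equal(hypergeom_bin_test(5, 6, 10, 20), hyper_upper_oracle(5, 6, 10, 20))
  # grid over modest margins against the binomial-coefficient oracle
  for (N in c(5, 12, 25)) {
    for (K in 0:N) {
      for (n in 0:N) {
        kmin <- max(0, n - (N - K))
        ks <- kmin:min(n, K)
        expect_equal(
          hypergeom_bin_test(ks, n, K, N),
          vapply(ks, hyper_upper_oracle, numeric(1), n = n, K = K, N = N),
          tolerance = 1e-12
        )
      }
    }
  }
  expect_error(hypergeom_bin_test(5, 4, 5, 10), "margins")
  expect_error(hypergeom_bin_test(2, 4, 1, 10), "margins")
})

test_that("enrichment regions merge adjacent significant bins", {
  ratio <- toy_ratio_track(rep(3, 10))
  ratio$p_value <- rep(1, 10)
  expect_equal(nrow(call_enrichment_regions(ratio)), 0)

  ratio$p_value <- c(1, 1, 1, 1e-9, 1e-9, 1e-9, 1, 1e-9, 1, 1)
  regs <- call_enrichment_regions(ratio)
  expect_equal(nrow(regs), 2)
  expect_equal(regs$start, c(15000, 35000))
  expect_equal(regs$n_bins, c(3L, 1L))

  # fold filter: a significant p with a sub-threshold fold is excluded
  ratio$ratio[5] <- 1.2
  regs2 <- call_enrichment_regions(ratio)
  expect_equal(regs2$n_bins, c(1L, 1L, 1L))

  # brute-force merge oracle on random toys
  withr::with_seed(9, {
    for (i in 1:20) {
      r <- toy_ratio_track(runif(20, 0.5, 4))
      r$p_value <- ifelse(runif(20) < 0.4, 1e-9, 1)
      got <- call_enrichment_regions(r)
      sig <- stats::p.adjust(r$p_value, "BH") < 0.05 & r$ratio >= 2
      runs <- rle(sig)
      expect_equal(nrow(got), sum(runs$values))
      expect_equal(sum(got$n_bins), sum(sig))
    }
  })
})

test_that("median smoothing matches per-window medians at every scale", {
  const <- toy_ratio_track(rep(4, 12))
  const$count <- const$ratio
  sm <- multiscale_median_smooth(const, scales = c(5000, 15000, 30000))
  for (s in sm) expect_true(all(s$value == 4))

  tr <- toy_ratio_track(c(1, 9, 2, 8)); tr$count <- c(1, 9, 2, 8)
  expect_equal(multiscale_median_smooth(tr, 10000)[["10000"]]$value, c(5, 5))

  # base scale is the identity
  expect_equal(multiscale_median_smooth(tr, 5000)[["5000"]]$value, tr$count)

  withr::with_seed(4, {
    v <- rpois(23, 8)
    tr2 <- toy_ratio_track(v + 0); tr2$count <- v
    got <- multiscale_median_smooth(tr2, 20000)[["20000"]]$value
    naive <- vapply(split(v, (seq_along(v) - 1) %/% 4), median, numeric(1))
    expect_equal(got, unname(naive))
  })

  expect_error(multiscale_median_smooth(tr, 7000), "multiple")
})

test_that("ratio classes form an ordered equal-count partition", {
  r <- toy_ratio_track(seq(100, 1, length.out = 100))
  cl <- split_ratio_classes(r)
  expect_equal(as.vector(table(cl$class)), rep(10L, 10))
  expect_equal(cl$class[1], 1L) # highest ratio first in genomic order here

  r2 <- toy_ratio_track(runif(101))
  cl2 <- split_ratio_classes(r2)
  expect_equal(as.vector(table(cl2$class)), c(11L, rep(10L, 9)))

  # all-equal ratios: classes are contiguous runs of genomic order
  r3 <- toy_ratio_track(rep(1, 50))
  cl3 <- split_ratio_classes(r3, 5)
  expect_equal(cl3$class, rep(1:5, each = 10))

  # concatenating classes in order recovers the descending sort
  withr::with_seed(5, {
    r4 <- toy_ratio_track(runif(63))
    cl4 <- split_ratio_classes(r4, 10)
    ord <- order(cl4$class, -cl4$ratio)
    expect_equal(cl4$ratio[ord], sort(cl4$ratio, decreasing = TRUE))
  })

  expect_error(split_ratio_classes(toy_ratio_track(c(1, 2)), 10), "fewer bins")
})
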