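test_that("loop matching requires exact snapped-bin identity", {
  a <- toy_loops("chr1", c(100000, 300000), c(200000, 500000), c(0.97, 0.96))
  m <- match_loops(a, a)
  expect_true(all(m$matched))

  b <- toy_loops("chr1", 700000, 900000, 0.99)
  m2 <- match_loops(a, b)
  expect_true(all(!m2$matched))
  expect_equal(sum(m2$p_b == 0), 2) # unmatched loops carry probability 0

  shifted <- toy_loops("chr1", c(110000, 300000), c(200000, 500000), c(0.97, 0.96))
  m3 <- match_loops(a, shifted)
  expect_equal(sum(m3$matched), 1) # one-bin anchor shift breaks the match

  # with slack 1 the shifted loop matches again
  m4 <- match_loops(a, shifted, slack = 1)
  expect_equal(sum(m4$matched), 2)
})

test_that("the probability-threshold rule calls gained and lost loops", {
  trt <- toy_loops("chr1", c(1e5, 2e5, 3e5, 4e5), c(5e5, 6e5, 7e5, 8e5),
                   c(0.97, 0.97, 0.70, 0.99), condition = "treated")
  ctl <- toy_loops("chr1", c(1e5, 2e5, 3e5, 4e5), c(5e5, 6e5, 7e5, 8e5),
                   c(0.70, 0.85, 0.99, 0.96), condition = "control")
  d <- call_differential_loops(trt, ctl)
  expect_equal(d$status[d$start1 == 1e5], "gained") # 0.97 vs 0.70
  expect_equal(d$status[d$start1 == 2e5], "stable") # 0.97 vs 0.85
  expect_equal(d$status[d$start1 == 3e5], "lost")
  expect_equal(d$status[d$start1 == 4e5], "stable")

  # label swap exchanges gained and lost exactly
  d2 <- call_differential_loops(ctl, trt)
  key <- function(x, st) {
    s <- differential_subset(x, st)
    paste(s$chrom, s$start1, s$start2)
  }
  expect_setequal(key(d, "gained"), key(d2, "lost"))
  expect_setequal(key(d, "lost"), key(d2, "gained"))

  # a loop absent from the control is gained when called strongly in treated
  solo <- toy_loops("chr1", 9e5, 12e5, 0.99, condition = "treated")
  d3 <- call_differential_loops(solo, ctl)
  expect_equal(d3$status[d3$start1 == 9e5], "gained")

  expect_error(call_differential_loops(trt, ctl, p_high = 0.5, p_low = 0.8),
               "p_low")
})

test_that("differential calls are invariant to loop-list ordering", {
  withr::with_seed(10, {
    n <- 50
    s1 <- sample(seq(0, 5e6, by = 1e4), n)
    s2 <- s1 + sample(seq(4e5, 2e6, by = 1e4), n, replace = TRUE)
    trt <- toy_loops("chr1", s1, s2, runif(n))
    ctl <- toy_loops("chr1", s1, s2, runif(n))
    d1 <- call_differential_loops(trt, ctl)
    perm <- sample(n)
    d2 <- call_differential_loops(trt[perm, ], ctl[sample(n), ])
    expect_equal(tibble::as_tibble(d1), tibble::as_tibble(d2))
  })
})

test_that("anchor tables count endpoint recurrence", {
  loops <- toy_loops("chr1", c(1e5, 1e5, 4e5), c(2e5, 3e5, 5e5))
  tab <- build_anchor_table(loops)
  expect_equal(sum(tab$frequency), 6)
  a <- tab[tab$start == 1e5, ]
  expect_equal(a$frequency, 2)
  expect_true(a$busy)
  expect_true(all(!tab$busy[tab$start != 1e5]))

  # brute-force endpoint count on random loops
  withr::with_seed(11, {
    s1 <- sample(seq(0, 1e7, by = 1e4), 1000, replace = TRUE)
    s2 <- s1 + sample(seq(1e5, 1e6, by = 1e4), 1000, replace = TRUE)
    rl <- toy_loops("chr1", s1, s2)
    tb <- build_anchor_table(rl)
    brute <- table(c(s1, s2))
    expect_equal(sum(tb$frequency), 2000)
    expect_equal(tb$frequency[match(as.numeric(names(brute)), tb$start)],
                 as.vector(brute))
  })
})

test_that("the 2x2 chi-square matches its closed forms and R's test", {
  res <- chisq_2x2(10, 20, 20, 10)
  expect_equal(res$statistic_uncorrected, 20 / 3, tolerance = 1e-12)
  expect_equal(res$statistic, 5.4, tolerance = 1e-12)

  ind <- chisq_2x2(10, 10, 10, 10)
  expect_equal(ind$statistic_uncorrected, 0)
  expect_equal(ind$p_value_uncorrected, 1)

  zero <- chisq_2x2(0, 0, 5, 5)
  expect_true(is.na(zero$p_value))

  withr::with_seed(12, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 20) + 1, 2)
      mine <- chisq_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
      ry <- suppressWarnings(chisq.test(tab, correct = TRUE))
      ru <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(mine$statistic, unname(ry$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value, ry$p.value, tolerance = 1e-10)
      expect_equal(mine$statistic_uncorrected, unname(ru$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value_uncorrected, ru$p.value, tolerance = 1e-10)
    }
  })
})

test_that("busy-anchor association builds the contingency table", {
  anchors <- tibble::tibble(
    chrom = "chr1", start = seq(0, 59) * 1e4, end = seq(1, 60) * 1e4,
    frequency = c(rep(3, 30), rep(1, 30)),
    busy = c(rep(TRUE, 30), rep(FALSE, 30)),
    in_differential = c(rep(TRUE, 10), rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 10))
  )
  res <- busy_anchor_association(anchors)
  expect_equal(res$table, matrix(c(10, 20, 20, 10), 2, byrow = TRUE,
                                 dimnames = dimnames(res$table)))
  expect_equal(res$statistic, 5.4, tolerance = 1e-12)
  expect_equal(res$statistic_uncorrected, 20 / 3, tolerance = 1e-12)

  # zero margin: table returned, p undefined
  anchors$in_differential <- FALSE
  res0 <- busy_anchor_association(anchors)
  expect_true(is.na(res0$p_value))
  expect_equal(sum(res0$table), 60)

  expect_error(busy_anchor_association(anchors[, 1:5]), "in_differential")
})

test_that("DSB regions covering exactly the anchors give a diagonal table", {
  binning <- make_bins(c(chr1 = 1e6), 5000)
  trt <- toy_loops("chr1", 1e5, 5e5, 0.99, condition = "treated")
  ctl <- toy_loops("chr1", 1e5, 5e5, 0.01, condition = "control")
  d <- call_differential_loops(trt, ctl)
  regions <- tibble::tibble(chrom = "chr1", start = c(1e5, 5e5), end = c(1.1e5, 5.1e5))
  res <- dsb_anchor_enrichment(regions, d, binning)
  expect_equal(res$table[1, 2], 0) # anchor bins not in a region
  expect_equal(res$table[2, 1], 0) # region bins outside anchors
  expect_equal(unname(res$overlap), 4) # two 10 kb anchors over 5 kb bins

  empty <- regions[0, ]
  res0 <- dsb_anchor_enrichment(empty, d, binning)
  expect_equal(unname(res0$overlap), 0)
  expect_true(is.na(res0$p_value))
})

test_that("random DSB regions show no anchor association", {
  binning <- make_bins(c(chr1 = 1e7), 5000)
  withr::with_seed(13, {
    s1 <- sample(seq(0, 7e6, by = 1e4), 60)
    s2 <- s1 + sample(seq(4e5, 2e6, by = 1e4), 60, replace = TRUE)
    trt <- toy_loops("chr1", s1, s2, 0.99, condition = "treated")
    ctl <- toy_loops("chr1", s1, s2, c(rep(0.2, 30), rep(0.99, 30)),
                     condition = "control")
    d <- call_differential_loops(trt, ctl)
    ps <- vapply(1:20, function(i) {
      st <- sample(seq(0, 9.9e6, by = 5000), 50)
      regions <- tibble::tibble(chrom = "chr1", start = st, end = st + 5000)
      dsb_anchor_enrichment(regions, d, binning)$p_value
    }, numeric(1))
    expect_gt(median(ps), 0.05)
  })
})
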