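test_that("gene-anchor assignment uses the TSS and half-open anchors", {
  trt <- toy_loops("chr1", 1e5, 5e5, 0.99, condition = "treated")
  ctl <- toy_loops("chr1", 1e5, 5e5, 0.1, condition = "control")
  d <- call_differential_loops(trt, ctl)
  genes <- toy_genes("chr1", c(105000, 110000, 502000, 9e5))
  # anchor [100000,110000): TSS at midpoint in, TSS at 110000 out (half-open)
  got <- genes_in_anchors(genes, d)
  expect_setequal(got$gene_id, c("g001", "g003"))
  expect_true(all(got$direction == "gained"))
})

test_that("expression-DSB binned correlation has exact degenerate behavior", {
  ratio <- toy_ratio_track(seq(5, 0.5, length.out = 200))
  genes <- toy_genes("chr1", seq(2500, 997500, by = 5000), fpkm_treated = 7)
  # identical expression: zero variance, undefined r
  out <- expression_dsb_correlation(genes, ratio, n_bins = 50)
  expect_true(is.na(attr(out, "pearson_r")))

  # identity binning: r equals the unbinned correlation
  withr::with_seed(14, {
    genes2 <- toy_genes("chr1", seq(2500, 997500, by = 5000),
                        fpkm_treated = runif(200, 2, 50))
    out2 <- expression_dsb_correlation(genes2, ratio, n_bins = 200)
    expect_equal(attr(out2, "pearson_r"),
                 unname(cor(ratio$ratio, genes2$fpkm_treated)),
                 tolerance = 1e-12)
  })

  # FPKM floor removes genes before binning
  genes3 <- toy_genes("chr1", seq(2500, 997500, by = 5000), fpkm_treated = 0.5)
  expect_error(expression_dsb_correlation(genes3, ratio, n_bins = 50), "eligible")
})

test_that("compartment classes follow the PC1 sign rule", {
  mk <- function(v) tibble::tibble(chrom = "chr1", start = seq_along(v) * 1e5 - 1e5,
                                   end = seq_along(v) * 1e5, value = v)
  ctl <- mk(c(0.5, 0.5, -0.3, -0.2, 0, 0.1))
  trt <- mk(c(0.1, -0.1, 0.4, -0.6, 0.2, NA))
  cls <- classify_compartment_bins(ctl, trt)
  expect_equal(cls$class,
               c("stableA", "AtoB", "BtoA", "stableB", "undefined", "undefined"))
  # defined classes are exclusive and exhaustive; switch fraction over defined
  expect_equal(attr(cls, "switch_fraction"), 2 / 4)
  expect_error(classify_compartment_bins(ctl, trt[1:3, ]), "share one binning")
})

test_that("DEG-compartment enrichment matches small-case enumeration", {
  comp <- tibble::tibble(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5),
                         pc1_control = c(1, -1), pc1_treated = c(1, -1),
                         class = c("stableA", "stableB"))
  genes <- toy_genes("chr1", c(seq(1000, 91000, by = 10000),
                               seq(101000, 191000, by = 10000)))
  genes$is_deg <- c(rep(TRUE, 5), rep(FALSE, 15))
  out <- deg_compartment_enrichment(genes, comp)
  a <- out[out$class == "stableA", ]
  # all 5 DEGs among the 10 stableA genes of a 20-gene universe
  expect_equal(a$n_deg, 5L)
  expect_equal(a$p_value, hyper_upper_oracle(5, 10, 5, 20), tolerance = 1e-12)

  genes$is_deg <- FALSE
  out0 <- deg_compartment_enrichment(genes, comp)
  expect_true(all(out0$p_value == 1))
})

test_that("uniformly scattered DEGs are not enriched in any class", {
  comp <- tibble::tibble(chrom = "chr1",
                         start = seq(0, 19) * 1e5, end = seq(1, 20) * 1e5,
                         pc1_control = rep(c(1, 1, -1, -1), 5),
                         pc1_treated = rep(c(1, -1, 1, -1), 5),
                         class = rep(c("stableA", "AtoB", "BtoA", "stableB"), 5))
  genes <- toy_genes("chr1", seq(5000, 1995000, by = 10000))
  minp <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      genes$is_deg <- seq_len(nrow(genes)) %in% sample(nrow(genes), 30)
      min(deg_compartment_enrichment(genes, comp)$p_value)
    })
  }, numeric(1))
  expect_gt(median(minp), 0.05)
})

test_that("TAD levels are assigned by the deepest covering domain", {
  tads <- tibble::tibble(chrom = "chr1",
                         start = c(0, 0, 3e5), end = c(1e6, 2e5, 4e5),
                         level = c(1L, 3L, 2L))
  ratio <- toy_ratio_track(runif(200))
  genes <- toy_genes("chr1", c(50000, 350000, 600000))
  res <- tad_level_association(tads, ratio, genes)
  # bin covered by nested TADs of levels {1,3} gets level 3
  expect_setequal(res$per_level$level, c(1L, 2L, 3L))
  lev3 <- res$per_level[res$per_level$level == 3, ]
  expect_equal(lev3$n_bins, 40L) # the first 200 kb of 5 kb bins
  expect_equal(lev3$n_genes, 1L)
})

test_that("level-proportional DSB rates produce an increasing trend", {
  tads <- tibble::tibble(chrom = "chr1",
                         start = c(0, 0, 0), end = c(3e6, 2e6, 1e6),
                         level = 1:3)
  withr::with_seed(15, {
    n <- 600 # 3 Mb of 5 kb bins
    lev <- c(rep(3, 200), rep(2, 200), rep(1, 200))
    ratio <- toy_ratio_track(rnorm(n, mean = lev, sd = 0.3))
    genes <- toy_genes("chr1", sort(sample(seq(1e4, 2.99e6, by = 1e4), 60)),
                       fpkm_treated = runif(60, 1, 20))
    res <- tad_level_association(tads, ratio, genes)
    pl <- res$per_level[order(res$per_level$level), ]
    expect_true(all(diff(pl$mean_ratio) > 0))
    rtests <- res$tests[res$tests$quantity == "dsb_ratio", ]
    expect_true(all(rtests$p_value < 0.01))
    expect_gt(res$trend_rho, 0.5)
  })

  # a single covered level yields summaries without tests
  one <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, level = 1L)
  res1 <- tad_level_association(one, toy_ratio_track(runif(200)),
                                toy_genes("chr1", 5e5))
  expect_equal(nrow(res1$tests), 0)
})

test_that("exclusive multi-set overlap has upset semantics", {
  out <- multi_evidence_overlap(list(s1 = c("a", "b"), s2 = c("b", "c")))
  cb <- out$combinations
  expect_equal(sum(cb$count), 3) # |union|
  both <- cb[cb$s1 & cb$s2, ]
  expect_equal(both$count, 1)
  expect_equal(both$genes[[1]], "b")
  only1 <- cb[cb$s1 & !cb$s2, ]
  expect_equal(only1$genes[[1]], "a")

  same <- multi_evidence_overlap(list(x = letters[1:4], y = letters[1:4]))
  expect_equal(nrow(same$combinations), 1)
  expect_equal(same$combinations$count, 4)

  # brute-force powerset oracle on random sets
  withr::with_seed(16, {
    for (i in 1:10) {
      k <- sample(2:5, 1)
      sets <- lapply(seq_len(k), function(j) sample(letters, sample(3:12, 1)))
      names(sets) <- paste0("S", seq_len(k))
      got <- multi_evidence_overlap(sets)
      uni <- sort(unique(unlist(sets)))
      expect_equal(sum(got$combinations$count), length(uni))
      for (r in seq_len(nrow(got$combinations))) {
        flags <- unlist(got$combinations[r, names(sets)])
        expected <- uni[vapply(uni, function(g) {
          all(vapply(seq_len(k), function(j) (g %in% sets[[j]]) == flags[j],
                     logical(1)))
        }, logical(1))]
        expect_setequal(got$combinations$genes[[r]], expected)
      }
    }
  })

  cand <- multi_evidence_overlap(list(s1 = c("a", "b"), s2 = c("b", "c")),
                                 candidate_sets = c("s1", "s2"))
  expect_equal(cand$candidates, "b")
  expect_error(multi_evidence_overlap(list(s1 = "a", s2 = "b"),
                                      candidate_sets = "zz"), "unknown set")
  expect_error(multi_evidence_overlap(list(s1 = "a")), "at least two")
})
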