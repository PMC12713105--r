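test_that("identity binning reproduces raw values in the distance profile", {
  withr::with_seed(6, {
    ratio <- toy_ratio_track(runif(500, 0.5, 5))
    genes <- toy_genes("chr1", sort(sample(seq(0, 2.49e6, by = 1000), 40)))
    prof <- tss_distance_profile(ratio, genes, n_bins = 500)
    expect_equal(nrow(prof), 500)
    expect_equal(sort(prof$mean_ratio), sort(ratio$ratio))
    d <- nearest_tss_distance(ratio, genes)
    expect_equal(
      attr(prof, "pearson_r"),
      unname(cor(ratio$ratio, d)),
      tolerance = 1e-12
    )
  })
  expect_error(
    tss_distance_profile(toy_ratio_track(runif(10)), toy_genes("chr1", 100), 500),
    "n_bins"
  )
})

test_that("regions on gene-free chromosomes are excluded from the profile", {
  ratio1 <- toy_ratio_track(runif(300, 0.5, 2))
  ratio2 <- toy_ratio_track(runif(100, 0.5, 2), chrom = "chr2")
  ratio <- structure(dplyr::bind_rows(ratio1, ratio2),
                     class = class(ratio1))
  ratio$bin <- seq_len(nrow(ratio))
  genes <- toy_genes("chr1", c(1e5, 5e5))
  prof <- tss_distance_profile(ratio, genes, n_bins = 300)
  expect_equal(attr(prof, "n_regions"), 300) # chr2 bins dropped
})

test_that("element fractions are well-defined per ratio class", {
  ratio <- toy_ratio_track(10:1)
  cl <- split_ratio_classes(ratio, 5)
  no_states <- tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric(), state = character())
  ef0 <- element_fraction_by_class(cl, no_states)
  expect_true(all(ef0$frac_tssa == 0))
  expect_true(all(ef0$frac_enha == 0))

  # TssA covering exactly the two highest-ratio bins
  states <- tibble::tibble(chrom = "chr1", start = c(0, 5000), end = c(5000, 10000),
                           state = "TssA")
  ef <- element_fraction_by_class(cl, states)
  expect_equal(ef$frac_tssa, c(1, 0, 0, 0, 0))
  expect_true(all(ef$frac_tssa >= 0 & ef$frac_tssa <= 1))
  expect_gt(attr(ef, "tssa_rho"), 0)
})

test_that("promoter-boosted treatment puts TssA bins in the top classes", {
  p <- medium_params(seed = 7, activity_coupling = 0)
  ann <- simulate_genome(p)
  dsb <- simulate_dsb_counts(ann, p)
  ratio <- dsb_ratio(dsb$treated, dsb$control)
  cl <- split_ratio_classes(ratio, 10)
  ef <- element_fraction_by_class(cl, ann$states)
  inversions <- sum(diff(ef$frac_tssa) > 1e-12)
  expect_lte(inversions, 2)
  expect_gt(ef$frac_tssa[1], ef$frac_tssa[10])
})

test_that("enhancer proximity follows the 20 kb edge-to-edge rule", {
  states <- tibble::tibble(
    chrom = "chr1",
    start = c(30000, 50000, 90500, 100000, 200000),
    end = c(30500, 51000, 91000, 101000, 201000),
    state = c("TssA", "EnhA1", "EnhA2", "EnhA1", "EnhA2")
  )
  out <- classify_enhancer_proximity(states, 20000)
  expect_true(is.na(out$proximity[1]))
  expect_equal(out$proximity[2], "proximal") # gap 19500
  expect_equal(out$proximity[3], "distal")   # gap 60000
  expect_equal(out$proximity[4], "distal")   # gap 69500

  # boundary cases: gap exactly 20000 is proximal, 20001 distal
  b <- tibble::tibble(chrom = "chr1", start = c(0, 20500), end = c(500, 21000),
                      state = c("TssA", "EnhA1"))
  expect_equal(classify_enhancer_proximity(b, 20000)$proximity[2], "proximal") # gap 20000
  b2 <- tibble::tibble(chrom = "chr1", start = c(0, 20501), end = c(500, 21001),
                       state = c("TssA", "EnhA1"))
  expect_equal(classify_enhancer_proximity(b2, 20000)$proximity[2], "distal")

  # overlap means distance zero
  ov <- tibble::tibble(chrom = "chr1", start = c(1000, 1200), end = c(2000, 2200),
                       state = c("TssA", "EnhA2"))
  expect_equal(classify_enhancer_proximity(ov)$proximity[2], "proximal")

  # no promoter anywhere: everything distal
  lone <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000, state = "EnhA1")
  expect_equal(classify_enhancer_proximity(lone)$proximity, "distal")
})

test_that("rank-sum comparison behaves at the null and on separated groups", {
  ratio <- toy_ratio_track(rep(c(1, 2, 3, 4, 5), 2))
  res <- compare_ratio_by_feature(ratio, 1:5) # identical multisets
  expect_gte(res$p_value, 0.5)

  ratio2 <- toy_ratio_track(c(1, 2, 3, 10, 11, 12))
  res2 <- compare_ratio_by_feature(ratio2, 1:3)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 2 / choose(6, 3)) # exact enumeration: 2/20

  expect_error(compare_ratio_by_feature(ratio2, integer(0)), "non-empty")
  expect_error(compare_ratio_by_feature(ratio2, 1:6), "non-empty")
})

test_that("enhancer boost is detected against enhancer-free bins", {
  ds <- study_dataset7()
  states_prox <- classify_enhancer_proximity(ds$annotation$states)
  cmp <- compare_ratio_by_enhancer(ds$ratio, states_prox)
  pn <- cmp$tests[cmp$tests$group1 == "proximal" & cmp$tests$group2 == "none", ]
  dn <- cmp$tests[cmp$tests$group1 == "distal" & cmp$tests$group2 == "none", ]
  expect_lt(pn$p_value, 0.01)
  expect_lt(dn$p_value, 0.01)
})

test_that("repeat-coverage correlation is signed correctly and bounded", {
  ratio <- toy_ratio_track(c(5, 4, 3, 2, 1, 1, 1, 1, 1, 1))
  reps <- tibble::tibble(chrom = "chr1", start = c(0, 5000), end = c(5000, 10000),
                         subtype = "L1")
  out <- repeat_subtype_correlation(ratio, reps)
  expect_gt(out$rho, 0)

  # constant coverage gives an undefined correlation
  full <- tibble::tibble(chrom = "chr1", start = 0, end = 50000, subtype = "L2")
  out2 <- repeat_subtype_correlation(ratio, full)
  expect_true(is.na(out2$rho))

  # coverage independent of the ratio stays near zero over seeds
  rhos <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      r <- toy_ratio_track(runif(200, 0.5, 4))
      st <- sort(sample(seq(0, 9.9e5, by = 100), 40))
      rp <- tibble::tibble(chrom = "chr1", start = st, end = st + 800, subtype = "B1")
      repeat_subtype_correlation(r, rp)$rho
    })
  }, numeric(1))
  expect_lt(median(abs(rhos)), 0.1)
})

test_that("TSS meta-profiles are oriented, normalized and shape-true", {
  cs <- c(chr1 = 100000)
  genes <- toy_genes("chr1", c(20000, 60000))
  # a site every 100 bp: perfectly uniform coverage, flat profile
  sites <- tibble::tibble(chrom = "chr1", start = seq(0, 99999, by = 100))
  sites$end <- sites$start + 1
  prof <- tss_meta_profile(sites, genes, cs)
  expect_equal(nrow(prof), 100)
  expect_true(all(abs(prof$density - prof$density[1]) < 1e-9))

  # symmetric signal about each TSS gives a symmetric profile
  sym <- tibble::tibble(chrom = "chr1",
                        start = c(20000 - 1050, 20000 + 1049, 60000 - 1050, 60000 + 1049))
  sym$end <- sym$start + 1
  ps <- tss_meta_profile(sym, genes, cs)
  expect_equal(ps$density, rev(ps$density))

  # minus-strand gene: signal 1 kb downstream of the TSS lands after the center
  gm <- toy_genes("chr1", 50000, strand = "-")
  s1 <- tibble::tibble(chrom = "chr1", start = 49000, end = 49001) # downstream for -
  pm <- tss_meta_profile(s1, gm, cs)
  expect_equal(which(pm$density > 0), 60)

  edge <- toy_genes("chr1", 1000) # window leaves the chromosome
  expect_error(tss_meta_profile(sites, edge, cs), "no gene window")
})
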