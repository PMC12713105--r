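# Small-genome simulation parameters for fast unit tests
small_params <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 1, chrom_len = 3e6, n_genes = 60,
         n_enhancers = 40, loop_n = 80),
    list(...)
  )
  do.call(sim_params, args)
}

# Medium single-chromosome genome: enough bins for the 500-group profile
medium_params <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 1, chrom_len = 1e7, n_genes = 100,
         n_enhancers = 60),
    list(...)
  )
  do.call(sim_params, args)
}

# Build a ratio-track-shaped tibble from explicit per-bin ratios, for
# functions that only consume the ratio/bin/coordinate columns.
toy_ratio_track <- function(ratio, bin_width = 5000, chrom = "chr1") {
  n <- length(ratio)
  structure(
    tibble::tibble(
      chrom = chrom,
      start = (seq_len(n) - 1) * bin_width,
      end = seq_len(n) * bin_width,
      bin = seq_len(n),
      ratio = ratio
    ),
    class = c("dsb_ratio_track", class(tibble::tibble()))
  )
}

# Contact tibble from a dense symmetric matrix (upper triangle stored)
toy_contacts <- function(mat, chrom = "chr1", resolution = 10000) {
  m <- nrow(mat)
  idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
  structure(
    tibble::tibble(chrom = chrom, bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   count = mat[idx]),
    resolution = as.integer(resolution),
    n_bins = stats::setNames(m, chrom),
    class = c("contact_matrix", class(tibble::tibble()))
  )
}

# Loop tibble straight from anchor start coordinates
toy_loops <- function(chrom, start1, start2, probability = 0.99,
                      resolution = 10000, condition = NA_character_) {
  dsbloop:::new_loopset(
    tibble::tibble(chrom = chrom, start1 = start1, start2 = start2,
                   probability = probability),
    resolution, condition
  )
}

# Gene table with the columns the analysis operations expect
toy_genes <- function(chrom, tss, strand = "+", fpkm_control = 10,
                      fpkm_treated = 10, is_deg = FALSE) {
  n <- length(tss)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    start = ifelse(rep_len(strand, n) == "+", tss, tss - 999),
    end = ifelse(rep_len(strand, n) == "+", tss + 1000, tss + 1),
    strand = rep_len(strand, n),
    tss = tss,
    fpkm_control = rep_len(fpkm_control, n),
    fpkm_treated = rep_len(fpkm_treated, n),
    is_deg = rep_len(is_deg, n)
  )
}

# Exhaustive upper-tail hypergeometric oracle from binomial coefficients
hyper_upper_oracle <- function(k, n, K, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  pmf <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(pmf[ks >= k])
}

# Shared seed-7 study-condition dataset, built once per test run
.acc_cache <- new.env(parent = emptyenv())
study_dataset7 <- function() {
  if (is.null(.acc_cache$ds7)) {
    p <- sim_params(seed = 7)
    ann <- simulate_genome(p)
    dsb <- simulate_dsb_counts(ann, p)
    loops <- simulate_loops(ann, dsb, p)
    genes <- simulate_expression(ann, loops$truth, p)
    ratio <- bin_enrichment_test(dsb_ratio(dsb$treated, dsb$control))
    .acc_cache$ds7 <- list(params = p, annotation = ann, dsb = dsb,
                           loops = loops, genes = genes, ratio = ratio)
  }
  .acc_cache$ds7
}
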