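#' Count breakpoint sites per genome bin
#'
#' Each site is assigned to exactly one bin by its 5' breakpoint coordinate
#' (the interval start, or `end - 1` for minus-strand records). Sites on
#' chromosomes absent from the binning, or past the chromosome end, are
#' skipped with a warning giving their number.
#'
#' @param sites Tibble of breakpoint records (`chrom`, `start`, `end`,
#'   optional `strand`), e.g. from [read_bed()].
#' @param binning A [make_bins()] object.
#' @return Count track: the binning tibble with a `count` column; total
#'   count equals the number of assigned sites.
#' @export
count_reads_per_bin <- function(sites, binning) {
  pos <- if ("strand" %in% names(sites)) {
    ifelse(!is.na(sites$strand) & sites$strand == "-", sites$end - 1, sites$start)
  } else {
    sites$start
  }
  idx <- bin_index(binning, sites$chrom, pos)
  n_skipped <- sum(is.na(idx))
  if (n_skipped > 0) {
    warning(n_skipped, " site(s) fell outside the binning and were skipped")
  }
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(binning))
  out <- tibble::as_tibble(binning)
  out$count <- counts
  out
}

#' Per-bin DSB ratio (treated over control)
#'
#' Counts are normalized to counts per million (CPM) within each library,
#' then the per-bin fold change is `(CPM_treated + pseudocount) /
#' (CPM_control + pseudocount)`. CPM normalization makes the ratio invariant
#' to global library scaling; the pseudocount keeps it finite at zero-count
#' bins. Two genome-wide summary statistics are carried as attributes (and
#' surfaced by [glance()]): the mean of per-bin ratios and the raw ratio of
#' library totals.
#'
#' @param treated,control Count tracks from [count_reads_per_bin()] on the
#'   same binning.
#' @param pseudocount Added to both CPMs (default 0.5).
#' @return A `dsb_ratio_track` tibble with `treated_cpm`, `control_cpm` and
#'   `ratio` columns.
#' @export
dsb_ratio <- function(treated, control, pseudocount = 0.5) {
  if (nrow(treated) != nrow(control) ||
      !identical(treated$chrom, control$chrom) ||
      !identical(treated$start, control$start)) {
    stop("`treated` and `control` must share one binning", call. = FALSE)
  }
  lib_t <- sum(treated$count)
  lib_c <- sum(control$count)
  if (lib_t <= 0 || lib_c <= 0) stop("library sizes must be positive", call. = FALSE)
  out <- tibble::as_tibble(treated[c("chrom", "start", "end", "bin")])
  out$treated_count <- treated$count
  out$control_count <- control$count
  out$treated_cpm <- treated$count / lib_t * 1e6
  out$control_cpm <- control$count / lib_c * 1e6
  out$ratio <- (out$treated_cpm + pseudocount) / (out$control_cpm + pseudocount)
  structure(out,
    pseudocount = pseudocount,
    lib_treated = lib_t, lib_control = lib_c,
    mean_bin_ratio = mean(out$ratio),
    median_bin_ratio = stats::median(out$ratio),
    totals_ratio = lib_t / lib_c,
    class = c("dsb_ratio_track", class(tibble::tibble()))
  )
}

#' Upper-tail hypergeometric enrichment test
#'
#' P(X >= k) with X ~ Hypergeometric(N, K, n): population = all reads of
#' both samples (N), marked = treated reads (K), draws = reads falling in
#' the bin (n), successes = treated reads in the bin (k). Vectorized.
#'
#' @param k Treated reads in the bin.
#' @param n Total reads in the bin (both samples).
#' @param K Treated library size.
#' @param N Grand total reads.
#' @return Upper-tail p-values.
#' @examples
#' hypergeom_bin_test(4, 4, 5, 10) # 5/210
#' @export
hypergeom_bin_test <- function(k, n, K, N) {
  bad <- k > n | k > K | n > N | K > N | k < 0 | n < 0 | K < 0 | N < 0 |
    (n - k) > (N - K)
  if (any(bad)) stop("inconsistent hypergeometric margins", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-bin enrichment p-values for a ratio track
#'
#' Applies [hypergeom_bin_test()] to every bin of a [dsb_ratio()] track.
#'
#' @param ratio A `dsb_ratio_track`.
#' @return The track with a `p_value` column appended.
#' @export
bin_enrichment_test <- function(ratio) {
  K <- attr(ratio, "lib_treated", exact = TRUE)
  N <- K + attr(ratio, "lib_control", exact = TRUE)
  ratio$p_value <- hypergeom_bin_test(
    k = ratio$treated_count,
    n = ratio$treated_count + ratio$control_count,
    K = K, N = N
  )
  ratio
}

#' Call DSB enrichment regions
#'
#' Benjamini-Hochberg adjusts the per-bin p-values; bins with q below
#' `q_threshold` and fold change at least `fold_threshold` are significant,
#' and runs of adjacent significant bins are merged into maximal regions.
#'
#' @param ratio A `dsb_ratio_track` with a `p_value` column (see
#'   [bin_enrichment_test()]).
#' @param q_threshold FDR threshold (default 0.05).
#' @param fold_threshold Minimum per-bin ratio (default 2).
#' @return Tibble of regions: `chrom`, `start`, `end`, `n_bins`, `fold`
#'   (max bin ratio), `p_value` (min), `q_value` (min).
#' @export
call_enrichment_regions <- function(ratio, q_threshold = 0.05, fold_threshold = 2) {
  if (!"p_value" %in% names(ratio)) {
    stop("run `bin_enrichment_test()` first: no `p_value` column", call. = FALSE)
  }
  q <- stats::p.adjust(ratio$p_value, method = "BH")
  sig <- q < q_threshold & ratio$ratio >= fold_threshold
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          n_bins = integer(), fold = numeric(),
                          p_value = numeric(), q_value = numeric())
  if (!any(sig)) return(empty)
  s <- which(sig)
  # split runs of adjacent bins (consecutive global index, same chromosome)
  brk <- c(TRUE, diff(s) != 1 | ratio$chrom[s[-1]] != ratio$chrom[s[-length(s)]])
  grp <- cumsum(brk)
  df <- tibble::tibble(i = s, grp = grp)
  out <- dplyr::summarise(dplyr::group_by(df, grp),
    chrom = ratio$chrom[i[1]],
    start = min(ratio$start[i]),
    end = max(ratio$end[i]),
    n_bins = length(i),
    fold = max(ratio$ratio[i]),
    p_value = min(ratio$p_value[i]),
    q_value = min(q[i]),
    .groups = "drop"
  )
  out$grp <- NULL
  out[order(out$chrom, out$start), ]
}

#' Median-smooth a count track across scales
#'
#' For each requested scale `k * base_width`, the chromosome is cut into
#' non-overlapping windows of `k` bins and each window's value is the median
#' of its raw values (the median of an even window is the mean of the two
#' central values); a trailing partial window uses whatever values it has.
#' The base scale is the identity.
#'
#' @param track A count track (binning columns plus `count` or `value`).
#' @param scales Scales in bp, each a multiple of the track's bin width.
#'   Defaults to 5 kb .. 1000 kb in 5 kb steps.
#' @return Named list (one element per scale, names in bp) of tibbles with
#'   `chrom`, `start`, `end`, `value`.
#' @export
multiscale_median_smooth <- function(track, scales = seq(5000, 1000000, by = 5000)) {
  value <- if ("count" %in% names(track)) track$count else track$value
  base <- unique(track$end - track$start)
  base_width <- max(base) # trailing partial bins are narrower
  if (any(scales %% base_width != 0) || any(scales <= 0)) {
    stop("every scale must be a positive multiple of the base bin width", call. = FALSE)
  }
  out <- lapply(scales, function(sc) {
    k <- sc %/% base_width
    pieces <- lapply(unique(track$chrom), function(ch) {
      idx <- which(track$chrom == ch)
      win <- (seq_along(idx) - 1L) %/% k
      win <- factor(win, levels = sort(unique(win)))
      v <- vapply(split(value[idx], win), stats::median, numeric(1))
      st <- vapply(split(track$start[idx], win), min, numeric(1))
      en <- vapply(split(track$end[idx], win), max, numeric(1))
      tibble::tibble(chrom = ch, start = st, end = en, value = unname(v))
    })
    dplyr::bind_rows(pieces)
  })
  stats::setNames(out, as.character(scales))
}

#' Split bins into equal-count DSB-ratio classes
#'
#' Bins are sorted in descending ratio order (ties broken by genomic order,
#' a stable rule) and partitioned into `n_classes` classes of equal size
#' (sizes differ by at most one; the larger classes come first). Class 1
#' holds the highest ratios.
#'
#' @param ratio A `dsb_ratio_track`.
#' @param n_classes Number of classes (default 10).
#' @return The track with an integer `class` column.
#' @export
split_ratio_classes <- function(ratio, n_classes = 10) {
  n <- nrow(ratio)
  if (n < n_classes) stop("fewer bins than classes", call. = FALSE)
  ord <- order(-ratio$ratio, ratio$bin)
  base <- n %/% n_classes
  extra <- n %% n_classes
  sizes <- rep(base, n_classes) + c(rep(1L, extra), rep(0L, n_classes - extra))
  cls <- rep(seq_len(n_classes), times = sizes)
  ratio$class <- NA_integer_
  ratio$class[ord] <- cls
  ratio
}

# shared equal-count grouping used by the binned-correlation procedures:
# items already sorted; n split into n_groups, larger groups first
equal_count_groups <- function(n, n_groups) {
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  rep(seq_len(n_groups), times = sizes)
}
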