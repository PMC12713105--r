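#' DSB ratio versus distance from gene TSS
#'
#' Bins with a defined nearest-TSS distance (distance from the bin's median
#' nucleotide to the nearest TSS on the same chromosome) are sorted in
#' descending ratio order and grouped into `n_bins` equal-count groups; per
#' group the mean ratio and mean distance are computed, and Spearman and
#' Pearson correlations are evaluated on the group means.
#'
#' @param ratio A [dsb_ratio()] track.
#' @param genes Gene table with `chrom` and `tss`.
#' @param n_bins Number of groups (default 500).
#' @return A `tss_distance_profile` tibble (one row per group: `group`,
#'   `mean_ratio`, `mean_tss_dist`, `n`) carrying the correlations as
#'   attributes; see [glance.tss_distance_profile()].
#' @export
tss_distance_profile <- function(ratio, genes, n_bins = 500) {
  dist <- nearest_tss_distance(ratio, genes)
  keep <- which(!is.na(dist))
  if (length(keep) < n_bins) {
    stop("need at least `n_bins` regions with a defined TSS distance", call. = FALSE)
  }
  ord <- keep[order(-ratio$ratio[keep], ratio$bin[keep])]
  grp <- equal_count_groups(length(ord), n_bins)
  df <- tibble::tibble(group = grp, ratio = ratio$ratio[ord], dist = dist[ord])
  prof <- dplyr::summarise(dplyr::group_by(df, group),
                           mean_ratio = mean(ratio),
                           mean_tss_dist = mean(dist),
                           n = dplyr::n(), .groups = "drop")
  sp <- suppressWarnings(stats::cor.test(prof$mean_ratio, prof$mean_tss_dist,
                                         method = "spearman", exact = FALSE))
  pe <- stats::cor.test(prof$mean_ratio, prof$mean_tss_dist, method = "pearson")
  structure(prof,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    n_regions = length(ord),
    class = c("tss_distance_profile", class(tibble::tibble()))
  )
}

#' Chromatin-element fraction per DSB-ratio class
#'
#' For each ratio class (see [split_ratio_classes()]) computes the fraction
#' of bins containing (>= 1 bp overlap) an active promoter (TssA) and an
#' active enhancer (EnhA1 or EnhA2), plus the Spearman correlation between
#' the class mean ratio and each fraction.
#'
#' @param classes Output of [split_ratio_classes()].
#' @param states Chromatin-state segments (`chrom`, `start`, `end`, `state`).
#' @return Tibble (one row per class: `class`, `n_bins`, `mean_ratio`,
#'   `frac_tssa`, `frac_enha`) with `tssa_rho` / `enha_rho` attributes.
#' @export
element_fraction_by_class <- function(classes, states) {
  has_state <- function(state_set) {
    seg <- states[states$state %in% state_set, , drop = FALSE]
    hit <- rep(FALSE, nrow(classes))
    if (nrow(seg) > 0) hit[unique(overlap_pairs(classes, seg)$qi)] <- TRUE
    hit
  }
  classes$has_tssa <- has_state("TssA")
  classes$has_enha <- has_state(c("EnhA1", "EnhA2"))
  out <- dplyr::summarise(dplyr::group_by(classes, class),
                          n_bins = dplyr::n(),
                          mean_ratio = mean(ratio),
                          frac_tssa = mean(has_tssa),
                          frac_enha = mean(has_enha), .groups = "drop")
  out <- out[order(out$class), ]
  rho <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(out$mean_ratio, x, method = "spearman")
  }
  structure(out,
    tssa_rho = rho(out$frac_tssa), enha_rho = rho(out$frac_enha),
    class = c("element_class_profile", class(tibble::tibble()))
  )
}

#' Classify enhancers as TSS-proximal or distal
#'
#' An active enhancer (EnhA1/EnhA2) is proximal when some TssA segment lies
#' within `window` bp edge-to-edge (an overlap counts as distance 0), and
#' distal otherwise; non-enhancer segments get `NA`.
#'
#' @param states Chromatin-state segments.
#' @param window Distance threshold in bp (default 20000, i.e. a TssA within
#'   20 kb upstream or downstream).
#' @return The segments with a `proximity` column (`"proximal"`,
#'   `"distal"`, or `NA`).
#' @export
classify_enhancer_proximity <- function(states, window = 20000) {
  is_enh <- states$state %in% c("EnhA1", "EnhA2")
  tssa <- states[states$state == "TssA", , drop = FALSE]
  states$proximity <- NA_character_
  if (!any(is_enh)) return(states)
  if (nrow(tssa) == 0) {
    states$proximity[is_enh] <- "distal"
    return(states)
  }
  enh <- states[is_enh, , drop = FALSE]
  hits <- GenomicRanges::distanceToNearest(as_granges0(enh), as_granges0(tssa))
  d <- rep(Inf, nrow(enh))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  states$proximity[is_enh] <- ifelse(d <= window, "proximal", "distal")
  states
}

#' Compare DSB ratios between bins with and without a feature
#'
#' Wilcoxon rank-sum test (two-sided) of the per-bin ratio in feature bins
#' versus the remaining bins.
#'
#' @param ratio A `dsb_ratio_track`.
#' @param feature_bins Global bin indices (or a logical vector over bins)
#'   carrying the feature.
#' @return One-row tibble: group sizes and medians, `statistic` (W) and
#'   `p_value`.
#' @export
compare_ratio_by_feature <- function(ratio, feature_bins) {
  if (is.logical(feature_bins)) feature_bins <- which(feature_bins)
  inside <- ratio$bin %in% feature_bins
  x <- ratio$ratio[inside]
  y <- ratio$ratio[!inside]
  if (length(x) == 0 || length(y) == 0) {
    stop("both feature and background groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y)) # ties fall back to the
  # normal approximation with continuity correction
  tibble::tibble(
    n_feature = length(x), n_background = length(y),
    median_feature = stats::median(x), median_background = stats::median(y),
    statistic = unname(wt$statistic), p_value = wt$p.value
  )
}

#' Pairwise ratio comparison across enhancer-proximity groups
#'
#' Assigns each bin to `proximal` / `distal` / `none` by its overlap with
#' classified enhancers (see [classify_enhancer_proximity()]) and runs
#' pairwise Wilcoxon rank-sum tests between the three groups.
#'
#' @param ratio A `dsb_ratio_track`.
#' @param states Segments with a `proximity` column.
#' @return List with `groups` (per-bin assignment counts and medians) and
#'   `tests` (one row per pair).
#' @export
compare_ratio_by_enhancer <- function(ratio, states) {
  if (!"proximity" %in% names(states)) {
    stop("run `classify_enhancer_proximity()` first", call. = FALSE)
  }
  assign_grp <- function(prox) {
    seg <- states[!is.na(states$proximity) & states$proximity == prox, , drop = FALSE]
    hit <- rep(FALSE, nrow(ratio))
    if (nrow(seg) > 0) hit[unique(overlap_pairs(ratio, seg)$qi)] <- TRUE
    hit
  }
  prox <- assign_grp("proximal")
  dist <- assign_grp("distal") & !prox # proximal wins when a bin has both
  grp <- dplyr::case_when(prox ~ "proximal", dist ~ "distal", TRUE ~ "none")
  groups <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = grp, ratio = ratio$ratio), group),
    n = dplyr::n(), median_ratio = stats::median(ratio), .groups = "drop"
  )
  pairs <- list(c("proximal", "distal"), c("proximal", "none"), c("distal", "none"))
  tests <- dplyr::bind_rows(lapply(pairs, function(p) {
    x <- ratio$ratio[grp == p[1]]
    y <- ratio$ratio[grp == p[2]]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(group1 = p[1], group2 = p[2],
                            statistic = NA_real_, p_value = NA_real_))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    tibble::tibble(group1 = p[1], group2 = p[2],
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  }))
  list(groups = groups, tests = tests)
}

#' Correlate DSB ratio with repeat-subtype coverage
#'
#' Per repeat subtype, computes each bin's coverage fraction (overlapping
#' repeat bp divided by bin length) and its Spearman correlation with the
#' DSB ratio.
#'
#' @param ratio A `dsb_ratio_track`.
#' @param repeats Repeat intervals with a `subtype` column.
#' @return Tibble: `subtype`, `rho`, `p_value`, `n_bins_covered`; `rho` is
#'   `NA` when coverage is constant.
#' @export
repeat_subtype_correlation <- function(ratio, repeats) {
  dplyr::bind_rows(lapply(sort(unique(repeats$subtype)), function(sub) {
    seg <- repeats[repeats$subtype == sub, , drop = FALSE]
    cov <- rep(0, nrow(ratio))
    hits <- overlap_pairs(ratio, seg)
    if (nrow(hits) > 0) {
      ov <- pmin(ratio$end[hits$qi], seg$end[hits$si]) -
        pmax(ratio$start[hits$qi], seg$start[hits$si])
      agg <- tapply(ov, hits$qi, sum)
      cov[as.integer(names(agg))] <- agg
    }
    frac <- cov / (ratio$end - ratio$start)
    if (stats::sd(frac) == 0) {
      return(tibble::tibble(subtype = sub, rho = NA_real_, p_value = NA_real_,
                            n_bins_covered = sum(frac > 0)))
    }
    ct <- suppressWarnings(stats::cor.test(ratio$ratio, frac,
                                           method = "spearman", exact = FALSE))
    tibble::tibble(subtype = sub, rho = unname(ct$estimate), p_value = ct$p.value,
                   n_bins_covered = sum(frac > 0))
  }))
}

#' Average signal profile around gene TSSs
#'
#' The window of `flank` bp either side of each TSS is split into `n_bins`
#' equal bins; per gene the breakpoint-site density in each bin is computed
#' in RPKM-like units (reads per kb per million total sites), minus-strand
#' genes are flipped so all profiles read 5' to 3', and profiles are
#' averaged over genes. Genes whose window leaves the chromosome are
#' excluded.
#'
#' @param sites Breakpoint records (`chrom`, `start`, optional `strand`,
#'   `end`); the 5' coordinate of each record is counted.
#' @param genes Gene table with `chrom`, `tss`, `strand`.
#' @param chrom_sizes Named chromosome lengths (for edge clipping).
#' @param flank Half-window in bp (default 5000).
#' @param n_bins Number of profile bins (default 100).
#' @return A `tss_profile` tibble: `bin` (1..n_bins), `offset` (bp of the
#'   bin center relative to the TSS, oriented), `density`.
#' @export
tss_meta_profile <- function(sites, genes, chrom_sizes, flank = 5000, n_bins = 100) {
  eligible <- genes$tss - flank >= 0 & genes$tss + flank <= chrom_sizes[genes$chrom]
  g <- genes[eligible, , drop = FALSE]
  if (nrow(g) == 0) stop("no gene window fits inside the genome", call. = FALSE)
  binw <- 2 * flank / n_bins
  pos <- if ("strand" %in% names(sites)) {
    ifelse(!is.na(sites$strand) & sites$strand == "-", sites$end - 1, sites$start)
  } else {
    sites$start
  }
  total <- nrow(sites)
  counts <- matrix(0, nrow = nrow(g), ncol = n_bins)
  windows <- tibble::tibble(chrom = g$chrom, start = g$tss - flank, end = g$tss + flank)
  pts <- tibble::tibble(chrom = sites$chrom, start = pos, end = pos + 1)
  hits <- overlap_pairs(pts, windows)
  if (nrow(hits) > 0) {
    off <- pos[hits$qi] - windows$start[hits$si]
    b <- pmin(off %/% binw + 1, n_bins)
    flip <- g$strand[hits$si] == "-"
    b[flip] <- n_bins + 1 - b[flip]
    for (r in seq_len(nrow(hits))) {
      counts[hits$si[r], b[r]] <- counts[hits$si[r], b[r]] + 1
    }
  }
  dens <- counts / (binw / 1000) / (total / 1e6)
  prof <- colMeans(dens)
  structure(
    tibble::tibble(
      bin = seq_len(n_bins),
      offset = -flank + (seq_len(n_bins) - 0.5) * binw,
      density = prof
    ),
    n_genes = nrow(g), flank = flank,
    class = c("tss_profile", class(tibble::tibble()))
  )
}
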