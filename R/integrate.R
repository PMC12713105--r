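#' Genes whose TSS lies in a differential loop anchor
#'
#' A gene is included when its TSS falls inside any anchor interval of a
#' gained or lost loop (half-open intervals; the TSS, not the gene body,
#' is the assignment point).
#'
#' @param genes Gene table with `chrom`, `tss`, `gene_id`.
#' @param diff A `diff_loops` tibble.
#' @return Tibble: `gene_id`, `direction` (`"gained"` / `"lost"`); genes in
#'   anchors of both directions appear once per direction.
#' @export
genes_in_anchors <- function(genes, diff) {
  res <- attr(diff, "resolution", exact = TRUE)
  out <- list()
  for (st in c("gained", "lost")) {
    d <- diff[diff$status == st, , drop = FALSE]
    if (nrow(d) == 0) next
    anchors <- loop_anchors(d, res)
    pts <- tibble::tibble(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1)
    hits <- overlap_pairs(pts, anchors)
    if (nrow(hits) == 0) next
    out[[st]] <- tibble::tibble(gene_id = unique(genes$gene_id[hits$qi]), direction = st)
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), direction = character()))
  }
  res_tbl <- dplyr::bind_rows(out)
  res_tbl[order(res_tbl$gene_id), ]
}

#' Binned correlation of gene expression with DSB enrichment
#'
#' Genes expressed above `min_fpkm` are ranked in descending order of DSB
#' enrichment (the ratio at the TSS-containing bin), split into `n_bins`
#' equal-count groups, and the Pearson correlation is computed on the group
#' means of enrichment and expression. When enrichment regions are
#' supplied, each gene is flagged as lying in one.
#'
#' @param genes Gene table with `fpkm_control`, `fpkm_treated`, `tss`.
#' @param ratio A `dsb_ratio_track`.
#' @param regions Optional enrichment regions for the `in_region` flag.
#' @param n_bins Number of gene groups (default 100).
#' @param expression Which condition's FPKM to correlate (default treated);
#'   the `min_fpkm` filter applies to the same column.
#' @param min_fpkm Expression floor for eligibility (default 1).
#' @return An `expression_dsb_profile` tibble (group means) with
#'   `pearson_r`, `pearson_p`, `n_genes` attributes.
#' @export
expression_dsb_correlation <- function(genes, ratio, regions = NULL, n_bins = 100,
                                       expression = c("treated", "control"),
                                       min_fpkm = 1) {
  expression <- match.arg(expression)
  fpkm <- if (expression == "treated") genes$fpkm_treated else genes$fpkm_control
  # locate each TSS's bin directly on the ratio track
  bw <- max(ratio$end - ratio$start)
  key <- paste(ratio$chrom, ratio$start %/% bw)
  gkey <- paste(genes$chrom, genes$tss %/% bw)
  idx <- match(gkey, key)
  eligible <- which(fpkm > min_fpkm & !is.na(idx))
  if (length(eligible) < n_bins) {
    stop("fewer than `n_bins` eligible genes; lower `n_bins`", call. = FALSE)
  }
  enrich <- ratio$ratio[idx[eligible]]
  in_region <- rep(FALSE, length(eligible))
  if (!is.null(regions) && nrow(regions) > 0) {
    pts <- tibble::tibble(chrom = genes$chrom[eligible],
                          start = genes$tss[eligible],
                          end = genes$tss[eligible] + 1)
    in_region[unique(overlap_pairs(pts, regions)$qi)] <- TRUE
  }
  ord <- order(-enrich, genes$gene_id[eligible])
  grp <- equal_count_groups(length(ord), n_bins)
  df <- tibble::tibble(group = grp,
                       enrichment = enrich[ord],
                       fpkm = fpkm[eligible][ord],
                       in_region = in_region[ord])
  prof <- dplyr::summarise(dplyr::group_by(df, group),
                           mean_enrichment = mean(enrichment),
                           mean_fpkm = mean(fpkm),
                           frac_in_region = mean(in_region),
                           n = dplyr::n(), .groups = "drop")
  if (stats::sd(prof$mean_fpkm) == 0 || stats::sd(prof$mean_enrichment) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(prof$mean_enrichment, prof$mean_fpkm, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(prof,
    pearson_r = r, pearson_p = p, n_genes = length(eligible),
    class = c("expression_dsb_profile", class(tibble::tibble()))
  )
}

#' Classify compartment bins by PC1 sign change
#'
#' Four-way sign classification of 100 kb compartment bins: (+,+) stable A,
#' (+,-) A-to-B, (-,+) B-to-A, (-,-) stable B; a zero or missing PC1 in
#' either condition gives `undefined`.
#'
#' @param pc1_control,pc1_treated bedGraph-style tibbles (`chrom`, `start`,
#'   `end`, `value`) on the same binning.
#' @return Tibble with `pc1_control`, `pc1_treated`, `class` columns and a
#'   `switch_fraction` attribute (switched / defined bins).
#' @export
classify_compartment_bins <- function(pc1_control, pc1_treated) {
  if (nrow(pc1_control) != nrow(pc1_treated) ||
      !identical(pc1_control$chrom, pc1_treated$chrom) ||
      !identical(pc1_control$start, pc1_treated$start)) {
    stop("PC1 tracks must share one binning", call. = FALSE)
  }
  ctl <- pc1_control$value
  trt <- pc1_treated$value
  cls <- dplyr::case_when(
    is.na(ctl) | is.na(trt) | ctl == 0 | trt == 0 ~ "undefined",
    ctl > 0 & trt > 0 ~ "stableA",
    ctl > 0 & trt < 0 ~ "AtoB",
    ctl < 0 & trt > 0 ~ "BtoA",
    TRUE ~ "stableB"
  )
  defined <- cls != "undefined"
  out <- tibble::tibble(chrom = pc1_control$chrom, start = pc1_control$start,
                        end = pc1_control$end,
                        pc1_control = ctl, pc1_treated = trt, class = cls)
  structure(out,
    switch_fraction = if (any(defined)) {
      sum(cls %in% c("AtoB", "BtoA")) / sum(defined)
    } else NA_real_,
    class = c("compartment_track", class(tibble::tibble()))
  )
}

#' DEG enrichment per compartment class
#'
#' Assigns each gene to the compartment class of its TSS bin and tests,
#' per class, whether DEGs are over-represented (upper-tail hypergeometric:
#' successes = DEGs in the class, draws = class genes, marked = all DEGs,
#' population = all assigned genes).
#'
#' @param genes Gene table with `is_deg`, `chrom`, `tss`.
#' @param compartments A [classify_compartment_bins()] track.
#' @return Tibble: `class`, `n_genes`, `n_deg`, `expected`, `p_value`.
#' @export
deg_compartment_enrichment <- function(genes, compartments) {
  if (nrow(genes) == 0) stop("empty gene universe", call. = FALSE)
  bw <- max(compartments$end - compartments$start)
  key <- paste(compartments$chrom, compartments$start %/% bw)
  idx <- match(paste(genes$chrom, genes$tss %/% bw), key)
  cls <- ifelse(is.na(idx), "undefined", compartments$class[idx])
  keep <- cls != "undefined"
  df <- tibble::tibble(class = cls[keep], is_deg = genes$is_deg[keep])
  N <- nrow(df)
  K <- sum(df$is_deg)
  out <- dplyr::summarise(dplyr::group_by(df, class),
                          n_genes = dplyr::n(), n_deg = sum(is_deg),
                          .groups = "drop")
  out$expected <- out$n_genes * K / N
  out$p_value <- if (K == 0) 1 else {
    hypergeom_bin_test(k = out$n_deg, n = out$n_genes, K = K, N = N)
  }
  out[order(out$class), ]
}

#' DSB ratio and expression across hierarchical TAD levels
#'
#' Each bin (and each gene, via its TSS) is assigned the deepest level of
#' the TADs covering it. Per level, the DSB-ratio and expression
#' distributions are summarised; consecutive levels are compared with
#' Wilcoxon rank-sum tests and the trend across levels with a Spearman
#' correlation on the bin-level (level, ratio) pairs.
#'
#' @param tads TAD calls (`chrom`, `start`, `end`, `level`).
#' @param ratio A `dsb_ratio_track`.
#' @param genes Gene table with `fpkm_treated`.
#' @return A `tad_association` list: `per_level`, `tests` (empty when only
#'   one level is covered), `trend_rho`.
#' @export
tad_level_association <- function(tads, ratio, genes) {
  bin_level <- rep(0L, nrow(ratio))
  hits <- overlap_pairs(ratio, tads)
  if (nrow(hits) > 0) {
    agg <- tapply(tads$level[hits$si], hits$qi, max)
    bin_level[as.integer(names(agg))] <- agg
  }
  gene_level <- rep(0L, nrow(genes))
  if (nrow(genes) > 0) {
    pts <- tibble::tibble(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1)
    gh <- overlap_pairs(pts, tads)
    if (nrow(gh) > 0) {
      agg <- tapply(tads$level[gh$si], gh$qi, max)
      gene_level[as.integer(names(agg))] <- agg
    }
  }
  bdf <- tibble::tibble(level = bin_level, ratio = ratio$ratio)[bin_level > 0, ]
  gdf <- tibble::tibble(level = gene_level,
                        fpkm = genes$fpkm_treated)[gene_level > 0, ]
  per_level <- dplyr::full_join(
    dplyr::summarise(dplyr::group_by(bdf, level), n_bins = dplyr::n(),
                     mean_ratio = mean(ratio), median_ratio = stats::median(ratio),
                     .groups = "drop"),
    dplyr::summarise(dplyr::group_by(gdf, level), n_genes = dplyr::n(),
                     mean_fpkm = mean(fpkm), median_fpkm = stats::median(fpkm),
                     .groups = "drop"),
    by = "level"
  )
  per_level <- per_level[order(per_level$level), ]
  levels_present <- sort(unique(bdf$level))
  tests <- tibble::tibble(level1 = integer(), level2 = integer(),
                          quantity = character(), statistic = numeric(),
                          p_value = numeric())
  if (length(levels_present) >= 2) {
    for (i in seq_len(length(levels_present) - 1)) {
      l1 <- levels_present[i]; l2 <- levels_present[i + 1]
      wt <- suppressWarnings(
        stats::wilcox.test(bdf$ratio[bdf$level == l1], bdf$ratio[bdf$level == l2])
      )
      tests <- dplyr::bind_rows(tests, tibble::tibble(
        level1 = l1, level2 = l2, quantity = "dsb_ratio",
        statistic = unname(wt$statistic), p_value = wt$p.value))
      x <- gdf$fpkm[gdf$level == l1]; y <- gdf$fpkm[gdf$level == l2]
      if (length(x) > 0 && length(y) > 0) {
        wg <- suppressWarnings(stats::wilcox.test(x, y))
        tests <- dplyr::bind_rows(tests, tibble::tibble(
          level1 = l1, level2 = l2, quantity = "fpkm",
          statistic = unname(wg$statistic), p_value = wg$p.value))
      }
    }
  }
  trend <- if (nrow(bdf) > 1 && stats::sd(bdf$level) > 0) {
    stats::cor(bdf$level, bdf$ratio, method = "spearman")
  } else NA_real_
  structure(list(per_level = per_level, tests = tests, trend_rho = trend),
            class = "tad_association")
}

#' Exclusive multi-set overlap (upset semantics)
#'
#' For every combination of set memberships, counts the genes belonging to
#' exactly that combination; the sum over combinations equals the size of
#' the union. Optionally emits the candidate list of genes present in every
#' one of a designated group of sets.
#'
#' @param sets Named list of character vectors (gene-id sets).
#' @param candidate_sets Optional character vector of set names; genes in
#'   the intersection of all of them become the `candidates` element.
#' @return A `multi_evidence` list: `combinations` (tibble with one logical
#'   column per set, `count`, and a `genes` list-column) and `candidates`.
#' @export
multi_evidence_overlap <- function(sets, candidate_sets = NULL) {
  if (length(sets) < 2) stop("need at least two sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  combos <- sort(unique(pattern))
  comb_tbl <- dplyr::bind_rows(lapply(combos, function(p) {
    flags <- as.logical(as.integer(strsplit(p, "")[[1]]))
    genes <- universe[pattern == p]
    row <- stats::setNames(as.list(flags), names(sets))
    row$count <- length(genes)
    row$genes <- list(genes)
    tibble::as_tibble(row)
  }))
  candidates <- character(0)
  if (!is.null(candidate_sets)) {
    missing <- setdiff(candidate_sets, names(sets))
    if (length(missing) > 0) {
      stop("unknown set name(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    candidates <- Reduce(intersect, sets[candidate_sets])
  }
  structure(list(combinations = comb_tbl, candidates = sort(candidates),
                 universe_size = length(universe)),
            class = "multi_evidence")
}
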