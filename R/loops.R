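#' Match loops across two conditions
#'
#' Loops match when both resolution-snapped anchor bins are identical; a
#' loop absent from the other condition carries probability 0 there (an
#' uncalled loop has effectively zero calling probability).
#'
#' @param a,b Loop tibbles at the same resolution (see [read_loops()]).
#' @param slack Allowed anchor shift in bins when matching (default 0,
#'   i.e. exact bin identity).
#' @return Tibble with `chrom`, `start1`, `start2`, `p_a`, `p_b`,
#'   `matched`.
#' @export
match_loops <- function(a, b, slack = 0) {
  res_a <- loop_resolution_of(a)
  res_b <- loop_resolution_of(b)
  if (!is.null(res_a) && !is.null(res_b) && res_a != res_b) {
    stop("loop sets have different resolutions", call. = FALSE)
  }
  res <- if (!is.null(res_a)) res_a else res_b
  ka <- tibble::tibble(chrom = a$chrom, start1 = a$start1, start2 = a$start2,
                       p_a = a$probability)
  kb <- tibble::tibble(chrom = b$chrom, start1 = b$start1, start2 = b$start2,
                       p_b = b$probability)
  if (slack > 0) {
    # match b loops within +/- slack bins per anchor onto unmatched a keys
    shift <- expand.grid(d1 = -slack:slack, d2 = -slack:slack)
    kb_exp <- dplyr::bind_rows(lapply(seq_len(nrow(shift)), function(i) {
      dplyr::mutate(kb,
                    start1 = start1 + shift$d1[i] * res,
                    start2 = start2 + shift$d2[i] * res,
                    pref = abs(shift$d1[i]) + abs(shift$d2[i]))
    }))
    kb_exp <- kb_exp[order(kb_exp$pref), ]
    kb <- dplyr::distinct(kb_exp, chrom, start1, start2, .keep_all = TRUE)
    kb$pref <- NULL
  }
  m <- dplyr::full_join(ka, kb, by = c("chrom", "start1", "start2"))
  m$matched <- !is.na(m$p_a) & !is.na(m$p_b)
  m$p_a[is.na(m$p_a)] <- 0
  m$p_b[is.na(m$p_b)] <- 0
  m <- m[order(m$chrom, m$start1, m$start2), ]
  structure(m, resolution = res, class = class(tibble::tibble()))
}

#' Call differential loops by probability thresholds
#'
#' A loop is gained when its calling probability exceeds `p_high` in the
#' treated condition and falls below `p_low` in the control, and lost in
#' the mirrored case (strict inequalities). Loops absent from one condition
#' count as probability 0 there, so condition-specific loops are eligible.
#'
#' @param treated,control Loop tibbles.
#' @param p_high,p_low Probability thresholds (defaults 0.95 and 0.8).
#' @return A `diff_loops` tibble of all matched loops with `p_treated`,
#'   `p_control` and `status` (`"gained"`, `"lost"`, `"stable"`) columns;
#'   thresholds and counts are attributes (see [glance.diff_loops()]).
#' @export
call_differential_loops <- function(treated, control, p_high = 0.95, p_low = 0.8) {
  if (p_low >= p_high) stop("`p_low` must be below `p_high`", call. = FALSE)
  m <- match_loops(treated, control)
  names(m)[names(m) == "p_a"] <- "p_treated"
  names(m)[names(m) == "p_b"] <- "p_control"
  m$status <- dplyr::case_when(
    m$p_treated > p_high & m$p_control < p_low ~ "gained",
    m$p_control > p_high & m$p_treated < p_low ~ "lost",
    TRUE ~ "stable"
  )
  structure(m,
    p_high = p_high, p_low = p_low,
    resolution = attr(m, "resolution", exact = TRUE),
    class = c("diff_loops", class(tibble::tibble()))
  )
}

#' Extract gained or lost loops
#' @param diff A `diff_loops` tibble.
#' @param status `"gained"` or `"lost"`.
#' @return The matching rows.
#' @export
differential_subset <- function(diff, status = c("gained", "lost")) {
  status <- match.arg(status)
  diff[diff$status == status, , drop = FALSE]
}

# anchor intervals (chrom,start,end) of a set of loops, one row per endpoint
loop_anchors <- function(loops, resolution) {
  tibble::tibble(
    chrom = rep(loops$chrom, 2),
    start = c(loops$start1, loops$start2),
    end = c(loops$start1, loops$start2) + resolution
  )
}

#' Build the anchor table with recurrence and busy status
#'
#' Counts how many loop endpoints fall on each distinct anchor bin; anchors
#' recurring at least `busy_min_frequency` times are busy (interaction
#' hubs). When a differential call is supplied, each anchor is additionally
#' flagged as participating in a differential loop.
#'
#' @param loops Loop tibble (typically the union of both conditions'
#'   loops, or a [match_loops()] / [call_differential_loops()] result).
#' @param diff Optional `diff_loops` tibble for the `in_differential` flag.
#' @param busy_min_frequency Minimum recurrence for busy status (default 2).
#' @return Tibble: `chrom`, `start`, `end`, `frequency`, `busy` and (when
#'   `diff` is given) `in_differential`. Frequencies sum to twice the loop
#'   count.
#' @export
build_anchor_table <- function(loops, diff = NULL, busy_min_frequency = 2) {
  res <- attr(loops, "resolution", exact = TRUE)
  if (is.null(res)) res <- loop_resolution_of(loops)
  if (is.null(res)) stop("loop set carries no resolution attribute", call. = FALSE)
  anchors <- loop_anchors(loops, res)
  tab <- dplyr::summarise(dplyr::group_by(anchors, chrom, start, end),
                          frequency = dplyr::n(), .groups = "drop")
  tab$busy <- tab$frequency >= busy_min_frequency
  if (!is.null(diff)) {
    d <- diff[diff$status %in% c("gained", "lost"), , drop = FALSE]
    da <- loop_anchors(d, res)
    key <- paste(da$chrom, da$start)
    tab$in_differential <- paste(tab$chrom, tab$start) %in% key
  }
  tab[order(tab$chrom, tab$start), ]
}

#' Chi-square test for a 2x2 table (closed form, vectorized)
#'
#' Uncorrected statistic `N (ad - bc)^2 / (r1 r2 c1 c2)` and the Yates
#' continuity-corrected statistic `N (max(|ad - bc| - N/2, 0))^2 /
#' (r1 r2 c1 c2)`, with 1 df p-values. Degenerate margins give `NaN`
#' statistics and `NA` p-values.
#'
#' @param a,b,c,d Cell counts (row-wise: `[[a, b], [c, d]]`), vectorized.
#' @return Tibble: `statistic`, `p_value` (Yates), `statistic_uncorrected`,
#'   `p_value_uncorrected`, `df`.
#' @examples
#' chisq_2x2(10, 20, 20, 10) # 5.4 corrected, 6.6667 uncorrected
#' @export
chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  det <- a * d - b * c
  stat_u <- n * det^2 / denom
  stat_y <- n * pmax(abs(det) - n / 2, 0)^2 / denom
  p_u <- ifelse(is.nan(stat_u) | !is.finite(stat_u), NA_real_,
                stats::pchisq(stat_u, df = 1, lower.tail = FALSE))
  p_y <- ifelse(is.nan(stat_y) | !is.finite(stat_y), NA_real_,
                stats::pchisq(stat_y, df = 1, lower.tail = FALSE))
  tibble::tibble(statistic = stat_y, p_value = p_y,
                 statistic_uncorrected = stat_u, p_value_uncorrected = p_u,
                 df = 1L)
}

#' Association between busy anchors and differential loops
#'
#' Tests independence in the 2x2 contingency table of anchor status
#' (busy / normal) against differential-loop membership, with Yates
#' continuity correction (the uncorrected statistic is also reported).
#'
#' @param anchors Anchor table from [build_anchor_table()] including the
#'   `in_differential` column.
#' @return An `assoc_test` object: list with `table` (2x2 matrix),
#'   `statistic`, `p_value`, `statistic_uncorrected`,
#'   `p_value_uncorrected`, `df`, `method`.
#' @export
busy_anchor_association <- function(anchors) {
  if (!"in_differential" %in% names(anchors)) {
    stop("anchor table lacks `in_differential`; pass `diff` to `build_anchor_table()`",
         call. = FALSE)
  }
  tab <- matrix(c(
    sum(anchors$busy & anchors$in_differential),
    sum(anchors$busy & !anchors$in_differential),
    sum(!anchors$busy & anchors$in_differential),
    sum(!anchors$busy & !anchors$in_differential)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("busy", "normal"), c("differential", "not")))
  assoc_from_table(tab, "busy-anchor vs differential-loop association")
}

assoc_from_table <- function(tab, method) {
  cs <- chisq_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  structure(list(
    table = tab,
    statistic = cs$statistic, p_value = cs$p_value,
    statistic_uncorrected = cs$statistic_uncorrected,
    p_value_uncorrected = cs$p_value_uncorrected,
    df = 1L, method = method
  ), class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(x$method, "\n")
  print(x$table)
  cat(sprintf("chi-square (Yates) = %.4f, df = 1, p = %.4g\n", x$statistic, x$p_value))
  cat(sprintf("chi-square (uncorrected) = %.4f, p = %.4g\n",
              x$statistic_uncorrected, x$p_value_uncorrected))
  invisible(x)
}

#' Colocalization of DSB enrichment regions with differential anchors
#'
#' Counts genomic bins falling in differential-loop anchors and in DSB
#' enrichment regions and tests their association with a Yates-corrected
#' chi-square on the 2x2 table over all bins.
#'
#' @param regions DSB enrichment regions ([call_enrichment_regions()]).
#' @param diff A `diff_loops` tibble.
#' @param binning The genome binning the counting unit comes from.
#' @return An `assoc_test` object with an extra `overlap` element: the
#'   number of bins in both a differential anchor and a DSB region.
#' @export
dsb_anchor_enrichment <- function(regions, diff, binning) {
  res <- attr(diff, "resolution", exact = TRUE)
  d <- diff[diff$status %in% c("gained", "lost"), , drop = FALSE]
  in_anchor <- rep(FALSE, nrow(binning))
  if (nrow(d) > 0) {
    da <- loop_anchors(d, res)
    in_anchor[unique(overlap_pairs(binning, da)$qi)] <- TRUE
  }
  in_region <- rep(FALSE, nrow(binning))
  if (nrow(regions) > 0) {
    in_region[unique(overlap_pairs(binning, regions)$qi)] <- TRUE
  }
  tab <- matrix(c(
    sum(in_anchor & in_region), sum(in_anchor & !in_region),
    sum(!in_anchor & in_region), sum(!in_anchor & !in_region)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("anchor", "no_anchor"), c("dsb_region", "no_region")))
  out <- assoc_from_table(tab, "DSB-region vs differential-anchor colocalization")
  out$overlap <- tab[1, 1]
  out
}
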