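#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an association test into a one-row tibble
#' @param x An `assoc_test` object.
#' @param ... Unused.
#' @return Tibble with statistics, p-values and the table cells.
#' @method tidy assoc_test
#' @export
tidy.assoc_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic, p_value = x$p_value,
    statistic_uncorrected = x$statistic_uncorrected,
    p_value_uncorrected = x$p_value_uncorrected,
    df = x$df,
    a = x$table[1, 1], b = x$table[1, 2], c = x$table[2, 1], d = x$table[2, 2]
  )
}

#' @rdname tidy.assoc_test
#' @method glance assoc_test
#' @export
glance.assoc_test <- function(x, ...) tidy(x)[c("statistic", "p_value", "df")]

#' One-row summary of a DSB ratio track
#' @param x A `dsb_ratio_track`.
#' @param ... Unused.
#' @return Tibble with library sizes, mean per-bin ratio and ratio of totals.
#' @method glance dsb_ratio_track
#' @export
glance.dsb_ratio_track <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x),
    lib_treated = attr(x, "lib_treated", exact = TRUE),
    lib_control = attr(x, "lib_control", exact = TRUE),
    pseudocount = attr(x, "pseudocount", exact = TRUE),
    mean_bin_ratio = attr(x, "mean_bin_ratio", exact = TRUE),
    median_bin_ratio = attr(x, "median_bin_ratio", exact = TRUE),
    totals_ratio = attr(x, "totals_ratio", exact = TRUE)
  )
}

#' One-row summary of a differential-loop call
#' @param x A `diff_loops` tibble.
#' @param ... Unused.
#' @return Tibble with gained/lost/stable counts and the thresholds.
#' @method glance diff_loops
#' @export
glance.diff_loops <- function(x, ...) {
  tibble::tibble(
    n_loops = nrow(x),
    n_gained = sum(x$status == "gained"),
    n_lost = sum(x$status == "lost"),
    n_stable = sum(x$status == "stable"),
    p_high = attr(x, "p_high", exact = TRUE),
    p_low = attr(x, "p_low", exact = TRUE)
  )
}

#' One-row summary of a TSS-distance profile
#' @param x A `tss_distance_profile`.
#' @param ... Unused.
#' @return Tibble with both correlations and the region count.
#' @method glance tss_distance_profile
#' @export
glance.tss_distance_profile <- function(x, ...) {
  tibble::tibble(
    spearman_rho = attr(x, "spearman_rho", exact = TRUE),
    spearman_p = attr(x, "spearman_p", exact = TRUE),
    pearson_r = attr(x, "pearson_r", exact = TRUE),
    pearson_p = attr(x, "pearson_p", exact = TRUE),
    n_groups = nrow(x),
    n_regions = attr(x, "n_regions", exact = TRUE)
  )
}

#' One-row summary of an expression-DSB profile
#' @param x An `expression_dsb_profile`.
#' @param ... Unused.
#' @return Tibble with the Pearson correlation and gene count.
#' @method glance expression_dsb_profile
#' @export
glance.expression_dsb_profile <- function(x, ...) {
  tibble::tibble(
    pearson_r = attr(x, "pearson_r", exact = TRUE),
    pearson_p = attr(x, "pearson_p", exact = TRUE),
    n_groups = nrow(x),
    n_genes = attr(x, "n_genes", exact = TRUE)
  )
}

#' One-row summary of an APA result
#' @param x An `apa_result`.
#' @param ... Unused.
#' @return Tibble with the score and loop counts.
#' @method glance apa_result
#' @export
glance.apa_result <- function(x, ...) {
  tibble::tibble(
    apa_score = x$apa_score,
    n_loops_used = x$n_loops_used,
    n_loops_dropped = x$n_loops_dropped,
    window = x$window
  )
}

#' Tidy an APA aggregate matrix into long form
#' @param x An `apa_result`.
#' @param ... Unused.
#' @return Tibble with `row_offset`, `col_offset` (bins from the loop
#'   pixel) and `oe` (aggregate observed/expected).
#' @method tidy apa_result
#' @export
tidy.apa_result <- function(x, ...) {
  w <- x$window
  offs <- -w:w
  tibble::tibble(
    row_offset = rep(offs, times = 2 * w + 1),
    col_offset = rep(offs, each = 2 * w + 1),
    oe = as.vector(x$matrix)
  )
}
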