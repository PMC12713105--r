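#' Plot a TSS-distance profile
#'
#' Scatter of group mean DSB ratio against group mean distance from the
#' nearest TSS, one point per equal-count ratio group.
#'
#' @param object A [tss_distance_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tss_distance_profile
#' @export
autoplot.tss_distance_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = mean_tss_dist / 1000, y = mean_ratio)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = "Mean distance from nearest TSS (kb)",
      y = "Mean DSB ratio (treated / control)",
      subtitle = sprintf("Spearman rho = %.2f",
                         attr(object, "spearman_rho", exact = TRUE))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an APA aggregate matrix
#'
#' Heatmap of the aggregate observed/expected submatrix around the loop
#' pixel; the score is the center over the lower-left corner block.
#'
#' @param object An [apa()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apa_result
#' @export
autoplot.apa_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = col_offset, y = row_offset, fill = oe)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "O/E") +
    ggplot2::labs(
      x = "Offset from anchor 2 (bins)", y = "Offset from anchor 1 (bins)",
      subtitle = sprintf("APA score = %.2f", object$apa_score)
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot element fractions across DSB-ratio classes
#'
#' Fraction of bins containing an active promoter (TssA) and an active
#' enhancer (EnhA) per descending-ratio class.
#'
#' @param object An [element_fraction_by_class()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot element_class_profile
#' @export
autoplot.element_class_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("class", "frac_tssa", "frac_enha")],
    cols = c("frac_tssa", "frac_enha"),
    names_to = "element", values_to = "fraction"
  )
  df$element <- ifelse(df$element == "frac_tssa", "TssA", "EnhA")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(class), y = fraction, fill = element)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "DSB-ratio class (1 = highest)", y = "Fraction of bins") +
    ggplot2::theme_minimal()
}

#' Plot a TSS meta-profile
#'
#' Average breakpoint density around the TSS, oriented 5' to 3'.
#'
#' @param object A [tss_meta_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tss_profile
#' @export
autoplot.tss_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = offset / 1000, y = density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Distance from TSS (kb)", y = "Density (RPKM-like)") +
    ggplot2::theme_minimal()
}
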