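#' Aggregate peak analysis (APA)
#'
#' For every usable loop, the `(2w+1) x (2w+1)` observed submatrix centered
#' on the loop pixel is extracted, divided pixel-wise by the
#' distance-expected contact (the mean count at each diagonal offset,
#' estimated from the whole matrix), and averaged across loops. The APA
#' score is the center pixel of the aggregate divided by the mean of its
#' 3x3 lower-left corner block (the short-distance background), the
#' standard convention. Loops whose anchor separation is at most
#' `min_separation` bins, or whose window leaves the matrix, are dropped
#' and counted.
#'
#' @param contacts A `contact_matrix` tibble (see [read_contacts()] /
#'   [simulate_contacts()]); upper-triangle storage, `bin_i <= bin_j`.
#' @param loops Loop tibble at the matrix resolution.
#' @param window Half-width `w` of the aggregate window in bins (default 10).
#' @param min_separation Minimum anchor separation in bins (default `3 * window`).
#' @return An `apa_result`: list with `matrix` (aggregate O/E), `apa_score`,
#'   `n_loops_used`, `n_loops_dropped`, `window`.
#' @export
apa <- function(contacts, loops, window = 10, min_separation = 3 * window) {
  res <- attr(contacts, "resolution", exact = TRUE)
  nb <- attr(contacts, "n_bins", exact = TRUE)
  w <- as.integer(window)
  size <- 2L * w + 1L

  # dense symmetric matrix and diagonal-mean expected per chromosome
  dense <- list()
  expected <- list()
  for (ch in names(nb)) {
    m <- nb[[ch]]
    cc <- contacts[contacts$chrom == ch, , drop = FALSE]
    M <- matrix(0, m, m)
    if (nrow(cc) > 0) {
      M[cbind(cc$bin_i + 1L, cc$bin_j + 1L)] <- cc$count
      low <- cc$bin_i != cc$bin_j
      M[cbind(cc$bin_j[low] + 1L, cc$bin_i[low] + 1L)] <- cc$count[low]
    }
    d <- 0:(m - 1)
    tot <- numeric(m)
    if (nrow(cc) > 0) {
      off <- cc$bin_j - cc$bin_i
      agg <- tapply(cc$count, off, sum)
      tot[as.integer(names(agg)) + 1L] <- agg
    }
    expected[[ch]] <- tot / (m - d) # mean over all pairs at each offset
    dense[[ch]] <- M
  }

  agg <- matrix(0, size, size)
  nmat <- matrix(0, size, size) # per-pixel denominator (expected can be 0)
  used <- 0L
  dropped <- 0L
  for (k in seq_len(nrow(loops))) {
    ch <- loops$chrom[k]
    if (!ch %in% names(nb)) { dropped <- dropped + 1L; next }
    i <- loops$start1[k] %/% res
    j <- loops$start2[k] %/% res
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    m <- nb[[ch]]
    if ((j - i) <= min_separation ||
        i - w < 0 || i + w >= m || j - w < 0 || j + w >= m) {
      dropped <- dropped + 1L
      next
    }
    sub <- dense[[ch]][(i - w):(i + w) + 1L, (j - w):(j + w) + 1L]
    offs <- abs(outer((i - w):(i + w), (j - w):(j + w), FUN = function(x, y) y - x))
    e <- matrix(expected[[ch]][offs + 1L], size, size)
    ok <- e > 0
    ratio <- matrix(0, size, size)
    ratio[ok] <- sub[ok] / e[ok]
    agg <- agg + ratio
    nmat <- nmat + ok
    used <- used + 1L
  }
  if (used == 0) stop("no usable loops for APA", call. = FALSE)
  agg <- agg / pmax(nmat, 1)
  corner <- agg[(size - 2):size, 1:3]
  score <- agg[w + 1L, w + 1L] / mean(corner)
  structure(list(matrix = agg, apa_score = score,
                 n_loops_used = used, n_loops_dropped = dropped, window = w),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA over %d loops (%d dropped), window %d bins\n",
              x$n_loops_used, x$n_loops_dropped, x$window))
  cat(sprintf("APA score (center / lower-left corner): %.3f\n", x$apa_score))
  invisible(x)
}
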