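#' Tile a genome into fixed-width bins
#'
#' Builds the shared genome binning used by every quantification step. Bins
#' are 0-based half-open intervals tiling each chromosome in the order the
#' chromosomes are given; the final bin of a chromosome may be shorter than
#' `bin_width` (it is retained, never dropped, so the bins always form a
#' partition of the genome).
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp, or a
#'   two-column data frame (chrom, size) as read by [read_chrom_sizes()].
#' @param bin_width Bin width in bp. Defaults to 5000, the resolution at
#'   which DSB signal is analysed.
#' @return A tibble of class `genome_bins` with columns `chrom`, `start`,
#'   `end`, `bin` (1-based global index), carrying `bin_width` and
#'   `chrom_sizes` attributes.
#' @examples
#' make_bins(c(chr1 = 12000), 5000)
#' @export
make_bins <- function(chrom_sizes, bin_width = 5000) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  }
  if (length(chrom_sizes) == 0) {
    stop("`chrom_sizes` must name at least one chromosome", call. = FALSE)
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("`chrom_sizes` must be a named vector", call. = FALSE)
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1 || is.na(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be a single positive number", call. = FALSE)
  }
  if (any(is.na(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  bin_width <- as.integer(bin_width)
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq.int(0L, len - 1L, by = bin_width)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + bin_width, len))
  })
  bins <- dplyr::bind_rows(pieces)
  bins$bin <- seq_len(nrow(bins))
  structure(bins,
    bin_width = bin_width,
    chrom_sizes = chrom_sizes,
    class = c("genome_bins", class(tibble::tibble()))
  )
}

bin_width_of <- function(binning) attr(binning, "bin_width", exact = TRUE)
chrom_sizes_of <- function(binning) attr(binning, "chrom_sizes", exact = TRUE)

# first global bin index and bin count per chromosome
chrom_offsets <- function(binning) {
  sizes <- chrom_sizes_of(binning)
  bw <- bin_width_of(binning)
  n <- ceiling(sizes / bw)
  tibble::tibble(
    chrom = names(sizes),
    n_bins = as.integer(n),
    offset = c(0L, cumsum(as.integer(n)))[seq_along(n)]
  )
}

#' Map genomic positions to bin indices
#'
#' @param binning A `genome_bins` object.
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Integer global bin indices; `NA` for positions off the binning.
#' @export
bin_index <- function(binning, chrom, pos) {
  off <- chrom_offsets(binning)
  i <- match(chrom, off$chrom)
  bw <- bin_width_of(binning)
  sizes <- chrom_sizes_of(binning)
  local <- pos %/% bw
  idx <- off$offset[i] + local + 1L
  bad <- is.na(i) | pos < 0 | pos >= sizes[i]
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Median nucleotide of a genomic interval
#'
#' The representative single base of a 0-based half-open interval:
#' `start + floor((end - start - 1) / 2)`. Even-length intervals take the
#' lower median, a deterministic tie rule.
#'
#' @param start,end Vectors of 0-based half-open interval bounds.
#' @return Integer positions, always inside the interval.
#' @examples
#' median_nucleotide(1000, 2000) # 1499
#' @export
median_nucleotide <- function(start, end) {
  if (any(end <= start)) stop("intervals must satisfy start < end", call. = FALSE)
  as.integer(start + (end - start - 1) %/% 2)
}

#' Distance from regions to the nearest gene TSS
#'
#' For each region, the minimum absolute distance between its median
#' nucleotide and the TSS of any gene on the same chromosome. Regions on
#' chromosomes with no gene get `NA` and are excluded from downstream
#' distance analyses. The choice of the nearest (rather than an assigned)
#' gene is a documented convention of this package.
#'
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @param genes Gene table with `chrom` and `tss` (see [gene_tss()]).
#' @return Numeric vector of distances in bp, one per region row.
#' @export
nearest_tss_distance <- function(regions, genes) {
  if (nrow(genes) == 0) stop("`genes` must contain at least one gene", call. = FALSE)
  mid <- median_nucleotide(regions$start, regions$end)
  out <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    tss <- sort(genes$tss[genes$chrom == ch])
    ri <- which(regions$chrom == ch)
    if (length(tss) == 0) next
    pos <- mid[ri]
    j <- findInterval(pos, tss)
    lo <- ifelse(j >= 1, tss[pmax(j, 1)], NA_real_)
    hi <- ifelse(j < length(tss), tss[pmin(j + 1, length(tss))], NA_real_)
    out[ri] <- pmin(abs(pos - lo), abs(hi - pos), na.rm = TRUE)
  }
  out
}

#' Compute TSS positions for a gene table
#'
#' TSS is the interval start for `+` strand genes and `end - 1` for `-`
#' strand genes (0-based).
#'
#' @param genes Data frame with `start`, `end`, `strand`.
#' @return The table with a `tss` column added (existing `tss` is replaced).
#' @export
gene_tss <- function(genes) {
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  genes
}

#' Half-open interval overlap test
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b Parallel vectors
#'   describing two sets of intervals compared element-wise.
#' @return Logical vector; intervals on different chromosomes do not overlap.
#' @export
overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

#' Bins overlapping an interval
#'
#' @param binning A `genome_bins` object.
#' @param chrom,start,end A single interval (0-based half-open).
#' @return Integer vector of global bin indices sharing at least 1 bp.
#' @export
bins_overlapping <- function(binning, chrom, start, end) {
  off <- chrom_offsets(binning)
  i <- match(chrom, off$chrom)
  if (is.na(i)) return(integer(0))
  bw <- bin_width_of(binning)
  sizes <- chrom_sizes_of(binning)
  if (start >= sizes[i] || end <= 0 || end <= start) return(integer(0))
  lo <- max(0, start) %/% bw
  hi <- min((min(end, sizes[i]) - 1) %/% bw, off$n_bins[i] - 1L)
  if (hi < lo) return(integer(0))
  as.integer(off$offset[i] + seq.int(lo, hi) + 1L)
}

# Internal: tibble (chrom,start,end in 0-based half-open) -> GRanges
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

# Internal: overlap pairs between two interval tibbles (>= 1 bp).
# Returns tibble(qi, si) of row indices.
overlap_pairs <- function(query, subject) {
  hits <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject))
  tibble::tibble(
    qi = S4Vectors::queryHits(hits),
    si = S4Vectors::subjectHits(hits)
  )
}
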