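#' Read a chrom.sizes file
#'
#' Two-column whitespace-separated text: chromosome name, length in bp.
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "", col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}

#' Write a chrom.sizes file
#' @param chrom_sizes Named numeric vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(
    tibble::tibble(chrom = names(chrom_sizes), size = as.integer(chrom_sizes)),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' BED3 through BED6; 0-based half-open coordinates are kept as-is. The
#' optional name column is returned as `name` (used for chromatin-state
#' labels and repeat subtypes), column 6 as `strand`.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  out <- tibble::tibble(
    chrom = df[[1]],
    start = as.numeric(df[[2]]),
    end = as.numeric(df[[3]])
  )
  if (ncol(df) >= 4) out$name <- df[[4]]
  if (ncol(df) >= 5) out$score <- suppressWarnings(as.numeric(df[[5]]))
  if (ncol(df) >= 6) out$strand <- df[[6]]
  out
}

#' Write intervals as BED
#'
#' Rows are sorted by (chrom, start) so output is deterministic.
#'
#' @param df Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(df))
  # BED columns are positional: truncate at the first absent one
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- match(FALSE, want %in% keep, nomatch = length(want) + 1L) - 1L
  out <- df[order(df$chrom, df$start), want[seq_len(upto)], drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  tibble::tibble(chrom = df[[1]], start = df[[2]], end = df[[3]], value = df[[4]])
}

#' Write a bedGraph track
#' @param df Tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column.
#' @export
write_bedgraph <- function(df, path, value = "value") {
  out <- tibble::tibble(
    chrom = df$chrom,
    start = format(df$start, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    value = format(df[[value]], scientific = FALSE, trim = TRUE, digits = 10)
  )
  readr::write_tsv(out[order(df$chrom, df$start), ], path, col_names = FALSE)
  invisible(path)
}

#' Read a GTF-lite gene table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `fpkm_control`, `fpkm_treated`, `deg_flag`. Coordinates are 0-based
#' half-open. This deliberately is not a full GTF parser.
#'
#' @param path File path.
#' @return Tibble with a computed `tss` column and logical `is_deg`.
#' @export
read_gene_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand",
            "fpkm_control", "fpkm_treated", "deg_flag")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("gene table missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$fpkm_control < 0) || any(df$fpkm_treated < 0)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  out <- gene_tss(df)
  out$is_deg <- as.logical(df$deg_flag)
  out
}

#' Write a GTF-lite gene table
#' @param genes Gene tibble (as from [simulate_genome()] or [read_gene_table()]).
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = genes$start, end = genes$end, strand = genes$strand,
    fpkm_control = genes$fpkm_control, fpkm_treated = genes$fpkm_treated,
    deg_flag = as.integer(genes$is_deg)
  )
  readr::write_tsv(out[order(out$chrom, out$start), ], path)
  invisible(path)
}

#' Read probability-scored loops from BEDPE
#'
#' Accepts 7+ column BEDPE. With exactly 7 columns the 7th is the calling
#' probability; with 8 or more, column 7 is the loop name and column 8 the
#' probability (10-column files additionally carry the two strands, which
#' are ignored). Anchors are snapped down to the loop-resolution grid and
#' ordered so anchor 1 is upstream. Inter-chromosomal rows and rows whose
#' two anchors snap to the same bin are skipped with a warning naming the
#' line numbers; a probability outside [0, 1] is a parse error.
#'
#' @param path File path.
#' @param resolution Anchor resolution in bp (default 10000).
#' @param condition Optional condition label stored on every loop.
#' @return A loop tibble: `chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `probability`, `condition`, with a `resolution` attribute.
#' @export
read_loops <- function(path, resolution = 10000, condition = NA_character_) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 7) stop("BEDPE must have at least 7 columns", call. = FALSE)
  prob_col <- if (ncol(df) >= 8) 8L else 7L
  prob <- suppressWarnings(as.numeric(df[[prob_col]]))
  s1 <- suppressWarnings(as.numeric(df[[2]]))
  s2 <- suppressWarnings(as.numeric(df[[5]]))
  e1 <- suppressWarnings(as.numeric(df[[3]]))
  e2 <- suppressWarnings(as.numeric(df[[6]]))
  malformed <- is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2) | is.na(prob)
  if (any(malformed)) {
    warning("skipping malformed BEDPE rows at lines: ",
            paste(which(malformed), collapse = ", "))
  }
  if (any(prob[!malformed] < 0 | prob[!malformed] > 1)) {
    stop("loop probability outside [0, 1] at lines: ",
         paste(which(!malformed & (prob < 0 | prob > 1)), collapse = ", "),
         call. = FALSE)
  }
  inter <- !malformed & df[[1]] != df[[4]]
  if (any(inter)) {
    warning("skipping inter-chromosomal rows at lines: ",
            paste(which(inter), collapse = ", "))
  }
  keep <- !malformed & !inter
  loops <- tibble::tibble(
    chrom = df[[1]][keep],
    start1 = (s1[keep] %/% resolution) * resolution,
    start2 = (s2[keep] %/% resolution) * resolution,
    probability = prob[keep]
  )
  # anchor1 upstream
  swap <- loops$start1 > loops$start2
  tmp <- loops$start1[swap]
  loops$start1[swap] <- loops$start2[swap]
  loops$start2[swap] <- tmp
  same <- loops$start1 == loops$start2
  if (any(same)) {
    warning("skipping rows whose anchors snap to the same bin at lines: ",
            paste(which(keep)[same], collapse = ", "))
    loops <- loops[!same, , drop = FALSE]
  }
  new_loopset(loops, resolution, condition)
}

new_loopset <- function(loops, resolution, condition = NA_character_) {
  out <- tibble::tibble(
    chrom = loops$chrom,
    start1 = loops$start1, end1 = loops$start1 + resolution,
    start2 = loops$start2, end2 = loops$start2 + resolution,
    probability = loops$probability,
    condition = if ("condition" %in% names(loops)) loops$condition else condition
  )
  structure(out, resolution = resolution,
            class = c("loop_set", class(tibble::tibble())))
}

loop_resolution_of <- function(loops) attr(loops, "resolution", exact = TRUE)

#' Write loops as 10-column BEDPE
#'
#' Columns: anchors (6), name, probability, strands ("." placeholders).
#' Rows sorted by (chrom, start1, start2).
#'
#' @param loops A loop tibble from [read_loops()] or [simulate_loops()].
#' @param path Output path.
#' @export
write_loops <- function(loops, path) {
  ord <- order(loops$chrom, loops$start1, loops$start2)
  l <- loops[ord, , drop = FALSE]
  out <- tibble::tibble(
    chrom1 = l$chrom,
    start1 = format(l$start1, scientific = FALSE, trim = TRUE),
    end1 = format(l$end1, scientific = FALSE, trim = TRUE),
    chrom2 = l$chrom,
    start2 = format(l$start2, scientific = FALSE, trim = TRUE),
    end2 = format(l$end2, scientific = FALSE, trim = TRUE),
    name = sprintf("loop_%d", seq_len(nrow(l))),
    probability = format(l$probability, scientific = FALSE, trim = TRUE, digits = 10),
    strand1 = ".", strand2 = "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a sparse contact matrix from triplet text
#'
#' Format: a header line `# resolution=<bp>` followed by header lines
#' `# chrom=<name> n_bins=<n>` (one per chromosome), then tab-separated
#' `chrom bin_i bin_j count` rows with 0-based local bin indices, i <= j.
#'
#' @param path File path.
#' @return A contact tibble (`chrom`, `bin_i`, `bin_j`, `count`) with
#'   `resolution` and `n_bins` (named integer vector) attributes.
#' @export
read_contacts <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  res <- as.integer(sub(".*resolution=([0-9]+).*", "\\1", hdr[grepl("resolution=", hdr)][1]))
  chr_hdr <- hdr[grepl("chrom=", hdr)]
  chroms <- sub(".*chrom=([^ ]+).*", "\\1", chr_hdr)
  nb <- as.integer(sub(".*n_bins=([0-9]+).*", "\\1", chr_hdr))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  df <- utils::read.table(text = body, sep = "\t",
                          col.names = c("chrom", "bin_i", "bin_j", "count"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  structure(tibble::as_tibble(df),
            resolution = res, n_bins = stats::setNames(nb, chroms),
            class = c("contact_matrix", class(tibble::tibble())))
}

#' Write a sparse contact matrix as triplet text
#' @param contacts A contact tibble from [simulate_contacts()] or [read_contacts()].
#' @param path Output path.
#' @export
write_contacts <- function(contacts, path) {
  nb <- attr(contacts, "n_bins", exact = TRUE)
  hdr <- c(
    sprintf("# resolution=%d", attr(contacts, "resolution", exact = TRUE)),
    sprintf("# chrom=%s n_bins=%d", names(nb), nb)
  )
  ord <- order(contacts$chrom, contacts$bin_i, contacts$bin_j)
  body <- sprintf("%s\t%d\t%d\t%s", contacts$chrom[ord],
                  contacts$bin_i[ord], contacts$bin_j[ord],
                  format(contacts$count[ord], scientific = FALSE, trim = TRUE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read hierarchical TAD calls
#'
#' Tab-separated with or without header: `chrom`, `start`, `end`, `level`.
#'
#' @param path File path.
#' @return Tibble with those four columns; `level` integer >= 1.
#' @export
read_tads <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- if (has_header) {
    utils::read.table(path, header = TRUE, sep = "\t")
  } else {
    utils::read.table(path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "start", "end", "level"))
  }
  names(df) <- c("chrom", "start", "end", "level")
  tibble::tibble(chrom = as.character(df$chrom), start = as.numeric(df$start),
                 end = as.numeric(df$end), level = as.integer(df$level))
}
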