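#' Simulation parameters
#'
#' Assembles (and validates) the parameter set for the synthetic-data
#' generator. Defaults describe the data structure the analysis assumes:
#' a small multi-chromosome genome binned at 5 kb, Poisson DSB counts whose
#' treatment effect decays with TSS distance and is boosted at active
#' enhancers, two-condition probability-scored loop lists with busy-anchor
#' hubs and planted differential loops co-located with DSB hotspots, contact
#' matrices with power-law distance decay and planted loop peaks, and
#' lognormal expression coupled to gained/lost loop anchors.
#'
#' @param seed Integer master seed; every generator stage derives a named
#'   substream from it, so one seed fully determines all outputs.
#' @param n_chrom,chrom_len Number of chromosomes and their common length (bp).
#' @param n_genes,n_enhancers Genes and active-enhancer segments to place.
#' @param bin_width DSB analysis resolution in bp (5 kb).
#' @param base_rate Expected control DSB reads per bin at a TSS.
#' @param floor_rate Additive background rate per bin.
#' @param tss_decay Exponential decay length (bp) of DSB rate with distance
#'   from the nearest TSS; `Inf` switches the decay off.
#' @param enhancer_boost Multiplicative boost (>= 0) of the control rate in
#'   enhancer bins.
#' @param treatment_fold Treatment multiplier f applied to the treated rate in
#'   regulatory bins (TSS-proximal and enhancer); the treated/control rate
#'   multiplier is `1 + (f - 1) * max(exp(-d/tau) * act, enh)` where `act`
#'   (mean 1 over genes) is the nearest gene's relative expression level,
#'   emulating transcription-coupled DSB accumulation at active genes.
#' @param activity_coupling Weight in [0, 1] of the expression coupling in
#'   `act`; 0 makes the treatment effect expression-independent.
#' @param overdispersion Optional negative-binomial size; `Inf` (default)
#'   gives Poisson counts.
#' @param loop_n Number of loops per condition.
#' @param busy_fraction Fraction of loops anchored at shared hub anchors
#'   (which therefore recur >= 2 times, i.e. are busy).
#' @param p_diff_busy,p_diff_normal Probability that a busy-anchored /
#'   normal-anchored loop is planted differential.
#' @param loop_resolution Loop anchor resolution in bp (10 kb).
#' @param dsb_coloc Probability that a planted differential loop's free
#'   anchor is drawn from the top-decile DSB-ratio bins.
#' @param min_loop_sep,max_loop_sep Anchor separation range in loop bins.
#' @param contact_depth Expected total read count of a contact matrix.
#' @param decay_exponent Power-law exponent of contact distance decay.
#' @param peak_factor Multiplicative enrichment at planted loop pixels.
#' @param expr_meanlog,expr_sdlog Lognormal baseline FPKM parameters.
#' @param expr_noise_sd Per-condition multiplicative noise, sd on log2 scale.
#' @param loop_effect log2 fold change applied in the treated condition to
#'   genes whose TSS lies in a gained (+) or lost (-) differential anchor.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 1e7,
                       n_genes = 300L,
                       n_enhancers = 200L,
                       bin_width = 5000L,
                       base_rate = 20,
                       floor_rate = 2,
                       tss_decay = 50000,
                       enhancer_boost = 1,
                       treatment_fold = 5,
                       activity_coupling = 1,
                       overdispersion = Inf,
                       loop_n = 400L,
                       busy_fraction = 0.3,
                       p_diff_busy = 0.4,
                       p_diff_normal = 0.1,
                       loop_resolution = 10000L,
                       dsb_coloc = 0.8,
                       min_loop_sep = 35L,
                       max_loop_sep = 250L,
                       contact_depth = 2e6,
                       decay_exponent = 1,
                       peak_factor = 3,
                       expr_meanlog = 1,
                       expr_sdlog = 1,
                       expr_noise_sd = 0.25,
                       loop_effect = 1) {
  p <- as.list(environment())
  rates <- c("base_rate", "floor_rate", "contact_depth")
  for (nm in rates) {
    if (p[[nm]] < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  for (nm in c("p_diff_busy", "p_diff_normal", "busy_fraction", "dsb_coloc",
               "activity_coupling")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop("`", nm, "` must be in [0, 1]", call. = FALSE)
  }
  for (nm in c("n_chrom", "chrom_len", "bin_width", "loop_resolution", "loop_n")) {
    if (p[[nm]] <= 0) stop("`", nm, "` must be positive", call. = FALSE)
  }
  if (p$treatment_fold < 1 - 1e-12) stop("`treatment_fold` must be >= 1", call. = FALSE)
  if (p$min_loop_sep >= p$max_loop_sep) {
    stop("`min_loop_sep` must be below `max_loop_sep`", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

# Named substream seed derived from the master seed; keeps every stage
# reproducible in isolation. Always < 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

#' Generate a synthetic annotated genome
#'
#' Places genes uniformly (distinct TSSs, gene bodies inside the
#' chromosome), gives each TSS a 1 kb active-promoter (TssA) segment,
#' scatters `n_enhancers` 1 kb EnhA1/EnhA2 segments in non-promoter space,
#' labels the remainder Quies/low so chromatin states partition each
#' chromosome, and draws repeat intervals for four subtypes. Baseline
#' expression (lognormal) is drawn here so DSB rates can couple to
#' expression rank.
#'
#' @param params A [sim_params()] object.
#' @return List with `binning` ([make_bins()] result), `genes`, `states`,
#'   `repeats`, `chrom_sizes` and the `params` used.
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  chrom_sizes <- stats::setNames(rep(params$chrom_len, params$n_chrom),
                                 paste0("chr", seq_len(params$n_chrom)))
  margin <- 60000
  if (params$n_genes * 6000 + params$n_enhancers * 2000 > 0.5 * sum(chrom_sizes)) {
    stop("placement too dense for the requested genome size", call. = FALSE)
  }
  with_substream(params$seed, "genome", {
    n <- params$n_genes
    genes <- if (n > 0) {
      chrom <- sample(names(chrom_sizes), n, replace = TRUE)
      tss <- numeric(n)
      for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        # distinct TSS positions on a 100 bp lattice, away from chromosome ends
        cand <- sample(seq(margin, chrom_sizes[[ch]] - margin, by = 100), length(idx))
        tss[idx] <- sort(cand)
      }
      strand <- sample(c("+", "-"), n, replace = TRUE)
      len <- sample(seq(2000, 50000, by = 100), n, replace = TRUE)
      baseline <- stats::rlnorm(n, meanlog = params$expr_meanlog, sdlog = params$expr_sdlog)
      g <- tibble::tibble(
        gene_id = sprintf("gene_%04d", seq_len(n)),
        chrom = chrom,
        start = ifelse(strand == "+", tss, tss - len + 1),
        end = ifelse(strand == "+", tss + len, tss + 1),
        strand = strand,
        tss = tss,
        baseline_fpkm = baseline
      )
      # relative expression level (mean 1, clamped) driving the
      # transcription-coupled DSB boost
      act <- pmin(g$baseline_fpkm / mean(g$baseline_fpkm), 10)
      g$activity <- act / mean(act)
      g[order(g$chrom, g$start), ]
    } else {
      tibble::tibble(gene_id = character(), chrom = character(), start = numeric(),
                     end = numeric(), strand = character(), tss = numeric(),
                     baseline_fpkm = numeric(), activity = numeric())
    }

    tssa <- if (nrow(genes) > 0) {
      seg <- tibble::tibble(chrom = genes$chrom,
                            start = pmax(0, genes$tss - 500),
                            end = pmin(genes$tss + 500, chrom_sizes[genes$chrom]),
                            state = "TssA")
      reduce_segments(seg, "TssA")
    } else {
      tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                     state = character())
    }

    enh <- place_enhancers(params$n_enhancers, chrom_sizes, genes)

    states <- fill_quies(dplyr::bind_rows(tssa, enh), chrom_sizes)

    repeats <- dplyr::bind_rows(lapply(
      c("L1", "L2", "B1_SINE", "Low_complexity"),
      function(sub) {
        m <- 300
        ch <- sample(names(chrom_sizes), m, replace = TRUE)
        st <- floor(stats::runif(m, 0, chrom_sizes[ch] - 2000))
        w <- sample(seq(200, 2000, by = 50), m, replace = TRUE)
        tibble::tibble(chrom = ch, start = st, end = st + w, subtype = sub)
      }
    ))
    repeats <- repeats[order(repeats$chrom, repeats$start), ]

    list(binning = make_bins(chrom_sizes, params$bin_width),
         genes = genes, states = states, repeats = repeats,
         chrom_sizes = chrom_sizes, params = params)
  })
}

# merge overlapping same-state segments into a flat set
reduce_segments <- function(seg, state) {
  if (nrow(seg) == 0) return(seg)
  gr <- GenomicRanges::reduce(as_granges0(seg))
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = GenomicRanges::end(gr),
                 state = state)
}

place_enhancers <- function(n_enh, chrom_sizes, genes) {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), state = character())
  if (n_enh == 0) return(empty)
  cand_n <- n_enh * 8
  ch <- sample(names(chrom_sizes), cand_n, replace = TRUE)
  st <- floor(stats::runif(cand_n, 0, chrom_sizes[ch] - 1000) / 100) * 100
  cand <- tibble::tibble(chrom = ch, start = st, end = st + 1000)
  # keep candidates outside promoter space (2.5 kb of any TSS)
  if (nrow(genes) > 0) {
    ok <- rep(TRUE, cand_n)
    for (c2 in unique(cand$chrom)) {
      tss <- sort(genes$tss[genes$chrom == c2])
      idx <- which(cand$chrom == c2)
      if (length(tss) == 0) next
      mid <- cand$start[idx] + 500
      j <- findInterval(mid, tss)
      d_lo <- ifelse(j >= 1, mid - tss[pmax(j, 1)], Inf)
      d_hi <- ifelse(j < length(tss), tss[pmin(j + 1, length(tss))] - mid, Inf)
      ok[idx] <- pmin(d_lo, d_hi) > 2500
    }
    cand <- cand[ok, ]
  }
  # greedy non-overlapping selection in genomic order, then subsample
  cand <- cand[order(cand$chrom, cand$start), ]
  keep <- logical(nrow(cand))
  last_end <- -Inf; last_chrom <- ""
  for (i in seq_len(nrow(cand))) {
    if (cand$chrom[i] != last_chrom || cand$start[i] >= last_end) {
      keep[i] <- TRUE
      last_chrom <- cand$chrom[i]; last_end <- cand$end[i]
    }
  }
  cand <- cand[keep, ]
  if (nrow(cand) < n_enh) stop("enhancer placement too dense", call. = FALSE)
  sel <- sort(sample(nrow(cand), n_enh))
  out <- cand[sel, ]
  out$state <- sample(c("EnhA1", "EnhA2"), n_enh, replace = TRUE)
  out
}

# fill gaps between labeled segments with Quies/low so states partition
fill_quies <- function(seg, chrom_sizes) {
  pieces <- lapply(names(chrom_sizes), function(ch) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    len <- chrom_sizes[[ch]]
    gaps_start <- c(0, s$end)
    gaps_end <- c(s$start, len)
    gaps <- tibble::tibble(chrom = ch, start = gaps_start, end = gaps_end,
                           state = "Quies/low")
    gaps <- gaps[gaps$end > gaps$start, ]
    dplyr::bind_rows(s, gaps)
  })
  out <- dplyr::bind_rows(pieces)
  out[order(out$chrom, out$start), ]
}

# nearest TSS distance and nearest gene index for a set of positions
nearest_tss_info <- function(chrom, pos, genes) {
  dist <- rep(NA_real_, length(pos))
  gidx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    gi <- which(genes$chrom == ch)
    ri <- which(chrom == ch)
    if (length(gi) == 0) next
    ord <- gi[order(genes$tss[gi])]
    tss <- genes$tss[ord]
    j <- findInterval(pos[ri], tss)
    d_lo <- ifelse(j >= 1, pos[ri] - tss[pmax(j, 1)], Inf)
    d_hi <- ifelse(j < length(tss), tss[pmin(j + 1, length(tss))] - pos[ri], Inf)
    use_lo <- d_lo <= d_hi
    dist[ri] <- pmin(d_lo, d_hi)
    gidx[ri] <- ifelse(use_lo, ord[pmax(j, 1)], ord[pmin(j + 1, length(tss))])
  }
  list(dist = dist, gene = gidx)
}

#' Generate DSB counts for control and treated conditions
#'
#' Control rate per 5 kb bin: `base_rate * (1 + enhancer_boost * enh) *
#' exp(-d/tss_decay) + floor_rate`, with `d` the distance from the bin's
#' median nucleotide to the nearest TSS. The treated rate multiplies this by
#' `1 + (treatment_fold - 1) * max(exp(-d/tss_decay) * act, enh)` where
#' `act` (mean 1) is the nearest gene's relative expression level: the
#' treatment effect is strongest at active promoters and enhancers and
#' decays into intergenic space, which is the structure the downstream
#' ratio, class and distance analyses assume. Counts are Poisson (or
#' negative binomial when `overdispersion` is finite).
#'
#' @param annotation Output of [simulate_genome()].
#' @param params A [sim_params()] object (defaults to the annotation's).
#' @return List with `control` and `treated` count tracks (tibbles with
#'   `chrom`, `start`, `end`, `bin`, `count`) and a `truth` tibble holding
#'   the per-bin rates, multiplier, TSS distance and regulatory indicators.
#' @export
simulate_dsb_counts <- function(annotation, params = annotation$params) {
  bins <- annotation$binning
  genes <- annotation$genes
  mid <- median_nucleotide(bins$start, bins$end)
  if (nrow(genes) > 0) {
    nt <- nearest_tss_info(bins$chrom, mid, genes)
    d <- nt$dist
    act_gene <- genes$activity[nt$gene]
  } else {
    d <- rep(Inf, nrow(bins))
    act_gene <- rep(0.5, nrow(bins))
  }
  enh_states <- annotation$states[annotation$states$state %in% c("EnhA1", "EnhA2"), ]
  tssa_states <- annotation$states[annotation$states$state == "TssA", ]
  enh <- rep(0, nrow(bins))
  if (nrow(enh_states) > 0) enh[unique(overlap_pairs(bins, enh_states)$qi)] <- 1
  tssa <- rep(FALSE, nrow(bins))
  if (nrow(tssa_states) > 0) tssa[unique(overlap_pairs(bins, tssa_states)$qi)] <- TRUE

  w <- if (is.finite(params$tss_decay)) exp(-d / params$tss_decay) else rep(1, nrow(bins))
  w[is.na(w)] <- 0
  # transcription-coupled modulation acts at the promoter itself (Pol II
  # stalling); away from TssA bins the treatment effect follows pure decay
  act <- (1 - params$activity_coupling) + params$activity_coupling * act_gene
  act[is.na(act) | !tssa] <- 1
  rate_control <- params$base_rate * (1 + params$enhancer_boost * enh) * w + params$floor_rate
  multiplier <- 1 + (params$treatment_fold - 1) * pmax(w * act, enh)
  rate_treated <- rate_control * multiplier

  draw <- function(rate) {
    if (is.finite(params$overdispersion)) {
      stats::rnbinom(length(rate), size = params$overdispersion, mu = rate)
    } else {
      stats::rpois(length(rate), rate)
    }
  }
  with_substream(params$seed, "dsb", {
    control <- draw(rate_control)
    treated <- draw(rate_treated)
    track <- function(count) {
      out <- tibble::as_tibble(bins)
      out$count <- count
      out
    }
    list(
      control = track(control),
      treated = track(treated),
      truth = tibble::tibble(
        bin = bins$bin, chrom = bins$chrom, start = bins$start, end = bins$end,
        rate_control = rate_control, rate_treated = rate_treated,
        multiplier = multiplier, tss_dist = d, enh = enh == 1, tssa = tssa
      )
    )
  })
}

#' Generate two-condition probability-scored loop lists
#'
#' Anchors are drawn on the loop-resolution grid. A `busy_fraction` of loops
#' share hub anchors (so those anchors recur at least twice). Each loop is
#' planted differential with probability `p_diff_busy` (hub-anchored) or
#' `p_diff_normal` (otherwise); differential loops get a probability above
#' 0.95 in one condition and below 0.8 in the other, all remaining loops sit
#' above 0.95 in both. Differential loops' free anchors are preferentially
#' relocated into top-decile DSB-multiplier bins (probability `dsb_coloc`),
#' planting the DSB--anchor colocalization.
#'
#' @param annotation Output of [simulate_genome()].
#' @param dsb Output of [simulate_dsb_counts()] (its `truth` drives hotspot
#'   placement); may be `NULL`, which disables colocalization.
#' @param params A [sim_params()] object.
#' @return List with `control` and `treated` loop tibbles (all loops with
#'   that condition's probability) and `truth` (planted flags per loop plus
#'   the differential anchor set).
#' @export
simulate_loops <- function(annotation, dsb = NULL, params = annotation$params) {
  res <- params$loop_resolution
  chrom_sizes <- annotation$chrom_sizes
  nb <- floor(chrom_sizes / res)
  n <- params$loop_n
  if (n > sum(nb * (params$max_loop_sep - params$min_loop_sep + 1)) / 2) {
    stop("`loop_n` exceeds the available anchor pairs", call. = FALSE)
  }

  hot <- NULL
  if (!is.null(dsb)) {
    tr <- dsb$truth
    lb <- tibble::tibble(chrom = tr$chrom, lbin = tr$start %/% res, m = tr$multiplier)
    lb <- dplyr::summarise(dplyr::group_by(lb, chrom, lbin), m = max(m), .groups = "drop")
    cut <- stats::quantile(lb$m, 0.9, names = FALSE)
    hot <- lb[lb$m >= cut, c("chrom", "lbin")]
  }

  with_substream(params$seed, "loops", {
    n_busy <- round(params$busy_fraction * n)
    n_hub <- max(1L, ceiling(n_busy / 3))
    universe_chrom <- rep(names(nb), nb)
    universe_bin <- unlist(lapply(nb, function(m) 0:(m - 1)), use.names = FALSE)
    nu <- length(universe_bin)
    if (2 * n > nu) stop("`loop_n` exceeds the available anchor pairs", call. = FALSE)

    # hub anchors are reused (busy); every other endpoint is a fresh bin,
    # so busy status is exactly the planted hub structure
    hub_idx <- sample.int(nu, n_hub)
    hub_chrom <- universe_chrom[hub_idx]
    hub_bin <- universe_bin[hub_idx]
    used <- paste(hub_chrom, hub_bin)

    is_busy <- seq_len(n) <= n_busy
    ch <- character(n); a <- numeric(n)
    if (n_busy > 0) {
      hub_id <- sample.int(n_hub, n_busy, replace = TRUE)
      ch[is_busy] <- hub_chrom[hub_id]
      a[is_busy] <- hub_bin[hub_id]
    }
    if (n_busy < n) {
      sel <- sample(setdiff(seq_len(nu), hub_idx), n - n_busy)
      ch[!is_busy] <- universe_chrom[sel]
      a[!is_busy] <- universe_bin[sel]
      used <- c(used, paste(ch[!is_busy], a[!is_busy]))
    }

    b <- rep(NA_real_, n)
    todo <- seq_len(n)
    for (it in 1:200) {
      if (length(todo) == 0) break
      sep <- sample(params$min_loop_sep:params$max_loop_sep, length(todo),
                    replace = TRUE)
      sgn <- sample(c(-1, 1), length(todo), replace = TRUE)
      cand <- a[todo] + sgn * sep
      key <- paste(ch[todo], cand)
      ok <- cand >= 0 & cand < nb[ch[todo]] & !(key %in% used) & !duplicated(key)
      b[todo[ok]] <- cand[ok]
      used <- c(used, key[ok])
      todo <- todo[!ok]
    }
    if (length(todo) > 0) {
      stop("`loop_n` exceeds the available anchor pairs", call. = FALSE)
    }
    loops <- tibble::tibble(chrom = ch, a = a, b = b, hub = is_busy)

    p_diff <- ifelse(loops$hub, params$p_diff_busy, params$p_diff_normal)
    loops$is_diff <- stats::runif(n) < p_diff
    loops$direction <- ifelse(loops$is_diff,
                              sample(c("gained", "lost"), n, replace = TRUE),
                              NA_character_)

    # colocalize differential loops' free anchors with DSB hotspots,
    # keeping every relocated endpoint a fresh bin
    if (!is.null(hot) && nrow(hot) > 0 && params$dsb_coloc > 0) {
      for (k in which(loops$is_diff)) {
        if (stats::runif(1) > params$dsb_coloc) next
        ch_k <- loops$chrom[k]
        anchor_fixed <- loops$a[k]
        cand <- hot$lbin[hot$chrom == ch_k &
                           abs(hot$lbin - anchor_fixed) >= params$min_loop_sep &
                           abs(hot$lbin - anchor_fixed) <= params$max_loop_sep]
        cand <- cand[!(paste(ch_k, cand) %in% used)]
        if (length(cand) == 0) next
        newb <- cand[sample.int(length(cand), 1)]
        used <- c(used, paste(ch_k, newb))
        loops$b[k] <- newb
      }
    }

    lo <- pmin(loops$a, loops$b) * res
    hi <- pmax(loops$a, loops$b) * res
    u <- function(m, lo_, hi_) stats::runif(m, lo_, hi_)
    p_t <- ifelse(loops$is_diff,
                  ifelse(loops$direction == "gained", u(n, 0.95, 1), u(n, 0, 0.8)),
                  u(n, 0.95, 1))
    p_c <- ifelse(loops$is_diff,
                  ifelse(loops$direction == "gained", u(n, 0, 0.8), u(n, 0.95, 1)),
                  u(n, 0.95, 1))

    base <- tibble::tibble(chrom = loops$chrom, start1 = lo, start2 = hi)
    control <- new_loopset(dplyr::mutate(base, probability = p_c), res, "control")
    treated <- new_loopset(dplyr::mutate(base, probability = p_t), res, "treated")

    diff_anchors <- tibble::tibble(
      chrom = rep(loops$chrom[loops$is_diff], 2),
      start = c(lo[loops$is_diff], hi[loops$is_diff]),
      direction = rep(loops$direction[loops$is_diff], 2)
    )
    diff_anchors$end <- diff_anchors$start + res
    diff_anchors <- dplyr::distinct(diff_anchors, chrom, start, end, direction)

    list(control = control, treated = treated,
         truth = list(
           loops = tibble::tibble(
             chrom = loops$chrom, start1 = lo, start2 = hi,
             busy_planned = loops$hub, is_diff = loops$is_diff,
             direction = loops$direction, p_control = p_c, p_treated = p_t
           ),
           diff_anchors = diff_anchors[order(diff_anchors$chrom, diff_anchors$start), ],
           hubs = tibble::tibble(chrom = hub_chrom, start = hub_bin * res,
                                 end = hub_bin * res + res)
         ))
  })
}

#' Generate a sparse contact matrix with planted loop peaks
#'
#' Expected count for a bin pair at separation `d` is `c / (d^alpha + 1)`
#' with `c` set so the matrix totals `contact_depth` reads in expectation,
#' multiplied by `peak_factor` at the pixels of the supplied loops; counts
#' are Poisson sampled and stored as the upper triangle (`bin_i <= bin_j`)
#' of a symmetric matrix.
#'
#' @param loops Loop tibble whose pixels receive the peak factor (pass the
#'   condition's high-probability loops).
#' @param chrom_sizes Named chromosome lengths.
#' @param params A [sim_params()] object.
#' @param stream Substream name so different conditions get independent draws.
#' @return A `contact_matrix` tibble (`chrom`, `bin_i`, `bin_j`, `count`)
#'   with `resolution` and `n_bins` attributes.
#' @export
simulate_contacts <- function(loops, chrom_sizes, params, stream = "contacts") {
  res <- params$loop_resolution
  nb <- stats::setNames(as.integer(floor(chrom_sizes / res)), names(chrom_sizes))
  alpha <- params$decay_exponent
  total_weight <- sum(vapply(nb, function(m) {
    d <- 0:(m - 1)
    sum((m - d) / (d^alpha + 1))
  }, numeric(1)))
  c_scale <- params$contact_depth / total_weight

  with_substream(params$seed, stream, {
    out <- lapply(names(nb), function(ch) {
      m <- nb[[ch]]
      # build (i, j) for all pairs i <= j via diagonal enumeration
      i <- unlist(lapply(0:(m - 1), function(dd) 0:(m - 1 - dd)), use.names = FALSE)
      dd <- rep.int(0:(m - 1), m:1)
      j <- i + dd
      mu <- c_scale / (dd^alpha + 1)
      lp <- loops[loops$chrom == ch, , drop = FALSE]
      if (nrow(lp) > 0) {
        key <- paste(pmin(lp$start1, lp$start2) %/% res,
                     pmax(lp$start1, lp$start2) %/% res)
        hit <- paste(i, j) %in% key
        mu[hit] <- mu[hit] * params$peak_factor
      }
      cnt <- stats::rpois(length(mu), mu)
      keep <- cnt > 0
      tibble::tibble(chrom = ch, bin_i = i[keep], bin_j = j[keep],
                     count = as.numeric(cnt[keep]))
    })
    structure(dplyr::bind_rows(out), resolution = as.integer(res), n_bins = nb,
              class = c("contact_matrix", class(tibble::tibble())))
  })
}

#' Generate two-condition expression with planted loop effects
#'
#' Baseline FPKM comes from the annotation's lognormal draw; genes whose TSS
#' falls in a gained differential anchor receive `+loop_effect` log2 fold in
#' the treated condition, genes in lost anchors `-loop_effect`, with
#' multiplicative lognormal noise on both conditions. The DEG flag marks
#' exactly the genes carrying a planted effect.
#'
#' @param annotation Output of [simulate_genome()].
#' @param loop_truth `truth` component of [simulate_loops()].
#' @param params A [sim_params()] object.
#' @return Gene tibble with `fpkm_control`, `fpkm_treated`, `planted_log2fc`
#'   and `is_deg` columns.
#' @export
simulate_expression <- function(annotation, loop_truth, params = annotation$params) {
  genes <- annotation$genes
  effect <- rep(0, nrow(genes))
  da <- loop_truth$diff_anchors
  if (!is.null(da) && nrow(da) > 0 && nrow(genes) > 0) {
    tsspts <- tibble::tibble(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1)
    hits <- overlap_pairs(tsspts, da)
    if (nrow(hits) > 0) {
      sgn <- ifelse(da$direction[hits$si] == "gained", 1, -1)
      for (r in seq_len(nrow(hits))) {
        effect[hits$qi[r]] <- effect[hits$qi[r]] + sgn[r]
      }
      effect <- sign(effect)  # net direction; opposing anchors cancel
    }
  }
  with_substream(params$seed, "expression", {
    noise_c <- stats::rnorm(nrow(genes), 0, params$expr_noise_sd)
    noise_t <- stats::rnorm(nrow(genes), 0, params$expr_noise_sd)
    genes$fpkm_control <- genes$baseline_fpkm * 2^noise_c
    genes$fpkm_treated <- genes$baseline_fpkm *
      2^(effect * params$loop_effect + noise_t)
    genes$planted_log2fc <- effect * params$loop_effect
    genes$is_deg <- effect != 0 & params$loop_effect != 0
    genes
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper running genome, DSB, loop, contact and expression
#' stages in order under one master seed.
#'
#' @param params A [sim_params()] object.
#' @param contacts Which condition matrices to generate: any of "control",
#'   "treated"; `character(0)` skips matrix generation.
#' @return List with `annotation`, `dsb`, `loops`, `contacts` (named list),
#'   `genes` (expression table) and `params`.
#' @export
simulate_dataset <- function(params = sim_params(),
                             contacts = c("control", "treated")) {
  annotation <- simulate_genome(params)
  dsb <- simulate_dsb_counts(annotation, params)
  loops <- simulate_loops(annotation, dsb, params)
  mats <- list()
  for (cond in contacts) {
    present <- loops[[cond]]
    present <- present[present$probability > 0.95, , drop = FALSE]
    mats[[cond]] <- simulate_contacts(present, annotation$chrom_sizes, params,
                                      stream = paste0("contacts:", cond))
  }
  genes <- simulate_expression(annotation, loops$truth, params)
  list(annotation = annotation, dsb = dsb, loops = loops,
       contacts = mats, genes = genes, params = params)
}
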