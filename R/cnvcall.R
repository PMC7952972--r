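#' Caller configuration
#'
#' Thresholds for QC, normalization, segmentation and copy-number calling.
#' The mosaic floor of 0.4 encodes the clinical rule that an embryo with a
#' mosaic rate above 40% is indicated as mosaic aneuploidy and not fit for
#' transfer; 0.8 is the symmetric complement separating "mosaic" from a full
#' integer call. The mosaic fraction of a segment is |c - expected| with
#' c = 2 x mean ratio, clipped to [0, 1].
#'
#' @param min_reads_per_bin QC: minimum mean usable reads per bin.
#' @param max_mapd QC: maximum MAPD (median absolute pairwise difference of
#'   neighbouring autosomal bin ratios).
#' @param min_panel Minimum number of reference samples.
#' @param mask_min_factor Reference-panel factor below which a bin is masked.
#' @param max_masked_frac Maximum tolerated masked-bin fraction at
#'   normalization.
#' @param gc_stratum Width of GC strata for residual GC correction.
#' @param min_stratum_bins Minimum diploid reference bins (from other
#'   chromosomes) a stratum needs before its correction factor is applied;
#'   sparser strata are left uncorrected rather than divided by a noisy
#'   median.
#' @param seg_threshold Segmentation acceptance threshold on the two-sided
#'   mean-shift statistic.
#' @param min_split_delta Minimum mean-ratio shift for accepting a split.
#' @param merge_delta Adjacent segments closer than this in mean ratio are
#'   merged.
#' @param min_seg_bins Minimum reported event size in bins (1-bin events are
#'   reported when the amplitude reaches `big_amp`).
#' @param big_amp Amplitude (|c - expected|) overriding `min_seg_bins`.
#' @param mosaic_floor,full_floor Mosaic and full-aneuploidy call floors on
#'   |c - expected|.
#' @param whole_chrom_frac Fraction of a chromosome's bins a segment must
#'   cover to be flagged whole-chromosome.
#' @param sd_floor Lower bound on the noise scale used by the segmentation
#'   statistic (guards noiseless input).
#' @return A `caller_config` object.
#' @export
caller_config <- function(min_reads_per_bin = 100, max_mapd = 0.35,
                          min_panel = 3, mask_min_factor = 0.1,
                          max_masked_frac = 0.2, gc_stratum = 0.02,
                          min_stratum_bins = 30,
                          seg_threshold = 5, min_split_delta = 0.1,
                          merge_delta = 0.1, min_seg_bins = 3, big_amp = 0.8,
                          mosaic_floor = 0.4, full_floor = 0.8,
                          whole_chrom_frac = 0.9, sd_floor = 0.01) {
  structure(as.list(environment()), class = "caller_config")
}

autosomal <- function(grid) !(grid$bins$chrom %in% c("X", "Y"))

#' Assess sample quality
#'
#' A sample is informative iff it has enough usable reads and its noise
#' metric (MAPD of neighbouring autosomal bin ratios) is below the
#' threshold. Deterministic.
#'
#' @param counts A `bin_counts`.
#' @param grid The `bin_grid` the counts are aligned to.
#' @param cfg A `caller_config`.
#' @return A `qc_result`: informative flag, `mapd`, `usable_reads`, reasons.
#' @export
qc_assess <- function(counts, grid, cfg = caller_config()) {
  stopifnot(inherits(counts, "bin_counts"), inherits(grid, "bin_grid"))
  if (length(counts$counts) != nrow(grid$bins))
    stop("bin count length does not match grid")
  auto <- autosomal(grid)
  usable <- counts$total_reads
  reasons <- character(0)
  med <- stats::median(counts$counts[auto])
  if (usable < cfg$min_reads_per_bin * nrow(grid$bins)) reasons <- c(reasons, "reads")
  if (med <= 0) {
    mapd <- Inf
    if (!"reads" %in% reasons) reasons <- c(reasons, "reads")
  } else {
    r <- counts$counts / med
    d <- unlist(lapply(unique(grid$bins$chrom[auto]), function(ch) {
      abs(diff(r[grid$bins$chrom == ch]))
    }))
    mapd <- stats::median(d)
    if (mapd > cfg$max_mapd) reasons <- c(reasons, "noise")
  }
  structure(list(informative = length(reasons) == 0, mapd = mapd,
                 usable_reads = usable, reasons = reasons),
            class = "qc_result")
}

#' Build a reference panel from euploid samples
#'
#' Per-bin factor = median across samples of (bin count / sample autosomal
#' median), rescaled to autosomal median 1; bins with factor below
#' `mask_min_factor` (or non-finite) are masked. The factor absorbs the
#' GC-dependent amplification bias shared across samples.
#'
#' @param normals List of informative euploid `bin_counts`.
#' @param grid A `bin_grid`.
#' @param cfg A `caller_config`.
#' @return A `reference_panel`: `factor`, logical `mask`, `n_samples`.
#' @export
build_reference <- function(normals, grid, cfg = caller_config()) {
  if (length(normals) < cfg$min_panel)
    stop("reference panel needs at least ", cfg$min_panel, " samples")
  auto <- autosomal(grid)
  mat <- vapply(normals, function(s) {
    stopifnot(inherits(s, "bin_counts"))
    if (length(s$counts) != nrow(grid$bins)) stop("panel sample not on grid")
    s$counts / stats::median(s$counts[auto])
  }, numeric(nrow(grid$bins)))
  factor <- apply(mat, 1, stats::median)
  factor <- factor / stats::median(factor[auto])
  mask <- !is.finite(factor) | factor < cfg$mask_min_factor
  factor[mask] <- NA_real_
  structure(list(factor = factor, mask = mask, n_samples = length(normals)),
            class = "reference_panel")
}

#' Normalize a sample against the reference panel
#'
#' ratio = (count / sample autosomal median) / panel factor, followed by a
#' residual GC correction (each bin divided by the median ratio of its GC
#' stratum) and a final rescale so the autosomal median ratio is 1. A ratio
#' of 1.0 corresponds to two copies: a gain from two to three copies gives a
#' 50% increase, a loss to one copy a 50% decrease. Sex is inferred from the
#' X and Y median raw ratios before any X/Y expectation is applied.
#'
#' @param counts A `bin_counts`.
#' @param panel A `reference_panel`.
#' @param grid A `bin_grid`.
#' @param cfg A `caller_config`.
#' @param qc Optional `qc_result`; non-informative samples error unless
#'   `force = TRUE`.
#' @param force Normalize even if QC failed.
#' @return A `normalized_profile`: per-bin `ratio` (NA where masked),
#'   `mask`, inferred `sex`, `x_ratio`, `y_ratio`, `sample_id`.
#' @export
normalize_counts <- function(counts, panel, grid, cfg = caller_config(),
                             qc = NULL, force = FALSE) {
  stopifnot(inherits(counts, "bin_counts"), inherits(panel, "reference_panel"))
  if (!is.null(qc) && !qc$informative && !force)
    stop("sample ", counts$sample_id, " is not informative (",
         paste(qc$reasons, collapse = ","), "); use force = TRUE to override")
  if (length(counts$counts) != nrow(grid$bins))
    stop("bin count length does not match grid")
  auto <- autosomal(grid)
  # diploid baseline as the median of per-autosome medians: robust to a
  # whole-chromosome aneuploidy even when that chromosome is a large share
  # of the genome (reduced grids)
  cmed <- vapply(unique(grid$bins$chrom[auto]), function(ch) {
    stats::median(counts$counts[grid$bins$chrom == ch])
  }, 0)
  med <- stats::median(cmed)
  if (med <= 0) stop("sample ", counts$sample_id, " has zero autosomal median")
  r0 <- counts$counts / med
  xb <- grid$bins$chrom == "X"; yb <- grid$bins$chrom == "Y"
  x_ratio <- if (any(xb)) stats::median(r0[xb]) else NA_real_
  y_ratio <- if (any(yb)) stats::median(r0[yb]) else NA_real_
  sex <- if (!any(xb)) NA_character_
         else if ((!is.na(y_ratio) && y_ratio > 0.25) || x_ratio < 0.75) "XY"
         else "XX"
  ratio <- r0 / panel$factor
  ratio[panel$mask] <- NA_real_
  # short zero-count runs (<= 2 bins) are MALBAC dropout at this depth: a
  # true homozygous loss of 1-2 Mb is below the detection floor at 0.04x,
  # while dropout pairs are common enough to masquerade as nullisomy
  zero <- counts$counts == 0 & !is.na(ratio)
  for (ch in unique(grid$bins$chrom)) {
    idx <- which(grid$bins$chrom == ch)
    z <- zero[idx]
    if (!any(z)) next
    r <- rle(z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths <= 2)) {
      ratio[idx[starts[k]:ends[k]]] <- NA_real_
    }
  }
  if (mean(is.na(ratio)) > cfg$max_masked_frac)
    stop("insufficient usable bins for ", counts$sample_id, ": ",
         round(100 * mean(is.na(ratio))), "% masked")
  # residual GC correction: stratified medians over diploid-looking
  # autosomal bins, so real copy-number signal is not absorbed into the
  # stratum factors; chromosomes that look aneuploid at the median level
  # are excluded wholesale (their bins would otherwise leak into the
  # reference through the bin-level window)
  cmed_r <- vapply(unique(grid$bins$chrom[auto]), function(ch) {
    stats::median(ratio[grid$bins$chrom == ch], na.rm = TRUE)
  }, 0)
  dip_ok_chrom <- names(cmed_r)[!is.na(cmed_r) & cmed_r > 0.85 & cmed_r < 1.15]
  diploidish <- grid$bins$chrom %in% dip_ok_chrom
  # leave-one-chromosome-out: a chromosome never contributes to its own
  # stratum factor, so diploid and aneuploid chromosomes are corrected
  # symmetrically
  stratum <- floor(grid$bins$gc / cfg$gc_stratum)
  ref_all <- auto & diploidish & !is.na(ratio) & ratio > 0.7 & ratio < 1.3
  corrfac <- rep(NA_real_, length(ratio))
  for (s in unique(stratum)) {
    sel <- stratum == s
    for (ch in unique(grid$bins$chrom[sel])) {
      ref <- sel & ref_all & grid$bins$chrom != ch
      if (sum(ref) >= cfg$min_stratum_bins) {
        msd <- stats::median(ratio[ref])
        if (is.finite(msd) && msd > 0)
          corrfac[sel & grid$bins$chrom == ch] <- msd
      }
    }
  }
  # mean-neutral: factors are relative to their own median, so the
  # correction rebalances strata without shifting the overall level (and is
  # an exact no-op on a bias-free profile)
  if (any(!is.na(corrfac))) {
    corrfac <- corrfac / stats::median(corrfac, na.rm = TRUE)
    ok <- !is.na(corrfac)
    ratio[ok] <- ratio[ok] / corrfac[ok]
  }
  # rescale to autosomal diploid level, two passes: a median-of-chromosome-
  # medians pilot flags aneuploid-looking chromosomes, then the unflagged
  # chromosome medians are averaged (the pilot median alone is biased when
  # one of few chromosomes is aneuploid: it picks the extreme of the rest)
  chrom_med <- vapply(unique(grid$bins$chrom[auto]), function(ch) {
    stats::median(ratio[grid$bins$chrom == ch], na.rm = TRUE)
  }, 0)
  pilot <- stats::median(chrom_med, na.rm = TRUE)
  keep <- !is.na(chrom_med) & chrom_med / pilot > 0.85 & chrom_med / pilot < 1.15
  scale <- if (any(keep)) mean(chrom_med[keep]) else pilot
  if (!is.finite(scale) || scale <= 0)
    stop("cannot establish diploid baseline for ", counts$sample_id)
  ratio <- ratio / scale
  structure(list(sample_id = counts$sample_id, ratio = ratio,
                 mask = is.na(ratio), sex = sex,
                 x_ratio = x_ratio, y_ratio = y_ratio),
            class = "normalized_profile")
}

# maximal two-sided mean-shift interval statistic: best sub-interval [i, j]
# of x against the rest of the segment, returned with its t value
best_interval <- function(x, s) {
  n <- length(x)
  if (n < 2) return(NULL)
  S0 <- c(0, cumsum(x))
  tot <- S0[n + 1]
  i <- rep(seq_len(n), times = n - seq_len(n) + 1)  # not used; build via outer
  sum_in <- outer(-S0[seq_len(n)], S0[-1], "+")     # (i, j): S[j] - S[i-1]
  n_in <- outer(-(seq_len(n) - 1), seq_len(n), "+") # j - i + 1
  valid <- n_in >= 1 & n_in < n
  n_in_c <- pmax(n_in, 1)
  n_out <- pmax(n - n_in, 1)
  mean_in <- sum_in / n_in_c
  mean_out <- (tot - sum_in) / n_out
  tstat <- abs(mean_in - mean_out) / (s * sqrt(1 / n_in_c + 1 / n_out))
  tstat[!valid] <- -Inf
  k <- arrayInd(which.max(tstat), dim(tstat))
  list(i = k[1], j = k[2], t = tstat[k[1], k[2]],
       delta = abs(mean_in[k[1], k[2]] - mean_out[k[1], k[2]]))
}

# single-bin upward outliers are MALBAC over-amplification spikes: a lone
# bin above both neighbours by several noise SDs is trimmed toward its
# local median before segmentation (losses are left untouched: zero runs
# are masked as dropout earlier and genuine 1-bin deletions stay callable)
trim_spikes <- function(x, cfg) {
  n <- length(x)
  if (n < 3) return(x)
  s <- max(stats::median(abs(diff(x))) / (sqrt(2) * 0.6745), cfg$sd_floor)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] + 3 * s && x[i] > x[i + 1] + 3 * s)
      x[i] <- max(x[i - 1], x[i + 1]) + 2 * s
  }
  x
}

segment_positions <- function(x, cfg) {
  # robust per-chromosome noise scale from neighbour differences
  s <- stats::median(abs(diff(x))) / (sqrt(2) * 0.6745)
  s <- max(s, cfg$sd_floor)
  bounds <- integer(0)
  recurse <- function(lo, hi) {
    if (hi - lo + 1 < 2) return(invisible())
    b <- best_interval(x[lo:hi], s)
    if (is.null(b) || b$t < cfg$seg_threshold || b$delta < cfg$min_split_delta)
      return(invisible())
    i <- lo + b$i - 1; j <- lo + b$j - 1
    bounds <<- c(bounds, i - 1, j)  # boundaries after position (0-based cuts)
    recurse(lo, i - 1)
    recurse(i, j)
    recurse(j + 1, hi)
  }
  recurse(1, length(x))
  sort(unique(bounds[bounds > 0 & bounds < length(x)]))
}

# boundary refinement: bins adjacent to a cut are reassigned to the segment
# whose mean is closer, so noisy flanking bins are not glued onto an event
refine_boundaries <- function(x, cuts) {
  if (length(cuts) == 0) return(cuts)
  for (iter in 1:10) {
    moved <- FALSE
    edges <- c(0, cuts, length(x))
    for (k in seq_along(cuts)) {
      cpos <- cuts[k]
      lo <- edges[k] + 1; hi <- edges[k + 2]
      nl <- cpos - lo + 1; nr <- hi - cpos
      if (nl > 1) {
        mL <- mean(x[lo:(cpos - 1)]); mR <- mean(x[(cpos + 1):hi])
        if (abs(x[cpos] - mR) < abs(x[cpos] - mL)) {
          cuts[k] <- cpos - 1; moved <- TRUE; edges <- c(0, cuts, length(x))
          next
        }
      }
      if (nr > 1) {
        mL <- mean(x[lo:cpos]); mR <- mean(x[(cpos + 2):hi])
        if (abs(x[cpos + 1] - mL) < abs(x[cpos + 1] - mR)) {
          cuts[k] <- cpos + 1; moved <- TRUE; edges <- c(0, cuts, length(x))
        }
      }
    }
    if (!moved) break
  }
  sort(unique(cuts))
}

merge_segments <- function(x, cuts, merge_delta) {
  repeat {
    edges <- c(0, cuts, length(x))
    if (length(cuts) == 0) break
    means <- vapply(seq_len(length(edges) - 1), function(k) {
      mean(x[(edges[k] + 1):edges[k + 1]])
    }, 0)
    d <- abs(diff(means))
    if (min(d) >= merge_delta) break
    cuts <- cuts[-which.min(d)]
  }
  cuts
}

#' Segment a normalized profile into constant-ratio pieces
#'
#' Per chromosome, recursive splitting that maximizes the two-sided
#' mean-shift statistic of a candidate interval against the rest of the
#' segment (so short interior events are found directly), accepting a split
#' when the statistic exceeds `seg_threshold`; adjacent segments closer than
#' `merge_delta` in mean ratio are re-merged. Masked bins are skipped.
#'
#' @param profile A `normalized_profile`.
#' @param grid A `bin_grid`.
#' @param cfg A `caller_config`.
#' @return data.frame of all segments: chrom, start, end, n_bins,
#'   mean_ratio.
#' @export
segment_profile <- function(profile, grid, cfg = caller_config()) {
  stopifnot(inherits(profile, "normalized_profile"))
  out <- list()
  for (ch in unique(grid$bins$chrom)) {
    idx <- which(grid$bins$chrom == ch & !profile$mask)
    if (length(idx) == 0) next
    x <- trim_spikes(profile$ratio[idx], cfg)
    cuts <- if (length(x) >= 2) segment_positions(x, cfg) else integer(0)
    cuts <- refine_boundaries(x, cuts)
    cuts <- merge_segments(x, cuts, cfg$merge_delta)
    edges <- c(0, cuts, length(x))
    for (k in seq_len(length(edges) - 1)) {
      sel <- idx[(edges[k] + 1):edges[k + 1]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = grid$bins$start[sel[1]],
        end = grid$bins$end[sel[length(sel)]],
        n_bins = length(sel), mean_ratio = mean(profile$ratio[sel]))
    }
  }
  do.call(rbind, out)
}

expected_copy <- function(chrom, sex) {
  if (!chrom %in% c("X", "Y")) return(2)
  if (is.na(sex)) return(2)
  if (sex == "XY") return(1)
  if (chrom == "X") return(2)
  NA_real_  # Y in XX: absence is not an event
}

#' Call integer copy number and mosaic fraction on segments
#'
#' Continuous copy number c = 2 x mean ratio (sex-adjusted expectation on
#' X/Y). |c - expected| >= 0.8 is a full aneuploidy (integer call round(c));
#' 0.4 < |c - expected| < 0.8 is a mosaic event with fraction
#' f = |c - expected|; below 0.4 no call. Segments shorter than
#' `min_seg_bins` are reported only at amplitude >= `big_amp`. A segment
#' covering at least 90% of its chromosome's usable bins is flagged
#' whole-chromosome.
#'
#' @param segments Segment table from [segment_profile()].
#' @param profile The `normalized_profile` the segments came from.
#' @param grid A `bin_grid`.
#' @param cfg A `caller_config`.
#' @param qc Optional `qc_result` carried into the call set.
#' @return An `embryo_callset`: sample id, sex call, QC, `calls` data.frame
#'   of abnormal segments, and per-chromosome status.
#' @export
call_segments <- function(segments, profile, grid, cfg = caller_config(),
                          qc = NULL) {
  sex <- profile$sex
  chrom_bins <- table(grid$bins$chrom[!profile$mask])
  calls <- list()
  if (!is.null(segments) && nrow(segments) > 0) {
    for (k in seq_len(nrow(segments))) {
      seg <- segments[k, ]
      exp_cp <- expected_copy(seg$chrom, sex)
      if (is.na(exp_cp)) next
      cc <- 2 * seg$mean_ratio
      delta <- cc - exp_cp
      f <- min(abs(delta), 1)
      # strict "> 40%" rule; epsilon guards the exact-boundary case against
      # floating-point residue from the normalization chain
      if (abs(delta) <= cfg$mosaic_floor + 1e-9) next
      if (seg$n_bins < cfg$min_seg_bins && abs(delta) < cfg$big_amp) next
      full <- abs(delta) >= cfg$full_floor - 1e-9
      call_int <- if (full) max(0L, as.integer(round(cc)))
                  else as.integer(exp_cp + sign(delta))
      calls[[length(calls) + 1]] <- data.frame(
        chrom = seg$chrom, start = seg$start, end = seg$end,
        n_bins = seg$n_bins, mean_ratio = seg$mean_ratio, cn = cc,
        call = call_int, f = f, mosaic = !full,
        direction = if (delta > 0) "gain" else "loss",
        whole_chromosome =
          seg$n_bins >= cfg$whole_chrom_frac * chrom_bins[[seg$chrom]],
        size_mb = (seg$end - seg$start) / 1e6)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else NULL
  status <- vapply(unique(grid$bins$chrom), function(ch) {
    if (is.null(calls) || !ch %in% calls$chrom) return("normal")
    cc <- calls[calls$chrom == ch, ]
    lab <- if (any(cc$direction == "gain") && any(cc$direction == "loss"))
      "complex" else cc$direction[1]
    if (all(cc$mosaic)) paste0("mosaic_", lab) else lab
  }, "")
  structure(list(sample_id = profile$sample_id, sex = sex, qc = qc,
                 informative = is.null(qc) || qc$informative,
                 calls = calls, chrom_status = status),
            class = "embryo_callset")
}

#' @export
print.embryo_callset <- function(x, ...) {
  n <- if (is.null(x$calls)) 0 else nrow(x$calls)
  cat("<embryo_callset> ", x$sample_id, " sex=", x$sex,
      if (!x$informative) " NOT-INFORMATIVE" else "",
      ": ", n, " abnormal segment(s)\n", sep = "")
  if (n > 0) print(x$calls[, c("chrom", "start", "end", "call", "f",
                               "mosaic", "whole_chromosome", "size_mb")])
  invisible(x)
}

#' Run QC, normalization, segmentation and calling for one sample
#'
#' @param counts A `bin_counts`.
#' @param panel A `reference_panel`.
#' @param grid A `bin_grid`.
#' @param cfg A `caller_config`.
#' @return An `embryo_callset`; non-informative samples return a callset
#'   with `informative = FALSE` and no calls.
#' @export
call_embryo <- function(counts, panel, grid, cfg = caller_config()) {
  qc <- qc_assess(counts, grid, cfg)
  if (!qc$informative) {
    return(structure(list(sample_id = counts$sample_id, sex = NA_character_,
                          qc = qc, informative = FALSE, calls = NULL,
                          chrom_status = NULL),
                     class = "embryo_callset"))
  }
  prof <- normalize_counts(counts, panel, grid, cfg, qc = qc)
  segs <- segment_profile(prof, grid, cfg)
  call_segments(segs, prof, grid, cfg, qc = qc)
}
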