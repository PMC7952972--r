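#' Simulation configuration for MALBAC-like low-pass blastomere counts
#'
#' Defaults emulate the study regime this package targets: ~3 million valid
#' single-end 55 bp reads per blastomere (~0.04x genome-wide depth) counted
#' in 1 Mb bins, GC-dependent amplification bias, negative-binomial
#' overdispersion with per-bin dropout, and a 5.7% whole-sample amplification
#' failure rate. Failure is emulated in-band (extreme dispersion plus heavy
#' dropout) so QC logic sees a chaotic profile rather than a missing file.
#'
#' @param reads Total reads per sample (default 3e6 on the full genome; use
#'   [scaled_reads()] for reduced grids).
#' @param read_length Read length in bp (metadata only).
#' @param target_depth Nominal genome-wide depth (metadata only).
#' @param gc_bias Coefficients `c(b1, b2)` of the multiplicative
#'   log-quadratic bias `exp(b1*g + b2*g^2)`, `g = gc - 0.40`.
#' @param overdispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha*mu^2); 0 gives Poisson counts.
#' @param dropout Per-bin zero-inflation probability (MALBAC locus dropout).
#' @param failure_prob Whole-sample amplification failure probability.
#' @param failure_dispersion,failure_dropout Noise parameters used for
#'   failed samples.
#' @param denovo_rate Poisson mean of de novo meiotic whole-chromosome
#'   aneuploidies per embryo.
#' @param denovo_weights Named per-chromosome sampling weights for de novo
#'   events (default peaks at chromosomes 22, 19, 21, 16).
#' @param chaos_prob Probability an embryo is chaotic (several additional
#'   aneuploidies; feeds multiple-aneuploidy embryos).
#' @param chaos_events Range (min, max) of extra events in chaotic embryos.
#' @param mosaic_prob Probability of one mitotic (mosaic) whole-chromosome
#'   event.
#' @param mosaic_fraction Range of the mosaic cell fraction (uniform draw).
#' @param noiseless If TRUE, counts are the exact expected values (no
#'   sampling, no dropout).
#' @return A `sim_config` object.
#' @export
sim_config <- function(reads = 3e6, read_length = 55, target_depth = 0.04,
                       gc_bias = c(-0.8, -8), overdispersion = 0.02,
                       dropout = 0.01, failure_prob = 0.057,
                       failure_dispersion = 5, failure_dropout = 0.5,
                       denovo_rate = 0.9, denovo_weights = NULL,
                       chaos_prob = 0.12, chaos_events = c(4, 8),
                       mosaic_prob = 0.2, mosaic_fraction = c(0.2, 1),
                       noiseless = FALSE) {
  stopifnot(reads > 0, overdispersion >= 0, dropout >= 0, dropout <= 1,
            failure_prob >= 0, failure_prob <= 1,
            mosaic_prob >= 0, mosaic_prob <= 1,
            all(mosaic_fraction > 0), all(mosaic_fraction <= 1))
  if (is.null(denovo_weights)) {
    denovo_weights <- stats::setNames(rep(1, 22), as.character(1:22))
    denovo_weights[c("22", "19", "21", "16")] <- c(4, 3.5, 3, 2.5)
  }
  structure(list(reads = reads, read_length = read_length,
                 target_depth = target_depth, gc_bias = gc_bias,
                 overdispersion = overdispersion, dropout = dropout,
                 failure_prob = failure_prob,
                 failure_dispersion = failure_dispersion,
                 failure_dropout = failure_dropout,
                 denovo_rate = denovo_rate, denovo_weights = denovo_weights,
                 chaos_prob = chaos_prob, chaos_events = chaos_events,
                 mosaic_prob = mosaic_prob, mosaic_fraction = mosaic_fraction,
                 noiseless = noiseless),
            class = "sim_config")
}

#' Scale the default read budget to a reduced bin grid
#'
#' Keeps reads-per-bin at the full-genome default level (~3e6 reads over
#' ~3100 one-megabase bins) when simulating on a reduced genome.
#'
#' @param grid A `bin_grid`.
#' @param reads_full Full-genome read budget.
#' @param full_bins Nominal full-genome bin count at 1 Mb.
#' @return Integer read count for the grid.
#' @export
scaled_reads <- function(grid, reads_full = 3e6, full_bins = 3100) {
  round(reads_full * nrow(grid$bins) / full_bins)
}

#' Tile a genome into fixed-size bins with synthetic GC content
#'
#' Bins tile each chromosome (last bin truncated at the chromosome end).
#' GC fractions come from a smooth spatially correlated model (an AR(1)
#' chain per chromosome, clipped to [0.30, 0.60]) unless supplied.
#'
#' @param m A `cytoband_map`.
#' @param bin_size Bin width in bp (>= 100 kb).
#' @param seed Seed for the GC model.
#' @param gc Optional numeric vector of per-bin GC fractions (recycled
#'   checks apply), or "model" to simulate.
#' @return A `bin_grid`: list with `bins` data.frame (chrom, start, end, gc)
#'   and `bin_size`.
#' @export
build_bin_grid <- function(m, bin_size = 1e6, seed = 1, gc = "model") {
  stopifnot(inherits(m, "cytoband_map"))
  if (bin_size < 1e5) stop("bin size below 100 kb is not supported")
  rows <- lapply(m$chroms, function(ch) {
    len <- m$chrom_lengths[[ch]]
    st <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = st, end = pmin(st + bin_size, len))
  })
  bins <- do.call(rbind, rows)
  if (identical(gc, "model")) {
    set.seed(seed)
    g <- numeric(nrow(bins))
    rho <- 0.98; sigma <- 0.04 * sqrt(1 - rho^2)
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      x <- numeric(length(idx))
      x[1] <- stats::rnorm(1, 0, 0.04)
      if (length(idx) > 1) {
        for (i in 2:length(idx)) x[i] <- rho * x[i - 1] + stats::rnorm(1, 0, sigma)
      }
      g[idx] <- x
    }
    bins$gc <- pmin(0.60, pmax(0.30, 0.42 + g))
  } else {
    stopifnot(is.numeric(gc), length(gc) == nrow(bins), all(gc >= 0), all(gc <= 1))
    bins$gc <- gc
  }
  structure(list(bins = bins, bin_size = bin_size), class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", nrow(x$bins), " bins of ", x$bin_size / 1e3, " kb over ",
      length(unique(x$bins$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

gc_bias_factor <- function(gc, coef) {
  g <- gc - 0.40
  exp(coef[1] * g + coef[2] * g^2)
}

# per-bin expected copy number from a diploid baseline plus imbalance profile;
# partial bin overlap contributes proportionally
bin_copy_number <- function(profile, sex, grid) {
  bins <- grid$bins
  cn <- rep(2, nrow(bins))
  if (!is.na(sex) && sex == "XY") {
    cn[bins$chrom == "X"] <- 1
    cn[bins$chrom == "Y"] <- 1
  } else {
    cn[bins$chrom == "Y"] <- 0
  }
  if (!is.null(profile) && nrow(profile) > 0) {
    for (i in seq_len(nrow(profile))) {
      sel <- bins$chrom == profile$chrom[i]
      if (!any(sel)) next
      ov <- pmax(0, pmin(bins$end[sel], profile$end[i]) -
                    pmax(bins$start[sel], profile$start[i]))
      frac <- ov / (bins$end[sel] - bins$start[sel])
      cn[sel] <- cn[sel] + profile$delta[i] * profile$fraction[i] * frac
    }
  }
  pmax(cn, 0)
}

new_bin_counts <- function(sample_id, counts, grid) {
  structure(list(sample_id = sample_id, counts = counts,
                 total_reads = sum(counts), n_bins = nrow(grid$bins)),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("<bin_counts> ", x$sample_id, ": ", x$n_bins, " bins, ",
      round(x$total_reads), " reads\n", sep = "")
  invisible(x)
}

#' Simulate per-bin read counts for one blastomere
#'
#' Expected count per bin is proportional to (local copy number / 2) x
#' GC-bias x reads/bins; counts are negative-binomial with the configured
#' overdispersion (Poisson in the zero-dispersion limit, exact expectations
#' in noiseless mode), with per-bin dropout. A copy-number gain from two to
#' three copies raises the affected bins' expectation by 50%; a loss to one
#' copy lowers it by 50%. Mosaic events enter as fractional copy number.
#'
#' @param profile Imbalance profile data.frame (chrom, start, end, delta,
#'   fraction) or NULL/empty for euploid.
#' @param sex "XX", "XY" or NA (no sex-chromosome adjustment).
#' @param grid A `bin_grid`.
#' @param cfg A `sim_config`.
#' @param sample_id Sample identifier.
#' @param failed Simulate a whole-sample amplification failure.
#' @param seed Optional seed.
#' @return A `bin_counts` object.
#' @export
simulate_blastomere_counts <- function(profile, sex, grid, cfg = sim_config(),
                                       sample_id = "sample", failed = FALSE,
                                       seed = NULL) {
  stopifnot(inherits(grid, "bin_grid"), inherits(cfg, "sim_config"))
  if (!is.null(profile) && nrow(profile) > 0) {
    bad <- !profile$chrom %in% grid$bins$chrom
    if (any(bad)) stop("profile chromosome not on grid: ",
                       paste(unique(profile$chrom[bad]), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  cn <- bin_copy_number(profile, sex, grid)
  w <- (cn / 2) * gc_bias_factor(grid$bins$gc, cfg$gc_bias)
  if (sum(w) <= 0) stop("degenerate profile: zero total weight")
  mu <- cfg$reads * w / sum(w)
  disp <- if (failed) cfg$failure_dispersion else cfg$overdispersion
  drop <- if (failed) cfg$failure_dropout else cfg$dropout
  # compensate dropout so the configured read budget is met in expectation
  if (!failed && drop > 0 && drop < 1) mu <- mu / (1 - drop)
  if (cfg$noiseless && !failed) {
    counts <- mu
  } else {
    counts <- if (disp <= 1e-12) stats::rpois(length(mu), mu)
              else stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
    if (drop > 0) counts[stats::runif(length(mu)) < drop] <- 0
  }
  new_bin_counts(sample_id, counts, grid)
}

sample_gamete <- function(gametes) {
  viable <- vapply(gametes, function(g) g$viable, TRUE)
  w <- vapply(gametes, function(g) g$weight, 0)
  w[!viable] <- 0
  gametes[[sample.int(length(gametes), 1, prob = w / sum(w))]]
}

draw_parent_imbalance <- function(k, m, w) {
  modes <- character(0)
  profs <- list()
  if (length(k$rearrangements) == 0) {
    return(list(modes = "normal", profile = empty_imbalance()))
  }
  for (r in k$rearrangements) {
    g <- sample_gamete(enumerate_gametes(r, m, w))
    modes <- c(modes, g$mode)
    profs[[length(profs) + 1]] <- gamete_imbalance(g, m)
  }
  list(modes = modes, profile = do.call(rbind, profs))
}

#' Simulate one embryo (single-blastomere biopsy) from a couple
#'
#' Draws one gamete per parent by segregation weights, adds de novo meiotic
#' aneuploidies (per-chromosome weights peaked at the common hotspot
#' chromosomes), optional chaotic multi-aneuploidy, and optional mitotic
#' events with mosaic fractions; composes the zygote profile and simulates
#' bin counts. The truth category applies the classifier's own rules to the
#' true event list (an event indistinguishable from a parental product is
#' labelled related in truth as well).
#'
#' @param km,kf Parental `karyotype`s (resolved or not).
#' @param m A `cytoband_map`.
#' @param grid A `bin_grid`.
#' @param cfg A `sim_config`.
#' @param w A `segregation_weights` (default realistic).
#' @param sample_id Sample identifier.
#' @param catalogue Optional precomputed catalogue from
#'   [expected_unbalanced_catalogue()] (avoids recomputation per embryo).
#' @param ccfg A `classifier_config` used for truth labelling.
#' @param seed Optional seed.
#' @return List with `counts` (a `bin_counts`) and `truth` (sample id,
#'   category, failed flag, sex, event table, gamete modes).
#' @export
simulate_embryo <- function(km, kf, m, grid, cfg = sim_config(),
                            w = segregation_weights("realistic"),
                            sample_id = "embryo", catalogue = NULL,
                            ccfg = classifier_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  km <- resolve_breakpoints(km, m)
  kf <- resolve_breakpoints(kf, m)
  if (is.null(catalogue)) catalogue <- expected_unbalanced_catalogue(km, kf, m)
  gm <- draw_parent_imbalance(km, m, w)
  gf <- draw_parent_imbalance(kf, m, w)
  sex <- if ("X" %in% grid$bins$chrom) sample(c("XX", "XY"), 1) else NA_character_
  events <- rbind(gm$profile, gf$profile)
  events <- if (nrow(events) > 0) combine_imbalances(list(events), m) else events

  grid_chroms <- unique(grid$bins$chrom)
  autosomes <- setdiff(grid_chroms, c("X", "Y"))
  add_whole <- function(events, ch, delta, fraction, provenance) {
    len_end <- max(grid$bins$end[grid$bins$chrom == ch])
    cur <- sum(events$delta[events$chrom == ch] * events$fraction[events$chrom == ch])
    if (2 + cur + delta * fraction < 0) return(events) # skip impossible nullisomy
    rbind(events, data.frame(chrom = ch, start = 0, end = len_end,
                             delta = delta, fraction = fraction,
                             provenance = provenance))
  }
  # de novo meiotic whole-chromosome events
  wts <- cfg$denovo_weights[intersect(names(cfg$denovo_weights), autosomes)]
  if (length(wts) == 0) wts <- stats::setNames(rep(1, length(autosomes)), autosomes)
  n_dn <- stats::rpois(1, cfg$denovo_rate)
  if (stats::runif(1) < cfg$chaos_prob) {
    n_dn <- n_dn + sample(seq(cfg$chaos_events[1], cfg$chaos_events[2]), 1)
  }
  n_dn <- min(n_dn, length(wts))
  if (n_dn > 0) {
    chs <- sample(names(wts), n_dn, prob = wts)
    for (ch in chs) {
      events <- add_whole(events, ch, sample(c(-1, 1), 1), 1, "de-novo-meiotic")
    }
  }
  # mitotic mosaic event
  if (stats::runif(1) < cfg$mosaic_prob && length(autosomes) > 0) {
    f <- stats::runif(1, cfg$mosaic_fraction[1], cfg$mosaic_fraction[2])
    events <- add_whole(events, sample(autosomes, 1), sample(c(-1, 1), 1),
                        f, "mitotic")
  }
  failed <- stats::runif(1) < cfg$failure_prob
  counts <- simulate_blastomere_counts(events, sex, grid, cfg,
                                       sample_id = sample_id, failed = failed)
  truth_cls <- truth_classification(events, catalogue, ccfg)
  truth <- list(sample_id = sample_id, failed = failed, sex = sex,
                category = truth_cls$category,
                n_related = truth_cls$n_related, n_denovo = truth_cls$n_denovo,
                gamete_modes = c(gm$modes, gf$modes), events = events)
  list(counts = counts, truth = truth)
}

#' Simulate a cohort of embryos with known ground truth
#'
#' @param spec List of group specs, each `list(name=, n=, km=, kf=)` with
#'   ISCN karyotype strings (or `karyotype` objects).
#' @param m A `cytoband_map`.
#' @param grid A `bin_grid`.
#' @param cfg A `sim_config`.
#' @param w A `segregation_weights`.
#' @param ccfg A `classifier_config` for truth labelling.
#' @param seed Seed; identical (spec, seed) give identical cohorts.
#' @return List with `samples` (list of `bin_counts`) and `truth`
#'   (data.frame: sample_id, group, failed, sex, category) plus per-embryo
#'   event tables in `events`.
#' @export
simulate_cohort <- function(spec, m, grid, cfg = sim_config(),
                            w = segregation_weights("realistic"),
                            ccfg = classifier_config(), seed = 1) {
  if (length(spec) == 0) stop("empty cohort spec")
  set.seed(seed)
  samples <- list(); truth_rows <- list(); events <- list()
  for (g in spec) {
    stopifnot(!is.null(g$name), !is.null(g$n))
    km <- if (inherits(g$km, "karyotype")) g$km else parse_karyotype(g$km)
    kf <- if (inherits(g$kf, "karyotype")) g$kf else parse_karyotype(g$kf)
    km <- resolve_breakpoints(km, m); kf <- resolve_breakpoints(kf, m)
    catalogue <- expected_unbalanced_catalogue(km, kf, m)
    for (i in seq_len(g$n)) {
      sid <- sprintf("%s_%04d", g$name, i)
      e <- simulate_embryo(km, kf, m, grid, cfg, w, sample_id = sid,
                           catalogue = catalogue, ccfg = ccfg)
      samples[[sid]] <- e$counts
      events[[sid]] <- e$truth$events
      truth_rows[[sid]] <- data.frame(
        sample_id = sid, group = g$name, failed = e$truth$failed,
        sex = e$truth$sex, category = e$truth$category,
        stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, truth = do.call(rbind, truth_rows), events = events)
}
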