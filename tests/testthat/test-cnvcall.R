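test_that("QC separates clean, failed and empty samples deterministically", {
  s <- toy_setup(3)
  ccfg <- caller_config()
  set.seed(4)
  clean <- simulate_blastomere_counts(NULL, NA, s$grid, s$cfg)
  qc <- qc_assess(clean, s$grid, ccfg)
  expect_true(qc$informative)
  expect_lt(qc$mapd, ccfg$max_mapd)

  set.seed(4)
  failed <- simulate_blastomere_counts(NULL, NA, s$grid, s$cfg, failed = TRUE)
  qf <- qc_assess(failed, s$grid, ccfg)
  expect_false(qf$informative)
  expect_true(length(qf$reasons) > 0)

  zero <- pgtcnv:::new_bin_counts("empty", rep(0, nrow(s$grid$bins)), s$grid)
  qz <- qc_assess(zero, s$grid, ccfg)
  expect_false(qz$informative)
  expect_true("reads" %in% qz$reasons)

  short <- pgtcnv:::new_bin_counts("short", rep(10, 5), s$grid)
  short$counts <- rep(10, 5)
  expect_error(qc_assess(short, s$grid, ccfg), "grid")
})

test_that("rising dispersion never flips a failed sample back to informative", {
  s <- toy_setup(3)
  ccfg <- caller_config()
  flags <- vapply(c(0.02, 0.2, 1, 5), function(a) {
    cfg <- sim_config(reads = s$cfg$reads, overdispersion = a)
    set.seed(21)
    qc_assess(simulate_blastomere_counts(NULL, NA, s$grid, cfg), s$grid,
              ccfg)$informative
  }, TRUE)
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("the reference panel captures the simulated GC bias shape", {
  s <- toy_setup(3, gc_bias = c(-2, -10), overdispersion = 0.005)
  panel <- toy_panel(s, n = 40)
  bias <- pgtcnv:::gc_bias_factor(s$grid$bins$gc, s$cfg$gc_bias)
  ok <- !panel$mask
  expect_gt(cor(panel$factor[ok], bias[ok]), 0.9)

  # identical flat samples give unit factors
  flat <- lapply(1:5, function(i)
    pgtcnv:::new_bin_counts(paste0("f", i), rep(100, nrow(s$grid$bins)), s$grid))
  pf <- build_reference(flat, s$grid, caller_config())
  expect_true(all(abs(pf$factor - 1) < 1e-12))

  # a bin zero in all normals is masked
  flat0 <- lapply(flat, function(x) { x$counts[7] <- 0; x })
  p0 <- build_reference(flat0, s$grid, caller_config())
  expect_true(p0$mask[7])

  expect_error(build_reference(flat[1:2], s$grid, caller_config()),
               "at least 3")
})

test_that("normalization recovers 50% shifts for trisomy and monosomy", {
  s <- toy_setup(3)
  panel <- toy_panel(s, n = 20)
  ccfg <- caller_config()
  shifts <- sapply(c(1, -1), function(d) {
    prof <- data.frame(chrom = "3", start = 0, end = 5e7, delta = d,
                       fraction = 1)
    mean(sapply(1:10, function(seed) {
      set.seed(seed)
      cts <- simulate_blastomere_counts(prof, NA, s$grid, s$cfg)
      np <- normalize_counts(cts, panel, s$grid, ccfg)
      mean(np$ratio[s$grid$bins$chrom == "3"], na.rm = TRUE)
    }))
  })
  expect_equal(shifts[1], 1.5, tolerance = 0.04)
  expect_equal(shifts[2], 0.5, tolerance = 0.08)
  # euploid chromosome medians sit at 1
  set.seed(1)
  eu <- simulate_blastomere_counts(NULL, NA, s$grid, s$cfg)
  np <- normalize_counts(eu, panel, s$grid, caller_config())
  meds <- tapply(np$ratio, s$grid$bins$chrom, median, na.rm = TRUE)
  expect_true(all(abs(meds - 1) < 0.06))
})

test_that("estimated copy number is linear across simulated states", {
  s <- toy_setup(3)
  panel <- toy_panel(s, n = 20)
  ccfg <- caller_config()
  states <- c(1, 1.5, 2, 2.5, 3)
  est <- vapply(states, function(cn) {
    prof <- if (cn == 2) NULL else
      data.frame(chrom = "3", start = 0, end = 5e7, delta = sign(cn - 2),
                 fraction = abs(cn - 2))
    mean(vapply(1:20, function(seed) {
      set.seed(seed + 400)
      cts <- simulate_blastomere_counts(prof, NA, s$grid, s$cfg)
      np <- normalize_counts(cts, panel, s$grid, ccfg)
      2 * mean(np$ratio[s$grid$bins$chrom == "3"], na.rm = TRUE)
    }, 0))
  }, 0)
  expect_true(all(abs(est - states) <= 0.1))
})

test_that("sex inference reads X and Y dosage from raw ratios", {
  grid <- fx_grid()
  panel <- fx_panel()
  cfg <- sim_config()
  ccfg <- caller_config()
  for (i in 1:3) {
    set.seed(500 + i)
    male <- simulate_blastomere_counts(NULL, "XY", grid, cfg)
    np <- normalize_counts(male, panel, grid, ccfg)
    expect_equal(np$sex, "XY")
    expect_equal(np$x_ratio, 0.5, tolerance = 0.12)
    expect_gt(np$y_ratio, 0.25)
    set.seed(600 + i)
    female <- simulate_blastomere_counts(NULL, "XX", grid, cfg)
    npf <- normalize_counts(female, panel, grid, ccfg)
    expect_equal(npf$sex, "XX")
    expect_lt(npf$y_ratio, 0.1)
  }
})

test_that("normalization refuses QC failures and over-masked samples", {
  s <- toy_setup(3)
  panel <- toy_panel(s)
  set.seed(9)
  failed <- simulate_blastomere_counts(NULL, NA, s$grid, s$cfg, failed = TRUE)
  qc <- qc_assess(failed, s$grid, caller_config())
  expect_error(normalize_counts(failed, panel, s$grid, caller_config(),
                                qc = qc), "not informative")
  # force flag overrides for a noisy-but-covered failure (heavy dropout
  # still trips the usable-bin guard below)
  noisy_cfg <- sim_config(reads = s$cfg$reads, failure_dropout = 0.05)
  set.seed(10)
  noisy <- simulate_blastomere_counts(NULL, NA, s$grid, noisy_cfg,
                                      failed = TRUE)
  qn <- qc_assess(noisy, s$grid, caller_config())
  expect_false(qn$informative)
  expect_s3_class(normalize_counts(noisy, panel, s$grid, caller_config(),
                                   qc = qn, force = TRUE),
                  "normalized_profile")
  # mask most bins -> insufficient usable bins
  panel_bad <- panel
  panel_bad$mask[1:100] <- TRUE
  panel_bad$factor[1:100] <- NA
  set.seed(9)
  ok <- simulate_blastomere_counts(NULL, NA, s$grid, s$cfg)
  expect_error(normalize_counts(ok, panel_bad, s$grid, caller_config()),
               "insufficient usable bins")
})

test_that("segmentation equals the noiseless changepoint oracle on <=50-bin instances", {
  ccfg <- caller_config()
  set.seed(77)
  cases <- list(
    rep(1, 10),                                  # flat
    c(rep(1, 20), rep(0.5, 5), rep(1, 20)),      # short interior loss
    c(rep(1.5, 3), rep(1, 40)),                  # edge gain
    c(rep(1, 24), rep(1.5, 26)),                 # half split
    c(rep(0.5, 4), rep(1, 5), rep(1.5, 4)))      # double step
  for (i in 1:25) {                              # random piecewise signals
    n_seg <- sample(1:4, 1)
    lens <- pmax(3, as.integer(stats::rmultinom(1, 40, rep(1, n_seg))))
    lv <- numeric(0); prev <- -1
    for (k in seq_len(n_seg)) {
      lev <- sample(setdiff(c(0.5, 1, 1.5, 2), prev), 1)
      lv <- c(lv, rep(lev, lens[k])); prev <- lev
    }
    cases[[length(cases) + 1]] <- lv
  }
  for (x in cases) {
    grid1 <- one_chrom_grid(length(x))
    segs <- segment_profile(flat_profile(x), grid1, ccfg)
    got <- if (nrow(segs) > 1) segs$end[-nrow(segs)] / 1e6 else numeric(0)
    expect_equal(got, as.numeric(oracle_changepoints(x)))
    # and the segment means are the true levels
    expect_equal(segs$mean_ratio,
                 as.numeric(tapply(x, cumsum(c(1, diff(x) != 0)), mean)),
                 ignore_attr = TRUE)
  }
})

test_that("call thresholds implement the 40%/80% mosaic logic", {
  ccfg <- caller_config()
  grid1 <- one_chrom_grid(30)
  mk <- function(level) {
    segs <- segment_profile(flat_profile(rep(level, 30)), grid1, ccfg)
    call_segments(segs, flat_profile(rep(level, 30)), grid1, ccfg)
  }
  full <- mk(1.5)   # c = 3.0: full trisomy
  expect_equal(full$calls$call, 3L)
  expect_equal(full$calls$f, 1)
  expect_false(full$calls$mosaic)
  expect_true(full$calls$whole_chromosome)

  mos <- mk(1.25)   # c = 2.5: mosaic gain, f = 0.5
  expect_true(mos$calls$mosaic)
  expect_equal(mos$calls$f, 0.5)
  expect_equal(mos$calls$call, 3L)

  none <- mk(1.1)   # c = 2.2: below the 40% floor
  expect_null(none$calls)
  expect_equal(unname(none$chrom_status["1"]), "normal")
})

test_that("short segments need high amplitude, long mosaic segments are kept", {
  ccfg <- caller_config()
  grid1 <- one_chrom_grid(40)
  # 2-bin mosaic dip (|c-2| = 0.5 < big_amp) is filtered by min_seg_bins
  x <- c(rep(1, 19), rep(0.75, 2), rep(1, 19))
  cs <- call_segments(segment_profile(flat_profile(x), grid1, ccfg),
                      flat_profile(x), grid1, ccfg)
  expect_null(cs$calls)
  # 1-bin full deletion passes the amplitude override
  x2 <- c(rep(1, 19), 0.45, rep(1, 20))
  cs2 <- call_segments(segment_profile(flat_profile(x2), grid1, ccfg),
                       flat_profile(x2), grid1, ccfg)
  expect_equal(nrow(cs2$calls), 1)
  expect_equal(cs2$calls$direction, "loss")
  expect_equal(cs2$calls$n_bins, 1)
})

test_that("a simulated 4.6 Mb deletion in 21q22.3 is called at the right size", {
  m <- fx_map(); grid <- fx_grid(); panel <- fx_panel()
  ccfg <- caller_config()
  band <- band_interval(m, "21", "q22.3")
  start <- band[1] + (diff(band) - 4.6e6) / 2  # centred in the band
  prof <- data.frame(chrom = "21", start = start, end = start + 4.6e6,
                     delta = -1, fraction = 1)
  hits <- vapply(1:5, function(seed) {
    set.seed(seed)
    cts <- simulate_blastomere_counts(prof, "XX", grid, sim_config())
    cs <- call_embryo(cts, panel, grid, ccfg)
    loss <- cs$calls[cs$calls$chrom == "21" & cs$calls$direction == "loss", ,
                     drop = FALSE]
    if (is.null(loss) || nrow(loss) == 0) return(NA_real_)
    loss$size_mb[which.max(loss$n_bins)]
  }, 0)
  expect_true(all(!is.na(hits)))              # the loss is always detected
  expect_gte(sum(abs(hits - 4.6) <= 1), 4)    # and sized to the bin in most runs
  expect_true(all(abs(hits - 4.6) <= 3))      # never wildly off
})
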