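# Shared lazily-built fixtures; heavyweight objects (full-genome grid and
# reference panel) are constructed once per test run.

.fx <- new.env(parent = emptyenv())

fx_map <- function() {
  if (is.null(.fx$map)) .fx$map <- cytoband_map()
  .fx$map
}

fx_grid <- function() {
  if (is.null(.fx$grid)) .fx$grid <- build_bin_grid(fx_map(), 1e6, seed = 1)
  .fx$grid
}

fx_panel <- function() {
  if (is.null(.fx$panel)) {
    set.seed(20240901)
    cfg <- sim_config()
    normals <- lapply(1:20, function(i) {
      simulate_blastomere_counts(NULL, "XX", fx_grid(), cfg,
                                 sample_id = sprintf("panel_%02d", i))
    })
    .fx$panel <- build_reference(normals, fx_grid(), caller_config())
  }
  .fx$panel
}

toy_setup <- function(n_chrom = 3, seed = 1, ...) {
  m <- toy_cytoband_map(n_chrom, 5e7)
  grid <- build_bin_grid(m, 1e6, seed = seed)
  cfg <- sim_config(reads = scaled_reads(grid), ...)
  list(m = m, grid = grid, cfg = cfg)
}

toy_panel <- function(setup, n = 10, seed = 99) {
  set.seed(seed)
  normals <- lapply(seq_len(n), function(i) {
    simulate_blastomere_counts(NULL, NA, setup$grid, setup$cfg,
                               sample_id = sprintf("n%02d", i))
  })
  build_reference(normals, setup$grid, caller_config())
}

# synthetic noiseless normalized profile on a single-chromosome toy grid
flat_profile <- function(x, sample_id = "toy") {
  structure(list(sample_id = sample_id, ratio = x,
                 mask = rep(FALSE, length(x)), sex = NA_character_,
                 x_ratio = NA_real_, y_ratio = NA_real_),
            class = "normalized_profile")
}

one_chrom_grid <- function(n) build_bin_grid(toy_cytoband_map(1, n * 1e6), 1e6)

# independent oracle: true changepoints of a noiseless piecewise signal
oracle_changepoints <- function(x) which(diff(x) != 0)
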