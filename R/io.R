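#' Write per-bin counts as BED-like TSV
#'
#' Tab-separated, '#'-prefixed header, no quoting: columns chrom, start,
#' end, count in grid order.
#'
#' @param x A `bin_counts`.
#' @param grid The `bin_grid` the counts are aligned to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(x, grid, path) {
  stopifnot(inherits(x, "bin_counts"), inherits(grid, "bin_grid"),
            length(x$counts) == nrow(grid$bins))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tcount", con)
  utils::write.table(
    data.frame(grid$bins$chrom, grid$bins$start, grid$bins$end, x$counts),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-bin counts from BED-like TSV
#'
#' Strict validation: four columns, non-negative counts (error reports the
#' offending line number), and bin coordinates must match the active grid
#' row-for-row ("not grid-ordered" otherwise).
#'
#' @param path Input TSV path.
#' @param grid The active `bin_grid`.
#' @param sample_id Sample identifier (default: file base name).
#' @return A `bin_counts`.
#' @export
read_bin_counts <- function(path, grid, sample_id = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- startsWith(lines, "#")
  body <- lines[!hdr]
  line_no <- which(!hdr)
  if (length(body) != nrow(grid$bins))
    stop("file has ", length(body), " data rows but grid has ",
         nrow(grid$bins), " bins")
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 4)
      stop("malformed row at line ", line_no[i], ": expected 4 columns")
    num <- suppressWarnings(as.numeric(p[2:4]))
    if (any(is.na(num)))
      stop("malformed row at line ", line_no[i], ": non-numeric field")
    if (num[3] < 0)
      stop("negative count at line ", line_no[i])
  }
  chrom <- vapply(parts, `[`, "", 1)
  start <- as.numeric(vapply(parts, `[`, "", 2))
  end <- as.numeric(vapply(parts, `[`, "", 3))
  count <- as.numeric(vapply(parts, `[`, "", 4))
  if (!all(chrom == grid$bins$chrom & start == grid$bins$start &
           end == grid$bins$end))
    stop("not grid-ordered: bin coordinates do not match the active grid")
  new_bin_counts(sample_id, count, grid)
}

pipeline_config_defaults <- function() {
  list(
    genome = "toy",           # "toy" or "full"
    toy_chromosomes = 3L,
    toy_chrom_length = 5e7,
    bin_size = 1e6,
    seed = 1L,
    n_panel = 10L,
    groups = list(list(name = "demo", n = 20L, km = "46,XX", kf = "46,XY")),
    weights = list(kind = "realistic", convention = "classes18"),
    sim = list(),             # sim_config() overrides
    caller = list(),          # caller_config() overrides
    classifier = list())      # classifier_config() overrides
}

#' Read and validate a pipeline configuration (YAML or JSON)
#'
#' Unknown keys (top-level or in the sim/caller/classifier/weights blocks)
#' are rejected before any stage runs; omitted keys take the documented
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = FALSE)
         else stop("config must be .yaml/.yml or .json")
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration list
#'
#' @param cfg Named list of configuration values.
#' @return A completed `pipeline_config` with defaults filled in.
#' @export
validate_pipeline_config <- function(cfg) {
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- defaults
  for (nm in names(cfg)) out[[nm]] <- cfg[[nm]]  # wholesale replacement
  check_block <- function(block, allowed, label) {
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop("unknown ", label, " key(s): ", paste(extra, collapse = ", "))
  }
  check_block(out$sim, names(formals(sim_config)), "sim")
  check_block(out$caller, names(formals(caller_config)), "caller")
  check_block(out$classifier, names(formals(classifier_config)), "classifier")
  check_block(out$weights, c("kind", "convention", "inversion_recombination"),
              "weights")
  if (!out$genome %in% c("toy", "full")) stop("genome must be 'toy' or 'full'")
  out$groups <- lapply(out$groups, function(g) {
    # YAML 1.1 reads a bare `n` key as a boolean, so the config key is
    # n_embryos; plain `n` is accepted from programmatic lists
    if (is.null(g$n) && !is.null(g$n_embryos)) g$n <- g$n_embryos
    g$n_embryos <- NULL
    if (!all(c("name", "n", "km", "kf") %in% names(g)))
      stop("each group needs name, n_embryos, km, kf")
    g
  })
  structure(out, class = "pipeline_config")
}

#' Run the full pipeline: simulate, QC, normalize, segment, call, classify,
#' tabulate
#'
#' Executes the end-to-end analysis on a simulated cohort defined by the
#' configuration and returns a report with per-embryo and cohort sections.
#' Identical (config, seed) give identical reports (the timestamp field
#' aside).
#'
#' @param cfg A `pipeline_config` (list accepted; validated first).
#' @param quiet Suppress progress messages.
#' @return A report list: resolved config, seed, panel and QC summaries,
#'   per-embryo results, cohort table, and truth-vs-called concordance.
#' @export
run_pipeline <- function(cfg, quiet = TRUE) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_pipeline_config(cfg)
  say <- function(...) if (!quiet) message(...)
  m <- if (cfg$genome == "full") cytoband_map()
       else toy_cytoband_map(cfg$toy_chromosomes, cfg$toy_chrom_length)
  grid <- build_bin_grid(m, bin_size = cfg$bin_size, seed = cfg$seed)
  scfg <- do.call(sim_config, cfg$sim)
  if (is.null(cfg$sim$reads)) scfg$reads <- scaled_reads(grid)
  ccfg <- do.call(caller_config, cfg$caller)
  lcfg <- do.call(classifier_config, cfg$classifier)
  w <- do.call(segregation_weights, cfg$weights)

  say("simulating reference panel (", cfg$n_panel, " euploid samples)")
  set.seed(cfg$seed + 7777)
  panel_cfg <- scfg; panel_cfg$failure_prob <- 0
  normals <- lapply(seq_len(cfg$n_panel), function(i) {
    simulate_blastomere_counts(NULL, if ("X" %in% grid$bins$chrom) "XX" else NA,
                               grid, panel_cfg,
                               sample_id = sprintf("panel_%02d", i))
  })
  panel <- build_reference(normals, grid, ccfg)

  say("simulating cohort")
  cohort <- simulate_cohort(cfg$groups, m, grid, scfg, w, lcfg,
                            seed = cfg$seed)
  catalogues <- lapply(cfg$groups, function(g) {
    km <- resolve_breakpoints(parse_karyotype(g$km), m)
    kf <- resolve_breakpoints(parse_karyotype(g$kf), m)
    list(km = km, kf = kf,
         catalogue = expected_unbalanced_catalogue(km, kf, m))
  })
  names(catalogues) <- vapply(cfg$groups, `[[`, "", "name")

  say("calling and classifying ", length(cohort$samples), " embryos")
  per_embryo <- list()
  records <- list()
  for (sid in names(cohort$samples)) {
    group <- cohort$truth$group[cohort$truth$sample_id == sid]
    ctx <- catalogues[[group]]
    cs <- tryCatch(call_embryo(cohort$samples[[sid]], panel, grid, ccfg),
                   error = function(e) stop("stage call failed for sample ",
                                            sid, ": ", conditionMessage(e)))
    if (cs$informative) {
      cls <- classify_embryo(cs, ctx$km, ctx$kf, m, lcfg,
                             catalogue = ctx$catalogue)
      category <- cls$category
      transferable <- cls$transferable
    } else {
      category <- NA_character_
      transferable <- FALSE
    }
    n_calls <- if (is.null(cs$calls)) 0L else nrow(cs$calls)
    per_embryo[[sid]] <- list(sample_id = sid, group = group,
                              informative = cs$informative,
                              sex = cs$sex, category = category,
                              transferable = transferable,
                              n_abnormal_segments = n_calls,
                              mapd = cs$qc$mapd)
    records[[sid]] <- data.frame(sample_id = sid, group = group,
                                 informative = cs$informative,
                                 category = category,
                                 truth_category = cohort$truth$category[
                                   cohort$truth$sample_id == sid],
                                 stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, records)
  table <- tabulate_cohort(records)
  inf <- records[records$informative, ]
  concordance <- if (nrow(inf)) mean(inf$category == inf$truth_category) else NA
  list(config = unclass(cfg), seed = cfg$seed,
       n_samples = length(cohort$samples),
       panel = list(n_samples = panel$n_samples,
                    masked_bins = sum(panel$mask)),
       per_embryo = per_embryo,
       cohort_table = table,
       records = records,
       truth_concordance = concordance,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a pipeline report as JSON
#'
#' @param report Report list from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
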