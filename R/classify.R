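#' Classifier configuration
#'
#' @param mac_threshold Distinct abnormal chromosomes at or above which an
#'   embryo is labelled multiple aneuploidy of chromosomes (Type IV,
#'   overriding Types I-III).
#' @param tolerance Breakpoint-matching tolerance in bp for relating a
#'   segmental event to a parental-rearrangement breakpoint.
#' @param min_overlap Minimum reciprocal overlap between a called event and
#'   a catalogue imbalance.
#' @param mosaic_floor Mosaic fractions at or below this are not counted as
#'   events (the "> 40% mosaic rate" transfer rule).
#' @param edge_margin Breakpoints within this distance of a chromosome end
#'   or start are treated as terminal, not matchable breakpoints.
#' @param whole_chrom_frac Fraction of a chromosome an event must span to
#'   count as whole-chromosome during matching.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(mac_threshold = 3, tolerance = 5e6,
                              min_overlap = 0.5, mosaic_floor = 0.4,
                              edge_margin = 2e6, whole_chrom_frac = 0.9) {
  structure(as.list(environment()), class = "classifier_config")
}

#' Catalogue of zygote-level imbalances expected from the parents
#'
#' Union over both parents of the imbalance profiles of all unbalanced
#' gamete classes (at the diploid baseline, i.e. paired with a normal
#' gamete), deduplicated. For deletion/duplication carriers the carried
#' imbalance itself enters the catalogue, so an inherited microdeletion is
#' matched as parental-related.
#'
#' @param km,kf Parental `karyotype`s.
#' @param m A `cytoband_map`.
#' @param w A `segregation_weights` (class contents do not depend on the
#'   weight kind).
#' @return data.frame of catalogue rows (chrom, start, end, delta) with the
#'   chromosome lengths attached as an attribute; zero rows for a
#'   structurally normal couple.
#' @export
expected_unbalanced_catalogue <- function(km, kf, m = cytoband_map(),
                                          w = segregation_weights()) {
  rows <- list()
  for (k in list(km, kf)) {
    k <- resolve_breakpoints(k, m)
    for (r in k$rearrangements) {
      for (g in enumerate_gametes(r, m, w)) {
        if (g$balanced || !g$viable) next
        p <- gamete_imbalance(g, m)
        if (nrow(p) > 0) rows[[length(rows) + 1]] <- p[, c("chrom", "start",
                                                           "end", "delta")]
      }
    }
  }
  cat_df <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               delta = numeric())
  rownames(cat_df) <- NULL
  attr(cat_df, "chrom_lengths") <- m$chrom_lengths
  cat_df
}

internal_breakpoints <- function(start, end, chrom_len, edge_margin) {
  bp <- c(start, end)
  bp[bp > edge_margin & bp < chrom_len - edge_margin]
}

#' Match one called event against the parental catalogue
#'
#' An event is parental-related iff some catalogue imbalance has the same
#' sign on the same chromosome AND either both are whole-chromosome scale
#' (a chromosome fully involved in the rearrangement, as for Robertsonian
#' products) or the event is segmental with a non-centromeric breakpoint
#' within `tolerance` of a catalogue breakpoint and reciprocal overlap at
#' least `min_overlap`. Everything else is de novo.
#'
#' @param chrom,start,end,sign Event coordinates and sign (+1 gain,
#'   -1 loss).
#' @param catalogue From [expected_unbalanced_catalogue()].
#' @param cfg A `classifier_config`.
#' @return List: `origin` ("related"/"de_novo"), `overlap` (best reciprocal
#'   overlap), `bp_distance` (best breakpoint distance, bp).
#' @export
match_event <- function(chrom, start, end, sign, catalogue,
                        cfg = classifier_config()) {
  lens <- attr(catalogue, "chrom_lengths")
  clen <- lens[[chrom]]
  cand <- catalogue[catalogue$chrom == chrom & sign(catalogue$delta) == sign, ,
                    drop = FALSE]
  best_ov <- 0; best_bd <- Inf
  if (nrow(cand) == 0) {
    return(list(origin = "de_novo", overlap = 0, bp_distance = Inf))
  }
  ev_whole <- (end - start) >= cfg$whole_chrom_frac * clen
  ev_bp <- internal_breakpoints(start, end, clen, cfg$edge_margin)
  related <- FALSE
  for (i in seq_len(nrow(cand))) {
    cs <- cand$start[i]; ce <- cand$end[i]
    ov <- max(0, min(end, ce) - max(start, cs))
    rec_ov <- min(ov / (end - start), ov / (ce - cs))
    cat_whole <- (ce - cs) >= cfg$whole_chrom_frac * clen
    cat_bp <- internal_breakpoints(cs, ce, clen, cfg$edge_margin)
    bd <- if (length(ev_bp) && length(cat_bp))
      min(outer(ev_bp, cat_bp, function(a, b) abs(a - b))) else Inf
    best_ov <- max(best_ov, rec_ov); best_bd <- min(best_bd, bd)
    if (ev_whole && cat_whole) related <- TRUE
    if (!ev_whole && rec_ov >= cfg$min_overlap && bd <= cfg$tolerance)
      related <- TRUE
  }
  list(origin = if (related) "related" else "de_novo",
       overlap = best_ov, bp_distance = best_bd)
}

# shared category engine: `events` has chrom, start, end, sign, mosaic flag.
# Events are assumed already filtered to reportable (fraction above the
# mosaic floor).
categorize_events <- function(events, catalogue, cfg) {
  if (is.null(events) || nrow(events) == 0) {
    return(list(category = "V", related = events, de_novo = events,
                n_related = 0L, n_denovo = 0L, origins = character(0)))
  }
  origins <- vapply(seq_len(nrow(events)), function(i) {
    match_event(events$chrom[i], events$start[i], events$end[i],
                events$sign[i], catalogue, cfg)$origin
  }, "")
  n_chrom <- length(unique(events$chrom))
  category <- if (n_chrom >= cfg$mac_threshold) "IV"
    else if (all(origins == "related")) "I"
    else if (all(origins == "de_novo")) "II"
    else "III"
  list(category = category,
       related = events[origins == "related", , drop = FALSE],
       de_novo = events[origins == "de_novo", , drop = FALSE],
       n_related = sum(origins == "related"),
       n_denovo = sum(origins == "de_novo"), origins = origins)
}

# truth labelling: apply the classifier's rules to a true event profile
truth_classification <- function(events, catalogue, cfg = classifier_config()) {
  lens <- attr(catalogue, "chrom_lengths")
  if (is.null(events) || nrow(events) == 0) {
    return(list(category = "V", n_related = 0L, n_denovo = 0L))
  }
  keep <- abs(events$delta) * events$fraction > cfg$mosaic_floor
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) == 0) return(list(category = "V", n_related = 0L, n_denovo = 0L))
  ev_std <- data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                       sign = sign(ev$delta), mosaic = ev$fraction < 1)
  res <- categorize_events(ev_std, catalogue, cfg)
  list(category = res$category, n_related = res$n_related,
       n_denovo = res$n_denovo)
}

#' Classify a called embryo into Types I-V and apply the transfer policy
#'
#' Type I: abnormalities related to the parental rearrangement only;
#' Type II: de novo abnormalities only; Type III: both; Type IV: multiple
#' aneuploidy of chromosomes (>= `mac_threshold` distinct abnormal
#' chromosomes, overriding I-III); Type V: normal/balanced. An embryo is
#' transferable iff it is Type V (any reported event, including a mosaic
#' event above the 40% rule, blocks transfer).
#'
#' @param callset An `embryo_callset` from an informative sample.
#' @param km,kf Parental `karyotype`s.
#' @param m A `cytoband_map`.
#' @param cfg A `classifier_config`.
#' @param catalogue Optional precomputed catalogue.
#' @return An `embryo_classification`: category, related / de novo / mosaic
#'   event tables with matching evidence, transferable flag.
#' @export
classify_embryo <- function(callset, km, kf, m = cytoband_map(),
                            cfg = classifier_config(), catalogue = NULL) {
  stopifnot(inherits(callset, "embryo_callset"))
  if (!callset$informative)
    stop("no result: sample ", callset$sample_id,
         " is not informative and is excluded from classification")
  if (is.null(catalogue)) catalogue <- expected_unbalanced_catalogue(km, kf, m)
  calls <- callset$calls
  if (is.null(calls) || nrow(calls) == 0) {
    cls <- list(category = "V", related = NULL, de_novo = NULL,
                n_related = 0L, n_denovo = 0L, origins = character(0))
    evidence <- NULL
  } else {
    ev_std <- data.frame(chrom = calls$chrom, start = calls$start,
                         end = calls$end,
                         sign = ifelse(calls$direction == "gain", 1, -1),
                         mosaic = calls$mosaic)
    cls <- categorize_events(ev_std, catalogue, cfg)
    evidence <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
      mm <- match_event(ev_std$chrom[i], ev_std$start[i], ev_std$end[i],
                        ev_std$sign[i], catalogue, cfg)
      data.frame(chrom = ev_std$chrom[i], origin = mm$origin,
                 overlap = mm$overlap, bp_distance = mm$bp_distance)
    }))
  }
  mosaic_events <- if (!is.null(calls)) calls[calls$mosaic, , drop = FALSE] else NULL
  structure(list(sample_id = callset$sample_id, category = cls$category,
                 related = cls$related, de_novo = cls$de_novo,
                 mosaic_events = mosaic_events,
                 transferable = cls$category == "V",
                 evidence = evidence, sex = callset$sex),
            class = "embryo_classification")
}

#' @export
print.embryo_classification <- function(x, ...) {
  cat("<embryo_classification> ", x$sample_id, ": Type ", x$category,
      if (x$transferable) " (transferable)" else " (not transferable)",
      "\n", sep = "")
  invisible(x)
}
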