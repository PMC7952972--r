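#' Format a rate as "x.y(n/d)"
#'
#' One-decimal percentage with the explicit fraction, the layout used in
#' clinical PGT rate tables, so tabulated output can be compared against
#' printed tables directly. Undefined rates (zero denominator) render "NA".
#'
#' @param n Numerator.
#' @param d Denominator.
#' @return Character scalar.
#' @export
format_rate <- function(n, d) {
  if (is.na(d) || d == 0) return("NA")
  sprintf("%.1f(%d/%d)", 100 * n / d, as.integer(n), as.integer(d))
}

#' Tabulate embryo classifications into a cohort rate table
#'
#' Per-group counts of biopsied and informative embryos and Type I-V rates
#' (informative embryos are the denominator, QC failures are excluded), plus
#' the combined Type I+III (parental-rearrangement-related) and II+III
#' (any de novo) rates and an overall row.
#'
#' @param records data.frame with one row per embryo: `group`,
#'   `informative` (logical), `category` ("I".."V", NA when not
#'   informative).
#' @param groups Optional explicit group order; records with a group label
#'   outside this set raise an error.
#' @return A `cohort_table` data.frame (one row per group plus "Overall").
#' @export
tabulate_cohort <- function(records, groups = NULL) {
  stopifnot(is.data.frame(records),
            all(c("group", "informative", "category") %in% names(records)))
  if (any(is.na(records$group))) stop("records with missing group label")
  if (is.null(groups)) groups <- unique(records$group)
  bad <- setdiff(unique(records$group), groups)
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  one <- function(sel, name) {
    r <- records[sel, , drop = FALSE]
    n_b <- nrow(r)
    inf <- r[r$informative, , drop = FALSE]
    n_i <- nrow(inf)
    cnt <- function(types) sum(inf$category %in% types)
    if (n_i > 0 && any(is.na(inf$category)))
      stop("informative embryo without category in group ", name)
    data.frame(
      group = name, biopsied = n_b, informative = n_i,
      informative_rate = format_rate(n_i, n_b),
      euploid = cnt("V"), euploid_rate = format_rate(cnt("V"), n_i),
      type_I = format_rate(cnt("I"), n_i),
      type_II = format_rate(cnt("II"), n_i),
      type_III = format_rate(cnt("III"), n_i),
      type_IV = format_rate(cnt("IV"), n_i),
      type_I_III = format_rate(cnt(c("I", "III")), n_i),
      type_II_III = format_rate(cnt(c("II", "III")), n_i),
      stringsAsFactors = FALSE)
  }
  rows <- lapply(groups, function(g) one(records$group == g, g))
  rows[[length(rows) + 1]] <- one(rep(TRUE, nrow(records)), "Overall")
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(", df = ", x$df) else "",
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1),
#' upper-tail chi-square p-value.
#'
#' @param tab Matrix of non-negative counts, at least 2x2.
#' @return A `test_result`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), nrow(tab) >= 2, ncol(tab) >= 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: zero marginal total")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_test_result(unname(ht$statistic), unname(ht$parameter),
                  unname(ht$p.value), "Pearson chi-square")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities not exceeding
#' the observed table's.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return A `test_result`.
#' @export
fisher_exact_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(dim(tab) == c(2, 2)))
  ht <- stats::fisher.test(tab)
  new_test_result(NA_real_, NA_real_, unname(ht$p.value), "Fisher's exact")
}

#' Compare two groups, choosing the test by expected counts
#'
#' Chi-square without continuity correction, switching to Fisher's exact
#' when any expected cell count is below 5 (common practice; both tests are
#' also exposed directly).
#'
#' @param tab 2x2 matrix of counts.
#' @return A `test_result`.
#' @export
compare_counts <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5) && all(dim(tab) == c(2, 2))) fisher_exact_test(tab)
  else chi_square_test(tab)
}

#' Summarize transfer-cycle clinical outcomes
#'
#' Implantation rate = gestational sacs per embryo transferred; clinical
#' pregnancy, live birth and early miscarriage rates are per transfer
#' cycle.
#'
#' @param records data.frame with one row per transfer cycle: columns
#'   `embryos_transferred`, `sacs`, `clinical_pregnancy`, `live_birth`,
#'   `early_miscarriage` (0/1 or logical).
#' @return List of counts and formatted rates.
#' @export
outcome_summary <- function(records) {
  need <- c("embryos_transferred", "sacs", "clinical_pregnancy", "live_birth",
            "early_miscarriage")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (any(records$sacs > records$embryos_transferred))
    stop("gestational sacs exceed embryos transferred in some cycle")
  n_cycles <- nrow(records)
  n_emb <- sum(records$embryos_transferred)
  n_sacs <- sum(records$sacs)
  n_cp <- sum(records$clinical_pregnancy > 0)
  n_lb <- sum(records$live_birth > 0)
  n_mc <- sum(records$early_miscarriage > 0)
  list(cycles = n_cycles, embryos_transferred = n_emb, sacs = n_sacs,
       clinical_pregnancies = n_cp, live_births = n_lb,
       early_miscarriages = n_mc,
       implantation_rate = format_rate(n_sacs, n_emb),
       clinical_pregnancy_rate = format_rate(n_cp, n_cycles),
       live_birth_rate = format_rate(n_lb, n_cycles),
       early_miscarriage_rate = format_rate(n_mc, n_cycles))
}

#' Load a bundled cohort fixture table
#'
#' `"rearrangement"`: per-group embryo counts (biopsied, informative,
#' euploid, Type I-IV) mirroring the published per-rearrangement
#' distribution; the small mixed "Other" carrier group's within-row type
#' split is a reconstruction (marked in the file header). `"transfers"`:
#' per-cycle transfer outcome records consistent with the published
#' single/double-embryo-transfer marginals.
#'
#' @param name Fixture name.
#' @return data.frame.
#' @export
pgt_fixture <- function(name = c("rearrangement", "transfers")) {
  name <- match.arg(name)
  file <- c(rearrangement = "fixture_table_rearrangement.tsv",
            transfers = "fixture_transfer_cycles.tsv")[[name]]
  path <- system.file("extdata", file, package = "pgtcnv", mustWork = TRUE)
  first <- readLines(path, n = 20)
  skip <- sum(startsWith(first, "#")) - 1  # last '#' line is the header
  hdr <- sub("^#", "", first[skip + 1])
  df <- utils::read.table(path, sep = "\t", skip = skip + 1,
                          col.names = strsplit(hdr, "\t")[[1]],
                          stringsAsFactors = FALSE)
  df
}

#' Expand aggregated classification counts into per-embryo records
#'
#' Turns a counts table (columns group, biopsied, informative, euploid,
#' typeI..typeIV) into one row per embryo so the standard tabulation path
#' can be exercised on fixture data.
#'
#' @param counts Aggregated counts data.frame.
#' @return Per-embryo records data.frame for [tabulate_cohort()].
#' @export
expand_classification_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    cats <- c(rep("I", r$typeI), rep("II", r$typeII), rep("III", r$typeIII),
              rep("IV", r$typeIV), rep("V", r$euploid))
    stopifnot(length(cats) == r$informative)
    data.frame(
      group = r$group,
      informative = c(rep(TRUE, r$informative),
                      rep(FALSE, r$biopsied - r$informative)),
      category = c(cats, rep(NA_character_, r$biopsied - r$informative)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
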