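#' Segregation weight sets for gamete enumeration
#'
#' `"theoretical"` weights are uniform across gamete classes, the convention
#' behind counselling-style euploidy probabilities (a reciprocal-translocation
#' carrier has balanced mass 2/18 under the default 18-class counting, so a
#' couple of two independent carriers has (1/9)^2 = 1/81). `"realistic"`
#' weights skew mass toward alternate segregation and are the simulator's
#' default for cohort generation.
#'
#' Two reciprocal-translocation counting conventions are provided and never
#' silently reconciled: `"classes18"` (default; the three 2:2 modes contribute
#' 2 classes each, 3:1 contributes 8, and 4:0 contributes 4 - the two 4:0
#' products listed once per division orientation), giving balanced mass 1/9;
#' and `"classes16"` (distinct compositions only), giving balanced mass 1/8.
#'
#' @param kind "theoretical" (uniform over classes) or "realistic".
#' @param convention "classes18" or "classes16" reciprocal counting.
#' @param reciprocal,robertsonian Optional named mode-mass overrides
#'   (e.g. `c(alternate = .5, "adjacent-1" = .3, "adjacent-2" = .1,
#'   "3:1" = .1, "4:0" = 0)`); renormalized to sum 1.
#' @param inversion_recombination Optional recombination probability for
#'   inversion carriers (mass on the two recombinant classes).
#' @return A `segregation_weights` object.
#' @export
segregation_weights <- function(kind = c("theoretical", "realistic"),
                                convention = c("classes18", "classes16"),
                                reciprocal = NULL, robertsonian = NULL,
                                inversion_recombination = NULL) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  n40 <- if (convention == "classes18") 4L else 2L
  ntot <- 6L + 8L + n40
  if (kind == "theoretical") {
    rec <- c("alternate" = 2, "adjacent-1" = 2, "adjacent-2" = 2,
             "3:1" = 8, "4:0" = n40) / ntot
    rob <- c("rob-alternate" = 2, "rob-adjacent" = 4, "rob-3:0" = 2) / 8
    invr <- 0.5
  } else {
    rec <- c("alternate" = 0.45, "adjacent-1" = 0.30, "adjacent-2" = 0.10,
             "3:1" = 0.12, "4:0" = 0.03)
    rob <- c("rob-alternate" = 0.85, "rob-adjacent" = 0.13, "rob-3:0" = 0.02)
    invr <- 0.2
  }
  if (!is.null(reciprocal)) {
    stopifnot(all(names(reciprocal) %in% names(rec)))
    rec[names(reciprocal)] <- reciprocal
    rec <- rec / sum(rec)
  }
  if (!is.null(robertsonian)) {
    stopifnot(all(names(robertsonian) %in% names(rob)))
    rob[names(robertsonian)] <- robertsonian
    rob <- rob / sum(rob)
  }
  if (!is.null(inversion_recombination)) invr <- inversion_recombination
  stopifnot(invr >= 0, invr <= 1)
  structure(list(kind = kind, convention = convention, reciprocal = rec,
                 robertsonian = rob, inversion_recombination = invr),
            class = "segregation_weights")
}

empty_imbalance <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             delta = numeric(), fraction = numeric(), provenance = character())
}

new_gamete <- function(mode, label, segments, balanced, weight,
                       viable = TRUE, chroms = character(0)) {
  structure(list(mode = mode, label = label, segments = segments,
                 balanced = balanced, weight = weight, viable = viable,
                 chroms = chroms),
            class = "gamete_class")
}

# piecewise coverage (copies) of `segs` over the named chromosomes
coverage_profile <- function(segs, chroms, m) {
  out <- lapply(chroms, function(ch) {
    len <- m$chrom_lengths[[ch]]
    s <- segs[segs$chrom == ch, , drop = FALSE]
    cuts <- sort(unique(c(0, len, s$start, s$end)))
    st <- cuts[-length(cuts)]; en <- cuts[-1]
    cp <- vapply(seq_along(st), function(i) {
      sum(s$start <= st[i] & s$end >= en[i])
    }, 0)
    data.frame(chrom = ch, start = st, end = en, copies = cp)
  })
  do.call(rbind, out)
}

merge_equal_runs <- function(df, value_col) {
  if (nrow(df) < 2) return(df)
  keep <- list(); i <- 1
  while (i <= nrow(df)) {
    j <- i
    while (j < nrow(df) && df$chrom[j + 1] == df$chrom[i] &&
           df$start[j + 1] == df$end[j] &&
           df[[value_col]][j + 1] == df[[value_col]][i]) j <- j + 1
    row <- df[i, ]; row$end <- df$end[j]
    keep[[length(keep) + 1]] <- row
    i <- j + 1
  }
  do.call(rbind, keep)
}

#' Enumerate the gamete classes of a rearrangement carrier
#'
#' Reciprocal translocations enumerate the quadrivalent's 2:2 (alternate,
#' adjacent-1, adjacent-2), 3:1, and 4:0 segregation products; Robertsonian
#' translocations the trivalent's 2:1 and 3:0 products (8 classes, 2
#' balanced); inversions the non-recombinant and single-crossover recombinant
#' chromatids (4 classes, 2 balanced; paracentric recombinants are flagged
#' nonviable); deletion/duplication carriers transmit the normal or the
#' rearranged homolog; insertion carriers additionally produce the
#' segment-duplication and segment-deletion recombinants.
#'
#' @param r A resolved `rearrangement`, or `NULL` for a structurally normal
#'   parent (single balanced class of weight 1).
#' @param m A `cytoband_map`.
#' @param w A `segregation_weights` object.
#' @return List of `gamete_class` objects; weights sum to 1.
#' @export
enumerate_gametes <- function(r, m, w = segregation_weights()) {
  stopifnot(inherits(w, "segregation_weights"))
  if (is.null(r)) {
    return(list(new_gamete("normal", "normal", NULL, TRUE, 1)))
  }
  stopifnot(inherits(r, "rearrangement"))
  switch(r$kind,
    reciprocal_translocation = gametes_reciprocal(r, m, w),
    robertsonian_translocation = gametes_robertsonian(r, m, w),
    inversion = gametes_inversion(r, m, w),
    deletion = gametes_carried_interval(r, m, w, -1),
    duplication = gametes_carried_interval(r, m, w, +1),
    insertion = gametes_insertion(r, m, w),
    stop("unsupported rearrangement kind '", r$kind, "'"))
}

quadrivalent_elements <- function(r, m) {
  part <- segment_partition(r, m)
  chA <- r$chroms[1]; chB <- r$chroms[2]
  pick <- function(ch, role) part[part$chrom == ch & part$role == role,
                                  c("chrom", "start", "end")]
  list(
    A    = rbind(pick(chA, "centric"), pick(chA, "translocated")),
    B    = rbind(pick(chB, "centric"), pick(chB, "translocated")),
    derA = rbind(pick(chA, "centric"), pick(chB, "translocated")),
    derB = rbind(pick(chB, "centric"), pick(chA, "translocated")))
}

gamete_from_elements <- function(mode, label, elems, members, weight, m, chroms) {
  segs <- if (length(members) == 0) {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  } else do.call(rbind, elems[members])
  cov <- coverage_profile(segs, chroms, m)
  balanced <- all(cov$copies == 1)
  new_gamete(mode, label, segs, balanced, weight, chroms = chroms)
}

gametes_reciprocal <- function(r, m, w) {
  elems <- quadrivalent_elements(r, m)
  chroms <- r$chroms
  g <- function(mode, label, members, weight)
    gamete_from_elements(mode, label, elems, members, weight, m, chroms)
  mw <- w$reciprocal
  n40 <- if (w$convention == "classes18") 4L else 2L
  out <- list(
    g("alternate", "alternate/normal", c("A", "B"), mw[["alternate"]] / 2),
    g("alternate", "alternate/balanced", c("derA", "derB"), mw[["alternate"]] / 2),
    g("adjacent-1", "adjacent-1 (A,derB)", c("A", "derB"), mw[["adjacent-1"]] / 2),
    g("adjacent-1", "adjacent-1 (derA,B)", c("derA", "B"), mw[["adjacent-1"]] / 2),
    g("adjacent-2", "adjacent-2 (A,derA)", c("A", "derA"), mw[["adjacent-2"]] / 2),
    g("adjacent-2", "adjacent-2 (B,derB)", c("B", "derB"), mw[["adjacent-2"]] / 2),
    g("3:1", "3:1 (A,B,derA)", c("A", "B", "derA"), mw[["3:1"]] / 8),
    g("3:1", "3:1 (A,B,derB)", c("A", "B", "derB"), mw[["3:1"]] / 8),
    g("3:1", "3:1 (A,derA,derB)", c("A", "derA", "derB"), mw[["3:1"]] / 8),
    g("3:1", "3:1 (B,derA,derB)", c("B", "derA", "derB"), mw[["3:1"]] / 8),
    g("3:1", "3:1 (derB)", "derB", mw[["3:1"]] / 8),
    g("3:1", "3:1 (derA)", "derA", mw[["3:1"]] / 8),
    g("3:1", "3:1 (B)", "B", mw[["3:1"]] / 8),
    g("3:1", "3:1 (A)", "A", mw[["3:1"]] / 8),
    g("4:0", "4:0 (all)", c("A", "B", "derA", "derB"), mw[["4:0"]] / n40),
    g("4:0", "4:0 (none)", character(0), mw[["4:0"]] / n40))
  if (w$convention == "classes18") {
    out <- c(out, list(
      g("4:0", "4:0 (all)", c("A", "B", "derA", "derB"), mw[["4:0"]] / n40),
      g("4:0", "4:0 (none)", character(0), mw[["4:0"]] / n40)))
  }
  out
}

gametes_robertsonian <- function(r, m, w) {
  chA <- r$chroms[1]; chB <- r$chroms[2]
  whole <- function(ch) data.frame(chrom = ch, start = 0,
                                   end = m$chrom_lengths[[ch]])
  # der(A;B) carries the full dosage-relevant content of both acrocentrics
  # (the lost short arms are satellite material, ignored for copy number)
  elems <- list(A = whole(chA), B = whole(chB), der = rbind(whole(chA), whole(chB)))
  g <- function(mode, label, members, weight)
    gamete_from_elements(mode, label, elems, members, weight, m, r$chroms)
  mw <- w$robertsonian
  list(
    g("rob-alternate", "alternate/normal", c("A", "B"), mw[["rob-alternate"]] / 2),
    g("rob-alternate", "alternate/balanced der", "der", mw[["rob-alternate"]] / 2),
    g("rob-adjacent", paste0("adjacent (der,", chA, ")"), c("der", "A"),
      mw[["rob-adjacent"]] / 4),
    g("rob-adjacent", paste0("adjacent (der,", chB, ")"), c("der", "B"),
      mw[["rob-adjacent"]] / 4),
    g("rob-adjacent", paste0("adjacent (", chA, ")"), "A", mw[["rob-adjacent"]] / 4),
    g("rob-adjacent", paste0("adjacent (", chB, ")"), "B", mw[["rob-adjacent"]] / 4),
    g("rob-3:0", "3:0 (all)", c("der", "A", "B"), mw[["rob-3:0"]] / 2),
    g("rob-3:0", "3:0 (none)", character(0), mw[["rob-3:0"]] / 2))
}

gametes_inversion <- function(r, m, w) {
  part <- segment_partition(r, m)
  ch <- r$chroms[1]
  seg <- function(role) part[part$role == role, c("chrom", "start", "end")]
  whole <- data.frame(chrom = ch, start = 0, end = m$chrom_lengths[[ch]])
  rec_viable <- identical(r$subtype, "pericentric")
  p_rec <- w$inversion_recombination
  cov <- function(segs) coverage_profile(segs, ch, m)
  mk <- function(mode, label, segs, weight, viable = TRUE) {
    cc <- cov(segs)
    new_gamete(mode, label, segs, all(cc$copies == 1), weight, viable,
               chroms = ch)
  }
  list(
    mk("non-recombinant", "normal", whole, (1 - p_rec) / 2),
    mk("non-recombinant", "inversion carrier", whole, (1 - p_rec) / 2),
    mk("recombinant", "recombinant dup(left)+del(right)",
       rbind(seg("left_flank"), seg("left_flank"), seg("inverted")),
       p_rec / 2, rec_viable),
    mk("recombinant", "recombinant dup(right)+del(left)",
       rbind(seg("right_flank"), seg("right_flank"), seg("inverted")),
       p_rec / 2, rec_viable))
}

gametes_carried_interval <- function(r, m, w, sign) {
  ch <- r$interval$chrom
  len <- m$chrom_lengths[[ch]]
  whole <- data.frame(chrom = ch, start = 0, end = len)
  iv <- data.frame(chrom = ch, start = r$interval$start, end = r$interval$end)
  carried <- if (sign < 0) {
    # deleted homolog: whole chromosome minus the interval
    data.frame(chrom = ch, start = c(0, iv$end), end = c(iv$start, len))
  } else rbind(whole, iv)
  carried <- carried[carried$end > carried$start, , drop = FALSE]
  label <- if (sign < 0) "deletion carrier homolog" else "duplication carrier homolog"
  list(
    new_gamete("normal", "normal homolog", whole, TRUE, 0.5, chroms = ch),
    new_gamete("normal", label, carried,
               all(coverage_profile(carried, ch, m)$copies == 1), 0.5,
               chroms = ch))
}

gametes_insertion <- function(r, m, w) {
  # balanced insertion carrier: normal, balanced, segment-duplication,
  # segment-deletion products (uniform weights)
  donor <- r$interval$chrom
  len <- m$chrom_lengths[[donor]]
  whole <- data.frame(chrom = donor, start = 0, end = len)
  iv <- data.frame(chrom = donor, start = r$interval$start, end = r$interval$end)
  del_hom <- data.frame(chrom = donor, start = c(0, iv$end), end = c(iv$start, len))
  del_hom <- del_hom[del_hom$end > del_hom$start, , drop = FALSE]
  list(
    new_gamete("normal", "normal", whole, TRUE, 0.25, chroms = donor),
    new_gamete("normal", "balanced insertion carrier", whole, TRUE, 0.25,
               chroms = donor),
    new_gamete("recombinant", "segment duplication", rbind(whole, iv), FALSE,
               0.25, chroms = donor),
    new_gamete("recombinant", "segment deletion", del_hom, FALSE, 0.25,
               chroms = donor))
}

#' Copy-number imbalance of a gamete relative to a balanced haploid set
#'
#' @param g A `gamete_class`.
#' @param m A `cytoband_map`.
#' @return An imbalance profile data.frame (chrom, start, end, delta,
#'   fraction, provenance); empty for balanced gametes. Deltas are per-region
#'   copy differences vs one haploid copy.
#' @export
gamete_imbalance <- function(g, m) {
  stopifnot(inherits(g, "gamete_class"))
  if (is.null(g$segments) || g$balanced) return(empty_imbalance())
  chroms <- g$chroms
  if (length(chroms) == 0) chroms <- unique(g$segments$chrom)
  if (length(chroms) == 0) return(empty_imbalance())
  cov <- coverage_profile(g$segments, chroms, m)
  cov$delta <- cov$copies - 1
  cov <- cov[cov$delta != 0, c("chrom", "start", "end", "delta")]
  if (nrow(cov) == 0) return(empty_imbalance())
  cov <- merge_equal_runs(cov, "delta")
  cov$fraction <- 1
  cov$provenance <- "parental-rearrangement"
  rownames(cov) <- NULL
  cov
}

#' Theoretical probability that a couple produces a euploid conceptus
#'
#' Product over the two parents of the balanced-gamete probability mass from
#' [enumerate_gametes()]. Under theoretical (uniform) weights the result is
#' exact rational arithmetic: a reciprocal-translocation carrier contributes
#' 2/18 = 1/9 under the default 18-class counting, so a couple of two
#' independent reciprocal carriers yields 1/81. De novo errors are outside
#' this meiotic model (normal x normal gives 1).
#'
#' @param km,kf Parsed parental `karyotype`s (maternal, paternal).
#' @param m A `cytoband_map`.
#' @param w A `segregation_weights` object.
#' @return An object of class `euploid_probability`: list with `value` and,
#'   under theoretical weights, exact integer `numerator`/`denominator`.
#' @export
couple_euploid_probability <- function(km, kf, m = cytoband_map(),
                                       w = segregation_weights()) {
  parent_mass <- function(k) {
    k <- resolve_breakpoints(k, m)
    num <- 1L; den <- 1L; val <- 1
    for (r in k$rearrangements) {
      gam <- enumerate_gametes(r, m, w)
      bal <- sum(vapply(gam, function(g) if (g$balanced) g$weight else 0, 0))
      val <- val * bal
      nb <- sum(vapply(gam, function(g) g$balanced, TRUE))
      num <- num * nb
      den <- den * length(gam)
    }
    list(val = val, num = num, den = den)
  }
  pm <- parent_mass(km); pf <- parent_mass(kf)
  value <- pm$val * pf$val
  if (w$kind == "theoretical") {
    num <- pm$num * pf$num; den <- pm$den * pf$den
    g <- gcd_int(num, den)
    out <- list(value = num / den, numerator = num %/% g, denominator = den %/% g)
  } else {
    out <- list(value = value, numerator = NA_integer_, denominator = NA_integer_)
  }
  structure(out, class = "euploid_probability")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' @export
print.euploid_probability <- function(x, ...) {
  if (!is.na(x$numerator)) {
    cat(sprintf("euploid probability = %d/%d (%.5f)\n",
                x$numerator, x$denominator, x$value))
  } else {
    cat(sprintf("euploid probability = %.5f\n", x$value))
  }
  invisible(x)
}

#' Expected copy-number profile of a zygote from two gametes
#'
#' Per region, expected copy number is 2 plus the sum of the parental gamete
#' deltas; a euploid zygote has an empty profile.
#'
#' @param gm,gf Maternal and paternal `gamete_class` objects.
#' @param m A `cytoband_map`.
#' @return Imbalance profile data.frame at the zygote (diploid) level.
#' @export
zygote_profile <- function(gm, gf, m) {
  pm <- gamete_imbalance(gm, m)
  pf <- gamete_imbalance(gf, m)
  combine_imbalances(list(pm, pf), m)
}

# sum a list of imbalance profiles on the diploid baseline; error below zero
combine_imbalances <- function(profiles, m) {
  all <- do.call(rbind, profiles)
  if (is.null(all) || nrow(all) == 0) return(empty_imbalance())
  out <- lapply(unique(all$chrom), function(ch) {
    s <- all[all$chrom == ch, , drop = FALSE]
    cuts <- sort(unique(c(s$start, s$end)))
    st <- cuts[-length(cuts)]; en <- cuts[-1]
    delta <- vapply(seq_along(st), function(i) {
      sum(s$delta[s$start <= st[i] & s$end >= en[i]] *
            s$fraction[s$start <= st[i] & s$end >= en[i]])
    }, 0)
    keep <- delta != 0
    if (any(2 + delta < 0))
      stop("impossible zygote: expected copy number below zero on chromosome ", ch)
    data.frame(chrom = ch, start = st[keep], end = en[keep], delta = delta[keep])
  })
  out <- do.call(rbind, out)
  if (nrow(out) == 0) return(empty_imbalance())
  out <- merge_equal_runs(out, "delta")
  out$fraction <- 1
  out$provenance <- "parental-rearrangement"
  rownames(out) <- NULL
  out
}

#' Dump a gamete enumeration as a table
#'
#' @param gametes List of `gamete_class` from [enumerate_gametes()].
#' @return data.frame with mode, label, segment summary, balanced flag,
#'   viability and weight (counselling-style report).
#' @export
gamete_table <- function(gametes) {
  do.call(rbind, lapply(gametes, function(g) {
    segs <- if (is.null(g$segments) || nrow(g$segments) == 0) "" else
      paste(sprintf("%s:%.1f-%.1fMb", g$segments$chrom,
                    g$segments$start / 1e6, g$segments$end / 1e6), collapse = ",")
    data.frame(mode = g$mode, label = g$label, segments = segs,
               balanced = g$balanced, viable = g$viable, weight = g$weight)
  }))
}
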