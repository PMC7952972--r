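#' @title ISCN karyotype parsing
#' @description Parse the ISCN subset used in PGT-SR referral karyotypes:
#' reciprocal translocations `t(A;B)(bandA;bandB)`, Robertsonian
#' translocations `rob(A;B)(q10;q10)` / `der(A;B)(q10;q10)`, inversions
#' `inv(A)(band1band2)`, deletions/duplications `del|dup(A)(band1[band2])`,
#' and insertions `ins(A;B)(band;band1band2)` / `ins(A)(band1band2band3)`.
#' Everything outside this subset raises an explicit "unsupported" error;
#' a malformed term raises a parse error naming the offending token.
#' @name karyotype-parsing
NULL

CHROM_RE <- "(?:[0-9]{1,2}|X|Y)"
BAND_RE <- "[pq][0-9]+(?:\\.[0-9]+)?"

pgt_parse_error <- function(msg, token) {
  stop(structure(class = c("pgtcnv_parse_error", "error", "condition"),
                 list(message = paste0(msg, ": '", token, "'"), call = NULL)))
}

pgt_unsupported_error <- function(token) {
  stop(structure(class = c("pgtcnv_unsupported_error", "error", "condition"),
                 list(message = paste0("unsupported ISCN construct: '", token, "'"),
                      call = NULL)))
}

new_rearrangement <- function(kind, chroms, bands, subtype = NA_character_) {
  structure(list(kind = kind, chroms = chroms, bands = bands,
                 subtype = subtype, breakpoints = NULL),
            class = "rearrangement")
}

# split on commas that are not inside parentheses
split_terms <- function(x) {
  depth <- 0L
  out <- character()
  cur <- ""
  for (chs in strsplit(x, "")[[1]]) {
    if (chs == "(") depth <- depth + 1L
    if (chs == ")") depth <- depth - 1L
    if (chs == "," && depth == 0L) {
      out <- c(out, cur); cur <- ""
    } else cur <- paste0(cur, chs)
  }
  c(out, cur)
}

#' Parse an ISCN karyotype string
#'
#' @param iscn Karyotype string, e.g. `"46,XX,t(2;8)(q24;p22)"`. Whitespace
#'   is ignored.
#' @return A `karyotype` object with fields `modal` (integer), `sex`
#'   ("XX", "XY", "X", ...), `rearrangements` (list of `rearrangement`),
#'   and `raw` (the normalized string).
#' @examples
#' k <- parse_karyotype("46,XX,t(2;8)(q24;p22)")
#' k$rearrangements[[1]]$kind
#' @export
parse_karyotype <- function(iscn) {
  stopifnot(is.character(iscn), length(iscn) == 1, nzchar(trimws(iscn)))
  s <- gsub("[[:space:]]", "", iscn)
  terms <- split_terms(s)
  if (length(terms) < 2) pgt_parse_error("karyotype needs modal count and sex", s)
  if (!grepl("^[0-9]{2}$", terms[1]))
    pgt_parse_error("bad modal chromosome count", terms[1])
  modal <- as.integer(terms[1])
  if (!grepl("^[XY]{1,2}$", terms[2]))
    pgt_parse_error("bad sex designation", terms[2])
  sex <- terms[2]
  rearr <- lapply(terms[-(1:2)], parse_term)
  structure(list(modal = modal, sex = sex, rearrangements = rearr,
                 raw = format_karyotype_fields(modal, sex, rearr)),
            class = "karyotype")
}

parse_term <- function(tok) {
  two_chrom <- function(re, kind, n_bands = 2) {
    m <- regmatches(tok, regexec(re, tok, perl = TRUE))[[1]]
    if (length(m) == 0) return(NULL)
    m
  }
  # reciprocal translocation t(2;8)(q24;p22)
  re_t <- paste0("^t\\((", CHROM_RE, ");(", CHROM_RE, ")\\)\\((", BAND_RE,
                 ");(", BAND_RE, ")\\)$")
  m <- regmatches(tok, regexec(re_t, tok, perl = TRUE))[[1]]
  if (length(m)) {
    return(new_rearrangement("reciprocal_translocation", m[2:3],
                             list(m[4], m[5])))
  }
  # Robertsonian rob(13;14)(q10;q10) or der(13;14)(q10;q10)
  re_rob <- paste0("^(?:rob|der)\\((", CHROM_RE, ");(", CHROM_RE,
                   ")\\)\\(q10;q10\\)$")
  m <- regmatches(tok, regexec(re_rob, tok, perl = TRUE))[[1]]
  if (length(m)) {
    acro <- c("13", "14", "15", "21", "22")
    if (!all(m[2:3] %in% acro))
      pgt_parse_error("Robertsonian translocation requires acrocentric chromosomes", tok)
    return(new_rearrangement("robertsonian_translocation", m[2:3],
                             list("q10", "q10")))
  }
  # inversion inv(9)(p12q13)
  re_inv <- paste0("^inv\\((", CHROM_RE, ")\\)\\((", BAND_RE, ")(", BAND_RE, ")\\)$")
  m <- regmatches(tok, regexec(re_inv, tok, perl = TRUE))[[1]]
  if (length(m)) {
    arms <- substr(c(m[3], m[4]), 1, 1)
    subtype <- if (arms[1] != arms[2]) "pericentric" else "paracentric"
    return(new_rearrangement("inversion", m[2], list(c(m[3], m[4])),
                             subtype = subtype))
  }
  # deletion / duplication del(X)(p22.2p22.33), dup(X)(q21.31q22.1), del(21)(q22.3)
  re_dd <- paste0("^(del|dup)\\((", CHROM_RE, ")\\)\\((", BAND_RE,
                  ")(", BAND_RE, ")?\\)$")
  m <- regmatches(tok, regexec(re_dd, tok, perl = TRUE))[[1]]
  if (length(m)) {
    kind <- if (m[2] == "del") "deletion" else "duplication"
    bands <- if (nzchar(m[5])) c(m[4], m[5]) else m[4]
    return(new_rearrangement(kind, m[3], list(bands)))
  }
  # bare del(21) / dup(21): breakpoints unknown, kept but unresolvable
  re_bare <- paste0("^(del|dup)\\((", CHROM_RE, ")\\)$")
  m <- regmatches(tok, regexec(re_bare, tok, perl = TRUE))[[1]]
  if (length(m)) {
    kind <- if (m[2] == "del") "deletion" else "duplication"
    return(new_rearrangement(kind, m[3], list(character(0))))
  }
  # insertion: ins(A)(b1b2b3) within-chromosome, ins(A;B)(b;b1b2) between
  re_ins1 <- paste0("^ins\\((", CHROM_RE, ")\\)\\((", BAND_RE, ")(", BAND_RE,
                    ")(", BAND_RE, ")\\)$")
  m <- regmatches(tok, regexec(re_ins1, tok, perl = TRUE))[[1]]
  if (length(m)) {
    return(new_rearrangement("insertion", m[2], list(c(m[3], m[4], m[5]))))
  }
  re_ins2 <- paste0("^ins\\((", CHROM_RE, ");(", CHROM_RE, ")\\)\\((", BAND_RE,
                    ");(", BAND_RE, ")(", BAND_RE, ")\\)$")
  m <- regmatches(tok, regexec(re_ins2, tok, perl = TRUE))[[1]]
  if (length(m)) {
    return(new_rearrangement("insertion", m[2:3], list(m[4], c(m[5], m[6]))))
  }
  # a supported constructor with a malformed body is a parse error;
  # recognizable-but-unsupported ISCN constructs raise "unsupported"
  if (grepl("^(t|rob|der|inv|del|dup|ins)\\(", tok))
    pgt_parse_error("malformed karyotype term", tok)
  if (grepl("^(r|mar|idic|i|add|\\+|-)", tok))
    pgt_unsupported_error(tok)
  pgt_parse_error("unparseable karyotype term", tok)
}

format_karyotype_fields <- function(modal, sex, rearr) {
  terms <- vapply(rearr, format_rearrangement, "")
  paste(c(modal, sex, terms), collapse = ",")
}

format_rearrangement <- function(r) {
  bj <- function(b) paste(b, collapse = "")
  switch(r$kind,
    reciprocal_translocation = sprintf("t(%s;%s)(%s;%s)", r$chroms[1], r$chroms[2],
                                       r$bands[[1]], r$bands[[2]]),
    robertsonian_translocation = sprintf("rob(%s;%s)(q10;q10)",
                                         r$chroms[1], r$chroms[2]),
    inversion = sprintf("inv(%s)(%s)", r$chroms[1], bj(r$bands[[1]])),
    deletion = if (length(r$bands[[1]]) == 0) sprintf("del(%s)", r$chroms[1])
               else sprintf("del(%s)(%s)", r$chroms[1], bj(r$bands[[1]])),
    duplication = if (length(r$bands[[1]]) == 0) sprintf("dup(%s)", r$chroms[1])
                  else sprintf("dup(%s)(%s)", r$chroms[1], bj(r$bands[[1]])),
    insertion = if (length(r$chroms) == 1)
                  sprintf("ins(%s)(%s)", r$chroms[1], bj(r$bands[[1]]))
                else sprintf("ins(%s;%s)(%s;%s)", r$chroms[1], r$chroms[2],
                             r$bands[[1]], bj(r$bands[[2]])),
    stop("unknown rearrangement kind"))
}

#' @export
format.karyotype <- function(x, ...) x$raw

#' @export
print.karyotype <- function(x, ...) {
  cat("<karyotype> ", x$raw, "\n", sep = "")
  invisible(x)
}

#' Resolve band-level breakpoints to genomic intervals
#'
#' Each breakpoint band is annotated with its full bp interval from the band
#' map; a band pair (deletion/duplication/inversion span) resolves to the
#' hull of the two band intervals. Band-level breakpoints used downstream
#' are placed at the band midpoint.
#'
#' @param k A `karyotype` from [parse_karyotype()].
#' @param m A `cytoband_map`.
#' @return The karyotype with each rearrangement carrying a `breakpoints`
#'   data.frame (chrom, band, start, end) and, for span-type rearrangements,
#'   an `interval` field (chrom, start, end).
#' @export
resolve_breakpoints <- function(k, m) {
  stopifnot(inherits(k, "karyotype"), inherits(m, "cytoband_map"))
  k$rearrangements <- lapply(k$rearrangements, resolve_rearrangement, m = m)
  k
}

resolve_rearrangement <- function(r, m) {
  look <- function(chrom, band) {
    iv <- band_interval(m, chrom, band)
    data.frame(chrom = chrom, band = band, start = iv[1], end = iv[2])
  }
  if (r$kind %in% c("deletion", "duplication")) {
    bands <- r$bands[[1]]
    if (length(bands) == 0)
      stop("cannot resolve ", r$kind, " on chromosome ", r$chroms[1],
           ": no bands given in the karyotype")
    bp <- do.call(rbind, lapply(bands, look, chrom = r$chroms[1]))
    r$breakpoints <- bp
    r$interval <- data.frame(chrom = r$chroms[1],
                             start = min(bp$start), end = max(bp$end))
  } else if (r$kind == "inversion") {
    bp <- do.call(rbind, lapply(r$bands[[1]], look, chrom = r$chroms[1]))
    r$breakpoints <- bp
  } else if (r$kind == "insertion") {
    bp <- do.call(rbind, Map(function(ch, bands) {
      do.call(rbind, lapply(bands, look, chrom = ch))
    }, as.list(if (length(r$chroms) == 1) r$chroms else r$chroms),
       r$bands[seq_along(r$chroms)]))
    r$breakpoints <- bp
    seg_bands <- r$bands[[length(r$bands)]]
    donor <- r$chroms[length(r$chroms)]
    segi <- do.call(rbind, lapply(utils::tail(seg_bands, 2), look, chrom = donor))
    r$interval <- data.frame(chrom = donor, start = min(segi$start),
                             end = max(segi$end))
  } else {
    r$breakpoints <- do.call(rbind, Map(function(ch, b) look(ch, b),
                                        r$chroms, unlist(r$bands)))
  }
  r
}

band_midpoint <- function(bp_row) (bp_row$start + bp_row$end) / 2

#' Partition the involved chromosomes of a rearrangement into segments
#'
#' For a reciprocal translocation on A;B, four segments (A-centric,
#' A-translocated, B-centric, B-translocated) cut at the band midpoints;
#' for a Robertsonian, the two acrocentric long arms; for an inversion, the
#' inverted interval plus its flanks; for a deletion/duplication/insertion,
#' the carried interval and its flanks.
#'
#' @param r A resolved `rearrangement` (see [resolve_breakpoints()]).
#' @param m A `cytoband_map`.
#' @return data.frame with columns chrom, start, end, role.
#' @export
segment_partition <- function(r, m) {
  stopifnot(inherits(r, "rearrangement"))
  if (is.null(r$breakpoints)) stop("breakpoints not resolved; call resolve_breakpoints()")
  lens <- m$chrom_lengths
  cens <- m$centromeres
  if (r$kind == "reciprocal_translocation") {
    out <- lapply(1:2, function(i) {
      ch <- r$chroms[i]
      cut <- band_midpoint(r$breakpoints[i, ])
      cen <- cens[[ch]]
      if (cut >= cen) {
        data.frame(chrom = ch, start = c(0, cut), end = c(cut, lens[[ch]]),
                   role = c("centric", "translocated"))
      } else {
        data.frame(chrom = ch, start = c(0, cut), end = c(cut, lens[[ch]]),
                   role = c("translocated", "centric"))
      }
    })
    do.call(rbind, out)
  } else if (r$kind == "robertsonian_translocation") {
    do.call(rbind, lapply(r$chroms, function(ch) {
      data.frame(chrom = ch, start = cens[[ch]], end = lens[[ch]], role = "q_arm")
    }))
  } else if (r$kind == "inversion") {
    ch <- r$chroms[1]
    cuts <- sort(c(band_midpoint(r$breakpoints[1, ]),
                   band_midpoint(r$breakpoints[2, ])))
    out <- data.frame(chrom = ch, start = c(0, cuts[1], cuts[2]),
                      end = c(cuts[1], cuts[2], lens[[ch]]),
                      role = c("left_flank", "inverted", "right_flank"))
    out[out$end > out$start, , drop = FALSE]
  } else if (r$kind %in% c("deletion", "duplication", "insertion")) {
    ch <- r$interval$chrom
    s <- r$interval$start; e <- r$interval$end
    out <- data.frame(chrom = ch, start = c(0, s, e),
                      end = c(s, e, lens[[ch]]),
                      role = c("left_flank", "interval", "right_flank"))
    out[out$end > out$start, , drop = FALSE]
  } else stop("unknown rearrangement kind '", r$kind, "'")
}
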