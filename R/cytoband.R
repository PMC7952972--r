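#' Load a cytogenetic band map
#'
#' Reads a band map TSV (columns chrom, start, end, band, stain; 0-based
#' half-open coordinates) and validates that bands tile every chromosome.
#' The default is the bundled synthetic hg19-compatible map: chromosome
#' lengths and centromere positions are standard hg19 values, band names are
#' the ISCN major-band lists, and band boundaries are spaced uniformly within
#' each arm (a declared convention, not measured band sizes).
#'
#' @param path Path to a band map TSV. `NULL` loads the bundled map.
#' @return A `cytoband_map` object: list with `bands` (data.frame), named
#'   numeric vectors `chrom_lengths` and `centromeres`, and `chroms` in
#'   karyotype order.
#' @export
cytoband_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cytoband_hg19_synthetic.tsv",
                        package = "pgtcnv", mustWork = TRUE)
  }
  bands <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                             col.names = c("chrom", "start", "end", "band", "stain"),
                             colClasses = c("character", "numeric", "numeric",
                                            "character", "character"))
  new_cytoband_map(bands)
}

new_cytoband_map <- function(bands) {
  chroms <- unique(bands$chrom)
  lens <- vapply(chroms, function(ch) max(bands$end[bands$chrom == ch]), 0)
  cens <- vapply(chroms, function(ch) {
    b <- bands[bands$chrom == ch, ]
    qb <- b[grepl("^q", b$band), ]
    if (nrow(qb) == 0) return(0) # toy chromosomes may be all-q
    min(qb$start)
  }, 0)
  m <- structure(list(bands = bands, chrom_lengths = lens,
                      centromeres = cens, chroms = chroms),
                 class = "cytoband_map")
  validate_cytoband_map(m)
  m
}

validate_cytoband_map <- function(m) {
  for (ch in m$chroms) {
    b <- m$bands[m$bands$chrom == ch, ]
    b <- b[order(b$start), ]
    if (b$start[1] != 0) stop("bands on ", ch, " do not start at 0")
    if (any(b$start[-1] != b$end[-nrow(b)]))
      stop("bands on ", ch, " are not contiguous")
    if (any(b$end <= b$start)) stop("empty band on ", ch)
  }
  invisible(m)
}

#' @export
print.cytoband_map <- function(x, ...) {
  cat("<cytoband_map> ", length(x$chroms), " chromosomes, ",
      nrow(x$bands), " bands, total ",
      round(sum(x$chrom_lengths) / 1e6), " Mb\n", sep = "")
  invisible(x)
}

#' Build a reduced synthetic genome for fast tests
#'
#' A small genome of identical metacentric chromosomes (labels "1", "2", ...),
#' each with four uniform bands (p12, p11, q11, q12). Desk-scale stand-in for
#' the full band map in simulation and caller tests.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return A `cytoband_map`.
#' @export
toy_cytoband_map <- function(n_chrom = 3, chrom_length = 5e7) {
  stopifnot(n_chrom >= 1, chrom_length >= 4e6)
  e <- round(seq(0, chrom_length, length.out = 5))
  rows <- lapply(as.character(seq_len(n_chrom)), function(ch) {
    data.frame(chrom = ch, start = e[1:4], end = e[2:5],
               band = c("p12", "p11", "q11", "q12"),
               stain = c("gneg", "acen", "acen", "gneg"))
  })
  new_cytoband_map(do.call(rbind, rows))
}

#' Look up the genomic interval of a cytogenetic band
#'
#' Sub-band names absent from the map fall back to their parent band
#' ("q22.31" -> "q22.3" -> "q22"). The ISCN centromere symbols "p10"/"q10"
#' resolve to the centromere-adjacent band of the respective arm.
#'
#' @param m A `cytoband_map`.
#' @param chrom Chromosome label ("1".."22", "X", "Y").
#' @param band Band name, e.g. "q22.3".
#' @return Numeric `c(start, end)` in bp (0-based half-open).
#' @export
band_interval <- function(m, chrom, band) {
  stopifnot(inherits(m, "cytoband_map"))
  if (!chrom %in% m$chroms) stop("unknown chromosome '", chrom, "'")
  b <- m$bands[m$bands$chrom == chrom, ]
  b <- b[order(b$start), ]
  if (band %in% c("p10", "q10")) {
    arm <- b[substr(b$band, 1, 1) == substr(band, 1, 1), ]
    if (nrow(arm) == 0) stop("chromosome ", chrom, " has no ", substr(band, 1, 1), " arm")
    # centromere-adjacent band of the arm
    row <- if (band == "p10") arm[nrow(arm), ] else arm[1, ]
    return(c(row$start, row$end))
  }
  cand <- band
  while (!cand %in% b$band && grepl("\\.", cand)) {
    cand <- sub("\\.?[0-9]$", "", cand)   # strip one trailing sub-band digit
    cand <- sub("\\.$", "", cand)
  }
  if (!cand %in% b$band) {
    # also try major band prefix of an un-dotted sub-band ("q221" style not used)
    stop("unknown band '", band, "' on chromosome ", chrom)
  }
  row <- b[b$band == cand, ][1, ]
  c(row$start, row$end)
}
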