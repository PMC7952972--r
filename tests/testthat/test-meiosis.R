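rec_t28 <- function(m) {
  k <- resolve_breakpoints(parse_karyotype("46,XX,t(2;8)(q24;p22)"), m)
  k$rearrangements[[1]]
}

test_that("reciprocal translocation enumerations have the documented class counts", {
  m <- fx_map()
  r <- rec_t28(m)
  g18 <- enumerate_gametes(r, m, segregation_weights())
  expect_length(g18, 18)
  expect_equal(sum(vapply(g18, function(g) g$balanced, TRUE)), 2L)
  expect_equal(sum(vapply(g18, function(g) g$weight, 0)), 1)
  # uniform weights under the theoretical convention
  expect_true(all(abs(vapply(g18, function(g) g$weight, 0) - 1 / 18) < 1e-12))

  g16 <- enumerate_gametes(r, m, segregation_weights(convention = "classes16"))
  expect_length(g16, 16)
  expect_equal(sum(vapply(g16, function(g) g$balanced, TRUE)), 2L)
  expect_equal(sum(vapply(g16, function(g) g$weight, 0)), 1)
})

test_that("enumeration matches a brute-force subset oracle of the quadrivalent", {
  m <- fx_map()
  r <- rec_t28(m)
  g16 <- enumerate_gametes(r, m, segregation_weights(convention = "classes16"))
  # oracle: enumerate all subsets of the 4 quadrivalent elements and bucket
  # by arity; element content built independently from the partition table
  part <- segment_partition(r, m)
  pick <- function(ch, role) part[part$chrom == ch & part$role == role,
                                  c("chrom", "start", "end")]
  elems <- list(A = rbind(pick("2", "centric"), pick("2", "translocated")),
                B = rbind(pick("8", "centric"), pick("8", "translocated")),
                derA = rbind(pick("2", "centric"), pick("8", "translocated")),
                derB = rbind(pick("8", "centric"), pick("2", "translocated")))
  key <- function(df) {
    if (nrow(df) == 0) return("")
    df <- df[order(df$chrom, df$start, df$end), ]
    paste(df$chrom, df$start, df$end, sep = ":", collapse = "|")
  }
  subsets <- unlist(lapply(0:4, function(k) {
    combn(names(elems), k, simplify = FALSE)
  }), recursive = FALSE)
  oracle_keys <- sort(vapply(subsets, function(s) {
    key(if (length(s)) do.call(rbind, elems[s]) else elems$A[0, ])
  }, ""))
  enum_keys <- sort(vapply(g16, function(g) key(g$segments), ""))
  expect_equal(enum_keys, oracle_keys)
})

test_that("complementary 2:2 gametes jointly contain the full quadrivalent", {
  m <- fx_map()
  r <- rec_t28(m)
  g <- enumerate_gametes(r, m, segregation_weights(convention = "classes16"))
  pairs <- list(c(1, 2), c(3, 4), c(5, 6))  # alternate, adjacent-1, adjacent-2
  full_len <- sum(m$chrom_lengths[c("2", "8")])
  for (p in pairs) {
    segs <- rbind(g[[p[1]]]$segments, g[[p[2]]]$segments)
    cov <- pgtcnv:::coverage_profile(segs, c("2", "8"), m)
    expect_true(all(cov$copies == 2))  # two full haploid complements
    expect_equal(sum(as.numeric(segs$end) - as.numeric(segs$start)),
                 2 * unname(full_len))
  }
})

test_that("Robertsonian trivalent yields 8 classes with the expected imbalances", {
  m <- fx_map()
  k <- resolve_breakpoints(parse_karyotype("45,XY,rob(13;14)(q10;q10)"), m)
  g <- enumerate_gametes(k$rearrangements[[1]], m, segregation_weights())
  expect_length(g, 8)
  expect_equal(sum(vapply(g, function(x) x$balanced, TRUE)), 2L)
  expect_equal(sum(vapply(g, function(x) x$weight, 0)), 1)
  imb <- lapply(g, gamete_imbalance, m = m)
  lab <- vapply(seq_along(g), function(i) {
    p <- imb[[i]]
    if (nrow(p) == 0) return("balanced")
    paste(sprintf("%s%+d", p$chrom, p$delta), collapse = ",")
  }, "")
  # unbalanced products cover trisomy/monosomy of each acrocentric and the 3:0 pair
  expect_setequal(unique(lab), c("balanced", "13+1", "14+1", "14-1", "13-1",
                                 "13+1,14+1", "13-1,14-1"))
})

test_that("inversion gametes: pericentric recombinants are dup+del, paracentric nonviable", {
  m <- fx_map()
  k <- resolve_breakpoints(parse_karyotype("46,XX,inv(9)(p12q13)"), m)
  g <- enumerate_gametes(k$rearrangements[[1]], m, segregation_weights())
  expect_length(g, 4)
  expect_equal(sum(vapply(g, function(x) x$balanced, TRUE)), 2L)
  rec <- Filter(function(x) x$mode == "recombinant", g)
  expect_true(all(vapply(rec, function(x) x$viable, TRUE)))
  p <- gamete_imbalance(rec[[1]], m)
  expect_setequal(p$delta, c(1, -1))  # duplicated flank + deleted flank
  # flanks are outside the inverted segment
  part <- segment_partition(k$rearrangements[[1]], m)
  invseg <- part[part$role == "inverted", ]
  expect_true(all(p$end <= invseg$start | p$start >= invseg$end))

  kpara <- resolve_breakpoints(parse_karyotype("46,XX,inv(2)(q21q31)"), m)
  gp <- enumerate_gametes(kpara$rearrangements[[1]], m, segregation_weights())
  recp <- Filter(function(x) x$mode == "recombinant", gp)
  expect_true(all(!vapply(recp, function(x) x$viable, TRUE)))
})

test_that("adjacent-1 imbalance is the reciprocal partial trisomy/monosomy pair", {
  m <- fx_map()
  r <- rec_t28(m)
  g <- enumerate_gametes(r, m, segregation_weights())
  adj1 <- Filter(function(x) x$mode == "adjacent-1", g)[[1]]  # {A, derB}
  p <- gamete_imbalance(adj1, m)
  # oracle: cut positions computed independently from band midpoints
  cut2 <- mean(band_interval(m, "2", "q24"))
  cut8 <- mean(band_interval(m, "8", "p22"))
  expect_equal(nrow(p), 2)
  gain <- p[p$delta == 1, ]; loss <- p[p$delta == -1, ]
  expect_equal(gain$chrom, "2")
  expect_equal(c(gain$start, gain$end), c(cut2, unname(m$chrom_lengths[["2"]])))
  expect_equal(loss$chrom, "8")
  expect_equal(c(loss$start, loss$end), c(0, cut8))
})

test_that("weights sum to one across kinds, conventions and weight sets", {
  m <- fx_map()
  rs <- list(
    rec_t28(m),
    resolve_breakpoints(parse_karyotype("45,XY,rob(13;14)(q10;q10)"),
                        m)$rearrangements[[1]],
    resolve_breakpoints(parse_karyotype("46,XX,inv(9)(p12q13)"),
                        m)$rearrangements[[1]],
    resolve_breakpoints(parse_karyotype("46,XX,del(21)(q22.3)"),
                        m)$rearrangements[[1]])
  for (r in rs) {
    for (w in list(segregation_weights(), segregation_weights("realistic"),
                   segregation_weights(convention = "classes16"),
                   segregation_weights(reciprocal = c("4:0" = 0)))) {
      g <- enumerate_gametes(r, m, w)
      expect_equal(sum(vapply(g, function(x) x$weight, 0)), 1)
    }
  }
})

test_that("couple euploidy probability reproduces the double-carrier 1/81", {
  m <- fx_map()
  km <- parse_karyotype("46,XX,t(2;8)(q24;p22)")
  kf <- parse_karyotype("46,XY,t(11;22)(q23;q11.2)")
  p <- couple_euploid_probability(km, kf, m)
  expect_equal(p$numerator, 1)
  expect_equal(p$denominator, 81)

  # single carrier x normal = 1/9; normal x normal = 1
  p1 <- couple_euploid_probability(km, parse_karyotype("46,XY"), m)
  expect_equal(c(p1$numerator, p1$denominator), c(1, 9))
  p0 <- couple_euploid_probability(parse_karyotype("46,XX"),
                                   parse_karyotype("46,XY"), m)
  expect_equal(p0$value, 1)

  # distinct-composition convention gives 1/8 per carrier
  p16 <- couple_euploid_probability(km, parse_karyotype("46,XY"), m,
                                    segregation_weights(convention = "classes16"))
  expect_equal(c(p16$numerator, p16$denominator), c(1, 8))

  # multiplicative over parents and bounded
  pr <- couple_euploid_probability(km, kf, m)
  expect_equal(pr$value, p1$value *
                 couple_euploid_probability(parse_karyotype("46,XX"), kf, m)$value)
  expect_true(pr$value >= 0 && pr$value <= 1)
})

test_that("zygote profiles add parental deltas on the diploid baseline", {
  m <- fx_map()
  r <- rec_t28(m)
  g <- enumerate_gametes(r, m, segregation_weights())
  bal <- Filter(function(x) x$balanced, g)[[1]]
  adj1 <- Filter(function(x) x$mode == "adjacent-1", g)[[1]]
  # balanced x balanced -> empty
  expect_equal(nrow(zygote_profile(bal, bal, m)), 0)
  # adjacent-1 x balanced -> the adjacent-1 imbalance itself
  z <- zygote_profile(adj1, bal, m)
  expect_equal(z[, c("chrom", "start", "end", "delta")],
               gamete_imbalance(adj1, m)[, c("chrom", "start", "end", "delta")])
  # 3:1 interchange-type gamete x balanced -> chromosome-scale trisomy pattern
  tri31 <- Filter(function(x) x$mode == "3:1" &&
                    nrow(x$segments) > 4, g)[[1]]  # a 3-element gamete
  z31 <- zygote_profile(tri31, bal, m)
  expect_true(all(z31$delta == 1))
  # double monosomy below zero is impossible
  none40 <- Filter(function(x) x$mode == "4:0" && nrow(x$segments) == 0, g)[[1]]
  expect_error(combine_imbalances <- pgtcnv:::combine_imbalances(
    list(gamete_imbalance(none40, m), gamete_imbalance(none40, m),
         gamete_imbalance(none40, m)), m), "below zero")
})
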