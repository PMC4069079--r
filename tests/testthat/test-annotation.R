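test_that("Fab-location codes follow the 1-14 walk over both chains", {
  # heavy: FR1(0..2) CDR1(3..5) FR2(6..7) CDR2(8..9) FR3(10..12)
  # CDR3(13..14) FR4(15..16); light analogous but shorter
  rg <- cdr_ranges(
    heavy = list(c(3L, 5L), c(8L, 9L), c(13L, 14L)),
    light = list(c(2L, 3L), c(6L, 7L), c(10L, 11L))
  )
  seqs <- list(heavy = strrep("A", 17), light = strrep("G", 14))
  ann <- annotate_regions(seqs, rg)
  h <- ann[ann$chain_role == "H", ]
  l <- ann[ann$chain_role == "L", ]
  expect_equal(h$fab_location[h$ordinal == 14], 6) # heavy CDR3
  expect_equal(h$cdr_loop[h$ordinal == 14], 3)
  expect_equal(h$fab_location[h$ordinal == 16], 7) # heavy FR4
  expect_equal(l$fab_location[l$ordinal == 13], 14) # light FR4
  expect_equal(l$cdr_loop[l$ordinal == 13], 0)
  expect_equal(l$fab_location[l$ordinal == 2], 9) # light CDR1
  # partition: every residue exactly one code; evens <=> in CDR
  expect_true(all(ann$in_cdr == (ann$fab_location %in% c(2, 4, 6, 9, 11, 13))))
  expect_true(all(ann$fab_location[ann$chain_role == "H"] <= 7))
  expect_true(all(ann$fab_location[ann$chain_role == "L"] >= 8))
  expect_equal(nrow(ann), 17 + 14)
  # concatenating regions 1..7 reproduces the heavy chain in order
  expect_equal(h$ordinal[order(h$fab_location, h$ordinal)], h$ordinal)
})

test_that("empty CDR ranges mean all-framework annotation, no error", {
  rg <- cdr_ranges(
    heavy = list(NULL, NULL, NULL),
    light = list(NULL, NULL, NULL)
  )
  ann <- annotate_regions(list(heavy = "ADGNAK", light = "GSAGSA"), rg)
  expect_true(all(!ann$in_cdr))
  expect_true(all(ann$cdr_loop == 0))
})

test_that("anchored synthetic sequences auto-detect CDR limits", {
  # heavy (1-based): E 1-21, C 22, AAA, D 26-31 (H1), W 32, G 33-52,
  # A 53-77, C 78, AA, D 81-86 (H3), WGQG 82-...
  heavy <- paste0(
    strrep("E", 21), "C", "AAA", "DDDDDD", "W",
    strrep("G", 20), strrep("A", 25), "C", "AA", "DDDDDD",
    "WGQG", "TTVSS"
  )
  light <- paste0(
    strrep("E", 22), "C", "DDDDD", "W", strrep("A", 20), "C",
    "DDDD", "FGQG", "TKV"
  )
  rg <- auto_cdr_ranges(heavy, light)
  h1 <- rg$H[[1]]
  expect_equal(h1[1], 25) # firstCys(ordinal 21) + 4
  expect_equal(substr(heavy, h1[1] + 1, h1[2] + 1), "DDDDDD")
  h3 <- rg$H[[3]]
  expect_equal(substr(heavy, h3[1] + 1, h3[2] + 1), "DDDDDD")
  l1 <- rg$L[[1]]
  expect_equal(substr(light, l1[1] + 1, l1[2] + 1), "DDDDD")
  l3 <- rg$L[[3]]
  expect_equal(substr(light, l3[1] + 1, l3[2] + 1), "DDDD")
  # failure is loud and actionable
  expect_error(auto_cdr_ranges("AAAA", "GGGG"), "auto-detection failed")
})

test_that("motif scan finds the nine motifs, CDR-restricted or not", {
  # CDR at ordinals 3..8: contains DG at 3 and NN at 6
  seqv <- "AAADGANNSAADG"
  r3 <- list(c(3L, 8L), NULL, NULL)
  hits <- motif_scan(seqv, r3, cdr_only = TRUE)
  expect_setequal(hits$motif, c("DG", "NN", "NS"))
  expect_true(all(hits$ordinal %in% 3:8))
  # full-chain scan is a superset
  all_hits <- motif_scan(seqv, r3, cdr_only = FALSE)
  expect_true(all(hits$ordinal %in% all_hits$ordinal))
  expect_true(11 %in% all_hits$ordinal) # framework DG
  # no Asn/Asp in CDR -> empty
  none <- motif_scan("AAAGGGAAA", list(c(3L, 5L), NULL, NULL))
  expect_equal(nrow(none), 0)
})

test_that("motif frequencies use CDR Asn/Asp denominators", {
  # one chain, CDR 0..5 = "DGADTA": two CDR Asp, one followed by G
  tb <- motif_frequencies("DGADTA", list(c(0L, 5L), NULL, NULL))
  expect_equal(tb$percent[tb$motif == "DG"], 50)
  expect_equal(tb$percent[tb$motif == "DT"], 50)
  expect_equal(tb$denominator[tb$motif == "DG"], 2)
  # zero denominator -> undefined, not zero
  tb0 <- motif_frequencies("AAAA", list(c(0L, 3L), NULL, NULL))
  expect_true(all(is.na(tb0$percent)))
})

test_that("planted motif counts are recovered exactly", {
  set.seed(7)
  # brute-force oracle: plant known motifs in random framework
  aas <- c("A", "G", "S", "T", "V", "L", "E", "K")
  mk <- function() paste(sample(aas, 30, replace = TRUE), collapse = "")
  seqs <- vapply(1:5, function(i) {
    s <- mk()
    # plant DG at ordinal 10 and NS at ordinal 14 (inside CDR 8..20)
    substr(s, 11, 12) <- "DG"
    substr(s, 15, 16) <- "NS"
    s
  }, character(1))
  r3 <- list(c(8L, 20L), NULL, NULL)
  tb <- motif_frequencies(seqs, r3)
  # direct string recount (CDR ordinals 8..20 are 1-based chars 9..21)
  n_d <- sum(vapply(seqs, function(s) {
    sum(strsplit(substr(s, 9, 21), "")[[1]] == "D")
  }, numeric(1)))
  n_n <- sum(vapply(seqs, function(s) {
    sum(strsplit(substr(s, 9, 21), "")[[1]] == "N")
  }, numeric(1)))
  expect_equal(tb$count[tb$motif == "DG"], 5)
  expect_equal(tb$count[tb$motif == "NS"], 5)
  expect_equal(tb$denominator[tb$motif == "DG"], n_d)
  expect_equal(tb$percent[tb$motif == "DG"], 100 * 5 / n_d)
  expect_equal(tb$percent[tb$motif == "NS"], 100 * 5 / n_n)
})
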