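test_that("the Asp tree structure matches the narrated splits node-for-node", {
  tr <- published_asp_tree()
  n1 <- tr$root
  expect_equal(n1$param, "rmsd")
  expect_equal(n1$value, 0.145)
  expect_equal(n1$yes$class, "non-hotspot")
  n2 <- n1$no
  expect_equal(n2$param, "successor_size")
  expect_equal(n2$yes$class, "non-hotspot")
  n3 <- n2$no
  expect_equal(n3$param, "rmsd")
  expect_equal(n3$value, 0.485)
  expect_equal(n3$yes$hotspot_class, 1L)
  n4 <- n3$no
  expect_equal(n4$param, "next_diff_ss_c")
  expect_equal(n4$value, 3)
  expect_equal(n4$yes$hotspot_class, 2L)
  n5 <- n4$no
  expect_equal(n5$param, "succ_aa")
  expect_equal(n5$value, "G")
  expect_equal(n5$yes$hotspot_class, 3L)
  expect_equal(n5$no$class, "non-hotspot")
  # the successor cut separates exactly {G,A,S,C,D} from the rest
  tb <- successor_size_table()
  small <- tb$aa[tb$size <= n2$value]
  expect_setequal(small, c("G", "A", "S", "C", "D"))
})

test_that("the Asn tree structure matches the narrated splits", {
  tr <- published_asn_tree()
  n1 <- tr$root
  expect_equal(n1$param, "successor_size")
  expect_equal(n1$yes$class, "non-hotspot")
  n2 <- n1$no
  expect_equal(n2$param, "rmsd")
  expect_equal(n2$value, 0.01)
  n3 <- n2$no
  expect_equal(n3$param, "successor_size")
  expect_equal(n3$value, 102.7)
  expect_equal(n3$yes$param, "cdr_loop")
  expect_equal(n3$yes$yes$hotspot_class, 1L)
  n4 <- n3$no
  expect_equal(n4$param, "phi")
  expect_equal(n4$value, -75.2)
  expect_equal(n4$yes$hotspot_class, 2L)
  expect_equal(n4$no$param, "res_sasa")
  expect_equal(n4$no$value, 89.4)
  expect_equal(n4$no$yes$param, "next_diff_ss_n")
  expect_equal(n4$no$yes$yes$hotspot_class, 3L)
  # the big-successor cut separates Asn-size from Val-size successors;
  # 102.7 partitions the table into {G,A,S,C} vs the rest
  tb <- successor_size_table()
  expect_setequal(tb$aa[tb$size <= 102.7], c("G", "A", "S", "C"))
  expect_setequal(
    tb$aa[tb$size > 102.7 & tb$size <= n1$value],
    c("D", "P", "T", "N")
  )
})

test_that("hand-traced vectors reach each narrated hotspot class", {
  asp <- published_asp_tree()
  asn <- published_asn_tree()
  # Asp class 1: very high flexibility, small successor
  r <- classify_residue(asp_vector(rmsd = 0.60, succ_aa = "G",
    next_diff_ss_c = 5), asp)
  expect_equal(r$class, "hotspot")
  expect_equal(r$hotspot_class, 1L)
  # Asp inflexible -> non-hotspot
  r <- classify_residue(asp_vector(rmsd = 0.05), asp)
  expect_equal(r$class, "non-hotspot")
  # Asp class 2: moderate flexibility, nearby C-terminal SS change
  r <- classify_residue(asp_vector(rmsd = 0.30, succ_aa = "S",
    next_diff_ss_c = 2), asp)
  expect_equal(r$hotspot_class, 2L)
  # Asp class 3: DG motif, moderate flexibility, distant SS change
  r <- classify_residue(asp_vector(rmsd = 0.30, succ_aa = "G",
    next_diff_ss_c = 5), asp)
  expect_equal(r$hotspot_class, 3L)
  # Asp large successor -> non-hotspot even when flexible
  r <- classify_residue(asp_vector(rmsd = 0.60, succ_aa = "W"), asp)
  expect_equal(r$class, "non-hotspot")
  # Asn class 2: small successor, flexible, phi < -75.2
  r <- classify_residue(asn_vector(succ_aa = "G", rmsd = 0.2, phi = -120), asn)
  expect_equal(r$hotspot_class, 2L)
  # Asn class 1: Thr successor (111.6), CDR loop 1
  r <- classify_residue(asn_vector(succ_aa = "T", rmsd = 0.2, cdr_loop = 1), asn)
  expect_equal(r$hotspot_class, 1L)
  # Asn class 3: phi >= -75.2, exposed, distant N-terminal SS change
  r <- classify_residue(asn_vector(succ_aa = "G", rmsd = 0.2, phi = -60,
    res_sasa = 120, next_diff_ss_n = 5), asn)
  expect_equal(r$hotspot_class, 3L)
  # Asn inflexible -> non-hotspot
  r <- classify_residue(asn_vector(rmsd = 0.0), asn)
  expect_equal(r$class, "non-hotspot")
  # leaf probabilities stay in [0.5, 1]
  expect_true(all(tidy(asp)$prob[tidy(asp)$type == "leaf"] >= 0.5))
})

leaf_signature <- function(res) paste(res$class, res$hotspot_class)

test_that("programmatic vectors reach every leaf of both trees", {
  asp <- published_asp_tree()
  asn <- published_asn_tree()
  asp_leaves <- sum(tidy(asp)$type == "leaf")
  asn_leaves <- sum(tidy(asn)$type == "leaf")
  # grid over the split variables
  hit_asp <- new.env()
  for (rmsd in c(0.05, 0.3, 0.6)) {
    for (succ in c("G", "S", "W")) {
      for (nds in c(1, 5)) {
        res <- classify_residue(asp_vector(rmsd, succ, nds), asp)
        # identify the leaf by the full path trace
        key <- paste(rmsd <= 0.145, fvhotspots::successor_size(succ) > 110.9,
          rmsd > 0.485, nds < 3, succ == "G")
        assign(key, leaf_signature(res), envir = hit_asp)
      }
    }
  }
  expect_gte(length(unique(unlist(as.list(hit_asp)))), 4) # all distinct outcomes
  # six vectors, one per leaf; the three non-hotspot leaves share one
  # signature, so four distinct outcomes prove all leaves reachable
  paths_asp <- unique(vapply(
    list(
      asp_vector(0.05), asp_vector(0.6, "W"), asp_vector(0.6, "G", 5),
      asp_vector(0.3, "S", 2), asp_vector(0.3, "G", 5),
      asp_vector(0.3, "S", 5)
    ),
    function(v) paste(unlist(classify_residue(v, asp)), collapse = "|"),
    character(1)
  ))
  expect_equal(length(paths_asp), 4)
  expect_equal(asp_leaves, 6)
  vs_asn <- list(
    asn_vector(succ_aa = "V"), # big successor
    asn_vector(rmsd = 0), # inflexible
    asn_vector(succ_aa = "T", cdr_loop = 1), # class 1
    asn_vector(succ_aa = "T", cdr_loop = 3), # mid successor, not loop 1
    asn_vector(succ_aa = "G", phi = -120), # class 2
    asn_vector(succ_aa = "G", phi = -60, res_sasa = 120, next_diff_ss_n = 5),
    asn_vector(succ_aa = "G", phi = -60, res_sasa = 120, next_diff_ss_n = 2),
    asn_vector(succ_aa = "G", phi = -60, res_sasa = 50)
  )
  sigs <- vapply(vs_asn, function(v) {
    r <- classify_residue(v, asn)
    paste(r$class, r$hotspot_class, r$prob)
  }, character(1))
  expect_equal(length(unique(sigs[c(3, 5, 6)])), 3) # three hotspot classes
  expect_equal(length(vs_asn), asn_leaves)
})

test_that("missing split inputs raise an error naming the field", {
  asp <- published_asp_tree()
  v <- asp_vector()
  v$rmsd <- NA_real_
  expect_error(classify_residue(v, asp), "rmsd")
  v2 <- asp_vector(rmsd = 0.3)
  v2$next_diff_ss_c <- NULL
  expect_error(classify_residue(v2, asp), "next_diff_ss_c")
})

test_that("monotonicity: flexibility and successor size act as narrated", {
  asp <- published_asp_tree()
  # on the class-1 path, increasing rmsd never flips hotspot -> non-hotspot
  calls <- vapply(c(0.5, 0.7, 1.2, 3), function(r) {
    classify_residue(asp_vector(r, "G", 5), asp)$class
  }, character(1))
  expect_true(all(calls == "hotspot"))
  # any successor beyond the large cut is always non-hotspot
  for (succ in c("P", "T", "N", "V", "W", "R")) {
    expect_equal(
      classify_residue(asp_vector(0.6, succ, 1), asp)$class,
      "non-hotspot"
    )
  }
})

test_that("trees serialize to JSON and reload identically", {
  for (tr in list(published_asp_tree(), published_asn_tree())) {
    path <- tempfile(fileext = ".json")
    write_tree_json(tr, path)
    tr2 <- read_tree_json(path)
    expect_equal(tidy(tr2), tidy(tr))
    # same classifications
    v <- asp_vector(0.3, "G", 5)
    if (tr$aa == "N") v <- asn_vector()
    expect_equal(classify_residue(v, tr2), classify_residue(v, tr))
  }
})
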