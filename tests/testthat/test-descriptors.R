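make_fixture <- function() {
  # D at ordinal 1 (successor G), N at ordinal 3 (successor R), D at the
  # C-terminus (terminal, no successor)
  rec <- peptide_recipe("ADGNRAD", phi = -100, psi = 125, chi1 = -60)
  m <- build_peptide(rec)
  rg <- cdr_ranges(
    heavy = list(c(1L, 4L), NULL, NULL), light = list(NULL, NULL, NULL)
  )
  list(model = m, ann = annotate_regions(m, rg))
}

test_that("successor sizes come from the printed lookup table", {
  fx <- make_fixture()
  d <- extract_descriptors(fx$model, fx$ann)
  expect_equal(d$successor_size[d$ordinal == 1], 23.13) # Asp -> Gly
  expect_equal(d$successor_size[d$ordinal == 3], 210.02) # Asn -> Arg
  tb <- successor_size_table()
  expect_equal(nrow(tb), 20)
  expect_equal(tb$size[tb$aa == "A"], 64.78)
  expect_equal(tb$size[tb$aa == "W"], 229.62)
  expect_equal(successor_size("G"), 23.13)
})

test_that("terminal residues are flagged and excluded from classification", {
  fx <- make_fixture()
  d <- extract_descriptors(fx$model, fx$ann)
  term <- d[d$ordinal == 6, ]
  expect_true(all(term$is_terminal))
  expect_true(all(is.na(term$psi))) # no successor
  pred <- classify_descriptors(d)
  expect_false(6 %in% pred$ordinal)
  expect_true(all(c(1, 3) %in% pred$ordinal))
})

test_that("missing side-chain atoms null the affected fields, keep the row", {
  fx <- make_fixture()
  m <- fx$model
  drop <- which(m$atoms$ordinal == 1 & m$atoms$chain_role == "H" &
    m$atoms$elety %in% c("CG", "OD1", "OD2"))
  m$atoms <- m$atoms[-drop, ]
  d <- extract_descriptors(m, fx$ann)
  row <- d[d$ordinal == 1, ]
  expect_equal(nrow(row), 1)
  expect_true(is.na(row$chi1))
  expect_true(is.na(row$dist_cg_n1))
  expect_true(is.na(row$cgonc))
  expect_false(is.na(row$phi)) # backbone fields unaffected
  expect_false(is.na(row$res_sasa))
})

test_that("extraction is deterministic and invariant to atom order", {
  fx <- make_fixture()
  d1 <- extract_descriptors(fx$model, fx$ann)
  m2 <- fx$model
  set.seed(2)
  m2$atoms <- m2$atoms[sample(nrow(m2$atoms)), ]
  d2 <- extract_descriptors(m2, fx$ann)
  d2 <- d2[order(d2$ordinal), ]
  d1 <- d1[order(d1$ordinal), ]
  for (col in c("phi", "psi", "chi1", "res_sasa", "dist_cg_n1", "cgonc")) {
    expect_equal(d2[[col]], d1[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("geometric fields agree with direct recomputation from atoms", {
  fx <- make_fixture()
  m <- fx$model
  d <- extract_descriptors(m, fx$ann)
  row <- d[d$ordinal == 1, ]
  cg <- atom_xyz_for_test(m, "H", 1, "CG")
  n2 <- atom_xyz_for_test(m, "H", 2, "N")
  expect_equal(row$dist_cg_n1, sqrt(sum((cg - n2)^2)))
  od1 <- atom_xyz_for_test(m, "H", 1, "OD1")
  c1 <- atom_xyz_for_test(m, "H", 1, "C")
  expect_equal(row$cgonc, dihedral(cg, od1, n2, c1))
  ca0 <- atom_xyz_for_test(m, "H", 0, "CA")
  ca2 <- atom_xyz_for_test(m, "H", 2, "CA")
  expect_equal(row$bend, sqrt(sum((ca0 - ca2)^2)))
})

test_that("the descriptor vector matches its golden snapshot", {
  # regression surface over the full field set on a fixed fixture
  fx <- make_fixture()
  d <- extract_descriptors(fx$model, fx$ann)
  row <- as.list(d[d$ordinal == 1, ])
  expect_equal(row$aa, "D")
  expect_equal(row$succ_aa, "G")
  expect_equal(row$motif, "DG")
  expect_equal(row$rmsd, 0) # single model
  expect_equal(row$fab_location, 2L)
  expect_equal(row$cdr_loop, 1L)
  expect_equal(row$sec_struct, "coil")
  # the N-terminal chain end is 2 residues away, an open-ended margin
  expect_equal(row$pos_in_coil, "margin")
  expect_equal(row$next_diff_ss_n, 2L)
  expect_true(row$open_n)
  expect_equal(row$next_diff_ss_c, 6L)
  expect_equal(row$phi, -100, tolerance = 1e-3)
  expect_equal(row$psi, 125, tolerance = 1e-3)
  expect_equal(row$chi1, -60, tolerance = 1e-3)
  expect_equal(row$dist_cg_n1, 2.789695, tolerance = 1e-5)
  expect_equal(row$cgonc, 88.235074, tolerance = 1e-4)
  expect_equal(row$bend, 6.524508, tolerance = 1e-5)
  expect_equal(row$res_sasa, 157.902041, tolerance = 1e-4)
  expect_equal(row$succ_N_sasa, 0.341746, tolerance = 1e-4)
  expect_equal(row$hb_sidechain, 0L)
  expect_equal(row$succ_N_hbonds, 0L)
  expect_true(is.na(row$pka))
})
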