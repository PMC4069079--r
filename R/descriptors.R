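## Extraction of the twenty structural descriptors for every Asn and Asp
## residue of an Fv ensemble: one row per (residue, ensemble member).
##
## Field summary (units):
##   hb_sidechain   H-bond count of the side-chain head group
##                  (Asp: OD1/OD2 oxygens; Asn: ND2 nitrogen)
##   pka            side-chain pKa from a pluggable provider (Asp; else NA)
##   succ_N_sasa    SASA of the successor's backbone N (A^2)
##   succ_N_hbonds  H-bond count of the successor's backbone N
##   dist_cg_n1     distance CG(n) - N(n+1) (A)
##   chi1           N-CA-CB-CG side-chain dihedral (deg)
##   cgonc          dihedral CG - OD1 - N(n+1) - C(n) (deg); the side-chain
##                  carbonyl oxygen and the backbone carbonyl carbon of n
##   res_sasa       whole-residue SASA (A^2)
##   successor_size fully-exposed SASA of the successor type (A^2, lookup)
##   phi, psi       backbone dihedrals (deg)
##   rmsd           per-residue ensemble CA RMSD (A; identical across rows
##                  of one residue)
##   sec_struct     helix | sheet | turn | coil
##   next_diff_ss_n / next_diff_ss_c  residues to the next different
##                  secondary-structure element (N-/C-terminal direction)
##   pos_in_coil    margin | center | n.a.
##   bend           distance CA(n-1) - CA(n+1) (A)
##   fab_location   1-14 region code; cdr_loop 0-3
##   aa, succ_aa, is_terminal   identity bookkeeping

descriptor_columns <- function() {
  c(
    "name", "model_index", "chain_role", "ordinal", "resno", "aa",
    "succ_aa", "motif", "is_terminal", "hb_sidechain", "pka",
    "succ_N_sasa", "succ_N_hbonds", "dist_cg_n1", "chi1", "cgonc",
    "res_sasa", "successor_size", "phi", "psi", "rmsd", "sec_struct",
    "next_diff_ss_n", "next_diff_ss_c", "open_n", "open_c", "pos_in_coil",
    "bend", "fab_location", "cdr_loop"
  )
}

#' Extract the structural descriptor set from an Fv ensemble
#'
#' Computes the twenty structural parameters for every Asn and Asp residue
#' in every ensemble member. Terminal residues (first/last of a chain,
#' which lack phi or psi) are flagged via `is_terminal` and are excluded
#' from classification downstream but still reported. Missing side-chain
#' atoms leave the affected geometric fields `NA` while the row is kept.
#'
#' @param ensemble An `fv_ensemble` (or single `fv_model`).
#' @param annotations Region annotations from [annotate_regions()]; `NULL`
#'   auto-detects CDRs from the sequence.
#' @param pka_provider Optional `function(model, chain_role, ordinal)`
#'   returning a side-chain pKa estimate (e.g. wrapping an external
#'   PROPKA-compatible tool); `NULL` leaves `pka` missing.
#' @param probe_radius,n_points SASA parameters (see [sasa_atoms()]).
#' @param criterion Hydrogen-bond criterion, see [hbond_criterion()].
#' @param superpose Superpose members on framework CA atoms before the
#'   flexibility (RMSD) calculation.
#' @return A tibble with one row per (Asn/Asp residue, model); columns as
#'   documented above, ready for [classify_descriptors()] or
#'   [write_descriptors()].
#' @export
extract_descriptors <- function(ensemble, annotations = NULL,
                                pka_provider = NULL, probe_radius = 1.4,
                                n_points = 960,
                                criterion = hbond_criterion(),
                                superpose = TRUE) {
  if (inherits(ensemble, "fv_model")) {
    ensemble <- build_fv_ensemble(list(ensemble))
  }
  if (is.null(annotations)) annotations <- annotate_regions(ensemble)
  if (superpose) {
    ensemble <- superpose_ensemble(ensemble, annotations)
  }
  rmsd_tb <- suppressMessages(ensemble_rmsd(ensemble))
  rs <- model_residues(ensemble$models[[1]])
  targets <- which(rs$aa %in% c("N", "D"))
  rows <- list()
  for (m in ensemble$models) {
    sasa <- sasa_atoms(m, probe_radius = probe_radius, n_points = n_points)
    res_sasa_tb <- m$atoms %>%
      mutate(atom_sasa = sasa) %>%
      group_by(.data$chain_role, .data$ordinal) %>%
      summarise(res_sasa = sum(.data$atom_sasa), .groups = "drop")
    ss_tb <- suppressWarnings(assign_secondary_structure(m))
    pairs <- hbond_pairs(m, criterion)
    for (t in targets) {
      rows[[length(rows) + 1]] <- descriptor_row(
        m, rs, t, res_sasa_tb, sasa, ss_tb, pairs, rmsd_tb,
        annotations, pka_provider, ensemble$name
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::as_tibble(setNames(
      rep(list(logical(0)), length(descriptor_columns())),
      descriptor_columns()
    )))
  }
  bind_rows(rows)
}

descriptor_row <- function(model, rs, t, res_sasa_tb, atom_sasa, ss_tb,
                           pairs, rmsd_tb, annotations, pka_provider,
                           name) {
  role <- rs$chain_role[t]
  ord <- rs$ordinal[t]
  aa <- rs$aa[t]
  chain_rs <- rs[rs$chain_role == role, ]
  last_ord <- max(chain_rs$ordinal)
  terminal <- ord == 0L || ord == last_ord

  gx <- function(o, nm) atom_xyz(model, role, o, nm)
  N0 <- gx(ord, "N")
  CA0 <- gx(ord, "CA")
  C0 <- gx(ord, "C")
  CB0 <- gx(ord, "CB")
  CG0 <- gx(ord, "CG")
  OD1 <- gx(ord, "OD1")
  Cprev <- if (ord > 0) gx(ord - 1, "C") else NULL
  CAprev <- if (ord > 0) gx(ord - 1, "CA") else NULL
  Nnext <- if (ord < last_ord) gx(ord + 1, "N") else NULL
  CAnext <- if (ord < last_ord) gx(ord + 1, "CA") else NULL

  dihe <- function(a, b, c, d) {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d)) {
      return(NA_real_)
    }
    dihedral(a, b, c, d)
  }
  dst <- function(a, b) {
    if (is.null(a) || is.null(b)) NA_real_ else dist3(a, b)
  }

  succ_aa <- if (ord < last_ord) {
    chain_rs$aa[match(ord + 1L, chain_rs$ordinal)]
  } else {
    NA_character_
  }

  head_atoms <- if (aa == "D") c("OD1", "OD2") else "ND2"
  hb_side <- count_hbonds(model, role, ord, head_atoms, pairs = pairs)
  succ_hb <- if (!is.null(Nnext)) {
    count_hbonds(model, role, ord + 1L, "N", pairs = pairs)
  } else {
    NA_integer_
  }
  succ_n_sasa <- if (!is.null(Nnext)) {
    i <- which(model$atoms$chain_role == role &
      model$atoms$ordinal == ord + 1L & model$atoms$elety == "N")
    if (length(i)) atom_sasa[i[1]] else NA_real_
  } else {
    NA_real_
  }

  ss_chain <- ss_tb$sec_struct[ss_tb$chain_role == role]
  ctx <- ss_context(ss_chain, ord)
  ann <- annotations[annotations$chain_role == role &
    annotations$ordinal == ord, ]
  motif <- if (!is.na(succ_aa) && paste0(aa, succ_aa) %in% HOTSPOT_MOTIFS) {
    paste0(aa, succ_aa)
  } else {
    NA_character_
  }
  pka <- if (!is.null(pka_provider) && aa == "D") {
    pka_provider(model, role, ord)
  } else {
    NA_real_
  }

  tibble(
    name = name, model_index = model$model_index, chain_role = role,
    ordinal = ord, resno = rs$resno[t], aa = aa, succ_aa = succ_aa,
    motif = motif, is_terminal = terminal,
    hb_sidechain = hb_side, pka = pka,
    succ_N_sasa = succ_n_sasa, succ_N_hbonds = succ_hb,
    dist_cg_n1 = dst(CG0, Nnext),
    chi1 = dihe(N0, CA0, CB0, CG0),
    cgonc = dihe(CG0, OD1, Nnext, C0),
    res_sasa = res_sasa_tb$res_sasa[res_sasa_tb$chain_role == role &
      res_sasa_tb$ordinal == ord],
    successor_size = if (is.na(succ_aa)) NA_real_ else successor_size(succ_aa),
    phi = dihe(Cprev, N0, CA0, C0),
    psi = dihe(N0, CA0, C0, Nnext),
    rmsd = rmsd_tb$rmsd[rmsd_tb$chain_role == role &
      rmsd_tb$ordinal == ord],
    sec_struct = ss_chain[ord + 1L],
    next_diff_ss_n = ctx$next_diff_ss_n,
    next_diff_ss_c = ctx$next_diff_ss_c,
    open_n = ctx$open_n, open_c = ctx$open_c,
    pos_in_coil = ctx$pos_in_coil,
    bend = dst(CAprev, CAnext),
    fab_location = ann$fab_location[1], cdr_loop = ann$cdr_loop[1]
  )
}

#' Write / read a descriptor table
#'
#' Stable CSV/TSV serialization of the descriptor contract; missing values
#' are written as empty fields. The format round-trips through
#' [read_descriptors()].
#'
#' @param descriptors A descriptor tibble from [extract_descriptors()].
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `path` invisibly (writer); the tibble (reader).
#' @export
write_descriptors <- function(descriptors, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(descriptors, path, na = "")
  } else {
    readr::write_csv(descriptors, path, na = "")
  }
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  tb <- reader(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("sec_struct", "pos_in_coil", "aa", "succ_aa", "motif")) {
    if (col %in% names(tb)) tb[[col]] <- as.character(tb[[col]])
  }
  tb
}
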