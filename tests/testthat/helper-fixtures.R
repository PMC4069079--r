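# Shared fixtures, all generated in code.

# A hand-written 3-residue-per-chain PDB for parser tests (coordinates
# arbitrary but finite; CA-only side would be incomplete, so N/CA/C/O are
# present).
tiny_pdb_lines <- function() {
  atom <- function(serial, name, res, chain, resno, x, y, z, occ = 1.0) {
    sprintf(
      "ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
      serial, name, res, chain, resno, x, y, z, occ, 20.0,
      substr(name, 1, 1)
    )
  }
  lines <- character(0)
  serial <- 0
  for (chain in c("H", "L")) {
    resn <- c("ALA", "ASP", "GLY")
    for (i in 1:3) {
      base_x <- i * 4 + ifelse(chain == "L", 40, 0)
      for (nm in c("N", "CA", "C", "O")) {
        serial <- serial + 1
        dx <- match(nm, c("N", "CA", "C", "O")) * 0.8
        lines <- c(lines, atom(
          serial, nm, resn[i], chain, i, base_x + dx, i * 1.1, 0.5
        ))
      }
    }
    lines <- c(lines, "TER")
  }
  c(lines, "END")
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_lines(), path)
  path
}

# Explicit CDR ranges for synthetic peptides: one heavy CDR covering the
# given ordinals, empty light CDRs.
simple_ranges <- function(h1 = c(8L, 12L)) {
  cdr_ranges(
    heavy = list(h1, NULL, NULL),
    light = list(NULL, NULL, NULL)
  )
}

# Jittered-ensemble fixture with a planted flexible Asp-Gly site inside
# the heavy "CDR" (ordinals 8..12); successor of the Asp (ordinal 9) is
# Gly.
planted_dg_recipe <- function(jitter_sd = 0.45, n_models = 5, seed = 42) {
  peptide_recipe(
    "AKTSVPTASDGYSLTVSSAK",
    phi = -120, psi = 130,
    jitter_sd = jitter_sd, loop_ordinals = 8:12,
    n_models = n_models, seed = seed, name = "planted_dg"
  )
}

# Minimal complete descriptor vector for direct tree classification.
asp_vector <- function(rmsd = 0.3, succ_aa = "S", next_diff_ss_c = 2,
                       successor_size = NULL) {
  list(
    rmsd = rmsd, succ_aa = succ_aa,
    successor_size = successor_size %||% fvhotspots::successor_size(succ_aa),
    next_diff_ss_c = next_diff_ss_c
  )
}

asn_vector <- function(rmsd = 0.2, succ_aa = "G", phi = -120,
                       res_sasa = 50, next_diff_ss_n = 2, cdr_loop = 2) {
  list(
    rmsd = rmsd, succ_aa = succ_aa,
    successor_size = fvhotspots::successor_size(succ_aa),
    phi = phi, res_sasa = res_sasa, next_diff_ss_n = next_diff_ss_n,
    cdr_loop = cdr_loop
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom_xyz_for_test <- function(...) fvhotspots:::atom_xyz(...)
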