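## Reading, writing and assembling Fv structure models.
##
## A model is held as an `fv_model`: a list with an atom tibble (one row per
## atom, coordinates in Angstrom) plus bookkeeping. Residues are addressed
## internally by a 0-based sequential ordinal per chain; author numbering
## (resno + insertion code) is carried along for reporting only.

AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aa_one <- function(resid3) {
  out <- unname(AA321[toupper(resid3)])
  out[is.na(out)] <- "X"
  out
}

element_from_name <- function(elety) {
  # PDB atom names start with the element once digits are stripped;
  # two-letter elements do not occur in standard amino acids without H.
  substr(gsub("^[0-9]*", "", toupper(elety)), 1, 1)
}

#' Read an Fv structure model from a PDB file
#'
#' Parses a PDB file (via bio3d) and extracts the designated heavy and
#' light chains as an `fv_model`. Waters and heteroatoms are excluded,
#' alternate locations are resolved to the highest-occupancy conformer
#' (ties: first encountered), and each residue receives a 0-based
#' sequential ordinal within its chain. Files with multiple `MODEL`
#' records yield a list of models.
#'
#' Residues missing any backbone N/CA/C atom are flagged incomplete but
#' retained; non-standard residues are mapped to amino-acid letter `"X"`
#' and skipped by descriptor extraction.
#'
#' @param path Path to a PDB file.
#' @param heavy_chain,light_chain Chain identifiers of the heavy and light
#'   chain in the file.
#' @param name Model name; defaults to the file name.
#' @return An `fv_model`, or a list of `fv_model`s when the file contains
#'   multiple MODEL records.
#' @export
read_fv_model <- function(path, heavy_chain = "H", light_chain = "L",
                          name = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read PDB file: ", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- as_tibble(pdb$atom)
  at <- filter(at, .data$type == "ATOM")
  chains <- unique(at$chain)
  for (ch in c(heavy_chain, light_chain)) {
    if (!ch %in% chains) {
      abort(paste0(
        "chain '", ch, "' not found in ", path,
        " (available: ", paste(chains, collapse = ", "), ")"
      ))
    }
  }
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  name <- name %||% sub("\\.pdb$", "", basename(path))

  build_one <- function(k) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[k, ] else as.numeric(pdb$xyz)
    idx <- which(pdb$atom$type == "ATOM")
    coords <- matrix(xyz, ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    tb <- mutate(at,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      o = ifelse(is.na(.data$o), 1, .data$o),
      b = ifelse(is.na(.data$b), 0, .data$b)
    )
    tb <- filter(tb, .data$chain %in% c(heavy_chain, light_chain))
    tb <- mutate(tb,
      chain_role = ifelse(.data$chain == heavy_chain, "H", "L"),
      insert = ifelse(is.na(.data$insert), "", .data$insert),
      alt = ifelse(is.na(.data$alt), "", .data$alt)
    )
    # altloc: keep the highest-occupancy conformer per atom name in a residue
    tb <- tb %>%
      group_by(.data$chain_role, .data$resno, .data$insert, .data$elety) %>%
      filter(row_number() == which.max(.data$o)) %>%
      ungroup()
    tb <- tb %>%
      group_by(.data$chain_role) %>%
      mutate(
        res_key = paste(.data$resno, .data$insert),
        ordinal = match(.data$res_key, unique(.data$res_key)) - 1L
      ) %>%
      ungroup() %>%
      select(-"res_key")
    tb <- mutate(tb,
      aa = aa_one(.data$resid),
      element = ifelse(is.na(.data$elesy) | .data$elesy == "",
        element_from_name(.data$elety), toupper(.data$elesy)
      )
    )
    atoms <- tb %>%
      arrange(match(.data$chain_role, c("H", "L")), .data$ordinal) %>%
      select(
        "chain_role", "chain", "ordinal", "resno", "insert", "aa",
        "elety", "element", "x", "y", "z", "o", "b"
      )
    stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
              all(is.finite(atoms$z)))
    new_fv_model(atoms, name = name, model_index = k - 1L)
  }

  models <- lapply(seq_len(n_models), build_one)
  if (n_models == 1L) models[[1]] else models
}

new_fv_model <- function(atoms, name = "model", model_index = 0L) {
  stopifnot(is_tibble(atoms))
  for (role in c("H", "L")) {
    if (!any(atoms$chain_role == role)) {
      abort(paste0("fv_model requires a non-empty '", role, "' chain"))
    }
  }
  structure(
    list(atoms = atoms, name = name, model_index = as.integer(model_index)),
    class = "fv_model"
  )
}

#' @export
print.fv_model <- function(x, ...) {
  rs <- model_residues(x)
  cat(
    "<fv_model> ", x$name, " (model ", x$model_index, "): ",
    sum(rs$chain_role == "H"), " H + ", sum(rs$chain_role == "L"),
    " L residues, ", nrow(x$atoms), " atoms\n",
    sep = ""
  )
  invisible(x)
}

#' Residue-level view of a model
#'
#' @param model An `fv_model`.
#' @return A tibble with one row per residue: `chain_role`, `ordinal`,
#'   `resno`, `insert`, `aa`, `is_terminal` (first/last residue of the
#'   chain) and `complete_backbone` (has N, CA and C atoms).
#' @export
model_residues <- function(model) {
  model$atoms %>%
    group_by(.data$chain_role, .data$ordinal) %>%
    summarise(
      resno = .data$resno[1], insert = .data$insert[1], aa = .data$aa[1],
      complete_backbone = all(c("N", "CA", "C") %in% .data$elety),
      .groups = "drop"
    ) %>%
    group_by(.data$chain_role) %>%
    mutate(is_terminal = .data$ordinal == min(.data$ordinal) |
      .data$ordinal == max(.data$ordinal)) %>%
    ungroup() %>%
    arrange(match(.data$chain_role, c("H", "L")), .data$ordinal)
}

#' One-letter sequence of one chain of a model
#'
#' @param model An `fv_model`.
#' @param chain_role `"H"` or `"L"`.
#' @return A single string.
#' @export
model_sequence <- function(model, chain_role = "H") {
  rs <- model_residues(model)
  paste(rs$aa[rs$chain_role == chain_role], collapse = "")
}

## Coordinates of one named atom of a residue, or NULL if absent.
atom_xyz <- function(model, chain_role, ordinal, elety) {
  a <- model$atoms
  i <- which(a$chain_role == chain_role & a$ordinal == ordinal &
    a$elety == elety)
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' Assemble an ensemble from structure models
#'
#' Verifies that all models share identical chain sequences (same amino
#' acid at the same ordinal on both chains) and wraps them as an
#' `fv_ensemble`, the unit of hotspot prediction. A single-model ensemble
#' is allowed; its per-residue flexibility (RMSD) is identically zero.
#'
#' @param models A list of `fv_model`s (typically 5), or a single model.
#' @param name Ensemble identifier.
#' @return An `fv_ensemble`.
#' @export
build_fv_ensemble <- function(models, name = NULL) {
  if (inherits(models, "fv_model")) models <- list(models)
  if (length(models) < 1) abort("an ensemble needs at least one model")
  ref <- model_residues(models[[1]])
  for (k in seq_along(models)[-1]) {
    cur <- model_residues(models[[k]])
    if (nrow(cur) != nrow(ref)) {
      abort(paste0("model ", k, " has a different residue count"))
    }
    diffs <- which(cur$aa != ref$aa | cur$chain_role != ref$chain_role)
    if (length(diffs) > 0) {
      d <- diffs[1]
      abort(paste0(
        "sequence mismatch across models at chain ", ref$chain_role[d],
        " ordinal ", ref$ordinal[d], " (", ref$aa[d], " vs ", cur$aa[d], ")"
      ))
    }
  }
  name <- name %||% models[[1]]$name
  models <- lapply(seq_along(models), function(k) {
    m <- models[[k]]
    m$model_index <- k - 1L
    m
  })
  structure(list(models = models, name = name), class = "fv_ensemble")
}

#' @export
print.fv_ensemble <- function(x, ...) {
  cat("<fv_ensemble> ", x$name, ": ", length(x$models), " model(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.fv_ensemble <- function(x) length(x$models)

#' Write a model (or ensemble) to a PDB file
#'
#' Single models are written as plain ATOM records; ensembles are written
#' with one MODEL record per member. Round-tripping through
#' [read_fv_model()] preserves ordinals, residue letters, and coordinates
#' to PDB precision (1e-3 Angstrom).
#'
#' @param x An `fv_model` or `fv_ensemble`.
#' @param path Output file path.
#' @param heavy_chain,light_chain Chain IDs to write for the H and L chain.
#' @return `path`, invisibly.
#' @export
write_fv_model <- function(x, path, heavy_chain = "H", light_chain = "L") {
  if (inherits(x, "fv_ensemble")) {
    atoms <- x$models[[1]]$atoms
    xyz <- do.call(rbind, lapply(x$models, function(m) {
      as.numeric(t(as.matrix(m$atoms[, c("x", "y", "z")])))
    }))
  } else {
    atoms <- x$atoms
    xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  }
  resid3 <- names(AA321)[match(atoms$aa, AA321)]
  resid3[is.na(resid3)] <- "UNK"
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = atoms$resno, resid = resid3,
    eleno = seq_len(nrow(atoms)), elety = atoms$elety,
    chain = ifelse(atoms$chain_role == "H", heavy_chain, light_chain),
    insert = ifelse(atoms$insert == "", NA, atoms$insert),
    o = atoms$o, b = atoms$b, elesy = atoms$element
  )
  invisible(path)
}
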