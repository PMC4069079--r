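## Synthetic inputs for testing and calibration: ideal-geometry peptides
## built from internal coordinates, perturbed ensembles with planted
## loop flexibility, and labelled descriptor tables with planted tree
## rules and class imbalance.
##
## Geometry constants are canonical peptide values (Engh-Huber-like):
## bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231, CA-CB
## 1.530 A; angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O
## 120.8, N-CA-CB 110.4 deg; omega fixed at 180.

PEP <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530, b_cb_cg = 1.520, b_cg_od1 = 1.231, b_cg_od2 = 1.249,
  b_cg_nd2 = 1.328,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.4, a_ca_cb_cg = 113.0, a_cb_cg_od1 = 119.0,
  a_cb_cg_oxd2 = 118.0
)

#' Recipe for a synthetic Fv peptide model
#'
#' Describes a toy two-chain polypeptide with controllable backbone and
#' side-chain torsions. Only N/CA/C/O/CB atoms are built, plus the
#' CG/OD1/OD2(ND2) head group for Asp and Asn so that every descriptor is
#' computable. The light chain defaults to a short extended stub placed
#' far from the heavy chain; supply `light_seq` and torsions to control
#' it.
#'
#' @param heavy_seq One-letter sequence of the heavy chain (length >= 3).
#' @param phi,psi Per-residue backbone torsion targets in degrees
#'   (recycled; terminal residues lack the corresponding torsion).
#' @param chi1 Side-chain chi1 targets (recycled; used for residues with
#'   a CG atom).
#' @param light_seq,light_phi,light_psi Light-chain counterparts.
#' @param jitter_sd Gaussian coordinate jitter (Angstrom) applied to loop
#'   residues by [build_ensemble_with_jitter()].
#' @param loop_ordinals Heavy-chain ordinals receiving jitter.
#' @param n_models Ensemble size for [build_ensemble_with_jitter()].
#' @param seed Seed for the jitter.
#' @param name Model/ensemble name.
#' @return A `peptide_recipe` list.
#' @export
peptide_recipe <- function(heavy_seq, phi = -120, psi = 130, chi1 = -60,
                           light_seq = "GSAGSA", light_phi = -120,
                           light_psi = 130, jitter_sd = 0,
                           loop_ordinals = integer(0), n_models = 5,
                           seed = 1, name = "synthetic") {
  if (nchar(heavy_seq) < 3) abort("sequence length must be >= 3")
  if (jitter_sd < 0) abort("jitter_sd must be >= 0")
  structure(
    list(
      heavy_seq = heavy_seq, phi = phi, psi = psi, chi1 = chi1,
      light_seq = light_seq, light_phi = light_phi,
      light_psi = light_psi, jitter_sd = jitter_sd,
      loop_ordinals = as.integer(loop_ordinals),
      n_models = n_models, seed = seed, name = name
    ),
    class = "peptide_recipe"
  )
}

## Build one chain from internal coordinates; returns an atom tibble.
build_chain <- function(seq, phi, psi, chi1, chain_role, origin = c(0, 0, 0)) {
  n <- nchar(seq)
  aa <- strsplit(seq, "")[[1]]
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  chi1 <- rep_len(chi1, n)
  rows <- list()
  add <- function(ord, aa1, elety, xyz) {
    rows[[length(rows) + 1]] <<- tibble(
      chain_role = chain_role, chain = chain_role, ordinal = ord,
      resno = ord + 1L, insert = "", aa = aa1, elety = elety,
      element = substr(elety, 1, 1), x = xyz[1], y = xyz[2], z = xyz[3],
      o = 1, b = 0
    )
  }
  # first residue: canonical frame
  N <- origin
  CA <- N + c(PEP$b_n_ca, 0, 0)
  ang <- rad(180 - PEP$a_n_ca_c)
  C <- CA + PEP$b_ca_c * c(cos(ang), sin(ang), 0)
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)) {
    ord <- i - 1L
    if (i > 1) {
      N <- place_atom(prev$N, prev$CA, prev$C, PEP$b_c_n, PEP$a_ca_c_n,
        psi[i - 1]
      )
      CA <- place_atom(prev$CA, prev$C, N, PEP$b_n_ca, PEP$a_c_n_ca, 180)
      C <- place_atom(prev$C, N, CA, PEP$b_ca_c, PEP$a_n_ca_c, phi[i])
    }
    add(ord, aa[i], "N", N)
    add(ord, aa[i], "CA", CA)
    add(ord, aa[i], "C", C)
    # carbonyl O: in the peptide plane, anti to the next N direction;
    # trans to CA(i) about the C-N axis approximated via psi + 180
    O <- place_atom(N, CA, C, PEP$b_c_o, PEP$a_ca_c_o, psi[i] + 180)
    add(ord, aa[i], "O", O)
    if (aa[i] != "G") {
      CB <- place_atom(C, N, CA, PEP$b_ca_cb, PEP$a_n_ca_cb, 122.55)
      add(ord, aa[i], "CB", CB)
      if (aa[i] %in% c("N", "D")) {
        CG <- place_atom(N, CA, CB, PEP$b_cb_cg, PEP$a_ca_cb_cg, chi1[i])
        add(ord, aa[i], "CG", CG)
        OD1 <- place_atom(CA, CB, CG, PEP$b_cg_od1, PEP$a_cb_cg_od1, -20)
        add(ord, aa[i], "OD1", OD1)
        if (aa[i] == "D") {
          OD2 <- place_atom(CA, CB, CG, PEP$b_cg_od2, PEP$a_cb_cg_oxd2, 160)
          add(ord, aa[i], "OD2", OD2)
        } else {
          ND2 <- place_atom(CA, CB, CG, PEP$b_cg_nd2, PEP$a_cb_cg_oxd2, 160)
          add(ord, aa[i], "ND2", ND2)
        }
      }
    }
    prev <- list(N = N, CA = CA, C = C)
  }
  bind_rows(rows)
}

#' Build a synthetic Fv model from a recipe
#'
#' Internal-coordinate construction with standard bond lengths and
#' angles; realized backbone and chi1 torsions reproduce the targets to
#' well under 0.5 degrees. The light chain is placed 60 Angstrom away so
#' the chains do not interact sterically.
#'
#' @param recipe A [peptide_recipe()].
#' @return An `fv_model`.
#' @export
build_peptide <- function(recipe) {
  h <- build_chain(
    recipe$heavy_seq, recipe$phi, recipe$psi, recipe$chi1, "H"
  )
  l <- build_chain(
    recipe$light_seq, recipe$light_phi, recipe$light_psi, -60, "L",
    origin = c(0, 60, 0)
  )
  new_fv_model(bind_rows(h, l), name = recipe$name, model_index = 0L)
}

#' Build a jittered ensemble with planted loop flexibility
#'
#' Replicates the recipe's base model `n_models` times and adds isotropic
#' Gaussian jitter of `jitter_sd` to every atom of the designated loop
#' residues (heavy chain); all other residues are identical across
#' members, emulating an ensemble whose loops were re-modelled while the
#' framework stayed fixed.
#'
#' @param recipe A [peptide_recipe()] with `loop_ordinals`, `jitter_sd`,
#'   `n_models` and `seed` set.
#' @return An `fv_ensemble`.
#' @export
build_ensemble_with_jitter <- function(recipe) {
  base <- build_peptide(recipe)
  set.seed(recipe$seed)
  models <- lapply(seq_len(recipe$n_models), function(k) {
    m <- base
    m$model_index <- k - 1L
    if (recipe$jitter_sd > 0 && length(recipe$loop_ordinals) > 0) {
      sel <- m$atoms$chain_role == "H" &
        m$atoms$ordinal %in% recipe$loop_ordinals
      nsel <- sum(sel)
      m$atoms$x[sel] <- m$atoms$x[sel] + rnorm(nsel, 0, recipe$jitter_sd)
      m$atoms$y[sel] <- m$atoms$y[sel] + rnorm(nsel, 0, recipe$jitter_sd)
      m$atoms$z[sel] <- m$atoms$z[sel] + rnorm(nsel, 0, recipe$jitter_sd)
    }
    m
  })
  build_fv_ensemble(models, name = recipe$name)
}

#' Build an ideal two-strand antiparallel beta fixture
#'
#' Two extended strands (phi = -139, psi = 135) paired antiparallel: the
#' second strand (as the L chain) is rigidly placed so that the canonical
#' N-H...O=C ladder across the strands is realized (refined numerically
#' from a pre-computed alignment). Interior residues of both strands are
#' assigned `sheet` by [assign_secondary_structure()].
#'
#' @param n_res Residues per strand (>= 5).
#' @return An `fv_model` with strands as the H and L chains.
#' @export
build_sheet_model <- function(n_res = 7) {
  if (n_res < 5) abort("need at least 5 residues per strand")
  seq1 <- strrep("A", n_res)
  sA <- build_chain(seq1, -139, 135, -60, "H")
  sB <- build_chain(seq1, -139, 135, -60, "L")
  getp <- function(tb, ord, el) {
    i <- which(tb$ordinal == ord & tb$elety == el)
    c(tb$x[i], tb$y[i], tb$z[i])
  }
  transform_B <- function(p) {
    th <- p[1:3]
    Rx <- matrix(c(
      1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])
    ), 3, 3, byrow = TRUE)
    Ry <- matrix(c(
      cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])
    ), 3, 3, byrow = TRUE)
    Rz <- matrix(c(
      cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1
    ), 3, 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    sweep(as.matrix(sB[, c("x", "y", "z")]) %*% t(R), 2, p[4:6], "+")
  }
  pairs <- seq(1, n_res - 2, by = 2)
  obj <- function(p) {
    xyz <- transform_B(p)
    B <- sB
    B$x <- xyz[, 1]; B$y <- xyz[, 2]; B$z <- xyz[, 3]
    s <- 0
    for (i in pairs) {
      j <- (n_res - 1) - i
      s <- s + (dist3(getp(sA, i, "N"), getp(B, j, "O")) - 2.9)^2
      s <- s + (dist3(getp(sA, i, "O"), getp(B, j, "N")) - 2.9)^2
    }
    for (i in 0:(n_res - 1)) {
      for (j in 0:(n_res - 1)) {
        d <- dist3(getp(sA, i, "CA"), getp(B, j, "CA"))
        if (d < 4.2) s <- s + (4.2 - d)^2
      }
    }
    s
  }
  # refined from a converged 7-residue alignment; BFGS re-polishes for
  # other strand lengths
  p0 <- c(4.877032, -0.622096, -2.609986, 21.988729, 8.520363, -3.890142)
  if (n_res != 7) {
    shift <- 3.3 * (n_res - 7) / 2
    p0[4] <- p0[4] + 2 * shift
  }
  o <- optim(p0, obj, method = "BFGS", control = list(maxit = 500))
  xyz <- transform_B(o$par)
  B <- sB
  B$x <- xyz[, 1]; B$y <- xyz[, 2]; B$z <- xyz[, 3]
  new_fv_model(bind_rows(sA, B), name = "sheet_fixture")
}

## ---- labelled descriptor-table simulator ----

## Per-field sampling distributions (documented in the vignette):
## group-level values are drawn once per residue group; member-level
## fields add small within-group perturbations so the five members are
## correlated but not identical.
sample_group <- function(aa) {
  # flexibility is the dominant discriminator (as in the published tree):
  # most residues are rigid, and small successors are common in CDR-like
  # sequence context, so the rmsd cut carries the most class information
  rigid <- runif(1) < 0.65
  rmsd <- if (rigid) abs(rnorm(1, 0.04, 0.04)) else rgamma(1, 2, scale = 0.25)
  succ_pool <- c(
    G = 0.16, A = 0.10, S = 0.14, C = 0.03, D = 0.09, T = 0.08,
    N = 0.06, P = 0.05, E = 0.05, Q = 0.04, K = 0.04, R = 0.03,
    L = 0.04, V = 0.04, I = 0.02, F = 0.01, Y = 0.01, W = 0.002,
    H = 0.008, M = 0.01
  )
  succ <- sample(names(succ_pool), 1, prob = succ_pool)
  cdr_loop <- sample(0:3, 1, prob = c(0.55, 0.15, 0.15, 0.15))
  ss <- sample(c("coil", "sheet", "turn", "helix"), 1,
    prob = c(0.5, 0.3, 0.1, 0.1)
  )
  list(
    aa = aa, succ_aa = succ, successor_size = successor_size(succ),
    rmsd = rmsd, cdr_loop = cdr_loop,
    fab_location = if (cdr_loop > 0) 2L * cdr_loop else 1L,
    sec_struct = ss,
    next_diff_ss_n = 1L + rpois(1, 1.6),
    next_diff_ss_c = 1L + rpois(1, 1.6),
    phi_mu = if (runif(1) < 0.6) rnorm(1, -120, 25) else rnorm(1, -65, 15),
    psi_mu = if (runif(1) < 0.6) rnorm(1, 135, 25) else rnorm(1, -45, 20),
    chi1_mu = sample(c(-60, 60, 180), 1) + rnorm(1, 0, 10),
    sasa_mu = rgamma(1, 2, scale = 35),
    succ_n_sasa_mu = rgamma(1, 1.5, scale = 4),
    dist_mu = max(2.5, rnorm(1, 4.5, 0.8)),
    bend_mu = rnorm(1, 5.5, 0.5),
    hb_sidechain = rpois(1, 0.8),
    succ_N_hbonds = rpois(1, 0.8)
  )
}

sample_member <- function(g) {
  tibble(
    aa = g$aa, succ_aa = g$succ_aa, successor_size = g$successor_size,
    rmsd = g$rmsd, cdr_loop = g$cdr_loop, fab_location = g$fab_location,
    sec_struct = g$sec_struct,
    next_diff_ss_n = g$next_diff_ss_n, next_diff_ss_c = g$next_diff_ss_c,
    phi = wrap_angle(g$phi_mu + rnorm(1, 0, 8)),
    psi = wrap_angle(g$psi_mu + rnorm(1, 0, 8)),
    chi1 = wrap_angle(g$chi1_mu + rnorm(1, 0, 8)),
    res_sasa = g$sasa_mu * exp(rnorm(1, 0, 0.15)),
    succ_N_sasa = g$succ_n_sasa_mu * exp(rnorm(1, 0, 0.2)),
    dist_cg_n1 = max(2.5, g$dist_mu + rnorm(1, 0, 0.2)),
    cgonc = wrap_angle(runif(1, -180, 180)),
    bend = max(3, g$bend_mu + rnorm(1, 0, 0.2)),
    hb_sidechain = g$hb_sidechain, succ_N_hbonds = g$succ_N_hbonds,
    pos_in_coil = if (g$sec_struct == "coil") {
      if (min(g$next_diff_ss_n, g$next_diff_ss_c) <= 2) "margin" else "center"
    } else {
      "n.a."
    },
    pka = NA_real_, is_terminal = FALSE
  )
}

#' Simulate a labelled descriptor dataset with planted tree rules
#'
#' Draws descriptor vectors from documented per-field distributions,
#' grouped into ensembles whose members share group-level values (the
#' flexibility, successor and location fields are ensemble properties;
#' dihedrals and surface areas vary per member). Each group is labelled
#' by applying `rule_tree` to its members with the at-least-one rule,
#' then the label is flipped with probability `noise`. When
#' `class_fraction` is given, groups are sampled by rejection until the
#' requested number of hotspot groups is reached, reproducing a chosen
#' class imbalance exactly (before noise).
#'
#' @param n_groups Number of residue groups.
#' @param class_fraction Desired hotspot fraction (e.g. 0.027), or `NULL`
#'   for the natural rate of the field distributions under `rule_tree`.
#' @param rule_tree The labelling `fv_tree` (e.g.
#'   [published_asp_tree()]).
#' @param noise Label-flip probability after assignment.
#' @param members Ensemble members per group.
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @return A tibble: descriptor columns plus `group_id`, `label`.
#' @export
simulate_labelled_dataset <- function(n_groups, class_fraction = NULL,
                                      rule_tree = published_asp_tree(),
                                      noise = 0, members = 5, seed = 1) {
  if (!is.null(class_fraction) &&
    (class_fraction <= 0 || class_fraction >= 1)) {
    abort("class_fraction must be in (0, 1)")
  }
  set.seed(seed)
  aa <- rule_tree$aa
  if (!aa %in% c("N", "D")) aa <- "D"
  make_group <- function(gid) {
    g <- sample_group(aa)
    mem <- bind_rows(lapply(seq_len(members), function(k) sample_member(g)))
    cls <- vapply(seq_len(members), function(k) {
      classify_residue(mem[k, ], rule_tree)$class
    }, character(1))
    lab <- if (any(cls == POS_CLASS)) POS_CLASS else NEG_CLASS
    mem$group_id <- gid
    mem$label <- lab
    mem
  }
  out <- list()
  if (is.null(class_fraction)) {
    for (i in seq_len(n_groups)) out[[i]] <- make_group(i)
  } else {
    want_pos <- round(n_groups * class_fraction)
    want_neg <- n_groups - want_pos
    got_pos <- 0L
    got_neg <- 0L
    tries <- 0L
    while (got_pos < want_pos || got_neg < want_neg) {
      tries <- tries + 1L
      if (tries > 500 * n_groups) {
        abort("rejection sampling failed to reach the class fraction")
      }
      g <- make_group(got_pos + got_neg + 1L)
      if (g$label[1] == POS_CLASS && got_pos < want_pos) {
        got_pos <- got_pos + 1L
        out[[length(out) + 1]] <- g
      } else if (g$label[1] == NEG_CLASS && got_neg < want_neg) {
        got_neg <- got_neg + 1L
        out[[length(out) + 1]] <- g
      }
    }
  }
  tb <- bind_rows(out)
  tb$group_id <- match(tb$group_id, unique(tb$group_id))
  if (noise > 0) {
    gids <- unique(tb$group_id)
    flip <- gids[runif(length(gids)) < noise]
    sel <- tb$group_id %in% flip
    tb$label[sel] <- ifelse(tb$label[sel] == POS_CLASS, NEG_CLASS, POS_CLASS)
  }
  tb
}
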