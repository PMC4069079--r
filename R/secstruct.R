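## Secondary-structure assignment in the Kabsch-Sander style: backbone
## amide hydrogens are placed geometrically, N-H...O=C hydrogen bonds are
## scored with the classical electrostatic energy term, and helices,
## sheets and turns are derived from n-turn and bridge patterns. The
## eight-letter alphabet is collapsed to the four classes used by the
## descriptor set: helix (H/G/I), sheet (E/B), turn (T), coil (everything
## else).

KS_Q <- 0.084 * 332 # kcal/mol * A, Kabsch-Sander coupling constant
KS_CUTOFF <- -0.5 # kcal/mol

## Backbone table of one model: one row per residue with N/CA/C/O coords
## and an inferred amide H (N-H antiparallel to the preceding C=O).
backbone_table <- function(model) {
  rs <- model_residues(model)
  get <- function(i, elety) {
    atom_xyz(model, rs$chain_role[i], rs$ordinal[i], elety)
  }
  n <- nrow(rs)
  N <- CA <- CC <- O <- H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C", "O")) {
      v <- get(i, nm)
      if (!is.null(v)) {
        switch(nm,
          N = N[i, ] <- v, CA = CA[i, ] <- v,
          C = CC[i, ] <- v, O = O[i, ] <- v
        )
      }
    }
  }
  for (i in seq_len(n)) {
    if (i == 1 || rs$chain_role[i] != rs$chain_role[i - 1]) next
    if (anyNA(c(N[i, ], CC[i - 1, ], O[i - 1, ]))) next
    co <- CC[i - 1, ] - O[i - 1, ]
    H[i, ] <- N[i, ] + co / vnorm(co)
  }
  list(res = rs, N = N, CA = CA, C = CC, O = O, H = H)
}

## Kabsch-Sander H-bond energy: donor residue i (N-H), acceptor residue j
## (C=O). Returns +Inf when atoms are missing.
ks_energy <- function(bb, i, j) {
  if (anyNA(c(bb$N[i, ], bb$H[i, ], bb$O[j, ], bb$C[j, ]))) return(Inf)
  rON <- dist3(bb$O[j, ], bb$N[i, ])
  rCH <- dist3(bb$C[j, ], bb$H[i, ])
  rOH <- dist3(bb$O[j, ], bb$H[i, ])
  rCN <- dist3(bb$C[j, ], bb$N[i, ])
  if (min(rON, rCH, rOH, rCN) < 0.5) return(Inf) # clashing geometry
  KS_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

## Boolean H-bond matrix hb[i, j]: N-H of residue i donates to C=O of j.
ks_hbond_matrix <- function(bb) {
  n <- nrow(bb$res)
  hb <- matrix(FALSE, n, n)
  ca_ok <- !is.na(bb$CA[, 1])
  for (i in seq_len(n)) {
    if (!ca_ok[i] || bb$res$aa[i] == "P") next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 &&
        bb$res$chain_role[i] == bb$res$chain_role[j]) {
        next
      }
      if (!ca_ok[j]) next
      if (dist3(bb$CA[i, ], bb$CA[j, ]) > 9) next
      if (ks_energy(bb, i, j) < KS_CUTOFF) hb[i, j] <- TRUE
    }
  }
  hb
}

#' Assign four-class secondary structure to every residue
#'
#' Hydrogen-bond based assignment in the Kabsch-Sander style, collapsed
#' to `helix` (alpha/3-10/pi), `sheet` (parallel or antiparallel bridges,
#' including isolated ones), `turn` (unpaired n-turns) and `coil`.
#' Residues with an incomplete backbone are assigned `coil` with a
#' warning.
#'
#' @param model An `fv_model`.
#' @return A tibble `chain_role`, `ordinal`, `sec_struct`.
#' @export
assign_secondary_structure <- function(model) {
  bb <- backbone_table(model)
  rs <- bb$res
  n <- nrow(rs)
  if (any(!rs$complete_backbone)) {
    warn("residues with incomplete backbone assigned 'coil'")
  }
  hb <- ks_hbond_matrix(bb)
  same_chain <- outer(rs$chain_role, rs$chain_role, "==")
  helix <- sheet <- turn <- rep(FALSE, n)
  # n-turns: donor i+k -> acceptor i; consecutive turns make a helix
  for (k in c(4, 3, 5)) {
    turn_start <- rep(FALSE, n)
    for (i in seq_len(max(0, n - k))) {
      if (same_chain[i, i + k] && hb[i + k, i]) turn_start[i] <- TRUE
    }
    for (i in which(turn_start)) {
      if (i > 1 && turn_start[i - 1]) {
        helix[i:(i + k - 1)] <- TRUE
      }
    }
    for (i in which(turn_start)) {
      span <- (i + 1):(i + k - 1)
      turn[span] <- TRUE
    }
  }
  # bridges (parallel / antiparallel)
  inner <- if (n >= 3) 2:(n - 1) else integer(0)
  for (i in inner) {
    for (j in inner) {
      if (i == j) next
      if (same_chain[i, j] && abs(i - j) < 3) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) sheet[i] <- TRUE
    }
  }
  cls <- rep("coil", n)
  cls[turn] <- "turn"
  cls[sheet] <- "sheet"
  cls[helix] <- "helix"
  cls[!rs$complete_backbone] <- "coil"
  tibble(
    chain_role = rs$chain_role, ordinal = rs$ordinal, sec_struct = cls
  )
}

#' Secondary-structure context of one residue
#'
#' Distances (in residues) to the next residue with a different
#' secondary-structure class in the N- and C-terminal direction, and the
#' position-in-coil label. A `margin` position has a different element
#' one or two residues away on either side; coil residues further from
#' any change are `center`; non-coil residues are `n.a.`. When no
#' different element occurs before the chain end, the distance runs to
#' one past the chain end and the corresponding `open_*` flag is set.
#'
#' @param ss Character vector of per-residue classes for one chain, in
#'   ordinal order.
#' @param ordinal 0-based position within the chain.
#' @return A one-row tibble `next_diff_ss_n`, `next_diff_ss_c`, `open_n`,
#'   `open_c`, `pos_in_coil`.
#' @export
ss_context <- function(ss, ordinal) {
  n <- length(ss)
  i <- ordinal + 1L
  if (i < 1 || i > n) abort("ordinal outside chain")
  dn <- dc <- NA_integer_
  open_n <- open_c <- FALSE
  js <- which(ss[seq_len(i - 1)] != ss[i])
  if (length(js) > 0) dn <- i - max(js) else {
    dn <- i # distance to one before the first residue
    open_n <- TRUE
  }
  js <- which(ss[seq(i, n)] != ss[i])
  if (length(js) > 0) dc <- min(js) - 1L else {
    dc <- n - i + 1L
    open_c <- TRUE
  }
  pos <- if (ss[i] != "coil") {
    "n.a."
  } else if (min(dn, dc) <= 2L) {
    "margin"
  } else {
    "center"
  }
  tibble(
    next_diff_ss_n = as.integer(dn), next_diff_ss_c = as.integer(dc),
    open_n = open_n, open_c = open_c, pos_in_coil = pos
  )
}
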