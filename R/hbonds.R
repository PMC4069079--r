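## Geometric hydrogen-bond detection on heavy atoms. The criterion
## (donor-acceptor distance <= 3.5 A, donor angle >= 120 deg with the
## hydrogen direction inferred from the donor's closest bonded heavy
## atom) is a conventional heavy-atom definition; both parameters are
## configurable.

## Donor / acceptor capability by PDB atom name.
DONOR_NAMES <- c(
  "N", "ND1", "ND2", "NE", "NE1", "NE2", "NH1", "NH2", "NZ",
  "OG", "OG1", "OH", "SG"
)
ACCEPTOR_NAMES <- c(
  "O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH", "OXT",
  "ND1", "NE2", "SD"
)

#' Hydrogen-bond criterion parameters
#'
#' @param dist_max Maximum donor-acceptor heavy-atom distance (Angstrom).
#' @param angle_min Minimum angle (degrees) at the donor between its
#'   closest bonded heavy atom, the donor, and the acceptor.
#' @return A named list.
#' @export
hbond_criterion <- function(dist_max = 3.5, angle_min = 120) {
  list(dist_max = dist_max, angle_min = angle_min)
}

## All donor-acceptor pairs of a model satisfying the criterion.
## Backbone amide of proline has no H and is excluded as a donor.
hbond_pairs <- function(model, criterion = hbond_criterion()) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  don <- which(a$elety %in% DONOR_NAMES & !(a$elety == "N" & a$aa == "P"))
  acc <- which(a$elety %in% ACCEPTOR_NAMES)
  if (length(don) == 0 || length(acc) == 0) {
    return(tibble(donor = integer(), acceptor = integer()))
  }
  # antecedent of each donor: closest heavy atom within covalent range
  antecedent <- function(i) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    d[i] <- Inf
    cand <- which(d < 1.8)
    if (length(cand) == 0) return(NA_integer_)
    cand[which.min(d[cand])]
  }
  ante <- vapply(don, antecedent, integer(1))
  res_key <- paste(a$chain_role, a$ordinal)
  out_d <- integer(0)
  out_a <- integer(0)
  for (k in seq_along(don)) {
    i <- don[k]
    if (is.na(ante[k])) next
    d <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[i, ])^2))
    ok <- which(d <= criterion$dist_max & res_key[acc] != res_key[i])
    for (j in acc[ok]) {
      ang <- vec_angle(xyz[ante[k], ], xyz[i, ], xyz[j, ])
      if (ang >= criterion$angle_min) {
        out_d <- c(out_d, i)
        out_a <- c(out_a, j)
      }
    }
  }
  tibble(donor = out_d, acceptor = out_a)
}

#' Count hydrogen bonds involving specific atoms
#'
#' Counts donor-acceptor pairs (per the geometric criterion) in which any
#' of the target atoms participates, on either side. Pairs within the
#' target residue itself are excluded. The per-residue head-group count of
#' the descriptor set sums over the head group's target atoms.
#'
#' @param model An `fv_model`.
#' @param chain_role,ordinal Residue address of the target atoms.
#' @param atom_names Atom names of interest (e.g. `c("OD1","OD2")` for an
#'   Asp side chain, `"ND2"` for Asn, `"N"` for a backbone nitrogen).
#' @param criterion A [hbond_criterion()].
#' @param pairs Optional precomputed [hbond_pairs()] table for the model
#'   (to avoid recomputation across residues).
#' @return Integer count.
#' @export
count_hbonds <- function(model, chain_role, ordinal, atom_names,
                         criterion = hbond_criterion(), pairs = NULL) {
  if (is.null(pairs)) pairs <- hbond_pairs(model, criterion)
  a <- model$atoms
  targets <- which(a$chain_role == chain_role & a$ordinal == ordinal &
    a$elety %in% atom_names)
  if (length(targets) == 0) return(NA_integer_)
  sum(pairs$donor %in% targets | pairs$acceptor %in% targets)
}
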