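## Solvent-accessible surface area by the Shrake-Rupley point-counting
## method: each atom is covered with a quasi-uniform sphere of test points
## at radius r_vdw + r_probe; a point is accessible if it lies outside the
## probe-expanded sphere of every neighbouring atom.

## Van der Waals radii (Angstrom), Bondi-style values common in SASA codes.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)
VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- unname(VDW_RADII[toupper(element)])
  miss <- is.na(r)
  if (any(miss)) {
    warn(paste0(
      "unknown element(s) ", paste(unique(element[miss]), collapse = ","),
      "; using default vdW radius ", VDW_DEFAULT, " A"
    ))
    r[miss] <- VDW_DEFAULT
  }
  r
}

## Deterministic quasi-uniform unit-sphere points (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley numeric SASA with a water-sized probe. An isolated atom
#' of vdW radius r yields the closed form 4*pi*(r + probe)^2; a fully
#' buried atom yields 0.
#'
#' @param coords Numeric matrix (n x 3) of atom coordinates (Angstrom), or
#'   an `fv_model` (its atom coordinates and elements are used).
#' @param elements Character vector of element symbols (ignored when
#'   `coords` is a model).
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom (>= 960 recommended).
#' @return Numeric vector of per-atom SASA in Angstrom^2.
#' @export
sasa_atoms <- function(coords, elements = NULL, probe_radius = 1.4,
                       n_points = 960) {
  if (inherits(coords, "fv_model")) {
    elements <- coords$atoms$element
    coords <- as.matrix(coords$atoms[, c("x", "y", "z")])
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0) return(numeric(0))
  radii <- vdw_radius(elements) + probe_radius
  pts <- sphere_points(n_points)
  # neighbour lists from the full distance matrix (Fv-sized systems)
  d2 <- as.matrix(stats::dist(coords))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (radii[i] + radii)^2
    nbr <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    p <- sweep(pts * radii[i], 2, coords[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(accessible)) break
      dx <- p[accessible, 1] - coords[j, 1]
      dy <- p[accessible, 2] - coords[j, 2]
      dz <- p[accessible, 3] - coords[j, 3]
      accessible[accessible] <- dx * dx + dy * dy + dz * dz > radii[j]^2
    }
    out[i] <- 4 * pi * radii[i]^2 * sum(accessible) / n_points
  }
  out
}

#' Per-residue SASA of a model
#'
#' @param model An `fv_model`.
#' @param probe_radius,n_points As in [sasa_atoms()].
#' @return A tibble `chain_role`, `ordinal`, `sasa` (sum over the
#'   residue's atoms, Angstrom^2).
#' @export
sasa_residues <- function(model, probe_radius = 1.4, n_points = 960) {
  s <- sasa_atoms(model, probe_radius = probe_radius, n_points = n_points)
  model$atoms %>%
    mutate(atom_sasa = s) %>%
    group_by(.data$chain_role, .data$ordinal) %>%
    summarise(sasa = sum(.data$atom_sasa), .groups = "drop")
}
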