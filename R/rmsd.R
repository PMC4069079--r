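## Ensemble superposition and per-residue CA flexibility.

## CA coordinate matrix (residues x 3) of a model, in residue-table order.
ca_matrix <- function(model) {
  rs <- model_residues(model)
  m <- matrix(NA_real_, nrow(rs), 3)
  for (i in seq_len(nrow(rs))) {
    v <- atom_xyz(model, rs$chain_role[i], rs$ordinal[i], "CA")
    if (!is.null(v)) m[i, ] <- v
  }
  m
}

## Kabsch least-squares superposition of `mobile` onto `fixed` using the
## paired rows `idx`; returns the transform applied to a full n x 3 set.
kabsch_transform <- function(fixed, mobile, idx) {
  A <- mobile[idx, , drop = FALSE]
  B <- fixed[idx, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, center_mobile = ca, center_fixed = cb)
}

apply_transform <- function(coords, tr) {
  sweep(sweep(coords, 2, tr$center_mobile) %*% t(tr$R), 2,
    tr$center_fixed, "+"
  )
}

#' Superpose all ensemble members on framework CA atoms
#'
#' Least-squares (Kabsch) superposition of every member onto the first,
#' fitted on framework CA atoms only (CDRs excluded) so that loop
#' variability is not absorbed into the fit. With `fit_cdr = TRUE` all CA
#' atoms are used instead.
#'
#' @param ensemble An `fv_ensemble`.
#' @param annotations Region annotations from [annotate_regions()]
#'   (needed to exclude CDRs); `NULL` fits on all CA atoms.
#' @param fit_cdr Include CDR residues in the fit.
#' @return A superposed `fv_ensemble`.
#' @export
superpose_ensemble <- function(ensemble, annotations = NULL,
                               fit_cdr = FALSE) {
  if (length(ensemble) == 1) return(ensemble)
  rs <- model_residues(ensemble$models[[1]])
  use <- rep(TRUE, nrow(rs))
  if (!fit_cdr && !is.null(annotations)) {
    ann <- left_join(rs, annotations,
      by = c("chain_role", "ordinal"),
      suffix = c("", ".ann")
    )
    use <- !ann$in_cdr
  }
  fixed <- ca_matrix(ensemble$models[[1]])
  models <- ensemble$models
  for (k in seq_along(models)[-1]) {
    mob <- ca_matrix(models[[k]])
    idx <- which(use & !is.na(fixed[, 1]) & !is.na(mob[, 1]))
    if (length(idx) < 3) abort("too few paired CA atoms for superposition")
    tr <- kabsch_transform(fixed, mob, idx)
    xyz <- as.matrix(models[[k]]$atoms[, c("x", "y", "z")])
    xyz <- apply_transform(xyz, tr)
    models[[k]]$atoms$x <- xyz[, 1]
    models[[k]]$atoms$y <- xyz[, 2]
    models[[k]]$atoms$z <- xyz[, 3]
  }
  ensemble$models <- models
  ensemble
}

#' Per-residue CA RMSD across an ensemble
#'
#' Root-mean-square deviation of each residue's CA position from its
#' ensemble-mean position, the flexibility proxy used by the hotspot
#' classifiers. For two models whose CA differ by d, the value is d/2;
#' for a single-model ensemble it is 0 for every residue.
#'
#' @param ensemble An `fv_ensemble`, ideally already superposed via
#'   [superpose_ensemble()].
#' @return A tibble `chain_role`, `ordinal`, `rmsd` (Angstrom).
#' @export
ensemble_rmsd <- function(ensemble) {
  rs <- model_residues(ensemble$models[[1]])
  mats <- lapply(ensemble$models, ca_matrix)
  if (length(mats) == 1) {
    inform("single-model ensemble: per-residue RMSD is 0")
    return(tibble(
      chain_role = rs$chain_role, ordinal = rs$ordinal,
      rmsd = ifelse(is.na(mats[[1]][, 1]), NA_real_, 0)
    ))
  }
  n <- nrow(rs)
  out <- numeric(n)
  for (i in seq_len(n)) {
    P <- do.call(rbind, lapply(mats, function(m) m[i, ]))
    if (anyNA(P)) {
      out[i] <- NA_real_
      next
    }
    mu <- colMeans(P)
    out[i] <- sqrt(mean(rowSums(sweep(P, 2, mu)^2)))
  }
  tibble(chain_role = rs$chain_role, ordinal = rs$ordinal, rmsd = out)
}
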