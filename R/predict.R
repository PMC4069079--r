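## Ensemble aggregation and end-to-end hotspot prediction.

#' Aggregate per-member classifications into a residue-level call
#'
#' Implements the ensemble alert rule: a residue is called a hotspot if
#' at least one ensemble member is classified as a hotspot. The
#' quantitative output is the mean and standard deviation of the members'
#' hotspot probabilities (a member at a non-hotspot leaf contributes
#' 1 - leaf probability).
#'
#' @param member_calls A data frame with one row per ensemble member and
#'   columns `class`, `p_hotspot`, `hotspot_class` (as produced by
#'   [classify_residue()]).
#' @return A one-row tibble: `call`, `hotspot_class` (most frequent class
#'   among hotspot members, `NA` if none), `p_mean`, `p_sd` (0 for a
#'   single member), `n_members_hotspot`, `n_members`.
#' @export
aggregate_ensemble <- function(member_calls) {
  if (is.null(member_calls) || nrow(member_calls) == 0) {
    abort("aggregate_ensemble needs at least one member result")
  }
  n_hot <- sum(member_calls$class == "hotspot")
  hs_class <- NA_integer_
  if (n_hot > 0) {
    cls <- member_calls$hotspot_class[member_calls$class == "hotspot"]
    cls <- cls[!is.na(cls)]
    if (length(cls) > 0) {
      hs_class <- as.integer(names(sort(table(cls), decreasing = TRUE))[1])
    }
  }
  p <- member_calls$p_hotspot
  tibble(
    call = if (n_hot >= 1) "hotspot" else "non-hotspot",
    hotspot_class = hs_class,
    p_mean = mean(p),
    p_sd = if (length(p) > 1) sd(p) else 0,
    n_members_hotspot = as.integer(n_hot),
    n_members = nrow(member_calls)
  )
}

#' Classify a descriptor table residue-by-residue
#'
#' Routes Asp rows to the Asp tree and Asn rows to the Asn tree, then
#' aggregates the ensemble members of each residue with the at-least-one
#' rule. Terminal residues are excluded (they lack phi/psi).
#'
#' @param descriptors Descriptor tibble from [extract_descriptors()] (or
#'   read back via [read_descriptors()]).
#' @param asp_tree,asn_tree Decision trees; default the published ones.
#' @return A tibble with one row per residue: identity columns (`name`,
#'   `chain_role`, `ordinal`, `resno`, `aa`, `succ_aa`, `motif`,
#'   `fab_location`, `cdr_loop`) and the aggregated prediction (`call`,
#'   `hotspot_class`, `p_mean`, `p_sd`, `n_members_hotspot`,
#'   `n_members`).
#' @export
classify_descriptors <- function(descriptors,
                                 asp_tree = published_asp_tree(),
                                 asn_tree = published_asn_tree()) {
  d <- filter(descriptors, !.data$is_terminal, .data$aa %in% c("N", "D"))
  if (nrow(d) == 0) {
    return(tibble(
      name = character(), chain_role = character(), ordinal = integer(),
      resno = integer(), aa = character(), succ_aa = character(),
      motif = character(), fab_location = integer(), cdr_loop = integer(),
      call = character(), hotspot_class = integer(), p_mean = numeric(),
      p_sd = numeric(), n_members_hotspot = integer(),
      n_members = integer()
    ))
  }
  keys <- distinct(d, .data$name, .data$chain_role, .data$ordinal)
  out <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- filter(
      d, .data$name == keys$name[i],
      .data$chain_role == keys$chain_role[i],
      .data$ordinal == keys$ordinal[i]
    )
    tree <- if (rows$aa[1] == "D") asp_tree else asn_tree
    calls <- bind_rows(lapply(seq_len(nrow(rows)), function(k) {
      res <- classify_residue(rows[k, ], tree)
      tibble(
        class = res$class, prob = res$prob,
        hotspot_class = res$hotspot_class, p_hotspot = res$p_hotspot
      )
    }))
    agg <- aggregate_ensemble(calls)
    bind_cols(
      rows[1, c(
        "name", "chain_role", "ordinal", "resno", "aa", "succ_aa",
        "motif", "fab_location", "cdr_loop"
      )],
      agg
    )
  })
  bind_rows(out)
}

#' Predict degradation hotspots for an Fv ensemble
#'
#' The full pipeline: annotate regions, extract descriptors, classify
#' every Asn/Asp with the published (or supplied) trees, and aggregate the
#' ensemble members into per-residue hotspot calls.
#'
#' @param ensemble An `fv_ensemble` or single `fv_model`.
#' @param ranges Optional [cdr_ranges()]; `NULL` auto-detects.
#' @param asp_tree,asn_tree Decision trees (defaults: published).
#' @param ... Passed to [extract_descriptors()].
#' @return The residue-level prediction tibble of
#'   [classify_descriptors()].
#' @export
predict_hotspots <- function(ensemble, ranges = NULL,
                             asp_tree = published_asp_tree(),
                             asn_tree = published_asn_tree(), ...) {
  if (inherits(ensemble, "fv_model")) {
    ensemble <- build_fv_ensemble(list(ensemble))
  }
  ann <- annotate_regions(ensemble, ranges)
  desc <- extract_descriptors(ensemble, annotations = ann, ...)
  classify_descriptors(desc, asp_tree = asp_tree, asn_tree = asn_tree)
}

#' Sequence-motif baseline hotspot prediction
#'
#' The sequence-only comparator: every Asn/Asp inside a CDR whose
#' successor forms one of the baseline motifs (NG, NS, NT, DG, DS, DT,
#' DD, DH; note NN is not part of this baseline) is called a hotspot.
#'
#' @param sequence One-letter chain sequence.
#' @param ranges3 CDR ranges of this chain (list of three
#'   `c(start, end)` ordinal pairs).
#' @param cdr_only Restrict calls to CDR residues (the published
#'   baseline); `FALSE` scans the whole chain.
#' @return A tibble with one row per Asn/Asp in scope: `ordinal`, `aa`,
#'   `motif` (`NA` when the successor forms no baseline motif), `call`.
#' @export
sequence_baseline <- function(sequence, ranges3, cdr_only = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  ords <- seq_along(chars) - 1L
  keep <- chars %in% c("N", "D")
  if (cdr_only) {
    keep <- keep &
      vapply(ords, function(o) cdr_loop_of(o, ranges3) > 0L, logical(1))
  }
  idx <- which(keep)
  motif <- vapply(idx, function(i) {
    if (i < length(chars)) paste0(chars[i], chars[i + 1]) else NA_character_
  }, character(1))
  motif[!motif %in% BASELINE_MOTIFS] <- NA_character_
  tibble(
    ordinal = ords[idx], aa = chars[idx], motif = motif,
    call = ifelse(is.na(motif), "non-hotspot", "hotspot")
  )
}
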