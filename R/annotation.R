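## CDR/framework annotation: Fab-location coding 1-14, CDR loop numbers,
## anchor-based CDR auto-detection, and sequence-motif scanning.
##
## The Fab-location code walks the Fv from the heavy chain N-terminus:
## 1 FR-H1, 2 CDR-H1, 3 FR-H2, 4 CDR-H2, 5 FR-H3, 6 CDR-H3, 7 FR-H4,
## then the light chain: 8 FR-L1, 9 CDR-L1, 10 FR-L2, 11 CDR-L2,
## 12 FR-L3, 13 CDR-L3, 14 FR-L4. Even codes are the CDRs.

#' Construct explicit CDR ranges
#'
#' Ranges are half-open nowhere: both ends are inclusive and given as
#' 0-based ordinals within the chain. Use [auto_cdr_ranges()] to detect
#' ranges from conserved anchor motifs instead.
#'
#' @param heavy,light Each a list of three `c(start, end)` integer vectors
#'   (0-based ordinals, inclusive) for CDR 1-3 of that chain. An empty
#'   CDR may be given as `NULL`.
#' @return A `cdr_ranges` object.
#' @export
cdr_ranges <- function(heavy, light) {
  check_side <- function(side, nm) {
    if (length(side) != 3) abort(paste0(nm, " must list exactly 3 CDRs"))
    prev_end <- -1L
    for (i in seq_len(3)) {
      r <- side[[i]]
      if (is.null(r)) next
      if (length(r) != 2 || r[1] > r[2] || r[1] < 0) {
        abort(paste0("invalid ", nm, " CDR", i, " range"))
      }
      if (r[1] <= prev_end) {
        abort(paste0(nm, " CDR ranges must be ascending and disjoint"))
      }
      prev_end <- r[2]
    }
    side
  }
  structure(
    list(H = check_side(heavy, "heavy"), L = check_side(light, "light")),
    class = "cdr_ranges"
  )
}

#' @export
print.cdr_ranges <- function(x, ...) {
  fmt <- function(r) if (is.null(r)) "-" else paste0(r[1], "..", r[2])
  for (role in c("H", "L")) {
    cat(role, ": ", paste(vapply(x[[role]], fmt, ""), collapse = "  "),
      "\n",
      sep = ""
    )
  }
  invisible(x)
}

## Anchor-motif heuristics for classical combined Kabat+Chothia CDR limits.
## These use the conserved Cys/Trp/Phe framework anchors rather than a full
## numbering-scheme alignment (see the package vignette for the rationale
## and limits of this choice).
auto_cdr_one <- function(seq, role) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  cys <- which(chars == "C")
  if (length(cys) < 2) {
    abort(paste0(
      "CDR auto-detection failed for the ", role, " chain ",
      "(need two conserved Cys); supply explicit cdr_ranges()"
    ))
  }
  c1 <- cys[1]
  c2 <- cys[length(cys)]
  fail <- function(what) {
    abort(paste0(
      "CDR auto-detection failed for the ", role, " chain (", what,
      " anchor not found); supply explicit cdr_ranges()"
    ))
  }
  if (role == "H") {
    # CDR-H1: starts 4 after the first Cys (combined definition begins at
    # Chothia 26), ends before the conserved Trp.
    w <- which(chars == "W")
    w <- w[w > c1 + 4]
    if (length(w) == 0) fail("Trp(H1)")
    h1 <- c(c1 + 4, w[1] - 1)
    # CDR-H3: starts 3 after the last Cys, ends before the W-G-x-G motif.
    wgxg <- regexpr("WG.G", substr(seq, c2, n))
    if (wgxg < 0) fail("WGxG")
    h3 <- c(c2 + 3, c2 + wgxg - 2)
    # CDR-H2: starts 15 after the end of H1 and ends 33 before the start
    # of H3 (classical spacing rules).
    h2 <- c(h1[2] + 15, h3[1] - 33)
    if (h2[1] > h2[2] || h2[2] <= h1[2] || h3[1] <= h2[2]) fail("H2 spacing")
    ranges <- list(h1, h2, h3)
  } else {
    # CDR-L1: from just after the first Cys to before the conserved Trp.
    w <- which(chars == "W")
    w <- w[w > c1 + 1]
    if (length(w) == 0) fail("Trp(L1)")
    l1 <- c(c1 + 1, w[1] - 1)
    # CDR-L2: starts 16 after the end of L1, 7 residues long.
    l2 <- c(l1[2] + 16, l1[2] + 22)
    # CDR-L3: starts 2 after the last Cys, ends before the F-G-x-G motif.
    fgxg <- regexpr("FG.G", substr(seq, c2, n))
    if (fgxg < 0) fail("FGxG")
    l3 <- c(c2 + 1, c2 + fgxg - 2)
    if (l2[2] >= l3[1] || l2[1] <= l1[2]) fail("L2 spacing")
    ranges <- list(l1, l2, l3)
  }
  lapply(ranges, function(r) as.integer(r - 1)) # to 0-based ordinals
}

#' Detect CDR ranges from conserved anchor motifs
#'
#' A light-weight alternative to full antibody numbering: CDR limits are
#' located relative to the conserved framework Cys/Trp anchors and the
#' `WGxG` / `FGxG` J-segment motifs, approximating combined Kabat+Chothia
#' loop definitions. Explicit [cdr_ranges()] always take precedence in
#' downstream functions; auto-detection fails loudly when an anchor is
#' missing.
#'
#' @param heavy_seq,light_seq One-letter amino-acid sequences of the heavy
#'   and light variable domains.
#' @return A `cdr_ranges` object (0-based ordinals).
#' @export
auto_cdr_ranges <- function(heavy_seq, light_seq) {
  cdr_ranges(
    heavy = auto_cdr_one(heavy_seq, "H"),
    light = auto_cdr_one(light_seq, "L")
  )
}

cdr_loop_of <- function(ordinal, ranges3) {
  for (i in seq_len(3)) {
    r <- ranges3[[i]]
    if (!is.null(r) && ordinal >= r[1] && ordinal <= r[2]) return(i)
  }
  0L
}

#' Annotate every Fv residue with region labels
#'
#' Assigns each residue of both chains its Fab-location code (1-14), CDR
#' loop number (0 for framework, 1-3 in a CDR) and an `in_cdr` flag.
#' Annotations depend only on the sequence, so they are identical across
#' ensemble members.
#'
#' @param x An `fv_ensemble`, `fv_model`, or a list with `heavy`/`light`
#'   one-letter sequences.
#' @param ranges A [cdr_ranges()] object, or `NULL` to auto-detect via
#'   [auto_cdr_ranges()].
#' @return A tibble with columns `chain_role`, `ordinal`, `aa`,
#'   `fab_location`, `cdr_loop`, `in_cdr`.
#' @export
annotate_regions <- function(x, ranges = NULL) {
  seqs <- fv_sequences(x)
  if (is.null(ranges)) {
    ranges <- auto_cdr_ranges(seqs$H, seqs$L)
  }
  out <- lapply(c("H", "L"), function(role) {
    chars <- strsplit(seqs[[role]], "")[[1]]
    ords <- seq_along(chars) - 1L
    loop <- vapply(ords, cdr_loop_of, integer(1), ranges3 = ranges[[role]])
    base <- if (role == "H") 0L else 7L
    # framework k precedes CDR k; framework 4 follows CDR 3
    fw <- cummax_loop(loop)
    fab <- ifelse(loop > 0L, base + 2L * loop, base + 2L * fw + 1L)
    tibble(
      chain_role = role, ordinal = ords, aa = chars,
      fab_location = as.integer(fab), cdr_loop = as.integer(loop),
      in_cdr = loop > 0L
    )
  })
  bind_rows(out)
}

## Number of CDR loops fully passed at each position (for framework codes).
cummax_loop <- function(loop) {
  passed <- 0L
  out <- integer(length(loop))
  for (i in seq_along(loop)) {
    if (loop[i] > 0L) passed <- max(passed, loop[i])
    out[i] <- if (loop[i] > 0L) passed else passed
  }
  out
}

fv_sequences <- function(x) {
  if (inherits(x, "fv_ensemble")) x <- x$models[[1]]
  if (inherits(x, "fv_model")) {
    list(H = model_sequence(x, "H"), L = model_sequence(x, "L"))
  } else if (is.list(x) && all(c("heavy", "light") %in% names(x))) {
    list(H = x$heavy, L = x$light)
  } else {
    abort("cannot derive chain sequences from this object")
  }
}

## The nine degradation-associated sequence motifs.
HOTSPOT_MOTIFS <- c("NG", "NN", "NS", "NT", "DG", "DS", "DT", "DD", "DH")
## The motif set of the sequence-only baseline predictor (excludes NN).
BASELINE_MOTIFS <- c("NG", "NS", "NT", "DG", "DS", "DT", "DD", "DH")

#' Scan a chain sequence for degradation motifs
#'
#' Finds each Asn/Asp whose C-terminal neighbour forms one of the nine
#' degradation-associated dipeptide motifs (NG, NN, NS, NT, DG, DS, DT,
#' DD, DH). By default only residues inside a CDR are reported.
#'
#' @param sequence One-letter amino-acid string.
#' @param ranges3 List of three `c(start, end)` 0-based ordinal ranges for
#'   the chain's CDRs (one element of a [cdr_ranges()] object), or `NULL`
#'   with `cdr_only = FALSE`.
#' @param cdr_only If `FALSE`, scan the full chain.
#' @return A tibble with columns `ordinal`, `aa`, `motif`, `cdr_loop`.
#' @export
motif_scan <- function(sequence, ranges3 = NULL, cdr_only = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (i in seq_len(max(0, n - 1))) {
    m <- paste0(chars[i], chars[i + 1])
    if (!m %in% HOTSPOT_MOTIFS) next
    ord <- i - 1L
    loop <- if (is.null(ranges3)) 0L else cdr_loop_of(ord, ranges3)
    if (cdr_only) {
      if (is.null(ranges3)) abort("cdr_only scan needs CDR ranges")
      if (loop == 0L) next
    }
    hits[[length(hits) + 1]] <- tibble(
      ordinal = ord, aa = chars[i], motif = m, cdr_loop = loop
    )
  }
  if (length(hits) == 0) {
    return(tibble(
      ordinal = integer(), aa = character(), motif = character(),
      cdr_loop = integer()
    ))
  }
  bind_rows(hits)
}

#' Motif frequencies across a sequence repertoire
#'
#' Counts each degradation motif across a repertoire of annotated chains
#' and expresses it as a percentage of all CDR Asn (for N-motifs) or all
#' CDR Asp (for D-motifs) - the denominators used when comparing a mAb
#' panel against natural repertoires.
#'
#' @param repertoire A data frame with columns `sequence` and `ranges3`
#'   (a list-column of per-chain CDR range lists), or a character vector of
#'   sequences plus a single `ranges3` shared by all.
#' @param ranges3 Shared CDR ranges when `repertoire` is a plain character
#'   vector.
#' @param cdr_only Restrict both numerator and denominator to CDR residues
#'   (the published comparison); `FALSE` uses whole chains.
#' @return A tibble with `motif`, `count`, `denominator`, `percent`.
#'   Percentages are `NA` (undefined), not 0, when a denominator is zero.
#' @export
motif_frequencies <- function(repertoire, ranges3 = NULL, cdr_only = TRUE) {
  if (is.character(repertoire)) {
    repertoire <- tibble(
      sequence = repertoire,
      ranges3 = replicate(length(repertoire), ranges3, simplify = FALSE)
    )
  }
  counts <- setNames(integer(length(HOTSPOT_MOTIFS)), HOTSPOT_MOTIFS)
  denom_n <- 0L
  denom_d <- 0L
  for (i in seq_len(nrow(repertoire))) {
    s <- repertoire$sequence[i]
    r3 <- repertoire$ranges3[[i]]
    chars <- strsplit(s, "")[[1]]
    ords <- seq_along(chars) - 1L
    in_scope <- if (cdr_only) {
      vapply(ords, function(o) cdr_loop_of(o, r3) > 0L, logical(1))
    } else {
      rep(TRUE, length(chars))
    }
    denom_n <- denom_n + sum(chars == "N" & in_scope)
    denom_d <- denom_d + sum(chars == "D" & in_scope)
    hits <- motif_scan(s, r3, cdr_only = cdr_only)
    for (m in hits$motif) counts[m] <- counts[m] + 1L
  }
  tibble(
    motif = HOTSPOT_MOTIFS,
    count = as.integer(counts),
    denominator = ifelse(startsWith(HOTSPOT_MOTIFS, "N"), denom_n, denom_d),
    percent = ifelse(denominator > 0, 100 * count / denominator, NA_real_)
  )
}
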