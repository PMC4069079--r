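## The successor-size lookup: solvent-accessible surface area of each
## fully exposed amino-acid type (Angstrom^2), used as the size proxy for
## the residue C-terminal to an Asn/Asp.

SUCCESSOR_SIZE <- c(
  A = 64.78, C = 95.24, D = 110.21, E = 143.92, F = 186.70,
  G = 23.13, H = 146.45, I = 151.24, K = 177.37, L = 139.52,
  M = 164.67, N = 113.19, P = 111.53, Q = 147.86, R = 210.02,
  S = 81.22, T = 111.60, V = 124.24, W = 229.62, Y = 200.31
)

#' Fully-exposed SASA lookup table for the 20 amino acids
#'
#' @return A tibble with columns `aa` (one-letter code) and `size`
#'   (Angstrom^2).
#' @export
successor_size_table <- function() {
  tibble(aa = names(SUCCESSOR_SIZE), size = unname(SUCCESSOR_SIZE))
}

#' Successor-size value for amino-acid letters
#'
#' @param aa Character vector of one-letter codes.
#' @return Numeric vector (Angstrom^2); `NA` for non-standard letters.
#' @export
successor_size <- function(aa) {
  unname(SUCCESSOR_SIZE[aa])
}
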