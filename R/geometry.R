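## Vector geometry primitives shared by descriptor extraction and the
## internal-coordinate peptide builder. Coordinates are in Angstrom, angles
## in degrees in (-180, 180].

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("zero-length vector has no direction")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

## Map any angle to the reporting convention (-180, 180].
wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  ifelse(y == -180, 180, y)
}

#' Angle at vertex b of the triple a-b-c, in degrees
#'
#' @param a,b,c Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in \[0, 180\].
#' @export
vec_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed torsion angle over four points
#'
#' Computes the dihedral angle defined by points `p1-p2-p3-p4` with the
#' IUPAC sign convention: looking along the `p2 -> p3` axis, a clockwise
#' rotation of the far bond relative to the near bond is positive. The
#' result is reported in degrees in (-180, 180]; an eclipsed (cis)
#' arrangement gives 0 and an anti (trans) arrangement gives 180.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees, or `NA_real_` for degenerate geometry
#'   (coincident neighbours or collinear central bond with a flank).
#' @export
#' @examples
#' dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)) # cis, 0
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9) {
    return(NA_real_)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    return(NA_real_) # collinear flank: torsion undefined
  }
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(deg(atan2(y, x)))
}

## Place atom D given reference atoms A, B, C, the bond length |C-D|, the
## angle B-C-D and the torsion A-B-C-D (natural-extension reference frame).
## Used by the synthetic peptide builder; exact up to float error, so
## realized torsions reproduce their targets.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  ang <- rad(180 - angle_deg)
  tor <- -rad(torsion_deg) # frame handedness vs the dihedral() convention
  d2 <- bond * c(cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Distance between two 3-vectors.
dist3 <- function(a, b) vnorm(a - b)
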