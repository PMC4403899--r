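## Small 3D geometry toolkit: ideal C-beta construction and internal-coordinate
## atom placement used by the synthetic-structure generator.

#' Construct an ideal virtual C-beta position
#'
#' Places the C-beta atom a residue would have, given its backbone N, CA and C
#' coordinates, using ideal tetrahedral branch geometry and a fixed CA-CB bond
#' length of 1.53 Angstrom (L-amino-acid chirality).  Used so that glycine
#' sites participate in the CB-based scoring function and the disulfide scan
#' on the same footing as all other residues.
#'
#' @param n,ca,c numeric length-3 backbone coordinates (Angstrom).
#' @return numeric length-3 CB coordinate with |CB - CA| = 1.53.
#' @export
#' @examples
#' virtualCbeta(c(1.46, 0, 0), c(0, 0, 0), c(-0.55, 1.42, 0))
virtualCbeta <- function(n, ca, c) {
  stopifnot(length(n) == 3L, length(ca) == 3L, length(c) == 3L)
  if (!all(is.finite(c(n, ca, c)))) .stop2("backbone coordinates must be finite")
  b <- ca - n
  cc <- c - ca
  a <- .vcross(b, cc)
  if (.vnorm(a) < 1e-8 * .vnorm(b) * .vnorm(cc))
    .stop2("degenerate geometry: N, CA and C are collinear")
  dir <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
  ca + 1.53 * .vunit(dir)
}

## Natural extension reference frame (NeRF): place atom D given A-B-C and the
## internal coordinates bond |CD|, angle B-C-D (deg) and torsion A-B-C-D (deg).
.placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign matches the .torsion measurement convention
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- .vunit(c - b)
  nv <- .vunit(.vcross(b - a, bc))
  m <- cbind(bc, .vcross(nv, bc), nv)
  as.numeric(m %*% d2 + c)
}

.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.angle3 <- function(p1, p2, p3) {
  u <- .vunit(p1 - p2); v <- .vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Rigid-body transform of a coordinate matrix (used by assemblies and tests).
.transformCoords <- function(xyz, rot, trans) {
  sweep(xyz %*% t(rot), 2L, trans, "+")
}
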