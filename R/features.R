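## The six non-SSF agent inputs and assembly of the nine-value feature vector.

#' Names of the nine agent input values, in canonical order
#'
#' Three scoring-function deltas, protein size, encoded secondary-structure
#' state, relative ASA and the three substitution property deltas.
#' @export
FEATURE_NAMES <- c("ds_pssf_ca", "ds_pssf_cb", "ds_cssf", "protein_size",
                   "ss_state", "rel_asa", "d_mass", "d_hydro", "d_iep")

.SS_ENCODING <- c(helix = 0, strand = 0.5, coil = 1)

#' Assign 3-state secondary structure from CA geometry
#'
#' A deterministic CA-trace assignment in the spirit of P-SEA: residue
#' windows are classified by characteristic CA(i)-CA(i+k) distances
#' (helix: d(i,i+3) and d(i,i+4); strand: d(i,i+2) and d(i,i+3)), and
#' segments shorter than the minimum length (helix 4, strand 3) are demoted
#' to coil.  Chains are processed independently; degenerate or short
#' geometry yields coil.
#'
#' @param structure a \code{ProteinStructure}.
#' @return character vector over residues with values "helix", "strand",
#'   "coil".
#' @export
assignSecondaryStructure <- function(structure) {
  r <- structure@residues
  out <- rep("coil", nrow(r))
  for (ch in unique(r$chain)) {
    idx <- which(r$chain == ch)
    n <- length(idx)
    if (n < 5L) next
    xyz <- as.matrix(r[idx, c("ca_x", "ca_y", "ca_z")])
    dk <- function(k) {
      m <- n - k
      if (m < 1L) return(numeric(0L))
      sqrt(rowSums((xyz[seq_len(m) + k, , drop = FALSE] -
                    xyz[seq_len(m), , drop = FALSE])^2))
    }
    d2 <- dk(2L); d3 <- dk(3L); d4 <- dk(4L)
    lab <- rep("coil", n)
    ## helix window starting at i covers i..i+3
    hstart <- which(d3 >= 4.6 & d3 <= 5.8 &
                    d4[seq_along(d3)] >= 5.5 & d4[seq_along(d3)] <= 6.9)
    for (i in hstart) lab[i:(i + 3L)] <- "helix"
    ## strand window starting at i covers i..i+2 (helix takes precedence)
    sstart <- which(d2 >= 6.2 & d2 <= 7.2 &
                    c(d3, Inf)[seq_along(d2)] >= 9.4)
    for (i in sstart) {
      span <- i:(i + 2L)
      lab[span][lab[span] == "coil"] <- "strand"
    }
    lab <- .demoteShortSegments(lab, minHelix = 4L, minStrand = 3L)
    out[idx] <- lab
  }
  out
}

.demoteShortSegments <- function(lab, minHelix, minStrand) {
  rl <- rle(lab)
  minLen <- ifelse(rl$values == "helix", minHelix,
                   ifelse(rl$values == "strand", minStrand, 1L))
  rl$values[rl$lengths < minLen] <- "coil"
  inverse.rle(rl)
}

## Deterministic quasi-uniform sphere point set (golden spiral).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Relative solvent accessibility of a residue
#'
#' A residue-level sphere-point (Shrake-Rupley style) estimate: each residue
#' is one sphere at its (possibly virtual) C-beta with a frozen
#' type-specific radius; test points on the probe-inflated sphere of the
#' query residue are accessible when outside every other residue's
#' probe-inflated sphere.  The accessible area is divided by the residue
#' type's isolated-sphere reference area, so an unoccluded residue scores 1.
#'
#' @param structure a \code{ProteinStructure}.
#' @param site residue row index (1-based) or a list/data.frame row with
#'   chain/resno/icode.
#' @param nPoints number of sphere test points (default 256).
#' @param probe probe radius in Angstrom (default 1.4).
#' @return relative ASA in [0, 1].
#' @export
computeRelASA <- function(structure, site, nPoints = 256L, probe = 1.4) {
  r <- structure@residues
  i <- if (is.numeric(site)) as.integer(site)
       else .mutationIndices(structure, mutationSet(
              data.frame(chain = site$chain, resno = site$resno,
                         icode = site$icode %||% "", wt = "A", mut = "G")))
  asaTab <- asaReference()
  rad <- asaTab$radius[match(r$aa, asaTab$aa)]
  centers <- as.matrix(r[, c("cb_x", "cb_y", "cb_z")])
  ri <- rad[i] + probe
  pts <- .spherePoints(nPoints) * ri
  pts <- sweep(pts, 2L, centers[i, ], "+")
  others <- setdiff(seq_len(nrow(r)), i)
  acc <- rep(TRUE, nPoints)
  if (length(others)) {
    d <- .cdist(pts, centers[others, , drop = FALSE])
    lim <- matrix(rad[others] + probe, nrow = nPoints,
                  ncol = length(others), byrow = TRUE)
    acc <- rowSums(d < lim) == 0L
  }
  area <- mean(acc) * 4 * pi * ri^2
  area / asaTab$max_asa[match(r$aa[i], asaTab$aa)]
}

#' Substitution property changes
#'
#' Mutant-minus-wild-type differences in mass, Hopp-Woods hydrophilicity and
#' isoelectric point, summed over the mutations of a multi-point set.
#'
#' @param ms a \code{MutationSet}.
#' @param properties property table (default \code{aaProperties()}).
#' @return named numeric: \code{d_mass}, \code{d_hydro}, \code{d_iep}.
#' @export
substitutionDeltas <- function(ms, properties = aaProperties()) {
  m <- ms@mutations
  if (nrow(m) == 0L) return(c(d_mass = 0, d_hydro = 0, d_iep = 0))
  iw <- match(m$wt, properties$aa)
  im <- match(m$mut, properties$aa)
  if (anyNA(iw) || anyNA(im)) .stop2("unknown residue type in mutation set")
  c(d_mass = sum(properties$mass[im] - properties$mass[iw]),
    d_hydro = sum(properties$hydrophilicity[im] - properties$hydrophilicity[iw]),
    d_iep = sum(properties$pi[im] - properties$pi[iw]))
}

#' Assemble the nine-value agent input vector
#'
#' The first three inputs are the mutant-minus-wild-type component score
#' differences of the three scoring functions; the remaining six are protein
#' size (residue count of the scored unit), the encoded secondary-structure
#' state at the site (helix 0, strand 0.5, coil 1), the relative ASA, and
#' the substitution deltas (mass, hydrophilicity, isoelectric point).  For
#' multi-point sets, site-local features are averaged over the mutated sites
#' and substitution deltas are summed.
#'
#' @inheritParams deltaScore
#' @param ssf an \code{SSFModelSet}.
#' @param properties amino-acid property table.
#' @param siteCache optional precomputed list from
#'   \code{precomputeSiteFeatures} (reused across many mutants of one
#'   structure).
#' @return named numeric of length 9 (see \code{FEATURE_NAMES}).
#' @export
buildFeatureVector <- function(structure, ms, ssf,
                               properties = aaProperties(),
                               context = NULL, siteCache = NULL) {
  ds <- .deltaScores(structure, ms, ssf, context)
  sc <- siteCache %||% precomputeSiteFeatures(structure)
  m <- ms@mutations
  if (nrow(m) > 0L) {
    idx <- .mutationIndices(structure, ms)
    ssState <- mean(.SS_ENCODING[sc$ss[idx]])
    relAsa <- mean(sc$asa[idx])
  } else {
    ssState <- 0; relAsa <- 0
  }
  pd <- substitutionDeltas(ms, properties)
  setNames(c(ds[["pssf_ca"]], ds[["pssf_cb"]], ds[["cssf"]],
             nResidues(structure), ssState, relAsa,
             pd[["d_mass"]], pd[["d_hydro"]], pd[["d_iep"]]),
           FEATURE_NAMES)
}

#' @rdname buildFeatureVector
#' @details \code{precomputeSiteFeatures} computes the per-residue secondary
#'   structure and relative ASA once for a structure so that many mutants
#'   can be featurized cheaply.
#' @export
precomputeSiteFeatures <- function(structure, nPoints = 256L) {
  list(ss = assignSecondaryStructure(structure),
       asa = vapply(seq_len(nResidues(structure)),
                    function(i) computeRelASA(structure, i, nPoints),
                    numeric(1L)))
}
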