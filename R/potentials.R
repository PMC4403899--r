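## Statistical scoring functions: compilation of the distance-dependent
## residue-pair potentials (CA-CA and CB-CB) and the CA-contact potential,
## their expected-energy normalizers, and the rank-sum scoring of structures.

.repAtomCoords <- function(structure, atomKind) {
  r <- structure@residues
  cols <- if (atomKind == "CA") c("ca_x", "ca_y", "ca_z")
          else c("cb_x", "cb_y", "cb_z")
  as.matrix(r[, cols])
}

## Sequential index within each chain (file order), used for the
## minimum-sequence-separation rule; inter-chain pairs are always counted.
.chainSeqIndex <- function(structure) {
  ch <- structure@residues$chain
  ave(seq_along(ch), ch, FUN = seq_along)
}

## All residue pairs (i < j) eligible for the pair SSF, with their distance bin.
.pairList <- function(structure, atomKind, breaks, minSeqSep) {
  xyz <- .repAtomCoords(structure, atomKind)
  n <- nrow(xyz)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), bin = integer()))
  d <- .cdist(xyz, xyz)
  ch <- structure@residues$chain
  si <- .chainSeqIndex(structure)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  dd <- d[ut]
  sameChain <- ch[i] == ch[j]
  ok <- (!sameChain | abs(si[i] - si[j]) >= minSeqSep) &
    dd >= breaks[1L] & dd < breaks[length(breaks)]
  bin <- findInterval(dd[ok], breaks, rightmost.closed = FALSE)
  data.frame(i = i[ok], j = j[ok], bin = bin)
}

#' Compile a distance-dependent residue-pair scoring function
#'
#' Counts all representative-atom pairs (CA-CA or CB-CB) with intra-chain
#' sequence separation of at least \code{minSeqSep} (inter-chain pairs are
#' always counted) into distance bins, converts the pseudocount-smoothed
#' counts into per-pair relative frequencies delta and a count-weighted
#' pooled reference rho, and derives observed energies
#' \code{E = -ln(delta / rho)} and per-pair expected energies (the
#' rho-weighted mean energy).
#'
#' @param structures a \code{ProteinStructure} or list of them.
#' @param atomKind "CA" or "CB".
#' @param breaks distance bin edges in Angstrom (default 1 A bins on
#'   [3, 15)); pairs outside the range are ignored.
#' @param minSeqSep minimum intra-chain sequence separation (default 2).
#' @param pseudocount additive smoothing on every count cell (default 1).
#' @return a \code{PairSSF}.
#' @export
compilePairSSF <- function(structures, atomKind = c("CA", "CB"),
                           breaks = 3:15, minSeqSep = 2L, pseudocount = 1) {
  atomKind <- match.arg(atomKind)
  if (is(structures, "ProteinStructure")) structures <- list(structures)
  if (!length(structures)) .stop2("need at least one structure")
  if (any(diff(breaks) <= 0)) .stop2("breaks must be strictly increasing")
  nb <- length(breaks) - 1L
  counts <- array(0, dim = c(20L, 20L, nb),
                  dimnames = list(.AA1, .AA1, NULL))
  for (st in structures) {
    aa <- match(st@residues$aa, .AA1)
    pl <- .pairList(st, atomKind, breaks, minSeqSep)
    if (!nrow(pl)) next
    a <- aa[pl$i]; b <- aa[pl$j]
    for (k in seq_len(nrow(pl))) {
      counts[a[k], b[k], pl$bin[k]] <- counts[a[k], b[k], pl$bin[k]] + 1
      counts[b[k], a[k], pl$bin[k]] <- counts[b[k], a[k], pl$bin[k]] + 1
    }
  }
  sm <- counts + pseudocount
  poolRef <- apply(sm, 3L, sum)
  if (any(poolRef <= 0))
    .stop2("reference distribution has empty bin(s) after smoothing; increase pseudocount")
  rho <- poolRef / sum(poolRef)
  tot <- apply(sm, c(1L, 2L), sum)
  delta <- sweep(sm, c(1L, 2L), tot, "/")
  energy <- -log(sweep(delta, 3L, rho, "/"))
  expected <- apply(sweep(energy, 3L, rho, "*"), c(1L, 2L), sum)
  new("PairSSF", atomKind = atomKind, breaks = as.numeric(breaks),
      counts = counts, delta = delta, rho = rho, energy = energy,
      expected = expected, minSeqSep = as.integer(minSeqSep),
      pseudocount = pseudocount)
}

## Per-residue CA contact counts (other CA atoms within radius, any chain,
## same model, excluding self), clamped at maxCount.
.contactCounts <- function(structure, radius, maxCount) {
  xyz <- .repAtomCoords(structure, "CA")
  d <- .cdist(xyz, xyz)
  cnt <- as.integer(colSums(d <= radius) - 1L)
  pmin(cnt, maxCount)
}

#' Compile the CA-contact scoring function
#'
#' For every residue the number of other CA atoms within \code{radius} is
#' counted (any chain, excluding the residue itself; counts above
#' \code{maxCount} are clamped).  Count histograms per residue type are
#' smoothed and normalized exactly as for the pair potential.
#'
#' @inheritParams compilePairSSF
#' @param radius contact radius in Angstrom (default 10).
#' @param maxCount clamp for the contact count (default 30).
#' @return a \code{ContactSSF}.
#' @export
compileContactSSF <- function(structures, radius = 10, maxCount = 30L,
                              pseudocount = 1) {
  if (is(structures, "ProteinStructure")) structures <- list(structures)
  if (!length(structures)) .stop2("need at least one structure")
  if (radius <= 0) .stop2("radius must be positive")
  counts <- matrix(0, 20L, maxCount + 1L, dimnames = list(.AA1, 0:maxCount))
  for (st in structures) {
    aa <- match(st@residues$aa, .AA1)
    cnt <- .contactCounts(st, radius, maxCount)
    for (k in seq_along(cnt))
      counts[aa[k], cnt[k] + 1L] <- counts[aa[k], cnt[k] + 1L] + 1
  }
  sm <- counts + pseudocount
  poolRef <- unname(colSums(sm))
  if (any(poolRef <= 0))
    .stop2("reference distribution has empty bin(s) after smoothing")
  rho <- poolRef / sum(poolRef)
  delta <- sweep(sm, 1L, rowSums(sm), "/")
  energy <- -log(sweep(delta, 2L, rho, "/"))
  expected <- as.numeric(energy %*% rho)
  names(expected) <- .AA1
  new("ContactSSF", radius = radius, maxCount = as.integer(maxCount),
      counts = counts, delta = delta, rho = rho, energy = energy,
      expected = expected, pseudocount = pseudocount)
}

#' @rdname compilePairSSF
#' @param ca,cb,contact compiled component scoring functions.
#' @export
ssfModelSet <- function(ca, cb, contact) {
  stopifnot(is(ca, "PairSSF"), ca@atomKind == "CA",
            is(cb, "PairSSF"), cb@atomKind == "CB",
            is(contact, "ContactSSF"))
  new("SSFModelSet", ca = ca, cb = cb, contact = contact)
}

#' Compile all three scoring functions from one structure set
#'
#' @inheritParams compilePairSSF
#' @param radius,maxCount contact-potential parameters.
#' @return an \code{SSFModelSet}.
#' @export
compileSSFModels <- function(structures, breaks = 3:15, minSeqSep = 2L,
                             radius = 10, maxCount = 30L, pseudocount = 1) {
  ssfModelSet(compilePairSSF(structures, "CA", breaks, minSeqSep, pseudocount),
              compilePairSSF(structures, "CB", breaks, minSeqSep, pseudocount),
              compileContactSSF(structures, radius, maxCount, pseudocount))
}

#' Wilcoxon-Mann-Whitney-style rank-sum score
#'
#' Ranks the union of the n observed and n expected energies (midranks for
#' ties), sums the ranks W of the observed set and standardizes it with the
#' null mean \code{n(2n+1)/2} and standard deviation
#' \code{sqrt(n^2(2n+1)/12)}.  Negative scores mean the observed energies
#' rank lower (are more favourable) than their expected counterparts.
#'
#' @param observed,expected equal-length numeric vectors.
#' @return list with \code{n}, \code{W}, \code{muW}, \code{sigmaW}, \code{s}.
#' @export
rankSumScore <- function(observed, expected) {
  n <- length(observed)
  if (n == 0L) .stop2("no scorable interactions (n = 0)")
  stopifnot(length(expected) == n)
  r <- rank(c(observed, expected), ties.method = "average")
  W <- sum(r[seq_len(n)])
  muW <- n * (2 * n + 1) / 2
  sigmaW <- sqrt(n^2 * (2 * n + 1) / 12)
  list(n = n, W = W, muW = muW, sigmaW = sigmaW, s = (W - muW) / sigmaW)
}

## Precomputed geometry for scoring one structure repeatedly under residue
## relabeling (all mutants share coordinates with the wild type).
.scoringContext <- function(structure, ssf) {
  list(aa = match(structure@residues$aa, .AA1),
       ca = .pairList(structure, "CA", ssf@ca@breaks, ssf@ca@minSeqSep),
       cb = .pairList(structure, "CB", ssf@cb@breaks, ssf@cb@minSeqSep),
       contact = .contactCounts(structure, ssf@contact@radius,
                                ssf@contact@maxCount),
       ssf = ssf)
}

.scoreAA <- function(ctx, aa) {
  ssf <- ctx$ssf
  pairScore <- function(pl, mod) {
    if (!nrow(pl)) .stop2("no scorable interactions (n = 0)")
    a <- aa[pl$i]; b <- aa[pl$j]
    obs <- mod@energy[cbind(a, b, pl$bin)]
    expv <- mod@expected[cbind(a, b)]
    rankSumScore(obs, expv)$s
  }
  sA <- pairScore(ctx$ca, ssf@ca)
  sB <- pairScore(ctx$cb, ssf@cb)
  obsC <- ssf@contact@energy[cbind(aa, ctx$contact + 1L)]
  expC <- ssf@contact@expected[aa]
  sC <- rankSumScore(obsC, expC)$s
  c(pssf_ca = sA, pssf_cb = sB, cssf = sC,
    combined = (sA + sB + sC) / sqrt(3))
}

#' Score a structure against compiled scoring functions
#'
#' For each scoring function the observed interaction energies are compared
#' with their expected counterparts through the rank-sum score; the three
#' component scores are combined by Stouffer's method (sum divided by
#' sqrt(3)).
#'
#' @param structure a \code{ProteinStructure}.
#' @param ssf an \code{SSFModelSet}.
#' @return named numeric: \code{pssf_ca}, \code{pssf_cb}, \code{cssf},
#'   \code{combined}.
#' @export
scoreStructure <- function(structure, ssf) {
  ctx <- .scoringContext(structure, ssf)
  .scoreAA(ctx, ctx$aa)
}

.mutantAA <- function(ctx, structure, ms) {
  aa <- ctx$aa
  if (nrow(ms@mutations)) {
    idx <- .mutationIndices(structure, ms)
    found <- structure@residues$aa[idx]
    bad <- found != ms@mutations$wt
    if (any(bad))
      .stop2("wild-type mismatch at %s",
             paste(sprintf("%s:%d%s (expected %s, found %s)",
                           ms@mutations$chain[bad], ms@mutations$resno[bad],
                           ms@mutations$icode[bad], ms@mutations$wt[bad],
                           found[bad]), collapse = "; "))
    aa[idx] <- match(ms@mutations$mut, .AA1)
  }
  aa
}

#' Scoring-function score change upon mutation
#'
#' \code{deltaScore} is the combined rank-sum score of the mutant minus that
#' of the wild type (coordinates fixed, residue types relabeled); negative
#' values predict stabilization.  \code{componentDeltaScores} returns the
#' three per-function differences, which are the first three agent inputs.
#'
#' @inheritParams scoreStructure
#' @param ms a \code{MutationSet}.
#' @param context optional precomputed scoring context (internal reuse).
#' @return \code{deltaScore}: a scalar; \code{componentDeltaScores}: named
#'   numeric length 3.
#' @export
deltaScore <- function(structure, ms, ssf, context = NULL) {
  unname(.deltaScores(structure, ms, ssf, context)["combined"])
}

#' @rdname deltaScore
#' @export
componentDeltaScores <- function(structure, ms, ssf, context = NULL) {
  .deltaScores(structure, ms, ssf, context)[c("pssf_ca", "pssf_cb", "cssf")]
}

.deltaScores <- function(structure, ms, ssf, context = NULL) {
  ctx <- context %||% .scoringContext(structure, ssf)
  wt <- .scoreAA(ctx, ctx$aa)
  if (nrow(ms@mutations) == 0L) return(wt - wt)
  mut <- .scoreAA(ctx, .mutantAA(ctx, structure, ms))
  mut - wt
}
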