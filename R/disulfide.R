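## Stabilizing disulfide-bond design: geometric penalty tables compiled from
## bonded cysteine pairs, candidate-pair enumeration under the 5 A CB-CB
## gate, and the combined z-score ranking S_ss.

#' Compile geometric penalty tables for disulfide screening
#'
#' From observed disulfide-bonded cysteine pairs, builds relative-frequency
#' histograms of (i) the CB-CB distance and (ii) the difference between the
#' CA-CA and CB-CB distances.  The penalties used at scan time are
#' \code{P = 1 - f} with \code{f} the bin frequency; geometries outside the
#' histogram support get penalty 1.
#'
#' @param x either a data.frame with columns \code{d_cb} and \code{d_ca}
#'   (one row per bonded pair), or a list of \code{ProteinStructure}s to
#'   scan for bonded pairs (SG-SG distance <= \code{sgCutoff}).
#' @param betaBreaks CB-CB histogram bin edges (default 0.25 A over
#'   [2.5, 6]).
#' @param diffBreaks difference histogram bin edges (default 0.25 A over
#'   [-2, 2]).
#' @param sgCutoff SG-SG detection distance (Angstrom).
#' @return a \code{PenaltyTables}.
#' @export
compilePenaltyTables <- function(x, betaBreaks = seq(2.5, 6, by = 0.25),
                                 diffBreaks = seq(-2, 2, by = 0.25),
                                 sgCutoff = 2.5) {
  if (is(x, "ProteinStructure")) x <- list(x)
  if (is.list(x) && !is.data.frame(x)) {
    pairs <- do.call(rbind, lapply(x, .bondedCysPairs, sgCutoff = sgCutoff))
  } else pairs <- x
  if (is.null(pairs) || nrow(pairs) == 0L)
    .stop2("no disulfide-bonded cysteine pairs found")
  fBeta <- .histFreq(pairs$d_cb, betaBreaks)
  fDiff <- .histFreq(pairs$d_ca - pairs$d_cb, diffBreaks)
  new("PenaltyTables", betaBreaks = betaBreaks, betaFreq = fBeta,
      diffBreaks = diffBreaks, diffFreq = fDiff,
      nPairs = nrow(pairs),
      meta = list(sgCutoff = sgCutoff, compiled = "prostab"))
}

.histFreq <- function(v, breaks) {
  inRange <- v >= breaks[1L] & v <= breaks[length(breaks)]
  if (!any(inRange)) .stop2("all observations fall outside the histogram range")
  h <- hist(v[inRange], breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  h$counts / sum(h$counts)
}

.bondedCysPairs <- function(st, sgCutoff = 2.5) {
  r <- st@residues
  cys <- which(r$aa == "C" & is.finite(r$sg_x))
  if (length(cys) < 2L) return(NULL)
  sg <- as.matrix(r[cys, c("sg_x", "sg_y", "sg_z")])
  ca <- as.matrix(r[cys, c("ca_x", "ca_y", "ca_z")])
  cb <- as.matrix(r[cys, c("cb_x", "cb_y", "cb_z")])
  d <- .cdist(sg, sg)
  ut <- which(upper.tri(d) & d <= sgCutoff, arr.ind = TRUE)
  if (!nrow(ut)) return(NULL)
  data.frame(d_cb = sqrt(rowSums((cb[ut[, 1L], , drop = FALSE] -
                                  cb[ut[, 2L], , drop = FALSE])^2)),
             d_ca = sqrt(rowSums((ca[ut[, 1L], , drop = FALSE] -
                                  ca[ut[, 2L], , drop = FALSE])^2)))
}

#' Penalty lookup for a candidate geometry
#'
#' @param tables a \code{PenaltyTables}.
#' @param dCb CB-CB distance (Angstrom).
#' @param dCa CA-CA distance (Angstrom).
#' @return named numeric: \code{P_beta}, \code{P_alpha_beta}.
#' @export
disulfidePenalties <- function(tables, dCb, dCa) {
  lookup <- function(v, breaks, freq) {
    if (v < breaks[1L] || v >= breaks[length(breaks)]) return(1)
    1 - freq[findInterval(v, breaks, rightmost.closed = FALSE)]
  }
  c(P_beta = lookup(dCb, tables@betaBreaks, tables@betaFreq),
    P_alpha_beta = lookup(dCa - dCb, tables@diffBreaks, tables@diffFreq))
}

#' Enumerate candidate disulfide pairs
#'
#' All unordered residue pairs (virtual C-betas included) with CB-CB
#' distance within the cutoff and intra-chain sequence separation of at
#' least 2; inter-chain pairs are always eligible.  Deterministic order
#' (first index, then second).
#'
#' @param structure a \code{ProteinStructure}.
#' @param cutoff CB-CB gate (default 5 Angstrom, inclusive).
#' @return data.frame: \code{i}, \code{j} (residue row indices),
#'   \code{d_cb}, \code{d_ca}.
#' @export
candidateDisulfidePairs <- function(structure, cutoff = 5) {
  r <- structure@residues
  if (nrow(r) < 2L)
    return(data.frame(i = integer(), j = integer(),
                      d_cb = numeric(), d_ca = numeric()))
  cb <- as.matrix(r[, c("cb_x", "cb_y", "cb_z")])
  ca <- as.matrix(r[, c("ca_x", "ca_y", "ca_z")])
  d <- .cdist(cb, cb)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  ## author-numbering separation: adjacent residues cannot form a bridge
  ok <- d[ut] <= cutoff &
    (r$chain[i] != r$chain[j] | abs(r$resno[i] - r$resno[j]) >= 2L)
  i <- i[ok]; j <- j[ok]
  ord <- order(i, j)
  data.frame(i = i[ord], j = j[ord], d_cb = d[cbind(i, j)][ord],
             d_ca = sqrt(rowSums((ca[i, , drop = FALSE] -
                                  ca[j, , drop = FALSE])^2))[ord])
}

#' Score and rank candidate disulfide pairs
#'
#' Each candidate pair is mutated to a double cysteine (a residue that is
#' already cysteine is left unchanged) and its ddG predicted; the geometric
#' penalties are looked up from the tables.  Per component, z-scores are
#' computed across the candidate list (components with zero variance yield
#' z = 0 with a warning) and combined as
#' \code{S_ss = (z_ddg + z_Pbeta + z_Pab) / sqrt(3)}; candidates are ranked
#' ascending by the selected score (lower = better).
#'
#' @param structure a \code{ProteinStructure}.
#' @param candidates data.frame from \code{candidateDisulfidePairs}.
#' @param predictor function mapping a \code{MutationSet} to a ddG (scalar,
#'   list or \code{StabilityPrediction}); for \code{scoreBy = "score"} it
#'   must return a list carrying \code{deltaScore}.
#' @param tables a \code{PenaltyTables}.
#' @param scoreBy ranking mode: \code{"sss"} (full combined score),
#'   \code{"ddg"} (ddG only), \code{"score"} (SSF delta-score replacing
#'   ddG), or \code{"penalty"} (geometric penalties only) - the component
#'   ablations.
#' @return data.frame: pair identifiers, distances, \code{ddg},
#'   \code{P_beta}, \code{P_alpha_beta}, component z-scores, \code{S_ss},
#'   \code{rank} and \code{relative_rank}.
#' @export
scoreDisulfideCandidates <- function(structure, candidates, predictor,
                                     tables,
                                     scoreBy = c("sss", "ddg", "score",
                                                 "penalty")) {
  scoreBy <- match.arg(scoreBy)
  if (nrow(candidates) < 2L)
    .stop2("need >= 2 candidate pairs for z-score ranking (got %d)",
           nrow(candidates))
  r <- structure@residues
  rows <- lapply(seq_len(nrow(candidates)), function(k) {
    i <- candidates$i[k]; j <- candidates$j[k]
    keep <- c(i, j)[r$aa[c(i, j)] != "C"]
    ms <- if (length(keep))
      mutationSet(data.frame(chain = r$chain[keep], resno = r$resno[keep],
                             icode = r$icode[keep], wt = r$aa[keep],
                             mut = "C", stringsAsFactors = FALSE))
    else emptyMutationSet()
    v <- predictor(ms)
    if (is.numeric(v)) v <- list(ddg = as.numeric(v))
    if (is(v, "StabilityPrediction"))
      v <- list(ddg = v@ddg, deltaScore = v@deltaScore)
    pen <- disulfidePenalties(tables, candidates$d_cb[k], candidates$d_ca[k])
    data.frame(i = i, j = j,
               pair = sprintf("%s:%d%s-%s:%d%s", r$chain[i], r$resno[i],
                              r$icode[i], r$chain[j], r$resno[j], r$icode[j]),
               d_cb = candidates$d_cb[k], d_ca = candidates$d_ca[k],
               ddg = v$ddg,
               delta_score = v$deltaScore %||% NA_real_,
               P_beta = pen[["P_beta"]], P_alpha_beta = pen[["P_alpha_beta"]],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  zify <- function(v, label) {
    s <- sd(v)
    if (!is.finite(s) || s < 1e-12) {
      warning(sprintf("zero variance in %s across candidates; z set to 0",
                      label), call. = FALSE)
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  first <- if (scoreBy == "score") df$delta_score else df$ddg
  df$z_ddg <- zify(first, if (scoreBy == "score") "delta-score" else "ddG")
  df$z_pb <- zify(df$P_beta, "P_beta")
  df$z_pab <- zify(df$P_alpha_beta, "P_alpha_beta")
  df$S_ss <- switch(scoreBy,
                    sss = , score = (df$z_ddg + df$z_pb + df$z_pab) / sqrt(3),
                    ddg = df$z_ddg,
                    penalty = (df$z_pb + df$z_pab) / sqrt(2))
  ord <- order(df$S_ss, df$pair, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$relative_rank <- df$rank / nrow(df)
  rownames(df) <- NULL
  df
}

#' Rank a known (native) disulfide pair among all candidates
#'
#' Runs the full disulfide scan on a structure whose native cysteines have
#' been replaced (e.g. by alanine) and reports the absolute and relative
#' rank of the native pair - the recovery evaluation for engineered or
#' removed bonds.  A native pair whose CB-CB distance exceeds the gate is
#' reported as unrankable.
#'
#' @inheritParams scoreDisulfideCandidates
#' @param nativePair integer length 2: residue row indices of the native
#'   pair.
#' @param cutoff CB-CB gate.
#' @return list: \code{absolute_rank}, \code{relative_rank},
#'   \code{n_candidates}, \code{rankable}, \code{table}.
#' @export
rankNativeBond <- function(structure, nativePair, predictor, tables,
                           cutoff = 5, scoreBy = "sss") {
  cands <- candidateDisulfidePairs(structure, cutoff)
  hit <- which((cands$i == min(nativePair) & cands$j == max(nativePair)))
  if (!length(hit))
    return(list(absolute_rank = NA_integer_, relative_rank = NA_real_,
                n_candidates = nrow(cands), rankable = FALSE, table = NULL))
  scored <- scoreDisulfideCandidates(structure, cands, predictor, tables,
                                     scoreBy = scoreBy)
  k <- which(scored$i == min(nativePair) & scored$j == max(nativePair))
  list(absolute_rank = scored$rank[k], relative_rank = scored$relative_rank[k],
       n_candidates = nrow(scored), rankable = TRUE, table = scored)
}

#' Persist penalty tables as versioned TSV
#'
#' @param tables a \code{PenaltyTables}; \code{path} a file path.
#' @param path file path.
#' @export
savePenaltyTables <- function(tables, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#prostab-penalty\tv1\tnPairs=%d", tables@nPairs), con)
  for (k in seq_along(tables@betaFreq))
    writeLines(paste("B", .fmtNum(tables@betaBreaks[k]),
                     .fmtNum(tables@betaBreaks[k + 1L]),
                     .fmtNum(tables@betaFreq[k]), sep = "\t"), con)
  for (k in seq_along(tables@diffFreq))
    writeLines(paste("D", .fmtNum(tables@diffBreaks[k]),
                     .fmtNum(tables@diffBreaks[k + 1L]),
                     .fmtNum(tables@diffFreq[k]), sep = "\t"), con)
  invisible(path)
}

#' @rdname savePenaltyTables
#' @export
readPenaltyTables <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1L], "\t")[[1L]]
  if (hd[1L] != "#prostab-penalty") .stop2("'%s' is not a penalty-table file", path)
  nPairs <- as.integer(sub("nPairs=", "", hd[3L]))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  tag <- vapply(body, `[`, "", 1L)
  parse <- function(t) {
    rows <- body[tag == t]
    lo <- vapply(rows, function(f) as.numeric(f[2L]), numeric(1L))
    hi <- vapply(rows, function(f) as.numeric(f[3L]), numeric(1L))
    fr <- vapply(rows, function(f) as.numeric(f[4L]), numeric(1L))
    list(breaks = c(lo, hi[length(hi)]), freq = fr)
  }
  b <- parse("B"); d <- parse("D")
  new("PenaltyTables", betaBreaks = b$breaks, betaFreq = b$freq,
      diffBreaks = d$breaks, diffFreq = d$freq, nPairs = nPairs,
      meta = list(loaded = path))
}
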