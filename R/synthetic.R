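## Synthetic fixtures: toy structures with ideal backbone geometry, synthetic
## training tables with a known linear ground truth, and the parser for
## experimental mutation/ddG tables.

.BOND_N_CA <- 1.458; .BOND_CA_C <- 1.525; .BOND_C_N <- 1.329
.ANG_N_CA_C <- 111.2; .ANG_CA_C_N <- 116.2; .ANG_C_N_CA <- 121.7
## frozen ideal-CB internal coordinates (L chirality): angle N-CA-CB and
## torsion C-N-CA-CB
.CB_BOND <- 1.53; .CB_ANG <- 110.31; .CB_TOR <- 122.47

.buildBackbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(.BOND_N_CA, 0, 0)
  ang <- .ANG_N_CA_C * pi / 180
  C[1L, ] <- CA[1L, ] + .BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L) + 1L) {
    N[i, ] <- .placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         .BOND_C_N, .ANG_CA_C_N, psi[i - 1L])
    CA[i, ] <- .placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          .BOND_N_CA, .ANG_C_N_CA, 180)
    C[i, ] <- .placeAtom(C[i - 1L, ], N[i, ], CA[i, ],
                         .BOND_CA_C, .ANG_N_CA_C, phi[i])
  }
  list(N = N, CA = CA, C = C)
}

.idealCB <- function(N, CA, C) {
  t(vapply(seq_len(nrow(N)),
           function(i) .placeAtom(C[i, ], N[i, ], CA[i, ],
                                  .CB_BOND, .CB_ANG, .CB_TOR),
           numeric(3L)))
}

#' Generate a toy protein structure
#'
#' Builds an ideal-geometry backbone (standard bond lengths and angles, NeRF
#' chain construction) in one of four folds: \code{"helix"} (phi -57, psi
#' -47), \code{"strand"} (fully extended, phi -139, psi 135),
#' \code{"hairpin"} (two extended strands joined by a two-residue turn) or
#' \code{"cluster"} (a compact quasi-random CA packing used for burial and
#' contact tests).  C-beta atoms are placed from frozen ideal internal
#' coordinates.  Output is a pure function of the arguments.
#'
#' @param nResidues number of residues (>= 3).
#' @param fold one of "helix", "strand", "hairpin", "cluster".
#' @param sequence optional 1-letter sequence string/vector; default random
#'   from \code{seed}.
#' @param seed integer seed controlling sequence and cluster geometry.
#' @param chain chain identifier.
#' @return a \code{ProteinStructure}.
#' @export
#' @examples
#' st <- makeToyStructure(20, "helix", seed = 1)
#' table(assignSecondaryStructure(st))
makeToyStructure <- function(nResidues, fold = c("helix", "strand", "hairpin",
                                                 "cluster"),
                             sequence = NULL, seed = 1L, chain = "A") {
  fold <- match.arg(fold)
  if (nResidues < 3L) .stop2("need at least 3 residues")
  if (is.null(sequence)) {
    set.seed(.deriveSeed(seed, 11L))
    sequence <- sample(.AA1, nResidues, replace = TRUE)
  } else {
    if (length(sequence) == 1L && nchar(sequence) > 1L)
      sequence <- strsplit(sequence, "")[[1L]]
    if (length(sequence) != nResidues) .stop2("sequence length != nResidues")
    if (!all(sequence %in% .AA1)) .stop2("non-canonical sequence letters")
  }
  if (fold == "cluster") {
    bb <- .clusterBackbone(nResidues, seed)
  } else {
    pp <- switch(fold,
      helix = list(phi = rep(-57, nResidues), psi = rep(-47, nResidues)),
      strand = list(phi = rep(-139, nResidues), psi = rep(135, nResidues)),
      hairpin = {
        h <- (nResidues - 2L) %/% 2L
        phi <- c(rep(-139, h), -60, -90, rep(-139, nResidues - h - 2L))
        psi <- c(rep(135, h), -30, 0, rep(135, nResidues - h - 2L))
        list(phi = phi, psi = psi)
      })
    bb <- .buildBackbone(pp$phi, pp$psi)
  }
  cb <- .idealCB(bb$N, bb$CA, bb$C)
  res <- data.frame(chain = chain, resno = seq_len(nResidues), icode = "",
                    aa = sequence,
                    n_x = bb$N[, 1L], n_y = bb$N[, 2L], n_z = bb$N[, 3L],
                    ca_x = bb$CA[, 1L], ca_y = bb$CA[, 2L], ca_z = bb$CA[, 3L],
                    c_x = bb$C[, 1L], c_y = bb$C[, 2L], c_z = bb$C[, 3L],
                    cb_x = cb[, 1L], cb_y = cb[, 2L], cb_z = cb[, 3L],
                    sg_x = NA_real_, sg_y = NA_real_, sg_z = NA_real_,
                    cb_virtual = sequence == "G", stringsAsFactors = FALSE)
  new("ProteinStructure", residues = res,
      sourceId = sprintf("toy-%s-%d-s%d", fold, nResidues, seed), model = 1L)
}

## Compact packing: CA positions drawn in a ball with a 3.8 A separation
## floor; local backbone frames oriented towards the centroid.
.clusterBackbone <- function(n, seed) {
  set.seed(.deriveSeed(seed, 23L))
  rad <- max(6, 2.4 * n^(1 / 3) * 1.8)
  CA <- matrix(NA_real_, n, 3L)
  placed <- 0L
  while (placed < n) {
    p <- runif(3L, -rad, rad)
    if (.vnorm(p) > rad) next
    if (placed > 0L) {
      d <- sqrt(colSums((t(CA[seq_len(placed), , drop = FALSE]) - p)^2))
      if (min(d) < 3.8) next
    }
    placed <- placed + 1L
    CA[placed, ] <- p
  }
  N <- C <- matrix(NA_real_, n, 3L)
  half <- .ANG_N_CA_C / 2 * pi / 180  # keep the ideal N-CA-C angle
  for (i in seq_len(n)) {
    u <- .vunit(if (.vnorm(CA[i, ]) > 1e-6) -CA[i, ] else c(0, 0, 1))
    w <- .vunit(.vcross(u, if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
    N[i, ] <- CA[i, ] + .BOND_N_CA * (sin(half) * w + cos(half) * u)
    C[i, ] <- CA[i, ] + .BOND_CA_C * (-sin(half) * w + cos(half) * u)
  }
  list(N = N, CA = CA, C = C)
}

#' Canonical generator coefficients for synthetic ddG tables
#'
#' A frozen choice of the linear ground-truth coefficients over the nine
#' features, scaled so that structure-derived mutant tables resemble curated
#' thermodynamic sets: ddG mean about +0.4 kcal/mol, sd about 1.7, with
#' both stabilizing and destabilizing substitutions well represented.
#'
#' @return named numeric of length 9.
#' @export
demoBeta <- function() {
  setNames(c(0.4, 0.4, 0.3, 0.002, 0.4, -1.2, 0.015, 0.45, 0.35),
           FEATURE_NAMES)
}

#' Generate a synthetic training table with linear ground truth
#'
#' Samples random mutation sets on the given structures, computes their true
#' nine-value feature vectors through the full pipeline and emits
#' \code{ddG = beta . features + N(0, noiseSd)}.  The returned records carry
#' protein and position keys for grouped cross-validation.  The generator is
#' a pure function of \code{seed}.
#'
#' @param structures list of \code{ProteinStructure}s (>= 1).
#' @param ssf an \code{SSFModelSet} used for the score features.
#' @param beta numeric length 9: true coefficients over
#'   \code{FEATURE_NAMES}.
#' @param noiseSd Gaussian noise standard deviation (kcal/mol).
#' @param nRows number of mutants to draw.
#' @param seed integer seed.
#' @param nPoints mutations per mutant (scalar or vector sampled from).
#' @return data.frame: \code{protein}, \code{position}, \code{mutations},
#'   \code{ddg}, plus the nine feature columns.
#' @export
makeTrainingTable <- function(structures, ssf, beta, noiseSd, nRows,
                              seed = 1L, nPoints = 1L) {
  if (is(structures, "ProteinStructure")) structures <- list(structures)
  stopifnot(length(beta) == 9L, nRows >= 1L)
  ctxs <- lapply(structures, .scoringContext, ssf = ssf)
  caches <- lapply(structures, precomputeSiteFeatures)
  set.seed(.deriveSeed(seed, 37L))
  rows <- vector("list", nRows)
  for (r in seq_len(nRows)) {
    si <- sample.int(length(structures), 1L)
    st <- structures[[si]]
    np <- if (length(nPoints) > 1L) sample(nPoints, 1L) else nPoints
    sites <- sample.int(nResidues(st), np)
    rt <- st@residues[sites, , drop = FALSE]
    muts <- vapply(rt$aa, function(a) sample(setdiff(.AA1, a), 1L), "")
    ms <- mutationSet(data.frame(chain = rt$chain, resno = rt$resno,
                                 icode = rt$icode, wt = rt$aa, mut = muts,
                                 stringsAsFactors = FALSE))
    fv <- buildFeatureVector(st, ms, ssf, context = ctxs[[si]],
                             siteCache = caches[[si]])
    rows[[r]] <- data.frame(protein = st@sourceId,
                            position = paste(sprintf("%s:%d%s", rt$chain,
                                                     rt$resno, rt$icode),
                                             collapse = ";"),
                            mutations = formatMutations(ms),
                            ddg = sum(beta * fv) + rnorm(1L, 0, noiseSd),
                            as.list(fv), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname makeTrainingTable
#' @details \code{makeSyntheticRecords} draws feature vectors directly from
#'   fixed distributions (no structures involved), optionally with
#'   sign-dependent slopes to emulate data where stabilizing and
#'   destabilizing substitutions follow different regimes.
#' @param n number of records.
#' @param signSlopes length-2 multiplier applied to the linear signal when
#'   it is negative / non-negative.
#' @export
makeSyntheticRecords <- function(n, beta, noiseSd, seed = 1L,
                                 signSlopes = c(1, 1)) {
  stopifnot(length(beta) == 9L)
  set.seed(.deriveSeed(seed, 53L))
  X <- cbind(rnorm(n), rnorm(n), rnorm(n),
             sample(c(60L, 120L, 200L, 300L), n, replace = TRUE),
             sample(c(0, 0.5, 1), n, replace = TRUE),
             runif(n),
             rnorm(n, 0, 40), rnorm(n, 0, 1.6), rnorm(n, 0, 1.2))
  colnames(X) <- FEATURE_NAMES
  lin <- as.numeric(X %*% beta)
  lin <- ifelse(lin < 0, signSlopes[1L] * lin, signSlopes[2L] * lin)
  data.frame(protein = paste0("P", rep_len(1:12, n)),
             position = paste0("A:", seq_len(n)),
             mutations = paste0("A:A", seq_len(n), "G"),
             ddg = lin + rnorm(n, 0, noiseSd), X,
             stringsAsFactors = FALSE)
}

#' Write / parse experimental-style mutation tables
#'
#' The on-disk dialect is a TSV with columns \code{pdb_id}, \code{chain},
#' \code{mutations} (semicolon-joined tokens like \code{A:N25K}),
#' \code{ddg} (kcal/mol, negative = stabilizing), \code{ph} and
#' \code{temperature} (Celsius).
#'
#' @param records data.frame with at least \code{protein}, \code{mutations},
#'   \code{ddg} (pH/temperature default to 7/25 when absent).
#' @param path output file.
#' @export
writeMutationTable <- function(records, path) {
  df <- data.frame(pdb_id = records$protein,
                   chain = records$chain %||% "A",
                   mutations = records$mutations,
                   ddg = records$ddg,
                   ph = records$ph %||% 7,
                   temperature = records$temperature %||% 25)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMutationTable
#' @details \code{parseMutationTable} drops rows outside the pH window,
#'   rejects malformed mutation tokens, and collapses duplicate mutations by
#'   keeping the measurement whose conditions are closest to 25 C / pH 7
#'   (temperature normalized by 10 C and pH by 1 unit before the Euclidean
#'   distance); exact-condition ties keep the median ddG.  When recency
#'   metadata is unavailable the remaining ties fall back to first
#'   occurrence.
#' @param phWindow numeric length 2: inclusive pH window.
#' @return \code{parseMutationTable}: list with \code{records} (distinct
#'   mutations) and \code{rejected} (rows with a \code{reason} column).
#' @export
parseMutationTable <- function(path, phWindow = c(5.5, 8.5)) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pdb_id", "chain", "mutations", "ddg", "ph", "temperature")
  if (!all(need %in% names(raw)))
    .stop2("mutation table must have columns: %s", paste(need, collapse = ", "))
  reject <- list()
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    bad <- NULL
    if (!is.finite(raw$ddg[i])) bad <- "non-finite ddg"
    else if (is.na(raw$ph[i]) || raw$ph[i] < phWindow[1L] ||
             raw$ph[i] > phWindow[2L]) bad <- "pH outside window"
    else if (inherits(try(parseMutations(raw$mutations[i]), silent = TRUE),
                      "try-error")) bad <- "malformed mutation token"
    if (!is.null(bad)) {
      keep[i] <- FALSE
      reject[[length(reject) + 1L]] <- cbind(raw[i, , drop = FALSE],
                                             reason = bad)
    }
  }
  ok <- raw[keep, , drop = FALSE]
  if (nrow(ok)) {
    ok$mutations <- vapply(ok$mutations,
                           function(t) formatMutations(parseMutations(t)), "")
    key <- paste(ok$pdb_id, ok$mutations)
    dist <- sqrt(((ok$temperature - 25) / 10)^2 + (ok$ph - 7)^2)
    picked <- lapply(split(seq_len(nrow(ok)), key), function(ii) {
      dd <- dist[ii]
      best <- ii[abs(dd - min(dd)) < 1e-12]
      row <- ok[best[1L], , drop = FALSE]
      row$ddg <- median(ok$ddg[best])
      row
    })
    out <- do.call(rbind, picked)
    out <- out[order(match(paste(out$pdb_id, out$mutations), key)), ,
               drop = FALSE]
    rownames(out) <- NULL
  } else out <- ok
  list(records = out,
       rejected = if (length(reject)) do.call(rbind, reject)
                  else cbind(raw[0L, , drop = FALSE], reason = character()))
}
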