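## Searching mutation space for stabilizing or destabilizing n-point mutants:
## exhaustive enumeration, greedy extension and a multi-population
## evolutionary algorithm, all driven by a pluggable predictor.

#' Define the constraint set for a mutation scan
#'
#' Sites can be selected by explicit position, wild-type amino-acid set
#' and/or relative-ASA interval (conjunctively); substitutions default to
#' the 19 non-wild-type residues per site.
#'
#' @param structure a \code{ProteinStructure}.
#' @param nPoints number of simultaneous mutations (>= 1).
#' @param objective "stabilize" (minimize predicted ddG) or "destabilize".
#' @param positions optional integer vector of author residue numbers, or
#'   character site keys \code{"chain:resno"}.
#' @param wildTypes optional set of allowed wild-type amino acids.
#' @param asaRange optional numeric length 2: relative-ASA interval.
#' @param substitutions optional amino-acid set allowed as replacements.
#' @param siteCache optional output of \code{precomputeSiteFeatures} (only
#'   needed for \code{asaRange}).
#' @return a \code{list} describing the constraint (sites with their allowed
#'   substitutions, \code{nPoints}, \code{objective}).
#' @export
mutationConstraint <- function(structure, nPoints = 1L,
                               objective = c("stabilize", "destabilize"),
                               positions = NULL, wildTypes = NULL,
                               asaRange = NULL, substitutions = NULL,
                               siteCache = NULL) {
  objective <- match.arg(objective)
  if (nPoints < 1L) .stop2("nPoints must be >= 1")
  r <- structure@residues
  keep <- rep(TRUE, nrow(r))
  if (!is.null(positions)) {
    if (is.character(positions))
      keep <- keep & paste0(r$chain, ":", r$resno, r$icode) %in% positions
    else keep <- keep & r$resno %in% positions
  }
  if (!is.null(wildTypes)) keep <- keep & r$aa %in% wildTypes
  if (!is.null(asaRange)) {
    asa <- (siteCache %||% precomputeSiteFeatures(structure))$asa
    keep <- keep & asa >= asaRange[1L] & asa <= asaRange[2L]
  }
  sites <- which(keep)
  if (!length(sites)) .stop2("constraint selects no sites")
  subs <- lapply(sites, function(i) {
    s <- substitutions %||% .AA1
    setdiff(s, r$aa[i])
  })
  empty <- lengths(subs) == 0L
  sites <- sites[!empty]; subs <- subs[!empty]
  if (!length(sites)) .stop2("constraint selects no sites")
  list(structure = structure, sites = sites, substitutions = subs,
       nPoints = as.integer(nPoints), objective = objective)
}

#' Count / enumerate candidate mutants under a constraint
#'
#' The candidate count is the sum, over all \code{nPoints}-subsets of the
#' allowed sites, of the product of the per-site substitution-set sizes
#' (\code{choose(a, n) * 19^n} in the unrestricted case).
#'
#' @param constraint a \code{mutationConstraint}.
#' @return \code{countCandidates}: a numeric scalar;
#'   \code{enumerateCandidates}: a list of \code{MutationSet}s (guarded by
#'   \code{limit}).
#' @export
countCandidates <- function(constraint) {
  sizes <- lengths(constraint$substitutions)
  n <- constraint$nPoints
  if (n > length(sizes)) return(0)
  ## elementary symmetric polynomial e_n of the per-site sizes
  e <- c(1, numeric(n))
  for (s in sizes)
    for (j in seq(n, 1L)) e[j + 1L] <- e[j + 1L] + s * e[j]
  e[n + 1L]
}

#' @rdname countCandidates
#' @param limit refuse to materialize more candidates than this.
#' @export
enumerateCandidates <- function(constraint, limit = 2e6) {
  total <- countCandidates(constraint)
  if (total > limit)
    .stop2("candidate space too large to enumerate (%.3g > %.3g); use the greedy or evolutionary search",
           total, limit)
  st <- constraint$structure
  n <- constraint$nPoints
  siteSets <- if (n == 1L) matrix(seq_along(constraint$sites), nrow = 1L)
              else combn(seq_along(constraint$sites), n)
  out <- vector("list", total)
  pos <- 0L
  for (cset in seq_len(ncol(siteSets))) {
    ss <- siteSets[, cset]
    subLists <- constraint$substitutions[ss]
    grid <- expand.grid(rev(subLists), stringsAsFactors = FALSE)
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
    rt <- st@residues[constraint$sites[ss], , drop = FALSE]
    for (g in seq_len(nrow(grid))) {
      pos <- pos + 1L
      out[[pos]] <- mutationSet(data.frame(chain = rt$chain, resno = rt$resno,
                                           icode = rt$icode, wt = rt$aa,
                                           mut = unlist(grid[g, ],
                                                        use.names = FALSE),
                                           stringsAsFactors = FALSE))
    }
  }
  out
}

.scanObjectiveSign <- function(objective) if (objective == "stabilize") 1 else -1

## Shared ranking: orders candidate rows by objective, deterministic
## tie-break on the canonical mutation string.
.rankScanRows <- function(df, objective, top) {
  sgn <- .scanObjectiveSign(objective)
  ord <- order(sgn * df$ddg, df$mutations, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- head(df, top)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", setdiff(names(df), "rank"))]
}

## Wrap a user predictor with canonical-key caching; predictor may return a
## scalar ddg or a list with ddg/cPred.
.cachingPredictor <- function(predictor) {
  cache <- new.env(parent = emptyenv())
  evals <- new.env(parent = emptyenv()); evals$n <- 0
  fn <- function(ms) {
    key <- formatMutations(ms)
    if (!is.null(cache[[key]])) return(cache[[key]])
    evals$n <- evals$n + 1
    v <- predictor(ms)
    if (is.numeric(v)) v <- list(ddg = as.numeric(v), cPred = NA_real_)
    if (is(v, "StabilityPrediction")) v <- list(ddg = v@ddg, cPred = v@cPred)
    cache[[key]] <- v
    v
  }
  attr(fn, "evals") <- evals
  fn
}

#' Exhaustive (optimal) mutation scan
#'
#' Evaluates every candidate under the constraint and returns the top-k
#' ranked by predicted ddG (ascending for "stabilize"; ties broken
#' lexicographically on the mutation string).
#'
#' @param constraint a \code{mutationConstraint}.
#' @param predictor function taking a \code{MutationSet} and returning a ddG
#'   (scalar), a list with \code{ddg}/\code{cPred}, or a
#'   \code{StabilityPrediction}.
#' @param top number of ranked mutants to keep.
#' @param budget maximum candidate count accepted before advising the
#'   heuristic searches.
#' @return a \code{ScanResult}.
#' @export
optimalScan <- function(constraint, predictor, top = 50L, budget = 2e6) {
  total <- countCandidates(constraint)
  if (total > budget)
    .stop2("optimal scan budget exceeded (%.3g candidates > %.3g); use greedyScan or eaScan",
           total, budget)
  pf <- .cachingPredictor(predictor)
  cands <- enumerateCandidates(constraint, limit = budget)
  rows <- lapply(cands, function(ms) {
    v <- pf(ms)
    data.frame(mutations = formatMutations(ms), ddg = v$ddg,
               confidence = v$cPred, stringsAsFactors = FALSE)
  })
  df <- .rankScanRows(do.call(rbind, rows), constraint$objective, top)
  new("ScanResult", results = df, algorithm = "optimal",
      evaluations = attr(pf, "evals")$n)
}

#' Greedy mutation scan
#'
#' Iteratively extends the current mutant by the best single-point addition
#' (the full extended mutant is re-predicted at every step) until
#' \code{nPoints} mutations are placed.  Fast, not guaranteed optimal.
#'
#' @inheritParams optimalScan
#' @return a \code{ScanResult} with the greedy trajectory (one row per
#'   size).
#' @export
greedyScan <- function(constraint, predictor, top = 50L) {
  st <- constraint$structure
  pf <- .cachingPredictor(predictor)
  sgn <- .scanObjectiveSign(constraint$objective)
  current <- data.frame(chain = character(), resno = integer(),
                        icode = character(), wt = character(),
                        mut = character(), stringsAsFactors = FALSE)
  trajectory <- list()
  usedSites <- integer()
  for (step in seq_len(constraint$nPoints)) {
    bestVal <- NULL; bestRow <- NULL; bestKey <- NULL; bestSite <- NULL
    for (si in seq_along(constraint$sites)) {
      i <- constraint$sites[si]
      if (i %in% usedSites) next
      rt <- st@residues[i, ]
      for (aa in constraint$substitutions[[si]]) {
        cand <- rbind(current,
                      data.frame(chain = rt$chain, resno = rt$resno,
                                 icode = rt$icode, wt = rt$aa, mut = aa,
                                 stringsAsFactors = FALSE))
        ms <- mutationSet(cand)
        v <- pf(ms)
        key <- formatMutations(ms)
        better <- is.null(bestVal) || sgn * v$ddg < sgn * bestVal$ddg ||
          (v$ddg == bestVal$ddg && key < bestKey)
        if (better) {
          bestVal <- v; bestRow <- cand; bestKey <- key; bestSite <- i
        }
      }
    }
    if (is.null(bestRow)) {
      warning("no legal extension; returning shorter mutant", call. = FALSE)
      break
    }
    current <- bestRow
    usedSites <- c(usedSites, bestSite)
    trajectory[[step]] <- data.frame(mutations = bestKey, ddg = bestVal$ddg,
                                     confidence = bestVal$cPred,
                                     stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rev(trajectory))
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  new("ScanResult", results = df[, c("rank", "mutations", "ddg", "confidence")],
      algorithm = "greedy", evaluations = attr(pf, "evals")$n)
}

#' Default evolutionary-algorithm parameters
#'
#' @param populations number of parallel populations (ring topology).
#' @param popSize individuals per population.
#' @param generations generation budget.
#' @param tournament tournament size for parent selection.
#' @param crossover crossover probability.
#' @param mutation per-gene mutation probability (resample the substitution
#'   or move the mutation to a fresh site, 50/50).
#' @param migrateEvery migration interval (generations).
#' @param migrants number of elite individuals passed to the next
#'   population.
#' @return a named list.
#' @export
eaParams <- function(populations = 4L, popSize = 50L, generations = 200L,
                     tournament = 3L, crossover = 0.9, mutation = 0.1,
                     migrateEvery = 10L, migrants = 2L) {
  list(populations = populations, popSize = popSize,
       generations = generations, tournament = tournament,
       crossover = crossover, mutation = mutation,
       migrateEvery = migrateEvery, migrants = migrants)
}

#' Evolutionary-algorithm mutation scan
#'
#' A multi-population EA over n-point mutants: tournament parent selection,
#' uniform site-wise crossover repaired to exactly n distinct sites,
#' per-gene mutation, ring migration of elites at fixed intervals and
#' elitism within each population.  Bit-reproducible under a fixed seed.
#'
#' @inheritParams optimalScan
#' @param params see \code{eaParams}.
#' @param seed integer seed.
#' @return a \code{ScanResult} (best individuals across all populations).
#' @export
eaScan <- function(constraint, predictor, params = eaParams(), seed = 1L,
                   top = 50L) {
  nSites <- length(constraint$sites)
  n <- constraint$nPoints
  if (nSites < n) .stop2("infeasible constraint: %d site(s) for %d mutations",
                         nSites, n)
  pf <- .cachingPredictor(predictor)
  sgn <- .scanObjectiveSign(constraint$objective)
  st <- constraint$structure
  set.seed(.deriveSeed(seed, 701L))

  randomGene <- function(si) {
    subs <- constraint$substitutions[[si]]
    subs[sample.int(length(subs), 1L)]
  }
  randomIndividual <- function() {
    ss <- sort(sample.int(nSites, n))
    list(sites = ss, subs = vapply(ss, randomGene, ""))
  }
  ## genotypes are valid by construction; skip S4 validity in the hot loop
  siteChain <- st@residues$chain[constraint$sites]
  siteResno <- st@residues$resno[constraint$sites]
  siteIcode <- st@residues$icode[constraint$sites]
  siteWt <- st@residues$aa[constraint$sites]
  msTemplate <- emptyMutationSet()
  toMS <- function(ind) {
    ms <- msTemplate
    ms@mutations <- data.frame(chain = siteChain[ind$sites],
                               resno = siteResno[ind$sites],
                               icode = siteIcode[ind$sites],
                               wt = siteWt[ind$sites], mut = ind$subs,
                               stringsAsFactors = FALSE)
    ms
  }
  ## fitness memoized on the integer genotype (cheaper than building a
  ## MutationSet for every lookup of an already-seen individual)
  fitCache <- new.env(parent = emptyenv())
  fitness <- function(ind) {
    key <- paste(ind$sites, ind$subs, collapse = " ")
    v <- fitCache[[key]]
    if (!is.null(v)) return(v)
    v <- sgn * pf(toMS(ind))$ddg
    fitCache[[key]] <- v
    v
  }

  crossoverOp <- function(p1, p2) {
    ## pooled parent genes; duplicate sites collapse to a random parent's
    ## substitution, then exactly n distinct sites are drawn (repair)
    s <- c(p1$sites, p2$sites)
    a <- c(p1$subs, p2$subs)
    perm <- sample.int(length(s))
    s <- s[perm]; a <- a[perm]
    keep <- !duplicated(s)
    s <- s[keep]; a <- a[keep]
    if (length(s) >= n) {
      pick <- sample.int(length(s), n)
      ss <- s[pick]; aa <- a[pick]
    } else {
      extra <- sample(setdiff(seq_len(nSites), s), n - length(s))
      ss <- c(s, extra); aa <- c(a, vapply(extra, randomGene, ""))
    }
    o <- order(ss)
    list(sites = ss[o], subs = aa[o])
  }
  mutateOp <- function(ind) {
    for (g in seq_len(n)) {
      if (runif(1L) >= params$mutation) next
      if (runif(1L) < 0.5) {
        ind$subs[g] <- randomGene(ind$sites[g])
      } else {
        free <- setdiff(seq_len(nSites), ind$sites)
        if (length(free)) {
          ns <- free[sample.int(length(free), 1L)]
          ind$sites[g] <- ns
          ind$subs[g] <- randomGene(ns)
        }
      }
    }
    o <- order(ind$sites)
    list(sites = ind$sites[o], subs = ind$subs[o])
  }

  pops <- lapply(seq_len(params$populations), function(p)
    lapply(seq_len(params$popSize), function(i) randomIndividual()))
  fits <- lapply(pops, function(pop) vapply(pop, fitness, numeric(1L)))

  for (gen in seq_len(params$generations)) {
    for (p in seq_along(pops)) {
      pop <- pops[[p]]; ft <- fits[[p]]
      elite <- which.min(ft)
      newPop <- list(pop[[elite]])
      while (length(newPop) < params$popSize) {
        pick <- function() {
          cand <- sample.int(length(pop), params$tournament)
          pop[[cand[which.min(ft[cand])]]]
        }
        child <- if (runif(1L) < params$crossover) crossoverOp(pick(), pick())
                 else pick()
        newPop[[length(newPop) + 1L]] <- mutateOp(child)
      }
      pops[[p]] <- newPop
      fits[[p]] <- vapply(newPop, fitness, numeric(1L))
    }
    if (params$populations > 1L && gen %% params$migrateEvery == 0L) {
      exports <- lapply(seq_along(pops), function(p) {
        ord <- order(fits[[p]])
        pops[[p]][ord[seq_len(min(params$migrants, length(ord)))]]
      })
      for (p in seq_along(pops)) {
        src <- exports[[if (p == 1L) length(pops) else p - 1L]]
        ord <- order(fits[[p]], decreasing = TRUE)
        repl <- ord[seq_along(src)]
        for (k in seq_along(src)) {
          pops[[p]][[repl[k]]] <- src[[k]]
          fits[[p]][repl[k]] <- fitness(src[[k]])
        }
      }
    }
  }

  rows <- list()
  for (p in seq_along(pops)) {
    for (i in seq_along(pops[[p]])) {
      v <- pf(toMS(pops[[p]][[i]]))
      rows[[length(rows) + 1L]] <-
        data.frame(mutations = formatMutations(toMS(pops[[p]][[i]])),
                   ddg = v$ddg, confidence = v$cPred,
                   stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df$mutations), , drop = FALSE]
  df <- .rankScanRows(df, constraint$objective, top)
  new("ScanResult", results = df, algorithm = "ea",
      evaluations = attr(pf, "evals")$n)
}
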