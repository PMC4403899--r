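## a cheap deterministic per-site-value predictor used throughout
additivePredictor <- function(st, seed = 42) {
  set.seed(seed)
  vals <- matrix(rnorm(nResidues(st) * 20), nResidues(st), 20,
                 dimnames = list(NULL, rownames(toySSF()@ca@expected)))
  key <- paste(st@residues$chain, st@residues$resno, st@residues$icode)
  list(fn = function(ms) {
    m <- ms@mutations
    idx <- match(paste(m$chain, m$resno, m$icode), key)
    sum(vals[cbind(idx, match(m$mut, colnames(vals)))])
  }, vals = vals)
}

test_that("candidate counting matches the combinatorial formula and enumeration", {
  st <- makeToyStructure(30, "helix", seed = 5)
  con3 <- mutationConstraint(st, nPoints = 3)
  expect_equal(countCandidates(con3), choose(30, 3) * 19^3)
  expect_equal(countCandidates(con3), 27847540)
  one <- mutationConstraint(makeToyStructure(3, "helix"), nPoints = 1,
                            positions = 1L)
  expect_equal(countCandidates(one), 19)
  st5 <- makeToyStructure(5, "helix", seed = 6)
  con2 <- mutationConstraint(st5, nPoints = 2)
  expect_equal(countCandidates(con2), 3610)
  cands <- enumerateCandidates(con2)
  expect_length(cands, 3610L)
  keys <- vapply(cands, formatMutations, "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("constraint selectors restrict sites and substitutions", {
  st <- makeToyStructure(20, "helix", seed = 7)
  con <- mutationConstraint(st, nPoints = 1, positions = 5:10,
                            wildTypes = st@residues$aa[c(5, 7)],
                            substitutions = c("K", "R", "E"))
  expect_true(all(st@residues$resno[con$sites] %in% 5:10))
  expect_true(all(st@residues$aa[con$sites] %in% st@residues$aa[c(5, 7)]))
  for (k in seq_along(con$sites)) {
    expect_false(st@residues$aa[con$sites[k]] %in% con$substitutions[[k]])
    expect_true(all(con$substitutions[[k]] %in% c("K", "R", "E")))
  }
  sc <- precomputeSiteFeatures(st)
  conA <- mutationConstraint(st, nPoints = 1, asaRange = c(0.5, 1.2),
                             siteCache = sc)
  expect_true(all(sc$asa[conA$sites] >= 0.5))
  expect_error(mutationConstraint(st, nPoints = 1, positions = 999),
               "no sites")
})

test_that("optimal scan equals an independent brute force and breaks ties deterministically", {
  st <- makeToyStructure(6, "helix", seed = 8)
  pred <- additivePredictor(st)
  con <- mutationConstraint(st, nPoints = 2,
                            substitutions = c("K", "R", "E"))
  res <- optimalScan(con, pred$fn, top = 10)
  expect_equal(res@evaluations, countCandidates(con))
  ## independent brute force in this test
  best <- Inf; bestKey <- NULL
  wt <- st@residues$aa
  for (i in 1:5) for (j in (i + 1):6)
    for (a in setdiff(c("K", "R", "E"), wt[i]))
      for (b in setdiff(c("K", "R", "E"), wt[j])) {
        v <- unname(pred$vals[i, a] + pred$vals[j, b])
        if (v < best) {
          best <- v
          bestKey <- formatMutations(mutationSet(data.frame(
            chain = "A", resno = c(i, j), icode = "", wt = wt[c(i, j)],
            mut = c(a, b))))
        }
      }
  expect_equal(res@results$ddg[1], best)
  expect_identical(res@results$mutations[1], bestKey)
  ## constant predictor: ranking falls back to the lexicographic tie-break
  resTie <- optimalScan(con, function(ms) 1, top = 5)
  expect_identical(resTie@results$mutations,
                   sort(resTie@results$mutations))
  expect_error(optimalScan(mutationConstraint(st, nPoints = 3), pred$fn,
                           budget = 100), "budget")
})

test_that("greedy equals optimal under additivity but can be trapped by epistasis", {
  st <- makeToyStructure(8, "helix", seed = 9)
  pred <- additivePredictor(st)
  subs <- c("K", "R", "E")
  con <- mutationConstraint(st, nPoints = 3, substitutions = subs)
  g <- greedyScan(con, pred$fn)
  o <- optimalScan(con, pred$fn, top = 1)
  expect_equal(g@results$ddg[1], o@results$ddg[1], tolerance = 1e-12)
  expect_identical(g@results$mutations[1], o@results$mutations[1])
  ## evaluation count: sum over steps of (remaining sites x substitutions);
  ## the trajectory rows (shortest mutant last) reveal the pick order
  sizes <- lengths(con$substitutions)
  steps <- rev(g@results$mutations)
  pickOrder <- integer(0)
  seen <- integer(0)
  for (tok in steps) {
    resnos <- parseMutations(tok)@mutations$resno
    new <- setdiff(match(resnos, st@residues$resno[con$sites]), seen)
    seen <- c(seen, new)
    pickOrder <- c(pickOrder, new)
  }
  expected <- sum(vapply(seq_along(pickOrder), function(s) {
    used <- pickOrder[seq_len(s - 1L)]
    sum(sizes[setdiff(seq_along(sizes), used)])
  }, numeric(1)))
  expect_equal(g@evaluations, expected)
  ## engineered two-site trap: the singly-best site is not in the best pair
  trap <- function(ms) {
    m <- ms@mutations
    v <- sum(ifelse(m$resno == 1, -1.0, ifelse(m$resno == 2, -0.8, -0.1)))
    if (all(c(2, 3) %in% m$resno)) v <- v - 5
    v
  }
  conT <- mutationConstraint(st, nPoints = 2, positions = 1:3,
                             substitutions = "G")
  gT <- greedyScan(conT, trap)
  oT <- optimalScan(conT, trap, top = 1)
  expect_lt(oT@results$ddg[1], gT@results$ddg[1])
})

test_that("the evolutionary search is seeded, elitist and finds small-instance optima", {
  st <- makeToyStructure(12, "helix", seed = 10)
  pred <- additivePredictor(st)
  con <- mutationConstraint(st, nPoints = 2, substitutions = c("K", "R", "E"))
  par <- eaParams(populations = 2L, popSize = 20L, generations = 30L)
  e1 <- eaScan(con, pred$fn, params = par, seed = 4)
  e2 <- eaScan(con, pred$fn, params = par, seed = 4)
  expect_identical(e1@results, e2@results)
  o <- optimalScan(con, pred$fn, top = 1)
  expect_equal(e1@results$ddg[1], o@results$ddg[1], tolerance = 1e-12)
  expect_error(eaScan(mutationConstraint(st, nPoints = 5, positions = 1:3),
                      pred$fn), "infeasible")
  ## degenerate single-population, no-variation run: best-of-random-sample
  par0 <- eaParams(populations = 1L, popSize = 15L, generations = 1L,
                   crossover = 0, mutation = 0)
  e0 <- eaScan(con, pred$fn, params = par0, seed = 6)
  expect_lte(e0@evaluations, 16L)
  expect_equal(e0@results$ddg[1], min(e0@results$ddg))
})

test_that("returned mutants always satisfy the constraint", {
  st <- makeToyStructure(15, "helix", seed = 11)
  pred <- additivePredictor(st)
  set.seed(13)
  for (k in 1:5) {
    sites <- sort(sample(1:15, sample(4:8, 1)))
    subs <- sample(c("K", "R", "E", "D", "Q"), 3)
    n <- sample(1:2, 1)
    con <- mutationConstraint(st, nPoints = n, positions = sites,
                              substitutions = subs)
    res <- eaScan(con, pred$fn,
                  params = eaParams(populations = 1L, popSize = 10L,
                                    generations = 10L), seed = k)
    for (tok in res@results$mutations) {
      ms <- parseMutations(tok)
      expect_identical(nrow(ms@mutations), n)
      expect_true(all(ms@mutations$resno %in% sites))
      expect_true(all(ms@mutations$mut %in% subs))
      expect_true(all(ms@mutations$mut != ms@mutations$wt))
    }
  }
})
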