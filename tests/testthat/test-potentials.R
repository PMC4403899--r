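test_that("a single all-covering bin gives identically zero energies", {
  st <- makeToyStructure(12, "helix", sequence = strrep("AV", 6))
  p <- compilePairSSF(st, "CA", breaks = c(3, 15))
  expect_true(all(abs(p@energy) < 1e-12))
  expect_true(all(abs(p@expected) < 1e-12))
})

test_that("pair tables match hand-counted frequencies and expected energies", {
  ## four residues on a line: eligible pairs (|i-j| >= 2) are
  ## (1,3) d=8 -> bin 1, (2,4) d=8 -> bin 1, (1,4) d=12 -> bin 2
  rows <- lapply(1:4, function(i)
    residueRow("A", i, c("A", "V", "A", "V")[i], ca = c(4 * (i - 1), 0, 0),
               cb = c(4 * (i - 1), 1.5, 0)))
  st <- do.call(structureFromRows, rows)
  breaks <- c(6, 10, 14)
  p <- compilePairSSF(st, "CA", breaks = breaks, minSeqSep = 2L,
                      pseudocount = 1)
  ## hand-built symmetric count tables: a same-type pair adds 2 to its own
  ## cell, a mixed pair adds 1 to each of the two mirror cells
  cAA <- c(2, 0); cVV <- c(2, 0); cAV <- c(0, 1)
  expect_equal(unname(p@counts["A", "A", ]), cAA)
  expect_equal(unname(p@counts["V", "V", ]), cVV)
  expect_equal(unname(p@counts["A", "V", ]), cAV)
  expect_equal(unname(p@counts["V", "A", ]), cAV)
  expect_equal(sum(p@counts), 6)
  ## smoothed cells: 400 (a,b) cells x 2 bins, +1 pseudocount everywhere
  total <- 400 * 2 + 6
  rho <- c(400 + 4, 400 + 2) / total
  expect_equal(p@rho, rho)
  dAA <- (cAA + 1) / sum(cAA + 1)
  eAA <- -log(dAA / rho)
  expect_equal(unname(p@energy["A", "A", ]), eAA)
  expect_equal(p@expected["A", "A"], sum(eAA * rho))
  dAV <- (cAV + 1) / sum(cAV + 1)
  eAV <- -log(dAV / rho)
  expect_equal(unname(p@energy["A", "V", ]), eAV)
  expect_equal(p@expected["A", "V"], sum(eAV * rho))
  ## symmetry of the full tables
  for (k in 1:2) {
    expect_identical(p@energy[, , k], t(p@energy[, , k]))
    expect_identical(p@counts[, , k], t(p@counts[, , k]))
  }
  expect_identical(p@expected, t(p@expected))
})

test_that("structures with no in-range pairs give uniform, zero-energy tables", {
  rows <- lapply(1:3, function(i)
    residueRow("A", i, "L", ca = c(40 * i, 0, 0)))
  st <- do.call(structureFromRows, rows)
  p <- compilePairSSF(st, "CA", breaks = 3:15)
  expect_true(all(abs(p@energy) < 1e-12))
  expect_true(all(abs(p@expected) < 1e-12))
  expect_error(compilePairSSF(list(), "CA"), "at least one")
  expect_error(compilePairSSF(st, "CA", breaks = c(5, 4)), "increasing")
  expect_error(compilePairSSF(st, "CA", breaks = 3:15, pseudocount = 0),
               "empty bin")
})

test_that("contact counts agree with a brute-force double loop", {
  st <- toyStructures()[[1]]
  cs <- compileContactSSF(st, radius = 10, maxCount = 30L)
  xyz <- as.matrix(st@residues[, c("ca_x", "ca_y", "ca_z")])
  n <- nrow(xyz)
  brute <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 10)
      brute[i] <- brute[i] + 1L
  bruteTab <- matrix(0, 20, 31)
  aaIdx <- match(st@residues$aa, rownames(cs@counts))
  for (i in seq_len(n))
    bruteTab[aaIdx[i], min(brute[i], 30L) + 1L] <-
      bruteTab[aaIdx[i], min(brute[i], 30L) + 1L] + 1
  expect_equal(unname(cs@counts), bruteTab)
  ## single residue: contact count zero
  one <- structureFromRows(residueRow("A", 1, "W", ca = c(0, 0, 0)))
  c1 <- compileContactSSF(one, radius = 10)
  expect_equal(unname(c1@counts["W", ]), c(1, rep(0, 30)))
})

test_that("rank-sum score matches enumerated ranks and the null moments", {
  ## n = 5, all observed strictly below all expected
  rs <- rankSumScore(1:5, 11:15)
  expect_equal(rs$W, 15)
  expect_equal(rs$muW, 27.5)
  expect_equal(rs$sigmaW, sqrt(275 / 12))
  expect_equal(rs$s, (15 - 27.5) / sqrt(275 / 12), tolerance = 1e-12)
  expect_equal(rs$s, -2.611, tolerance = 1e-3)
  ## perfect observed/expected ties: midranks make W = mu_W exactly
  v <- rnorm(8)
  expect_equal(rankSumScore(v, v)$s, 0)
  expect_error(rankSumScore(numeric(0), numeric(0)), "n = 0")
  ## Monte-Carlo null: mean/sd of W over random half-assignments
  set.seed(7)
  n <- 15L
  draws <- replicate(3000, sum(sample.int(2 * n, n)))
  mu <- n * (2 * n + 1) / 2
  sig <- sqrt(n^2 * (2 * n + 1) / 12)
  expect_lt(abs(mean(draws) - mu), 3 * sig / sqrt(3000))
  expect_lt(abs(sd(draws) / sig - 1), 0.1)
})

test_that("structure scores combine by Stouffer's rule and are rigid-motion invariant", {
  st <- toyStructures()[[2]]
  ssf <- toySSF()
  sc <- scoreStructure(st, ssf)
  expect_equal(sc[["combined"]],
               (sc[["pssf_ca"]] + sc[["pssf_cb"]] + sc[["cssf"]]) / sqrt(3))
  moved <- rigidTransform(st)
  expect_equal(scoreStructure(moved, ssf), sc, tolerance = 1e-9)
})

test_that("delta scores are antisymmetric, consistent and match full rescoring", {
  st <- toyStructures()[[1]]
  ssf <- toySSF()
  expect_equal(deltaScore(st, emptyMutationSet(), ssf), 0)
  wt <- st@residues$aa[10]
  mut <- setdiff(c("W", "F"), wt)[1]
  ms <- mutationSet(data.frame(chain = "A", resno = 10L, icode = "",
                               wt = wt, mut = mut))
  ds <- deltaScore(st, ms, ssf)
  ## oracle: two independent full scoreStructure calls
  mutant <- applyMutations(st, ms)
  expect_equal(ds, scoreStructure(mutant, ssf)[["combined"]] -
                   scoreStructure(st, ssf)[["combined"]], tolerance = 1e-12)
  ## antisymmetry under the reverse mutation on the mutant structure
  expect_equal(deltaScore(mutant, reverseMutations(ms), ssf), -ds,
               tolerance = 1e-12)
  comp <- componentDeltaScores(st, ms, ssf)
  expect_equal(sum(comp) / sqrt(3), ds, tolerance = 1e-12)
  expect_equal(unname(comp),
               unname((scoreStructure(mutant, ssf) -
                       scoreStructure(st, ssf))[c("pssf_ca", "pssf_cb",
                                                  "cssf")]),
               tolerance = 1e-12)
})

test_that("scoring-function files round-trip bit-exactly", {
  ssf <- toySSF()
  d <- withr::local_tempdir()
  saveSSFModelSet(ssf, d)
  back <- readSSFModelSet(d)
  for (sl in c("breaks", "counts", "delta", "rho", "energy", "expected"))
    expect_identical(slot(back@ca, sl), slot(ssf@ca, sl))
  expect_identical(back@cb@energy, ssf@cb@energy)
  for (sl in c("counts", "delta", "rho", "energy", "expected"))
    expect_identical(slot(back@contact, sl), slot(ssf@contact, sl))
  expect_identical(back@contact@radius, ssf@contact@radius)
})
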