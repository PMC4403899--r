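test_that("MLR agent is exact on noise-free linear data", {
  rec <- makeSyntheticRecords(120, demoBeta(), noiseSd = 0, seed = 5)
  m <- trainMLR(rec)
  Xs <- prostab:::.scaleFeatures(as.matrix(rec[, FEATURE_NAMES]),
                                 m@info$center, m@info$scale)
  pred <- as.numeric(cbind(1, Xs) %*% m@fit$coef)
  expect_equal(pred, rec$ddg, tolerance = 1e-6)
  ## constant target: intercept-only
  rec2 <- rec; rec2$ddg <- 1.5
  m2 <- trainMLR(rec2)
  expect_equal(unname(m2@fit$coef[1]), 1.5, tolerance = 1e-9)
  expect_true(all(abs(m2@fit$coef[-1]) < 1e-9))
  ## collinear columns are named in the error
  rec3 <- rec; rec3$d_iep <- rec3$d_mass
  expect_error(trainMLR(rec3), "rank deficient.*d_iep")
  expect_error(trainMLR(rec[1:5, ]), ">= 10")
})

test_that("ANN agent learns linear data and averages its member networks", {
  rec <- toyRecords(300, noise = 0.3, seed = 9)
  tr <- rec[1:240, ]; te <- rec[241:300, ]
  ag <- trainANNAgent(tr, hiddenGrid = c(3L, 5L), seed = 2,
                      config = fastConfig())
  expect_length(ag@fit, 10L)
  Xs <- prostab:::.scaleFeatures(as.matrix(te[, FEATURE_NAMES]),
                                 ag@info$center, ag@info$scale)
  pred <- prostab:::.agentPredict(ag, Xs)
  expect_gte(cor(pred, te$ddg), 0.95)
  ## agent output is the arithmetic mean of the member networks
  member <- sapply(ag@fit, function(net) as.numeric(predict(net, Xs)))
  expect_equal(pred, rowMeans(member), tolerance = 1e-12)
  ## determinism under the seed
  ag2 <- trainANNAgent(tr, hiddenGrid = c(3L, 5L), seed = 2,
                       config = fastConfig())
  expect_identical(prostab:::.agentPredict(ag2, Xs), pred)
  expect_error(trainANNAgent(rec[1:30, ]), ">= 50")
})

test_that("SVR agent learns linear data; singleton grid skips the search", {
  rec <- toyRecords(260, noise = 0.3, seed = 10)
  tr <- rec[1:200, ]; te <- rec[201:260, ]
  ag <- trainSVRAgent(tr, gammaGrid = c(0.05, 1 / 9), costGrid = c(1, 4),
                      seed = 3)
  Xs <- prostab:::.scaleFeatures(as.matrix(te[, FEATURE_NAMES]),
                                 ag@info$center, ag@info$scale)
  expect_gte(cor(prostab:::.agentPredict(ag, Xs), te$ddg), 0.9)
  one <- trainSVRAgent(tr, gammaGrid = 1 / 9, costGrid = 1, seed = 3)
  expect_identical(c(one@info$gamma, one@info$cost), c(1 / 9, 1))
  one2 <- trainSVRAgent(tr, gammaGrid = 1 / 9, costGrid = 1, seed = 3)
  expect_identical(prostab:::.agentPredict(one2, Xs),
                   prostab:::.agentPredict(one, Xs))
})

test_that("the full ensemble trains seven agents with sign specialists", {
  rec <- toyRecords(350)
  ens <- toyEnsemble()
  expect_setequal(names(ens@agents),
                  c("mlr", "ann_general", "ann_stabilizing",
                    "ann_destabilizing", "svr_general", "svr_stabilizing",
                    "svr_destabilizing"))
  nStab <- ens@agents$ann_stabilizing@info$n
  nDest <- ens@agents$ann_destabilizing@info$n
  expect_identical(nStab + nDest, nrow(rec))
  expect_identical(nStab, sum(rec$ddg < 0))
  expect_equal(ens@sigmaMax, 4 * sd(rec$ddg))
  allPos <- rec; allPos$ddg <- abs(allPos$ddg)
  expect_error(trainAgents(allPos, fastConfig()), "general-only")
})

test_that("consensus follows the iterated outlier-removal rule", {
  ## perfect consensus
  ens <- constantEnsemble(2, 2, 2, 2, 2, 2, 2, sigmaMax = 2)
  p <- predictDDG(zeroFeatures(), ens)
  expect_equal(p@ddg, 2)
  expect_equal(p@sigmaR, 0)
  expect_equal(p@cPred, 1)
  expect_length(p@removed, 0L)
  ## pool {1.0, 1.1, 0.9, 1.05, 6.0}; positive generals route to the
  ## destabilizing specialists.  Frozen hand-run of the removal rule:
  ## 6.0 goes first (|6 - 1.0125| > 2 * 0.0854); then 0.9
  ## (|0.9 - 1.05| = 0.15 > 2 * sd{1.0, 1.1, 1.05} = 0.10); then the
  ## first of the tied pair {1.0, 1.1} (both 0.075 > 2 * 0.0354), leaving
  ## {1.1, 1.05} at the two-value floor.
  ens2 <- constantEnsemble(mlr = 1.0, annG = 1.1, annStab = -9,
                           annDestab = 0.9, svrG = 1.05, svrStab = -9,
                           svrDestab = 6.0, sigmaMax = 2)
  p2 <- predictDDG(zeroFeatures(), ens2)
  expect_identical(p2@removed[1], "svr_specialist")
  expect_setequal(p2@removed, c("svr_specialist", "ann_specialist", "mlr"))
  expect_setequal(p2@retained, c("ann_general", "svr_general"))
  expect_equal(p2@ddg, mean(c(1.1, 1.05)))
  ## negative general predictions route to the stabilizing specialists
  ens3 <- constantEnsemble(mlr = -1, annG = -1, annStab = -1, annDestab = 9,
                           svrG = -1, svrStab = -1, svrDestab = 9,
                           sigmaMax = 2)
  p3 <- predictDDG(zeroFeatures(), ens3)
  expect_equal(p3@ddg, -1)
  expect_equal(p3@cPred, 1)
})

test_that("confidence is exactly piecewise linear in the retained spread", {
  ## pool {0, 1, 2, 3, 4} survives pruning; sd = sqrt(2.5)
  mk <- function(sigmaMax)
    constantEnsemble(mlr = 0, annG = 1, annStab = -9, annDestab = 2,
                     svrG = 3, svrStab = -9, svrDestab = 4,
                     sigmaMax = sigmaMax)
  s <- sqrt(2.5)
  atMax <- predictDDG(zeroFeatures(), mk(s))
  expect_length(atMax@removed, 0L)
  expect_equal(atMax@sigmaR, s)
  expect_equal(atMax@cPred, 0)
  expect_equal(predictDDG(zeroFeatures(), mk(2 * s))@cPred, 0.5)
  expect_equal(predictDDG(zeroFeatures(), mk(s * 0.999))@cPred, 0)
  expect_equal(predictDDG(zeroFeatures(), mk(1e6))@cPred, 1,
               tolerance = 1e-5)
})

test_that("outlier pruning terminates, keeps >= 2 values, and confidence is monotone", {
  set.seed(11)
  for (k in 1:40) {
    v <- rnorm(5, sd = runif(1, 0.1, 3))
    pr <- prostab:::.pruneOutliers(v)
    expect_gte(length(pr$keep), 2L)
    expect_lte(length(pr$removed), 3L)
    expect_setequal(c(pr$keep, pr$removed), seq_along(v))
  }
  ## c_pred non-increasing in sigma_r
  sm <- 2
  cp <- function(sr) if (sr > sm) 0 else 1 - sr / sm
  srs <- seq(0, 3, by = 0.05)
  expect_true(all(diff(vapply(srs, cp, numeric(1))) <= 0))
})

test_that("grouped cross-validation never splits a group and is reproducible", {
  rec <- toyRecords(300, seed = 21)
  rec$protein <- paste0("P", rep_len(1:8, 300))
  rec$position <- paste0("A:", rep_len(1:40, 300))
  cv <- crossValidate(rec, k = 4, grouping = "position", seed = 5,
                      config = fastConfig())
  byPos <- split(cv$predictions$fold, paste(rec$protein, rec$position))
  expect_true(all(vapply(byPos, function(f) length(unique(f)) == 1L,
                         logical(1))))
  ## at this small per-fold size the learnable-signal bar is a little looser
  ## than the full-scale recovery check
  expect_gte(cv$pooled$rho, 0.85)
  cv2 <- crossValidate(rec, k = 4, grouping = "position", seed = 5,
                       config = fastConfig())
  expect_identical(cv2$pooled, cv$pooled)
  expect_error(crossValidate(rec, k = 9, grouping = "protein"),
               "fewer groups")
})

test_that("ensemble bundles round-trip through the model directory", {
  ens <- toyEnsemble()
  d <- withr::local_tempdir()
  saveAgentEnsemble(ens, d)
  expect_true(file.exists(file.path(d, "meta.tsv")))
  back <- loadAgentEnsemble(d)
  fv <- unlist(toyRecords(350)[3, FEATURE_NAMES])
  expect_identical(predictDDG(fv, back)@ddg, predictDDG(fv, ens)@ddg)
  expect_identical(back@sigmaMax, ens@sigmaMax)
  expect_error(loadAgentEnsemble(file.path(d, "nope")), "bundle")
})
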