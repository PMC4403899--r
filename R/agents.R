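## The seven prediction agents, the outlier-pruned consensus and the
## confidence estimate, plus grouped cross-validation.

.recordMatrix <- function(records) {
  miss <- setdiff(FEATURE_NAMES, names(records))
  if (length(miss)) .stop2("records lack feature column(s): %s",
                           paste(miss, collapse = ", "))
  as.matrix(records[, FEATURE_NAMES])
}

.featureScaling <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

.scaleFeatures <- function(X, center, scale) {
  sweep(sweep(X, 2L, center), 2L, scale, "/")
}

#' Default agent-training configuration
#'
#' @param hiddenGrid hidden-layer sizes searched for the ANN agents.
#' @param gammaGrid,costGrid log-2 grids searched for the SVR agents.
#' @param epsilon SVR epsilon-insensitive tube width.
#' @param decay ANN weight-decay regularization.
#' @param maxit total ANN optimizer iterations (chunked with early stopping
#'   on the generalization fold).
#' @param minClass minimum records per sign class for specialist training.
#' @return a named list.
#' @export
agentConfig <- function(hiddenGrid = c(3L, 5L, 7L, 9L, 12L),
                        gammaGrid = 2^seq(-10, 2, by = 2),
                        costGrid = 2^seq(-4, 8, by = 2),
                        epsilon = 0.1, decay = 1e-3, maxit = 300L,
                        minClass = 25L) {
  list(hiddenGrid = hiddenGrid, gammaGrid = gammaGrid, costGrid = costGrid,
       epsilon = epsilon, decay = decay, maxit = maxit, minClass = minClass)
}

#' Train the multiple-linear-regression agent
#'
#' Ordinary least squares on the nine z-scaled inputs plus intercept.
#'
#' @param records training data.frame (feature columns plus \code{ddg}).
#' @param center,scale feature scaling statistics (defaults computed from
#'   \code{records}).
#' @return an \code{AgentModel}.
#' @export
trainMLR <- function(records, center = NULL, scale = NULL) {
  if (nrow(records) < 10L) .stop2("need >= 10 records for MLR")
  X <- .recordMatrix(records)
  if (is.null(center)) { sc <- .featureScaling(X); center <- sc$center; scale <- sc$scale }
  Xs <- .scaleFeatures(X, center, scale)
  q <- qr(cbind(1, Xs))
  if (q$rank < ncol(Xs) + 1L) {
    dropped <- setdiff(seq_len(ncol(Xs) + 1L), q$pivot[seq_len(q$rank)]) - 1L
    .stop2("design matrix is rank deficient; collinear column(s): %s",
           paste(colnames(Xs)[dropped[dropped > 0L]], collapse = ", "))
  }
  cf <- qr.coef(q, records$ddg)
  new("AgentModel", method = "MLR", specialization = "general",
      fit = list(coef = cf),
      info = list(n = nrow(records), center = center, scale = scale))
}

## Chunked BFGS training with early stopping on a generalization set: the
## network continues from its previous weights and keeps the checkpoint with
## the best generalization error (patience 2 chunks).
.fitANN <- function(Xtr, ytr, Xgen, ygen, size, decay, maxit, seed) {
  set.seed(seed)
  chunk <- 50L
  nChunks <- max(1L, ceiling(maxit / chunk))
  net <- nnet::nnet(Xtr, ytr, size = size, linout = TRUE, decay = decay,
                    maxit = chunk, trace = FALSE)
  best <- net
  bestErr <- mean((predict(net, Xgen) - ygen)^2)
  bad <- 0L
  for (k in seq_len(nChunks - 1L)) {
    net <- nnet::nnet(Xtr, ytr, size = size, linout = TRUE, decay = decay,
                      maxit = chunk, trace = FALSE, Wts = net$wts)
    err <- mean((predict(net, Xgen) - ygen)^2)
    if (err < bestErr - 1e-10) { best <- net; bestErr <- err; bad <- 0L }
    else { bad <- bad + 1L; if (bad >= 2L) break }
  }
  list(net = best, genErr = bestErr)
}

#' Train a neural-network agent
#'
#' The records are partitioned into ten folds.  Per fold rotation one fold
#' is the test set, the next the generalization set, and the remaining eight
#' train one 9-H-1 network (tanh hidden layer, linear output, weight decay,
#' BFGS optimization checkpointed against the generalization fold).  The
#' hidden size is chosen from \code{hiddenGrid} by mean test-fold error, and
#' the agent keeps that size's ten member networks; it predicts with their
#' average.
#'
#' @inheritParams trainMLR
#' @param hiddenGrid candidate hidden-layer sizes.
#' @param seed integer seed (fold shuffle and weight initialization).
#' @param specialization stored agent label.
#' @param config see \code{agentConfig}.
#' @return an \code{AgentModel} whose \code{fit} is the member-network list.
#' @export
trainANNAgent <- function(records, hiddenGrid = c(3L, 5L, 7L, 9L, 12L),
                          seed = 1L, center = NULL, scale = NULL,
                          specialization = "general", config = agentConfig(),
                          minRecords = 50L) {
  n <- nrow(records)
  if (n < minRecords)
    .stop2("need >= %d records to train an ANN agent (got %d)", minRecords, n)
  if (n < 20L) .stop2("too few records for the 10-fold rotation (got %d)", n)
  X <- .recordMatrix(records)
  if (is.null(center)) { sc <- .featureScaling(X); center <- sc$center; scale <- sc$scale }
  Xs <- .scaleFeatures(X, center, scale)
  y <- records$ddg
  set.seed(.deriveSeed(seed, 101L))
  fold <- sample(rep_len(1:10, n))
  results <- list()
  for (h in hiddenGrid) {
    nets <- vector("list", 10L)
    testErr <- numeric(10L)
    for (f in 1:10) {
      g <- f %% 10L + 1L
      tr <- !(fold %in% c(f, g))
      fit <- .fitANN(Xs[tr, , drop = FALSE], y[tr],
                     Xs[fold == g, , drop = FALSE], y[fold == g],
                     size = h, decay = config$decay, maxit = config$maxit,
                     seed = .deriveSeed(seed, 1000L * h + f))
      nets[[f]] <- fit$net
      testErr[f] <- mean((predict(fit$net, Xs[fold == f, , drop = FALSE]) -
                          y[fold == f])^2)
    }
    results[[as.character(h)]] <- list(nets = nets, err = mean(testErr))
  }
  errs <- vapply(results, `[[`, numeric(1L), "err")
  best <- names(results)[which.min(errs)]
  new("AgentModel", method = "ANN", specialization = specialization,
      fit = results[[best]]$nets,
      info = list(n = n, hidden = as.integer(best), testErr = errs,
                  center = center, scale = scale))
}

#' Train a support-vector-regression agent
#'
#' Epsilon-SVR with a Gaussian kernel; \code{gamma} and \code{cost} are
#' optimized by 10-fold cross-validated mean squared error over the log-2
#' grid, and the final model is refit on all records with the best pair.
#'
#' @inheritParams trainANNAgent
#' @param gammaGrid,costGrid searched parameter grids.
#' @return an \code{AgentModel}.
#' @export
trainSVRAgent <- function(records, gammaGrid = 2^seq(-10, 2, by = 2),
                          costGrid = 2^seq(-4, 8, by = 2), seed = 1L,
                          center = NULL, scale = NULL,
                          specialization = "general", config = agentConfig(),
                          minRecords = 50L) {
  n <- nrow(records)
  if (n < minRecords)
    .stop2("need >= %d records to train an SVR agent (got %d)", minRecords, n)
  X <- .recordMatrix(records)
  if (is.null(center)) { sc <- .featureScaling(X); center <- sc$center; scale <- sc$scale }
  Xs <- .scaleFeatures(X, center, scale)
  y <- records$ddg
  grid <- expand.grid(gamma = gammaGrid, cost = costGrid)
  if (nrow(grid) > 1L) {
    cvErr <- vapply(seq_len(nrow(grid)), function(i) {
      set.seed(.deriveSeed(seed, 200L + i))
      m <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                      gamma = grid$gamma[i], cost = grid$cost[i],
                      epsilon = config$epsilon, cross = 10, scale = FALSE)
      m$tot.MSE
    }, numeric(1L))
    bi <- which.min(cvErr)
  } else bi <- 1L
  set.seed(.deriveSeed(seed, 299L))
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    gamma = grid$gamma[bi], cost = grid$cost[bi],
                    epsilon = config$epsilon, scale = FALSE)
  new("AgentModel", method = "SVR", specialization = specialization,
      fit = fit, info = list(n = n, gamma = grid$gamma[bi],
                             cost = grid$cost[bi], center = center,
                             scale = scale))
}

.agentPredict <- function(agent, Xs) {
  switch(agent@method,
         MLR = as.numeric(cbind(1, Xs) %*% agent@fit$coef),
         ANN = {
           m <- vapply(agent@fit, function(net) as.numeric(predict(net, Xs)),
                       numeric(nrow(Xs)))
           if (is.matrix(m)) rowMeans(m) else mean(m)
         },
         SVR = as.numeric(predict(agent@fit, Xs)),
         .stop2("unknown agent method '%s'", agent@method))
}

#' Train the full seven-agent ensemble
#'
#' General MLR, ANN and SVR agents are trained on all records; ANN and SVR
#' specialists are trained on the stabilizing (ddG < 0) and destabilizing
#' (ddG >= 0) subsets respectively.  The confidence cutoff sigma_max is
#' stored as four times the standard deviation of the training ddG values.
#'
#' @param records training data.frame.
#' @param config see \code{agentConfig}.
#' @param seed integer seed for all stochastic steps.
#' @return an \code{AgentEnsemble}.
#' @export
trainAgents <- function(records, config = agentConfig(), seed = 1L) {
  stab <- records[records$ddg < 0, , drop = FALSE]
  dest <- records[records$ddg >= 0, , drop = FALSE]
  if (nrow(stab) < config$minClass || nrow(dest) < config$minClass)
    .stop2(paste("need >= %d records in each sign class (stabilizing %d,",
                 "destabilizing %d); consider a general-only prediction"),
           config$minClass, nrow(stab), nrow(dest))
  sc <- .featureScaling(.recordMatrix(records))
  ann <- function(data, spec, off)
    trainANNAgent(data, config$hiddenGrid, seed = .deriveSeed(seed, off),
                  center = sc$center, scale = sc$scale, specialization = spec,
                  config = config, minRecords = config$minClass)
  svr <- function(data, spec, off)
    trainSVRAgent(data, config$gammaGrid, config$costGrid,
                  seed = .deriveSeed(seed, off), center = sc$center,
                  scale = sc$scale, specialization = spec, config = config,
                  minRecords = config$minClass)
  agents <- list(
    mlr = trainMLR(records, center = sc$center, scale = sc$scale),
    ann_general = ann(records, "general", 1L),
    ann_stabilizing = ann(stab, "stabilizing", 2L),
    ann_destabilizing = ann(dest, "destabilizing", 3L),
    svr_general = svr(records, "general", 4L),
    svr_stabilizing = svr(stab, "stabilizing", 5L),
    svr_destabilizing = svr(dest, "destabilizing", 6L))
  new("AgentEnsemble", agents = agents, center = sc$center, scale = sc$scale,
      sigmaMax = 4 * sd(records$ddg),
      config = c(config, list(nRecords = nrow(records), seed = seed)))
}

## Iterative outlier pruning: repeatedly drop the value farthest from the
## mean of the others when its distance exceeds k times the sd of the
## others; stop when no outlier remains or only minRetained values are left.
.pruneOutliers <- function(values, k = 2, minRetained = 2L) {
  keep <- seq_along(values)
  removed <- integer()
  while (length(keep) > minRetained) {
    v <- values[keep]
    dist <- thr <- numeric(length(v))
    for (i in seq_along(v)) {
      others <- v[-i]
      dist[i] <- abs(v[i] - mean(others))
      thr[i] <- k * sd(others)
    }
    cand <- which(dist > thr)
    if (!length(cand)) break
    worst <- which.max(dist)
    removed <- c(removed, keep[worst])
    keep <- keep[-worst]
  }
  list(keep = keep, removed = removed)
}

#' Consensus ddG prediction with confidence
#'
#' The general agents predict first; the sign of the ANN / SVR general
#' prediction routes to the matching specialist.  The consensus pool (ANN
#' general + specialist, SVR general + specialist, MLR) is pruned by
#' iterative outlier removal, the retained values are averaged into the
#' consensus ddG, and the confidence is \code{1 - sigma_r / sigma_max}
#' (clamped to [0, 1]).
#'
#' @param features named numeric length 9 (see \code{FEATURE_NAMES}) or a
#'   1-row data.frame of feature columns.
#' @param ensemble a trained \code{AgentEnsemble}.
#' @param pool \code{"routed"} (the five-value consensus) or
#'   \code{"general"} (generals only, no specialists).
#' @param outlierK,minRetained outlier-pruning parameters.
#' @return a \code{StabilityPrediction}.
#' @export
predictDDG <- function(features, ensemble, pool = c("routed", "general"),
                       outlierK = 2, minRetained = 2L) {
  pool <- match.arg(pool)
  if (is.data.frame(features)) features <- unlist(features[1L, FEATURE_NAMES])
  stopifnot(all(FEATURE_NAMES %in% names(features)))
  Xs <- .scaleFeatures(matrix(features[FEATURE_NAMES], nrow = 1L,
                              dimnames = list(NULL, FEATURE_NAMES)),
                       ensemble@center, ensemble@scale)
  ag <- ensemble@agents
  p <- function(a) .agentPredict(a, Xs)
  mlr <- p(ag$mlr); annG <- p(ag$ann_general); svrG <- p(ag$svr_general)
  if (pool == "routed") {
    annS <- p(if (annG < 0) ag$ann_stabilizing else ag$ann_destabilizing)
    svrS <- p(if (svrG < 0) ag$svr_stabilizing else ag$svr_destabilizing)
    values <- c(mlr = mlr, ann_general = annG, ann_specialist = annS,
                svr_general = svrG, svr_specialist = svrS)
  } else {
    values <- c(mlr = mlr, ann_general = annG, svr_general = svrG)
  }
  pr <- .pruneOutliers(values, k = outlierK, minRetained = minRetained)
  retained <- values[pr$keep]
  sigmaR <- if (length(retained) > 1L) sd(retained) else 0
  cPred <- if (sigmaR > ensemble@sigmaMax) 0 else 1 - sigmaR / ensemble@sigmaMax
  new("StabilityPrediction",
      ddg = mean(retained),
      deltaScore = unname((features[["ds_pssf_ca"]] + features[["ds_pssf_cb"]] +
                           features[["ds_cssf"]]) / sqrt(3)),
      agentValues = values, retained = names(retained),
      removed = names(values)[pr$removed], sigmaR = sigmaR, cPred = cPred)
}

#' Predict the stability change of a mutant from a structure
#'
#' Convenience wrapper: builds the nine-value feature vector for the mutant
#' and runs the agent consensus.
#'
#' @inheritParams buildFeatureVector
#' @inheritParams predictDDG
#' @export
predictMutation <- function(structure, ms, ensemble, ssf,
                            pool = c("routed", "general"),
                            context = NULL, siteCache = NULL) {
  fv <- buildFeatureVector(structure, ms, ssf, context = context,
                           siteCache = siteCache)
  predictDDG(fv, ensemble, pool = match.arg(pool))
}

#' Grouped k-fold cross-validation of the ensemble
#'
#' Folds never split a group (record, mutation position, or protein).  Each
#' fold's training set is used to train a fresh seven-agent ensemble; the
#' held-out predictions are pooled into Pearson's correlation, the standard
#' error (root mean squared residual, kcal/mol) and the sign-classification
#' accuracy (negative ddG = stabilizing).
#'
#' @param records training data.frame with \code{protein} and
#'   \code{position} keys.
#' @param k number of folds (>= 2).
#' @param grouping "record", "position" or "protein".
#' @param seed integer seed.
#' @param config see \code{agentConfig}.
#' @param pool consensus pool passed to \code{predictDDG}.
#' @return list with \code{pooled} (rho, sigma, accuracy, n), \code{perFold}
#'   data.frame and \code{predictions}.
#' @export
crossValidate <- function(records, k = 10L,
                          grouping = c("record", "position", "protein"),
                          seed = 1L, config = agentConfig(),
                          pool = c("routed", "general")) {
  grouping <- match.arg(grouping)
  pool <- match.arg(pool)
  if (k < 2L) .stop2("k must be >= 2")
  key <- switch(grouping,
                record = as.character(seq_len(nrow(records))),
                position = paste(records$protein, records$position),
                protein = records$protein)
  groups <- unique(key)
  if (length(groups) < k)
    .stop2("fewer groups (%d) than folds (%d)", length(groups), k)
  set.seed(.deriveSeed(seed, 401L))
  ## balanced assignment: shuffle groups, deal round-robin
  foldOf <- setNames(rep_len(seq_len(k), length(groups)), sample(groups))
  fold <- foldOf[key]
  pred <- rep(NA_real_, nrow(records))
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- which(fold != f)
    teIdx <- which(fold == f)
    if (!length(teIdx)) next
    ens <- trainAgents(records[trIdx, , drop = FALSE], config = config,
                       seed = .deriveSeed(seed, 500L + f))
    Xte <- .recordMatrix(records[teIdx, , drop = FALSE])
    pred[teIdx] <- vapply(seq_along(teIdx), function(i)
      predictDDG(Xte[i, ], ens, pool = pool)@ddg, numeric(1L))
    resid <- pred[teIdx] - records$ddg[teIdx]
    perFold[[f]] <- data.frame(fold = f, n = length(teIdx),
                               rho = if (length(teIdx) > 2L)
                                 stats::cor(pred[teIdx], records$ddg[teIdx])
                               else NA_real_,
                               sigma = sqrt(mean(resid^2)))
  }
  obs <- records$ddg
  list(pooled = list(rho = stats::cor(pred, obs),
                     sigma = sqrt(mean((pred - obs)^2)),
                     accuracy = mean((pred < 0) == (obs < 0)),
                     n = length(obs)),
       perFold = do.call(rbind, perFold),
       predictions = data.frame(fold = fold, observed = obs,
                                predicted = pred))
}

#' Save / load a trained ensemble bundle
#'
#' The bundle is a directory with the serialized agents plus a readable
#' metadata file (format version, scaling, sigma_max); round-trips exactly.
#'
#' @param ensemble an \code{AgentEnsemble}.
#' @param dir bundle directory (created if needed).
#' @export
saveAgentEnsemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ensemble, file.path(dir, "agents.rds"))
  meta <- c("#prostab-model\tv1",
            paste0("sigmaMax\t", .fmtNum(ensemble@sigmaMax)),
            paste0("center\t", paste(.fmtNum(ensemble@center), collapse = ",")),
            paste0("scale\t", paste(.fmtNum(ensemble@scale), collapse = ",")),
            paste0("features\t", paste(FEATURE_NAMES, collapse = ",")))
  writeLines(meta, file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' @rdname saveAgentEnsemble
#' @export
loadAgentEnsemble <- function(dir) {
  f <- file.path(dir, "agents.rds")
  if (!file.exists(f)) .stop2("no model bundle at '%s'", dir)
  ens <- readRDS(f)
  validObject(ens)
  ens
}
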