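## Glue between the trained model and the search modes: a cached,
## precomputed predictor closure for one structure.

#' Build a reusable ddG predictor for one structure
#'
#' Precomputes the scoring context and per-site features once and returns a
#' closure mapping a \code{MutationSet} to a list with \code{ddg},
#' \code{cPred} and \code{deltaScore}.  This is the predictor handed to the
#' mutation-scan and disulfide-screening functions, which may call it many
#' thousands of times on mutants of the same structure.
#'
#' @inheritParams predictMutation
#' @return function(MutationSet) -> list(ddg, cPred, deltaScore).
#' @export
stabilityPredictor <- function(structure, ensemble, ssf,
                               pool = c("routed", "general")) {
  pool <- match.arg(pool)
  ctx <- .scoringContext(structure, ssf)
  siteCache <- precomputeSiteFeatures(structure)
  function(ms) {
    fv <- buildFeatureVector(structure, ms, ssf, context = ctx,
                             siteCache = siteCache)
    pr <- predictDDG(fv, ensemble, pool = pool)
    list(ddg = pr@ddg, cPred = pr@cPred, deltaScore = pr@deltaScore)
  }
}

#' Featurize a parsed mutation table against structures
#'
#' Computes the nine-value feature vector for every row of a mutation table
#' (as returned by \code{parseMutationTable}) so the result can be fed to
#' \code{trainAgents} or \code{crossValidate}.  Structures are provided as
#' a named list of \code{ProteinStructure}s or as a directory containing
#' \code{<pdb_id>.pdb} files.
#'
#' @param table data.frame with \code{pdb_id}, \code{chain},
#'   \code{mutations}, \code{ddg}.
#' @param structures named list of structures or a directory path.
#' @param ssf an \code{SSFModelSet}.
#' @return a records data.frame (protein/position/mutations/ddg + features).
#' @export
featurizeTable <- function(table, structures, ssf) {
  if (is.character(structures)) {
    dir <- structures
    ids <- unique(table$pdb_id)
    structures <- setNames(lapply(ids, function(id) {
      f <- file.path(dir, paste0(id, ".pdb"))
      if (!file.exists(f)) .stop2("structure file missing for '%s'", id)
      readPDB(f)
    }), ids)
  }
  ctxs <- lapply(structures, .scoringContext, ssf = ssf)
  caches <- lapply(structures, precomputeSiteFeatures)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    id <- table$pdb_id[i]
    st <- structures[[id]]
    if (is.null(st)) .stop2("no structure provided for '%s'", id)
    ms <- parseMutations(table$mutations[i])
    fv <- buildFeatureVector(st, ms, ssf, context = ctxs[[id]],
                             siteCache = caches[[id]])
    data.frame(protein = id,
               position = paste(sprintf("%s:%d%s", ms@mutations$chain,
                                        ms@mutations$resno,
                                        ms@mutations$icode), collapse = ";"),
               mutations = formatMutations(ms), ddg = table$ddg[i],
               as.list(fv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname stabilityPredictor
#' @details \code{deltaScorePredictor} is the model-free variant scoring
#'   mutants purely by the combined scoring-function change (used for
#'   score-only ablations and quick screens; no trained agents required).
#' @export
deltaScorePredictor <- function(structure, ssf) {
  ctx <- .scoringContext(structure, ssf)
  function(ms) {
    ds <- deltaScore(structure, ms, ssf, context = ctx)
    list(ddg = ds, cPred = NA_real_, deltaScore = ds)
  }
}
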