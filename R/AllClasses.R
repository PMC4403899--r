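## S4 classes for the package's central objects.

#' ProteinStructure: a reduced residue-level protein model
#'
#' One model of a protein structure reduced to the per-residue representative
#' atoms the scoring functions operate on: backbone N, CA, C, the (possibly
#' virtual) CB and, for cysteines, SG when present.  Residues keep the author
#' chain/number/insertion-code coordinate system of the source file; internal
#' indices are the 0-based order of rows in \code{residues}.
#'
#' @slot residues data.frame with one row per residue: \code{chain},
#'   \code{resno}, \code{icode}, \code{aa} (1-letter), coordinate columns
#'   \code{n_x..n_z}, \code{ca_x..ca_z}, \code{c_x..c_z}, \code{cb_x..cb_z},
#'   \code{sg_x..sg_z} and logical \code{cb_virtual}.
#' @slot sourceId character label (file name or synthetic id).
#' @slot model model number this object was extracted from (1 for X-ray).
#' @export
setClass("ProteinStructure",
         representation(residues = "data.frame",
                        sourceId = "character",
                        model = "integer"))

setValidity("ProteinStructure", function(object) {
  r <- object@residues
  need <- c("chain", "resno", "icode", "aa",
             paste0(rep(c("n_", "ca_", "c_", "cb_", "sg_"), each = 3),
                    c("x", "y", "z")),
             "cb_virtual")
  if (!all(need %in% names(r)))
    return(sprintf("missing residue columns: %s",
                   paste(setdiff(need, names(r)), collapse = ", ")))
  if (nrow(r) == 0L) return("structure has zero residues")
  if (!all(r$aa %in% .AA1))
    return(sprintf("non-canonical residue types: %s",
                   paste(unique(setdiff(r$aa, .AA1)), collapse = ", ")))
  ca <- as.matrix(r[, c("ca_x", "ca_y", "ca_z")])
  if (!all(is.finite(ca))) return("non-finite CA coordinates")
  cb <- as.matrix(r[, c("cb_x", "cb_y", "cb_z")])
  if (!all(is.finite(cb))) return("non-finite CB coordinates")
  key <- paste(r$chain, r$resno, r$icode)
  if (anyDuplicated(key))
    return(sprintf("duplicated residue identifiers: %s",
                   paste(unique(key[duplicated(key)]), collapse = ", ")))
  TRUE
})

#' @describeIn ProteinStructure number of residues
#' @param x,object a \code{ProteinStructure}
#' @export
nResidues <- function(x) nrow(x@residues)

#' @describeIn ProteinStructure residue table accessor
#' @export
residueTable <- function(x) x@residues

#' @describeIn ProteinStructure chain identifiers in file order
#' @export
chainIds <- function(x) unique(x@residues$chain)

#' @describeIn ProteinStructure one-letter sequence in file order
#' @export
residueSequence <- function(x) x@residues$aa

setMethod("show", "ProteinStructure", function(object) {
  r <- object@residues
  cat(sprintf("ProteinStructure '%s' (model %d): %d residues, %d chain(s) [%s]\n",
              object@sourceId, object@model, nrow(r),
              length(unique(r$chain)), paste(unique(r$chain), collapse = ",")))
  cat(sprintf("  virtual CB: %d residue(s)\n", sum(r$cb_virtual)))
})

#' MutationSet: one or more point substitutions at distinct sites
#'
#' @slot mutations data.frame with columns \code{chain}, \code{resno},
#'   \code{icode}, \code{wt}, \code{mut} (1-letter amino-acid codes).
#' @export
setClass("MutationSet", representation(mutations = "data.frame"))

setValidity("MutationSet", function(object) {
  m <- object@mutations
  need <- c("chain", "resno", "icode", "wt", "mut")
  if (!all(need %in% names(m))) return("missing mutation columns")
  if (nrow(m) > 0L) {
    if (!all(m$wt %in% .AA1) || !all(m$mut %in% .AA1))
      return("amino-acid codes must be canonical 1-letter symbols")
    if (any(m$wt == m$mut)) return("wild-type and mutant types must differ")
    key <- paste(m$chain, m$resno, m$icode)
    if (anyDuplicated(key)) return("mutations must be at pairwise-distinct sites")
  }
  TRUE
})

setMethod("show", "MutationSet", function(object) {
  cat("MutationSet:", if (nrow(object@mutations) == 0L) "(empty)"
      else formatMutations(object), "\n")
})

#' PairSSF: a distance-dependent residue-pair scoring function
#'
#' @slot atomKind "CA" or "CB": the representative atom of each residue.
#' @slot breaks distance bin edges (Angstrom, strictly increasing).
#' @slot counts raw pair counts, 20 x 20 x bins (symmetric in the aa axes).
#' @slot delta per-pair relative distance frequency (pseudocount-smoothed).
#' @slot rho pooled reference distance distribution (sums to 1).
#' @slot energy observed energies -ln(delta/rho).
#' @slot expected per-pair expected energy (frequency-weighted mean energy).
#' @slot minSeqSep minimum intra-chain sequence separation counted.
#' @slot pseudocount additive smoothing applied to every count cell.
#' @export
setClass("PairSSF",
         representation(atomKind = "character", breaks = "numeric",
                        counts = "array", delta = "array", rho = "numeric",
                        energy = "array", expected = "matrix",
                        minSeqSep = "integer", pseudocount = "numeric"))

setValidity("PairSSF", function(object) {
  nb <- length(object@breaks) - 1L
  if (nb < 1L || any(diff(object@breaks) <= 0))
    return("breaks must be strictly increasing with >= 1 bin")
  if (!identical(dim(object@energy), c(20L, 20L, nb)))
    return("energy table must be 20 x 20 x bins")
  if (abs(sum(object@rho) - 1) > 1e-8) return("rho must sum to 1")
  if (max(abs(object@expected - t(object@expected))) > 1e-9)
    return("expected-energy matrix must be symmetric")
  TRUE
})

setMethod("show", "PairSSF", function(object) {
  cat(sprintf("PairSSF (%s-%s): %d bins on [%g, %g) A, seq-sep >= %d, pseudocount %g, %d pairs\n",
              object@atomKind, object@atomKind,
              length(object@breaks) - 1L, min(object@breaks), max(object@breaks),
              object@minSeqSep, object@pseudocount, sum(object@counts) / 2))
})

#' ContactSSF: a CA-contact-count scoring function
#'
#' @slot radius contact radius (Angstrom).
#' @slot maxCount contact counts above this value are clamped.
#' @slot counts raw counts, 20 x (maxCount + 1).
#' @slot delta per-residue-type contact-count frequencies.
#' @slot rho pooled reference contact-count distribution.
#' @slot energy observed energies -ln(delta/rho).
#' @slot expected per-residue-type expected energy.
#' @slot pseudocount additive smoothing.
#' @export
setClass("ContactSSF",
         representation(radius = "numeric", maxCount = "integer",
                        counts = "matrix", delta = "matrix", rho = "numeric",
                        energy = "matrix", expected = "numeric",
                        pseudocount = "numeric"))

setValidity("ContactSSF", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (!identical(dim(object@energy), c(20L, object@maxCount + 1L)))
    return("energy table must be 20 x (maxCount + 1)")
  if (abs(sum(object@rho) - 1) > 1e-8) return("rho must sum to 1")
  TRUE
})

setMethod("show", "ContactSSF", function(object) {
  cat(sprintf("ContactSSF: radius %g A, counts clamped at %d, pseudocount %g, %d residues\n",
              object@radius, object@maxCount, object@pseudocount,
              sum(object@counts)))
})

#' SSFModelSet: the three compiled scoring functions used for prediction
#'
#' @slot ca CA-CA \code{PairSSF}
#' @slot cb CB-CB \code{PairSSF}
#' @slot contact \code{ContactSSF}
#' @export
setClass("SSFModelSet",
         representation(ca = "PairSSF", cb = "PairSSF", contact = "ContactSSF"))

setMethod("show", "SSFModelSet", function(object) {
  cat("SSFModelSet with components:\n  ")
  show(object@ca); cat("  "); show(object@cb); cat("  "); show(object@contact)
})

#' AgentModel: one trained prediction agent
#'
#' @slot method "MLR", "ANN" or "SVR".
#' @slot specialization "general", "stabilizing" or "destabilizing".
#' @slot fit the fitted model object(s); for ANN agents a list of member
#'   networks whose outputs are averaged.
#' @slot info list of training metadata (selected hyper-parameters, sizes).
#' @export
setClass("AgentModel",
         representation(method = "character", specialization = "character",
                        fit = "ANY", info = "list"))

setMethod("show", "AgentModel", function(object) {
  cat(sprintf("AgentModel %s/%s\n", object@method, object@specialization))
})

#' AgentEnsemble: the seven-agent prediction system
#'
#' Three general agents (MLR, ANN, SVR) plus ANN/SVR specialists for
#' stabilizing and destabilizing substitutions, together with the feature
#' z-scaling computed on the training set and the confidence cutoff
#' sigma_max (four times the training-set ddG standard deviation).
#'
#' @slot agents named list of seven \code{AgentModel}s.
#' @slot center,scale per-feature z-scaling statistics.
#' @slot sigmaMax confidence cutoff (kcal/mol).
#' @slot config training configuration used.
#' @export
setClass("AgentEnsemble",
         representation(agents = "list", center = "numeric", scale = "numeric",
                        sigmaMax = "numeric", config = "list"))

setValidity("AgentEnsemble", function(object) {
  need <- c("mlr", "ann_general", "ann_stabilizing", "ann_destabilizing",
            "svr_general", "svr_stabilizing", "svr_destabilizing")
  if (!all(need %in% names(object@agents)))
    return(sprintf("missing agents: %s",
                   paste(setdiff(need, names(object@agents)), collapse = ", ")))
  if (length(object@sigmaMax) != 1L || object@sigmaMax <= 0)
    return("sigmaMax must be a positive scalar")
  TRUE
})

setMethod("show", "AgentEnsemble", function(object) {
  cat(sprintf("AgentEnsemble: 7 agents, sigma_max = %.3f kcal/mol, trained on %d records\n",
              object@sigmaMax, object@config$nRecords %||% NA_integer_))
})

#' StabilityPrediction: consensus ddG with confidence
#'
#' @slot ddg consensus predicted ddG (kcal/mol, negative = stabilizing).
#' @slot deltaScore combined-SSF score difference (mutant minus wild type).
#' @slot agentValues the five values entering consensus.
#' @slot retained names of values kept after outlier pruning.
#' @slot removed names of pruned values.
#' @slot sigmaR standard deviation of the retained values.
#' @slot cPred confidence estimate in [0, 1].
#' @export
setClass("StabilityPrediction",
         representation(ddg = "numeric", deltaScore = "numeric",
                        agentValues = "numeric", retained = "character",
                        removed = "character", sigmaR = "numeric",
                        cPred = "numeric"))

setMethod("show", "StabilityPrediction", function(object) {
  cat(sprintf("StabilityPrediction: ddG = %+.3f kcal/mol (confidence %.2f, sigma_r %.3f)\n",
              object@ddg, object@cPred, object@sigmaR))
  if (length(object@removed))
    cat("  pruned agents:", paste(object@removed, collapse = ", "), "\n")
})

#' ScanResult: ranked mutants from a mutation scan
#'
#' @slot results data.frame: \code{rank}, \code{mutations} (token string),
#'   \code{ddg} and optionally \code{confidence}.
#' @slot algorithm "optimal", "greedy" or "ea".
#' @slot evaluations number of predictor calls performed.
#' @export
setClass("ScanResult",
         representation(results = "data.frame", algorithm = "character",
                        evaluations = "numeric"))

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s): %d ranked mutant(s), %d predictor evaluations\n",
              object@algorithm, nrow(object@results), object@evaluations))
  print(head(object@results, 5L))
})

#' PenaltyTables: geometric penalty histograms for disulfide screening
#'
#' Relative-frequency histograms of CB-CB distances and of (CA-CA minus
#' CB-CB) distance differences observed for disulfide-bonded cysteines.
#' Penalties are 1 - f with f the bin frequency (out-of-range: penalty 1).
#'
#' @slot betaBreaks,betaFreq CB-CB histogram (Angstrom bins; sums to 1).
#' @slot diffBreaks,diffFreq distance-difference histogram.
#' @slot nPairs number of bonded pairs the tables were compiled from.
#' @slot meta provenance metadata.
#' @export
setClass("PenaltyTables",
         representation(betaBreaks = "numeric", betaFreq = "numeric",
                        diffBreaks = "numeric", diffFreq = "numeric",
                        nPairs = "integer", meta = "list"))

setValidity("PenaltyTables", function(object) {
  if (abs(sum(object@betaFreq) - 1) > 1e-8) return("betaFreq must sum to 1")
  if (abs(sum(object@diffFreq) - 1) > 1e-8) return("diffFreq must sum to 1")
  if (length(object@betaFreq) != length(object@betaBreaks) - 1L)
    return("betaFreq length must match bins")
  if (length(object@diffFreq) != length(object@diffBreaks) - 1L)
    return("diffFreq length must match bins")
  TRUE
})

setMethod("show", "PenaltyTables", function(object) {
  cat(sprintf("PenaltyTables from %d bonded pair(s); CB-CB bins [%g, %g] A, diff bins [%g, %g] A\n",
              object@nPairs, min(object@betaBreaks), max(object@betaBreaks),
              min(object@diffBreaks), max(object@diffBreaks)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
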