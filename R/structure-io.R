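## Reading PDB files into the reduced residue model, applying in-silico
## mutations, biological-assembly expansion and a minimal PDB writer.

.COORD_COLS <- paste0(rep(c("n_", "ca_", "c_", "cb_", "sg_"), each = 3),
                      c("x", "y", "z"))

#' Read a PDB file into one or more ProteinStructure objects
#'
#' Coordinates are reduced to the residue-level representative atoms (N, CA,
#' C, CB, and SG for cysteines).  Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first in file).  Residues without a CA
#' are dropped with a warning; non-standard residues are mapped to their
#' standard parent where a common alias exists (e.g. MSE to MET), otherwise
#' dropped.  Missing C-beta atoms (glycine in particular) are reconstructed
#' as ideal virtual C-betas from the backbone.
#'
#' @param path PDB file.
#' @param chain optional character vector restricting to the given chains.
#' @param model model number, or \code{"all"} to return every model of an
#'   NMR-style multi-model entry.
#' @param assembly if TRUE, apply the REMARK 350 biological-assembly
#'   transforms; generated chain copies get suffixed identifiers
#'   (\code{A.2}, ...).
#' @return A \code{ProteinStructure}, or a list of them when
#'   \code{model = "all"} returns several models.
#' @export
readPDB <- function(path, chain = NULL, model = 1L, assembly = FALSE) {
  if (!file.exists(path)) .stop2("cannot read PDB file '%s'", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) .stop2("unreadable PDB file '%s': %s",
                                             path, conditionMessage(e)))
  nModels <- nrow(pdb$xyz)
  if (is.null(nModels)) nModels <- 1L
  wanted <- if (identical(model, "all")) seq_len(nModels) else {
    m <- as.integer(model)
    if (is.na(m) || m < 1L || m > nModels)
      .stop2("model %s not present (file has %d model(s))", model, nModels)
    m
  }
  biomt <- if (assembly) .parseBiomt(path) else NULL
  out <- lapply(wanted, function(m) {
    st <- .structureFromAtoms(pdb$atom, pdb$xyz[m, ], basename(path), m, chain)
    if (!is.null(biomt)) st <- .applyBiomt(st, biomt)
    st
  })
  if (identical(model, "all") && length(out) > 1L) out else out[[1L]]
}

.structureFromAtoms <- function(atom, xyz, sourceId, model, chain = NULL) {
  at <- atom
  at$x <- xyz[seq(1L, length(xyz), 3L)]
  at$y <- xyz[seq(2L, length(xyz), 3L)]
  at$z <- xyz[seq(3L, length(xyz), 3L)]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$chain[is.na(at$chain)] <- "_"
  ## standard residues as ATOM; aliased non-standard residues may be HETATM
  std <- at$resid %in% names(.AA3to1)
  ali <- at$resid %in% names(.AA_ALIASES)
  dropped <- unique(at$resid[at$type == "ATOM" & !std & !ali])
  if (length(dropped))
    warning(sprintf("dropping non-standard residue type(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  at <- at[std | ali, , drop = FALSE]
  if (nrow(at) == 0L) .stop2("no parseable residues in '%s'", sourceId)
  aliasMask <- at$resid %in% names(.AA_ALIASES)
  at$resid[aliasMask] <- .AA_ALIASES[at$resid[aliasMask]]
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (nrow(at) == 0L) .stop2("no residues left after chain filter")
  }
  ## alternate locations: highest occupancy, ties broken by file order
  atomKey <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(match(atomKey, unique(atomKey)), -at$o,
               seq_len(nrow(at)), method = "radix")
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
           drop = FALSE]
  resKey <- paste(at$chain, at$resno, at$insert)
  at <- at[order(match(resKey, unique(resKey))), , drop = FALSE]
  resKey <- paste(at$chain, at$resno, at$insert)
  idx <- split(seq_len(nrow(at)), factor(resKey, levels = unique(resKey)))
  rows <- lapply(idx, function(ii) {
    sub <- at[ii, , drop = FALSE]
    getAt <- function(name) {
      k <- which(sub$elety == name)
      if (length(k)) as.numeric(sub[k[1L], c("x", "y", "z")]) else rep(NA_real_, 3L)
    }
    ca <- getAt("CA")
    if (any(is.na(ca))) return(NULL)
    n <- getAt("N"); cc <- getAt("C"); cb <- getAt("CB"); sg <- getAt("SG")
    cbVirtual <- FALSE
    if (any(is.na(cb))) {
      if (any(is.na(n)) || any(is.na(cc))) return(NULL)
      cb <- tryCatch(virtualCbeta(n, ca, cc), error = function(e) NULL)
      if (is.null(cb)) return(NULL)
      cbVirtual <- TRUE
    }
    data.frame(chain = sub$chain[1L], resno = as.integer(sub$resno[1L]),
               icode = sub$insert[1L], aa = .AA3to1[[sub$resid[1L]]],
               n_x = n[1L], n_y = n[2L], n_z = n[3L],
               ca_x = ca[1L], ca_y = ca[2L], ca_z = ca[3L],
               c_x = cc[1L], c_y = cc[2L], c_z = cc[3L],
               cb_x = cb[1L], cb_y = cb[2L], cb_z = cb[3L],
               sg_x = sg[1L], sg_y = sg[2L], sg_z = sg[3L],
               cb_virtual = cbVirtual, stringsAsFactors = FALSE)
  })
  nDropped <- sum(vapply(rows, is.null, logical(1L)))
  if (nDropped > 0L)
    warning(sprintf("%s: dropped %d residue(s) without usable CA/backbone",
                    sourceId, nDropped), call. = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) .stop2("no parseable residues in '%s'", sourceId)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  new("ProteinStructure", residues = res, sourceId = sourceId,
      model = as.integer(model))
}

## REMARK 350 BIOMT parser: returns list of list(chains=, transforms=list of
## list(rot, trans)).
.parseBiomt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  r350 <- lines[startsWith(lines, "REMARK 350")]
  if (!length(r350)) return(NULL)
  out <- list(); chains <- character(); mat <- list()
  flush <- function() {
    if (length(chains) && length(mat))
      out[[length(out) + 1L]] <<- list(chains = chains, transforms = mat)
  }
  for (ln in r350) {
    if (grepl("APPLY THE FOLLOWING TO CHAINS:", ln, fixed = TRUE)) {
      flush(); mat <- list()
      chains <- trimws(strsplit(sub(".*CHAINS:", "", ln), ",")[[1L]])
      chains <- chains[nzchar(chains)]
    } else if (grepl("^REMARK 350   BIOMT([123])", ln)) {
      rowi <- as.integer(substr(ln, 19L, 19L))
      nums <- as.numeric(strsplit(trimws(substr(ln, 20L, nchar(ln))), "\\s+")[[1L]])
      opi <- as.integer(nums[1L])
      if (length(mat) < opi) mat[[opi]] <- list(rot = matrix(0, 3L, 3L),
                                                trans = numeric(3L))
      mat[[opi]]$rot[rowi, ] <- nums[2:4]
      mat[[opi]]$trans[rowi] <- nums[5L]
    }
  }
  flush()
  if (!length(out)) NULL else out
}

.applyBiomt <- function(st, biomt) {
  res <- st@residues
  pieces <- list()
  for (grp in biomt) {
    sub <- res[res$chain %in% grp$chains, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (k in seq_along(grp$transforms)) {
      tr <- grp$transforms[[k]]
      identityOp <- max(abs(tr$rot - diag(3))) < 1e-6 && max(abs(tr$trans)) < 1e-6
      cp <- sub
      for (atom in c("n_", "ca_", "c_", "cb_", "sg_")) {
        cols <- paste0(atom, c("x", "y", "z"))
        xyz <- as.matrix(cp[, cols])
        ok <- stats::complete.cases(xyz)
        if (any(ok)) cp[ok, cols] <- .transformCoords(xyz[ok, , drop = FALSE],
                                                      tr$rot, tr$trans)
      }
      if (!identityOp) cp$chain <- paste0(cp$chain, ".", k)
      pieces[[length(pieces) + 1L]] <- cp
    }
  }
  if (!length(pieces)) return(st)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  new("ProteinStructure", residues = out, sourceId = st@sourceId,
      model = st@model)
}

#' Write a ProteinStructure (or model list) as a PDB file
#'
#' Writes the reduced representation back out (N, CA, C, real CB, SG).
#' Virtual C-betas are not written; they are reconstructed deterministically
#' on re-reading, so parse/write/parse round-trips are stable at PDB
#' coordinate precision.
#'
#' @param x a \code{ProteinStructure} or a list of them (written as MODEL
#'   blocks).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(x, path) {
  if (is(x, "ProteinStructure")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x) > 1L
  for (m in seq_along(x)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    res <- x[[m]]@residues
    serial <- 0L
    for (i in seq_len(nrow(res))) {
      emit <- function(name, prefix) {
        xyz <- as.numeric(res[i, paste0(prefix, c("x", "y", "z"))])
        if (any(is.na(xyz))) return(invisible())
        serial <<- serial + 1L
        writeLines(sprintf("ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
                           serial, name, .AA3[[res$aa[i]]],
                           substr(res$chain[i], 1L, 1L), res$resno[i],
                           ifelse(nzchar(res$icode[i]), res$icode[i], " "),
                           xyz[1L], xyz[2L], xyz[3L]), con)
      }
      emit("N", "n_"); emit("CA", "ca_"); emit("C", "c_")
      if (!res$cb_virtual[i]) emit("CB", "cb_")
      emit("SG", "sg_")
    }
    if (multi) writeLines("ENDMDL", con) else writeLines("END", con)
  }
  if (multi) writeLines("END", con)
  invisible(path)
}

#' Parse mutation tokens into a MutationSet
#'
#' Token grammar: \code{CHAIN:WT POS [ICODE] MUT} in compact form, e.g.
#' \code{"A:N25K"}; multiple simultaneous mutations are joined with
#' \code{";"} (\code{"A:N25K;A:L30I"} is one 2-point mutant).
#'
#' @param tokens a single token string (possibly \code{";"}-joined) or a
#'   character vector of tokens.
#' @return a \code{MutationSet}.
#' @export
parseMutations <- function(tokens) {
  toks <- unlist(strsplit(tokens, ";", fixed = TRUE))
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(emptyMutationSet())
  m <- regmatches(toks, regexec("^([A-Za-z0-9]+):([A-Z])([0-9]+)([A-Z]?)([A-Z])$", toks))
  bad <- vapply(m, length, integer(1L)) == 0L
  if (any(bad)) .stop2("malformed mutation token(s): %s",
                       paste(toks[bad], collapse = ", "))
  df <- data.frame(chain = vapply(m, `[`, "", 2L),
                   resno = as.integer(vapply(m, `[`, "", 4L)),
                   icode = vapply(m, `[`, "", 5L),
                   wt = vapply(m, `[`, "", 3L),
                   mut = vapply(m, `[`, "", 6L),
                   stringsAsFactors = FALSE)
  new("MutationSet", mutations = df)
}

#' @rdname parseMutations
#' @param mutations a data.frame with columns chain, resno, icode, wt, mut.
#' @export
mutationSet <- function(mutations) {
  if (is.character(mutations)) return(parseMutations(mutations))
  mutations$icode <- mutations$icode %||% ""
  new("MutationSet", mutations = as.data.frame(mutations))
}

#' @rdname parseMutations
#' @export
emptyMutationSet <- function() {
  new("MutationSet",
      mutations = data.frame(chain = character(), resno = integer(),
                             icode = character(), wt = character(),
                             mut = character(), stringsAsFactors = FALSE))
}

#' @rdname parseMutations
#' @param x a \code{MutationSet}.
#' @return \code{formatMutations}: the canonical token string.
#' @export
formatMutations <- function(x) {
  m <- x@mutations
  if (nrow(m) == 0L) return("")
  ord <- order(m$chain, m$resno, m$icode, m$mut)
  paste(sprintf("%s:%s%d%s%s", m$chain[ord], m$wt[ord], m$resno[ord],
                m$icode[ord], m$mut[ord]), collapse = ";")
}

## 0-based -> 1-based row indices of the mutated sites in a structure.
.mutationIndices <- function(structure, ms) {
  r <- structure@residues
  m <- ms@mutations
  key <- paste(r$chain, r$resno, r$icode)
  idx <- match(paste(m$chain, m$resno, m$icode), key)
  if (anyNA(idx))
    .stop2("mutation site(s) not in structure: %s",
           paste(sprintf("%s:%d%s", m$chain, m$resno, m$icode)[is.na(idx)],
                 collapse = ", "))
  idx
}

#' Apply point mutations by residue-type relabeling
#'
#' The mutant keeps the main-chain and C-beta coordinates of the wild type;
#' only the residue type at the mutated sites changes (no side-chain
#' modelling, no minimization).
#'
#' @param structure a \code{ProteinStructure}.
#' @param ms a \code{MutationSet}; each wild-type code must match the
#'   structure.
#' @return the mutated \code{ProteinStructure}.
#' @export
applyMutations <- function(structure, ms) {
  m <- ms@mutations
  if (nrow(m) == 0L) return(structure)
  idx <- .mutationIndices(structure, ms)
  found <- structure@residues$aa[idx]
  bad <- found != m$wt
  if (any(bad))
    .stop2("wild-type mismatch at %s",
           paste(sprintf("%s:%d%s (expected %s, found %s)",
                         m$chain[bad], m$resno[bad], m$icode[bad],
                         m$wt[bad], found[bad]), collapse = "; "))
  out <- structure
  out@residues$aa[idx] <- m$mut
  out
}

#' @rdname applyMutations
#' @details \code{reverseMutations} swaps wild-type and mutant codes, giving
#'   the set that undoes a mutation.
#' @export
reverseMutations <- function(ms) {
  m <- ms@mutations
  new("MutationSet",
      mutations = data.frame(chain = m$chain, resno = m$resno,
                             icode = m$icode, wt = m$mut, mut = m$wt,
                             stringsAsFactors = FALSE))
}
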