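## Versioned flat-file persistence for compiled scoring functions.
## Numbers are written as %.17g, which round-trips IEEE doubles exactly.

#' Save / load compiled scoring functions
#'
#' Scoring functions are persisted as versioned TSV files: one header line
#' carrying the binning/radius/separation metadata, then one row per
#' (a, b, bin) or (a, count) cell with raw count, delta and energy, followed
#' by the reference distribution and the expected-energy rows.  The
#' round-trip is bit-exact.
#'
#' @param x a \code{PairSSF} or \code{ContactSSF}.
#' @param path file path.
#' @return \code{readSSFModel} returns the reconstructed object;
#'   \code{saveSSFModel} returns \code{path} invisibly.
#' @export
saveSSFModel <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is(x, "PairSSF")) {
    writeLines(sprintf("#prostab-ssf\tv1\tkind=pair\tatom=%s\tbreaks=%s\tminSeqSep=%d\tpseudocount=%s",
                       x@atomKind, paste(.fmtNum(x@breaks), collapse = ","),
                       x@minSeqSep, .fmtNum(x@pseudocount)), con)
    nb <- length(x@breaks) - 1L
    for (ai in 1:20) for (bi in ai:20) for (k in seq_len(nb))
      writeLines(paste("P", .AA1[ai], .AA1[bi], k,
                       .fmtNum(x@counts[ai, bi, k]),
                       .fmtNum(x@delta[ai, bi, k]),
                       .fmtNum(x@energy[ai, bi, k]), sep = "\t"), con)
    for (k in seq_len(nb))
      writeLines(paste("R", k, .fmtNum(x@rho[k]), sep = "\t"), con)
    for (ai in 1:20) for (bi in ai:20)
      writeLines(paste("E", .AA1[ai], .AA1[bi],
                       .fmtNum(x@expected[ai, bi]), sep = "\t"), con)
  } else if (is(x, "ContactSSF")) {
    writeLines(sprintf("#prostab-ssf\tv1\tkind=contact\tradius=%s\tmaxCount=%d\tpseudocount=%s",
                       .fmtNum(x@radius), x@maxCount, .fmtNum(x@pseudocount)), con)
    for (ai in 1:20) for (k in 0:x@maxCount)
      writeLines(paste("P", .AA1[ai], k,
                       .fmtNum(x@counts[ai, k + 1L]),
                       .fmtNum(x@delta[ai, k + 1L]),
                       .fmtNum(x@energy[ai, k + 1L]), sep = "\t"), con)
    for (k in 0:x@maxCount)
      writeLines(paste("R", k, .fmtNum(x@rho[k + 1L]), sep = "\t"), con)
    for (ai in 1:20)
      writeLines(paste("E", .AA1[ai], .fmtNum(x@expected[ai]), sep = "\t"), con)
  } else .stop2("not a scoring-function object")
  invisible(path)
}

#' @rdname saveSSFModel
#' @export
readSSFModel <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1L], "\t")[[1L]]
  if (hd[1L] != "#prostab-ssf" || hd[2L] != "v1")
    .stop2("'%s' is not a v1 scoring-function file", path)
  meta <- strsplit(hd[-(1:2)], "=", fixed = TRUE)
  meta <- setNames(vapply(meta, `[`, "", 2L), vapply(meta, `[`, "", 1L))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  tag <- vapply(body, `[`, "", 1L)
  if (meta[["kind"]] == "pair") {
    breaks <- as.numeric(strsplit(meta[["breaks"]], ",")[[1L]])
    nb <- length(breaks) - 1L
    counts <- delta <- energy <- array(NA_real_, c(20L, 20L, nb),
                                       dimnames = list(.AA1, .AA1, NULL))
    expected <- matrix(NA_real_, 20L, 20L, dimnames = list(.AA1, .AA1))
    rho <- numeric(nb)
    for (f in body[tag == "P"]) {
      ai <- match(f[2L], .AA1); bi <- match(f[3L], .AA1); k <- as.integer(f[4L])
      counts[ai, bi, k] <- counts[bi, ai, k] <- as.numeric(f[5L])
      delta[ai, bi, k] <- delta[bi, ai, k] <- as.numeric(f[6L])
      energy[ai, bi, k] <- energy[bi, ai, k] <- as.numeric(f[7L])
    }
    for (f in body[tag == "R"]) rho[as.integer(f[2L])] <- as.numeric(f[3L])
    for (f in body[tag == "E"]) {
      ai <- match(f[2L], .AA1); bi <- match(f[3L], .AA1)
      expected[ai, bi] <- expected[bi, ai] <- as.numeric(f[4L])
    }
    new("PairSSF", atomKind = meta[["atom"]], breaks = breaks, counts = counts,
        delta = delta, rho = rho, energy = energy, expected = expected,
        minSeqSep = as.integer(meta[["minSeqSep"]]),
        pseudocount = as.numeric(meta[["pseudocount"]]))
  } else {
    maxCount <- as.integer(meta[["maxCount"]])
    counts <- delta <- energy <- matrix(NA_real_, 20L, maxCount + 1L,
                                        dimnames = list(.AA1, 0:maxCount))
    expected <- setNames(numeric(20L), .AA1)
    rho <- numeric(maxCount + 1L)
    for (f in body[tag == "P"]) {
      ai <- match(f[2L], .AA1); k <- as.integer(f[3L]) + 1L
      counts[ai, k] <- as.numeric(f[4L])
      delta[ai, k] <- as.numeric(f[5L])
      energy[ai, k] <- as.numeric(f[6L])
    }
    for (f in body[tag == "R"]) rho[as.integer(f[2L]) + 1L] <- as.numeric(f[3L])
    for (f in body[tag == "E"]) expected[match(f[2L], .AA1)] <- as.numeric(f[3L])
    new("ContactSSF", radius = as.numeric(meta[["radius"]]),
        maxCount = maxCount, counts = counts, delta = delta, rho = rho,
        energy = energy, expected = expected,
        pseudocount = as.numeric(meta[["pseudocount"]]))
  }
}

#' @rdname saveSSFModel
#' @param set an \code{SSFModelSet}; \code{dir} a directory (created if
#'   needed) holding \code{ca.ssf}, \code{cb.ssf} and \code{contact.ssf}.
#' @param dir directory path.
#' @export
saveSSFModelSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveSSFModel(set@ca, file.path(dir, "ca.ssf"))
  saveSSFModel(set@cb, file.path(dir, "cb.ssf"))
  saveSSFModel(set@contact, file.path(dir, "contact.ssf"))
  invisible(dir)
}

#' @rdname saveSSFModel
#' @export
readSSFModelSet <- function(dir) {
  ssfModelSet(readSSFModel(file.path(dir, "ca.ssf")),
              readSSFModel(file.path(dir, "cb.ssf")),
              readSSFModel(file.path(dir, "contact.ssf")))
}
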