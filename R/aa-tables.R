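## Frozen amino-acid property tables shipped with the package.

.tableCache <- new.env(parent = emptyenv())

.readPropertyFile <- function(name) {
  path <- system.file("extdata", name, package = "prostab")
  if (!nzchar(path)) {
    ## during in-source testing (pkgload) system.file already resolves; this
    ## branch guards a broken installation only
    .stop2("property table '%s' not found in installed package", name)
  }
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Amino-acid substitution property table
#'
#' Returns the frozen per-residue table of average mass (Da), Hopp-Woods
#' hydrophilicity and isoelectric point used to derive the substitution
#' descriptors (delta mass, delta hydrophilicity, delta pI) that enter the
#' prediction agents.
#'
#' @return A data.frame with columns \code{aa}, \code{mass},
#'   \code{hydrophilicity}, \code{pi}, one row per canonical amino acid.
#' @export
#' @examples
#' head(aaProperties())
aaProperties <- function() {
  if (is.null(.tableCache$props)) {
    tab <- .readPropertyFile("aa_properties.tsv")
    stopifnot(setequal(tab$aa, .AA1))
    .tableCache$props <- tab[match(.AA1, tab$aa), ]
  }
  .tableCache$props
}

#' Residue-sphere ASA reference table
#'
#' The coarse residue-level solvent-accessibility model represents each side
#' chain as a single sphere centred on the (possibly virtual) C-beta atom.
#' This table freezes the per-residue sphere radius and the surface area of
#' the isolated probe-inflated sphere used to normalize accessible surface
#' into a relative ASA.
#'
#' @return A data.frame with columns \code{aa}, \code{radius} (Angstrom) and
#'   \code{max_asa} (Angstrom squared).
#' @export
asaReference <- function() {
  if (is.null(.tableCache$asa)) {
    tab <- .readPropertyFile("asa_reference.tsv")
    stopifnot(setequal(tab$aa, .AA1))
    .tableCache$asa <- tab[match(.AA1, tab$aa), ]
  }
  .tableCache$asa
}
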