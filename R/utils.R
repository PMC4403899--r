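## Internal helpers shared across the package.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats lm predict coef sd rnorm runif setNames aggregate median ave
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table head combn
NULL

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.AA3to1 <- setNames(names(.AA3), unname(.AA3))

## Non-standard residues with a standard parent (subset of common aliases).
.AA_ALIASES <- c(MSE = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS",
                 HYP = "PRO", MLY = "LYS", SEP = "SER", TPO = "THR",
                 PTR = "TYR", PYL = "LYS", KCX = "LYS", LLP = "LYS")

.stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) .stop2("degenerate geometry: zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Euclidean distance matrix between rows of two coordinate matrices.
.cdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Deterministic seed derivation: keeps derived seeds inside 32-bit range.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 7919) %% 2147483629)
}

.fmtNum <- function(x) sprintf("%.17g", x)
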