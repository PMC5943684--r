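# Internal helpers: residue keys, amino-acid tables, small vector geometry.

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

STANDARD_AA <- names(AA_3TO1)

# Canonical residue key: chain, author residue number, insertion code.
res_key <- function(chain, resseq, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  sprintf("%s:%d%s", chain, as.integer(resseq), icode)
}

aa_one <- function(resname) {
  out <- unname(AA_3TO1[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle a-b-c in degrees.
vangle <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Natural-extension-reference-frame placement: position atom d given the
# three preceding atoms a-b-c, the bond length |c-d|, the angle b-c-d and
# the torsion a-b-c-d (degrees).
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Integer percentages by largest-remainder rounding; sums to exactly 100.
largest_remainder_pct <- function(x) {
  if (sum(x) == 0) return(stats::setNames(rep(0L, length(x)), names(x)))
  p <- 100 * x / sum(x)
  fl <- floor(p)
  rem <- 100L - as.integer(sum(fl))
  ord <- order(p - fl, decreasing = TRUE)
  out <- as.integer(fl)
  if (rem > 0) out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  stats::setNames(out, names(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
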