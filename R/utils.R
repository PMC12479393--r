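# Shared helpers: amino-acid tables, RNG scoping, small geometry utilities.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom withr with_seed
NULL

# Canonical one-letter alphabet accepted on input (X = unknown).
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

# Three-letter -> one-letter map. Common modified residues fold back onto
# their parent so template sequences can be aligned against FASTA targets;
# anything unknown that still looks like a polymer residue becomes X.
AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C", KCX = "K", MLY = "K",
  CME = "C", OCS = "C", FME = "M", CSD = "C", LLP = "K"
)

AA1_TO_3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

assert_aa_string <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || nchar(s) == 0L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  bad <- setdiff(unique(seq_chars(s)), AA_LETTERS)
  if (length(bad))
    stop(what, " contains non-amino-acid characters: ",
         paste(bad, collapse = ""), call. = FALSE)
  invisible(s)
}

# Uniform random unit vector (direction uniform on the sphere).
runif_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Rotation matrix for a rotation of `angle_deg` degrees about unit `axis`
# (Rodrigues' formula).
rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# All pairwise Euclidean distances between rows of two coordinate matrices.
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
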