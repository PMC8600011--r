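## Internal helpers shared across modules.

# 3-letter <-> 1-letter amino-acid codes (20 standard residues)
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W",
          "Y", "V")

aa3to1 <- function(x) {
  out <- .AA1[match(toupper(x), .AA3)]
  out
}

aa1to3 <- function(x) {
  out <- .AA3[match(toupper(x), .AA1)]
  out
}

# Nucleotide residue vocabularies
.NUC_DNA    <- c("DA", "DC", "DG", "DT", "DU", "DI")
.NUC_RNA    <- c("A", "C", "G", "U", "I")
.NUC_ALL    <- c(.NUC_DNA, .NUC_RNA)
.NUC_PURINE     <- c("DA", "DG", "DI", "A", "G", "I")
.NUC_PYRIMIDINE <- c("DC", "DT", "DU", "C", "T", "U")

.WATER <- c("HOH", "WAT", "DOD", "H2O")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D bonded to C with |CD| = bond, angle(B,C,D) = ang (deg) and
# dihedral(A,B,C,D) = dih (deg).  Natural extension reference frame.
.place_atom <- function(A, B, C, bond, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- .unit(C - B)
  ab <- .unit(B - A)
  n  <- .unit(.cross(ab, bc))
  m  <- .cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix about z axis, angle in degrees
.rotz <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# FNV-1a 32-bit hash of a character vector; stable across sessions, used to
# fingerprint the feature schema stored inside model bundles.
.schema_hash <- function(x) {
  s <- paste(x, collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- .bitxor32(h, b)
    # multiply modulo 2^32, split to stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor for values in [0, 2^32): bitwXor works on 32-bit signed ints, so split
.bitxor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

# Euclidean distance matrix between two coordinate matrices (n x 3, m x 3)
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# element inference from an atom name (heavy atoms of standard residues plus
# common hetero species)
.infer_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "ZN", "MG", "MN", "FE", "CU", "NI", "CO", "SE")
  ifelse(two %in% known2, two, substr(nm, 1, 1))
}
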