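## Idealized internal-coordinate templates for amino-acid side chains and
## simplified nucleotide geometry.  These power the deterministic synthetic
## fixtures and the naive mutant builder.  Geometry is idealized (standard
## bond lengths and angles, canonical rotamers); no energetic refinement.

# Side-chain Z-matrix entries: atom, three reference atoms (A, B, C), bond
# length C-D, angle B-C-D (deg), dihedral A-B-C-D (deg).  CB is placed from
# (C, N, CA); remaining atoms chain off previously placed atoms.
.CB <- list(c("CB", "C", "N", "CA", "1.53", "110.4", "-122.0"))
.sc <- function(...) {
  lapply(list(...), function(x) x)
}
.AA_TEMPLATES <- list(
  GLY = list(),
  ALA = .CB,
  SER = c(.CB, .sc(c("OG", "N", "CA", "CB", "1.42", "110.8", "180"))),
  CYS = c(.CB, .sc(c("SG", "N", "CA", "CB", "1.81", "113.8", "180"))),
  VAL = c(.CB, .sc(c("CG1", "N", "CA", "CB", "1.52", "110.5", "180"),
                   c("CG2", "N", "CA", "CB", "1.52", "110.5", "-60"))),
  THR = c(.CB, .sc(c("OG1", "N", "CA", "CB", "1.43", "109.6", "60"),
                   c("CG2", "N", "CA", "CB", "1.52", "110.5", "180"))),
  ILE = c(.CB, .sc(c("CG1", "N", "CA", "CB", "1.53", "110.4", "180"),
                   c("CG2", "N", "CA", "CB", "1.53", "110.5", "-60"),
                   c("CD1", "CA", "CB", "CG1", "1.52", "113.9", "180"))),
  LEU = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.53", "116.3", "180"),
                   c("CD1", "CA", "CB", "CG", "1.52", "110.5", "60"),
                   c("CD2", "CA", "CB", "CG", "1.52", "110.5", "180"))),
  MET = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.52", "114.0", "180"),
                   c("SD", "CA", "CB", "CG", "1.80", "112.7", "180"),
                   c("CE", "CB", "CG", "SD", "1.79", "100.9", "180"))),
  PRO = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.49", "104.0", "30"),
                   c("CD", "CA", "CB", "CG", "1.50", "105.0", "-35"))),
  PHE = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.50", "113.8", "180"),
                   c("CD1", "CA", "CB", "CG", "1.39", "120.8", "90"),
                   c("CD2", "CA", "CB", "CG", "1.39", "120.8", "-90"),
                   c("CE1", "CB", "CG", "CD1", "1.39", "120.8", "180"),
                   c("CE2", "CB", "CG", "CD2", "1.39", "120.8", "180"),
                   c("CZ", "CG", "CD1", "CE1", "1.39", "120.0", "0"))),
  TYR = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.50", "113.8", "180"),
                   c("CD1", "CA", "CB", "CG", "1.39", "120.8", "90"),
                   c("CD2", "CA", "CB", "CG", "1.39", "120.8", "-90"),
                   c("CE1", "CB", "CG", "CD1", "1.39", "120.8", "180"),
                   c("CE2", "CB", "CG", "CD2", "1.39", "120.8", "180"),
                   c("CZ", "CG", "CD1", "CE1", "1.39", "120.0", "0"),
                   c("OH", "CD1", "CE1", "CZ", "1.38", "119.9", "180"))),
  TRP = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.50", "113.6", "180"),
                   c("CD1", "CA", "CB", "CG", "1.37", "126.9", "90"),
                   c("CD2", "CA", "CB", "CG", "1.43", "126.7", "-90"),
                   c("NE1", "CB", "CG", "CD1", "1.38", "110.2", "180"),
                   c("CE2", "CG", "CD1", "NE1", "1.37", "109.0", "0"),
                   c("CE3", "CB", "CG", "CD2", "1.40", "133.9", "180"),
                   c("CZ2", "CD1", "NE1", "CE2", "1.40", "130.1", "180"),
                   c("CZ3", "CG", "CD2", "CE3", "1.39", "118.7", "0"),
                   c("CH2", "CD2", "CE3", "CZ3", "1.37", "121.2", "0"))),
  ASP = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.52", "113.0", "180"),
                   c("OD1", "CA", "CB", "CG", "1.25", "118.5", "0"),
                   c("OD2", "CA", "CB", "CG", "1.25", "118.5", "180"))),
  GLU = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.52", "114.0", "180"),
                   c("CD", "CA", "CB", "CG", "1.52", "112.6", "180"),
                   c("OE1", "CB", "CG", "CD", "1.25", "118.5", "0"),
                   c("OE2", "CB", "CG", "CD", "1.25", "118.5", "180"))),
  ASN = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.52", "113.0", "180"),
                   c("OD1", "CA", "CB", "CG", "1.23", "120.8", "0"),
                   c("ND2", "CA", "CB", "CG", "1.33", "116.4", "180"))),
  GLN = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.52", "114.0", "180"),
                   c("CD", "CA", "CB", "CG", "1.52", "112.6", "180"),
                   c("OE1", "CB", "CG", "CD", "1.23", "120.8", "0"),
                   c("NE2", "CB", "CG", "CD", "1.33", "116.4", "180"))),
  LYS = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.52", "114.0", "180"),
                   c("CD", "CA", "CB", "CG", "1.52", "111.3", "180"),
                   c("CE", "CB", "CG", "CD", "1.52", "111.3", "180"),
                   c("NZ", "CG", "CD", "CE", "1.49", "111.9", "180"))),
  ARG = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.52", "114.0", "180"),
                   c("CD", "CA", "CB", "CG", "1.52", "111.3", "180"),
                   c("NE", "CB", "CG", "CD", "1.46", "111.5", "180"),
                   c("CZ", "CG", "CD", "NE", "1.33", "124.8", "180"),
                   c("NH1", "CD", "NE", "CZ", "1.33", "120.0", "0"),
                   c("NH2", "CD", "NE", "CZ", "1.33", "120.0", "180"))),
  HIS = c(.CB, .sc(c("CG", "N", "CA", "CB", "1.50", "113.8", "180"),
                   c("ND1", "CA", "CB", "CG", "1.38", "122.7", "90"),
                   c("CD2", "CA", "CB", "CG", "1.36", "131.0", "-90"),
                   c("CE1", "CB", "CG", "ND1", "1.32", "109.2", "180"),
                   c("NE2", "CG", "ND1", "CE1", "1.32", "108.2", "0")))
)

# build side-chain coordinates for a residue given a named list of placed
# atom coordinates (must contain N, CA, C); returns named list of new atoms
.build_side_chain <- function(res3, placed) {
  tmpl <- .AA_TEMPLATES[[res3]]
  if (is.null(tmpl)) stop("no template for residue ", res3)
  for (e in tmpl) {
    nm <- e[1]
    if (!is.null(placed[[nm]])) next  # keep an existing atom (e.g. wild CB)
    A <- placed[[e[2]]]; B <- placed[[e[3]]]; C <- placed[[e[4]]]
    if (is.null(A) || is.null(B) || is.null(C)) {
      stop("missing reference atom for ", res3, " ", nm)
    }
    placed[[nm]] <- .place_atom(A, B, C, as.numeric(e[5]), as.numeric(e[6]),
                                as.numeric(e[7]))
  }
  placed
}

.side_chain_atom_names <- function(res3) {
  vapply(.AA_TEMPLATES[[res3]], function(e) e[1], character(1))
}

## ---- nucleotide geometry ---------------------------------------------------

# planar idealized base coordinates (x, y); rings are regular polygons with
# 1.39 A sides.  WC-edge atom: purine N1, pyrimidine N3.
.base_coords <- function(resname) {
  r <- 1.39
  ang <- (0:5) * 60 * pi / 180
  hex <- cbind(r * cos(ang), r * sin(ang))
  rownames(hex) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  radial <- function(vertex, dist) {
    v <- hex[vertex, ]
    v + dist * v / sqrt(sum(v^2))
  }
  core <- sub("^D", "", resname)
  purine <- core %in% c("A", "G", "I")
  out <- hex
  if (purine) {
    # pentagon fused on the C4-C5 edge, outward from the hexagon centre
    P1 <- hex["C4", ]; P2 <- hex["C5", ]
    e <- .unit2(P2 - P1)
    nrm <- c(-e[2], e[1])
    M <- (P1 + P2) / 2
    if (sum(nrm * M) < 0) nrm <- -nrm  # outward
    s <- 1.39
    N9 <- P1 + s * (cos(108 * pi / 180) * e + sin(108 * pi / 180) * nrm)
    N7 <- P2 + s * (-cos(108 * pi / 180) * e + sin(108 * pi / 180) * nrm)
    mid <- (N9 + N7) / 2
    h <- sqrt(max(s^2 - sum((N7 - N9)^2) / 4, 0.1))
    C8 <- mid + h * nrm
    out <- rbind(out, N9 = N9, N7 = N7, C8 = C8)
    if (core == "A") out <- rbind(out, N6 = radial("C6", 1.34))
    if (core == "G") out <- rbind(out, O6 = radial("C6", 1.24),
                                  N2 = radial("C2", 1.34))
  } else {
    out <- rbind(out, O2 = radial("C2", 1.24))
    if (core == "C") out <- rbind(out, N4 = radial("C4", 1.34))
    if (core %in% c("T", "U")) out <- rbind(out, O4 = radial("C4", 1.24))
    if (core == "T") out <- rbind(out, C7 = radial("C5", 1.50))
  }
  out
}

.unit2 <- function(v) v / sqrt(sum(v^2))

# full nucleotide (base + sugar + phosphate) in the base-pair frame of
# strand 1: WC-edge atom at (-1.45, 0, 0), ring centre toward -x.
# Returns a named coordinate matrix (n x 3).
.nucleotide_coords <- function(resname, rna = FALSE) {
  base2d <- .base_coords(resname)
  purine <- sub("^D", "", resname) %in% c("A", "G", "I")
  wc <- if (purine) "N1" else "N3"
  # rotate the base so the WC atom sits at local angle 0, then put the ring
  # centre at (-2.84, 0): WC atom lands at (-1.45, 0)
  wcv <- base2d[wc, ]
  th <- -atan2(wcv[2], wcv[1])
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  # after the rotation the WC atom sits at (+1.39, 0) with the ring centre at
  # the origin, i.e. the centre lies toward -x from the WC atom; translate so
  # the WC atom lands at (-1.45, 0) and the centre at (-2.84, 0)
  b <- t(R %*% t(base2d))
  b <- cbind(b[, 1] - 2.84, b[, 2], 0)
  rownames(b) <- rownames(base2d)

  glyc <- if (purine) "N9" else "N1"
  G <- b[glyc, ]
  ctr <- c(-1.45 - 1.39, 0, 0)
  o <- .unit(G - ctr)           # outward, in plane
  z <- c(0, 0, 1)
  t_ <- .cross(z, o)
  frame <- function(co, ct, cz, bond, from) {
    from + bond * .unit(co * o + ct * t_ + cz * z)
  }
  sugar <- list()
  sugar[["C1'"]] <- G + 1.47 * o
  sugar[["O4'"]] <- frame(0.6, -0.7, 0.4, 1.42, sugar[["C1'"]])
  sugar[["C2'"]] <- frame(0.6, 0.8, 0.1, 1.53, sugar[["C1'"]])
  if (rna) sugar[["O2'"]] <- frame(0.2, 0.8, -0.6, 1.41, sugar[["C2'"]])
  sugar[["C3'"]] <- frame(0.9, -0.3, 0.3, 1.53, sugar[["C2'"]])
  sugar[["O3'"]] <- frame(0.4, 0.2, -0.9, 1.42, sugar[["C3'"]])
  sugar[["C4'"]] <- frame(0.3, -0.9, 0.3, 1.53, sugar[["C3'"]])
  sugar[["C5'"]] <- frame(0.5, -0.5, 0.7, 1.51, sugar[["C4'"]])
  sugar[["O5'"]] <- frame(0.2, -0.5, 0.8, 1.42, sugar[["C5'"]])
  sugar[["P"]]   <- frame(0.1, -0.4, 0.9, 1.59, sugar[["O5'"]])
  sugar[["OP1"]] <- frame(0.8, 0.5, 0.3, 1.48, sugar[["P"]])
  sugar[["OP2"]] <- frame(-0.7, -0.5, 0.5, 1.48, sugar[["P"]])
  s <- do.call(rbind, sugar)
  rbind(b, s)
}

.COMPLEMENT <- c(DA = "DT", DT = "DA", DC = "DG", DG = "DC",
                 A = "U", U = "A", C = "G", G = "C")
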