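## Parsing, writing and geometry of protein-nucleic acid complex structures.
## PDB reading/writing is delegated to bio3d; this module adds first-model
## selection, altloc resolution, hydrogen/water stripping, chain
## classification and nucleic-acid typing.

#' Parse a protein-nucleic acid complex from PDB text
#'
#' Reads ATOM (and optionally HETATM) records, keeps the first model only,
#' resolves alternate locations by occupancy (ties broken by the
#' alphabetically first altloc), strips hydrogens and waters, and classifies
#' every chain as protein, nucleic or other from its residue-name vocabulary.
#'
#' @param pdb_text Character scalar or vector of PDB-format lines.
#' @param keep_hetero Keep HETATM records (metal ions, ligands)? Default
#'   `FALSE`; waters are always dropped.
#' @param id Identifier stored on the returned object.
#' @return A `ComplexStructure`: list with `atoms` (data.frame with columns
#'   serial, name, element, residue_name, chain_id, residue_number,
#'   insertion_code, x, y, z, occupancy, altloc, het), `chains` (named
#'   character vector, values `"protein"`, `"nucleic"` or `"other"`), `id`.
#' @export
parse_structure <- function(pdb_text, keep_hetero = FALSE, id = "complex") {
  if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  }
  if (length(pdb_text) == 0L || !any(grepl("^ATOM", pdb_text))) {
    stop("parse error: input contains no ATOM records")
  }
  # first model only
  ends <- grep("^ENDMDL", pdb_text)
  if (length(ends) > 0L) pdb_text <- pdb_text[seq_len(ends[1] - 1L)]

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom

  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% .WATER), , drop = FALSE]
  if (nrow(at) == 0L) stop("parse error: no atoms retained")

  elem <- at$elesy
  miss <- is.na(elem) | trimws(elem) == ""
  elem[miss] <- .infer_element(at$elety[miss])
  elem <- toupper(trimws(elem))
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(elem %in% c("H", "D"))]

  icode <- at$insert
  icode[is.na(icode)] <- ""
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = elem,
    residue_name = toupper(trimws(at$resid)),
    chain_id = at$chain,
    residue_number = at$resno,
    insertion_code = icode,
    x = at$x, y = at$y, z = at$z,
    occupancy = occ,
    altloc = alt,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )

  # altloc resolution: within each (chain, resno, icode, atom name) group keep
  # the highest-occupancy conformer; ties -> alphabetically first altloc
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(match(paste(atoms$chain_id, atoms$residue_number,
                                     atoms$insertion_code, atoms$name,
                                     sep = "\r"),
                               unique(key))), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("parse error: non-finite coordinates")
  }

  chains <- .classify_chains(atoms)
  structure(list(atoms = atoms, chains = chains, id = id),
            class = "ComplexStructure")
}

.classify_chains <- function(atoms) {
  ids <- unique(atoms$chain_id)
  cls <- vapply(ids, function(ch) {
    res <- unique(paste(atoms$residue_number, atoms$insertion_code,
                        atoms$residue_name)[atoms$chain_id == ch])
    rn <- sub("^.* ", "", res)
    n_aa <- sum(rn %in% .AA3)
    n_nuc <- sum(rn %in% .NUC_ALL)
    if (n_aa > length(rn) / 2) "protein"
    else if (n_nuc > length(rn) / 2) "nucleic"
    else "other"
  }, character(1))
  names(cls) <- ids
  cls
}

#' @export
print.ComplexStructure <- function(x, ...) {
  cat(sprintf("ComplexStructure '%s': %d atoms, %d chains (%s)\n",
              x$id, nrow(x$atoms), length(x$chains),
              paste(sprintf("%s=%s", names(x$chains), x$chains),
                    collapse = ", ")))
  invisible(x)
}

#' Write a ComplexStructure to PDB format
#'
#' @param structure A `ComplexStructure`.
#' @param file Output path; if `NULL`, the PDB text is returned as a
#'   character vector of lines.
#' @return Invisibly the file path, or the PDB lines when `file` is `NULL`.
#' @export
write_structure <- function(structure, file = NULL) {
  a <- structure$atoms
  tf <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    pdb = NULL, file = tf,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$residue_number, resid = a$residue_name,
    eleno = a$serial, elety = a$name, chain = a$chain_id,
    insert = ifelse(a$insertion_code == "", NA, a$insertion_code),
    o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element
  )
  if (is.null(file)) {
    out <- readLines(tf)
    unlink(tf)
    return(out)
  }
  invisible(file)
}

# index vector of the atoms of one residue; error if absent
.residue_atoms <- function(structure, chain_id, residue_number,
                           insertion_code = "") {
  a <- structure$atoms
  idx <- which(a$chain_id == chain_id &
               a$residue_number == residue_number &
               a$insertion_code == insertion_code)
  if (length(idx) == 0L) {
    stop(sprintf("residue not found: chain %s residue %s%s",
                 chain_id, residue_number, insertion_code))
  }
  idx
}

.coords <- function(structure, idx = NULL) {
  a <- structure$atoms
  m <- as.matrix(a[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

.nucleic_atom_idx <- function(structure) {
  nuc <- names(structure$chains)[structure$chains == "nucleic"]
  which(structure$atoms$chain_id %in% nuc)
}

#' Determine the nucleic-acid type of a complex
#'
#' RNA is recognised by the presence of O2' atoms (or ribonucleotide residue
#' codes); a complex is double-stranded when at least three Watson-Crick-like
#' base pairs exist, a pair being a purine N1 within 3.5 Angstrom of a
#' pyrimidine N3 on a different residue.  Single-stranded nucleic acids that
#' form such pairs are therefore classified as double-stranded.
#'
#' @param structure A `ComplexStructure` with at least one nucleic chain.
#' @param override Optional user override, one of `"ssDNA"`, `"dsDNA"`,
#'   `"ssRNA"`, `"dsRNA"` (case-insensitive); skips detection.
#' @param min_pairs Minimum number of paired bases to call a duplex (3).
#' @param pair_cutoff Maximum purine-N1 to pyrimidine-N3 distance (3.5 A).
#' @return A `NucleicAcidType`: list with `kind`, `is_rna`, `is_double`.
#' @export
detect_na_type <- function(structure, override = NULL, min_pairs = 3,
                           pair_cutoff = 3.5) {
  if (!is.null(override)) {
    kind <- c(ssdna = "ssDNA", dsdna = "dsDNA",
              ssrna = "ssRNA", dsrna = "dsRNA")[tolower(override)]
    if (is.na(kind)) stop("unknown NA-type override: ", override)
    return(.na_type(unname(kind)))
  }
  nuc_idx <- .nucleic_atom_idx(structure)
  if (length(nuc_idx) == 0L) {
    stop("no-NA error: structure has no nucleic chain")
  }
  a <- structure$atoms[nuc_idx, , drop = FALSE]

  # RNA vs DNA, per chain, majority over chains
  chains <- unique(a$chain_id)
  chain_rna <- vapply(chains, function(ch) {
    sub <- a[a$chain_id == ch, , drop = FALSE]
    any(sub$name == "O2'") || any(sub$residue_name %in% .NUC_RNA)
  }, logical(1))
  if (length(unique(chain_rna)) > 1L) {
    warning("complex mixes DNA and RNA chains; typed by majority chain")
  }
  is_rna <- mean(chain_rna) >= 0.5

  # Watson-Crick-geometry pairing: purine N1 vs pyrimidine N3
  pur <- a[a$residue_name %in% .NUC_PURINE & a$name == "N1", , drop = FALSE]
  pyr <- a[a$residue_name %in% .NUC_PYRIMIDINE & a$name == "N3", , drop = FALSE]
  n_pairs <- 0L
  if (nrow(pur) > 0L && nrow(pyr) > 0L) {
    d <- .cross_dist(as.matrix(pur[, c("x", "y", "z")]),
                     as.matrix(pyr[, c("x", "y", "z")]))
    n_pairs <- sum(d <= pair_cutoff)
  }
  is_double <- n_pairs >= min_pairs
  kind <- paste0(if (is_double) "ds" else "ss", if (is_rna) "RNA" else "DNA")
  .na_type(kind)
}

.na_type <- function(kind) {
  structure(list(kind = kind,
                 is_rna = as.integer(kind %in% c("ssRNA", "dsRNA")),
                 is_double = as.integer(kind %in% c("dsDNA", "dsRNA"))),
            class = "NucleicAcidType")
}

#' @export
print.NucleicAcidType <- function(x, ...) {
  cat(sprintf("NucleicAcidType: %s (is_rna=%d, is_double=%d)\n",
              x$kind, x$is_rna, x$is_double))
  invisible(x)
}

#' Minimum heavy-atom distance from a protein residue to the nucleic acid
#'
#' @param structure A `ComplexStructure`.
#' @param chain_id,residue_number,insertion_code Residue identity (author
#'   numbering).
#' @param cutoff Proximal/distal boundary in Angstrom (8, inclusive).
#' @return List with `distance` (A) and `label` (`"proximal"` if the distance
#'   is at most `cutoff`, else `"distal"`).
#' @export
min_distance_to_na <- function(structure, chain_id, residue_number,
                               insertion_code = "", cutoff = 8.0) {
  idx <- .residue_atoms(structure, chain_id, residue_number, insertion_code)
  if (structure$chains[[chain_id]] != "protein") {
    stop(sprintf("residue %s %s is not on a protein chain",
                 chain_id, residue_number))
  }
  nuc_idx <- .nucleic_atom_idx(structure)
  if (length(nuc_idx) == 0L) {
    stop("no-NA error: structure has no nucleic chain")
  }
  d <- .cross_dist(.coords(structure, idx), .coords(structure, nuc_idx))
  dmin <- min(d)
  list(distance = dmin, label = if (dmin <= cutoff) "proximal" else "distal")
}

#' Interface protein residues within a distance of the nucleic acid
#'
#' @param structure A `ComplexStructure`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (8, inclusive).
#' @return Data frame with columns chain_id, residue_number, insertion_code,
#'   residue_name, min_distance; sorted by chain then residue number.
#' @export
interface_residues <- function(structure, cutoff = 8.0) {
  a <- structure$atoms
  prot <- names(structure$chains)[structure$chains == "protein"]
  pidx <- which(a$chain_id %in% prot)
  nidx <- .nucleic_atom_idx(structure)
  if (length(nidx) == 0L) stop("no-NA error: structure has no nucleic chain")
  d <- .cross_dist(.coords(structure, pidx), .coords(structure, nidx))
  dmin_atom <- apply(d, 1, min)
  res <- data.frame(
    chain_id = a$chain_id[pidx],
    residue_number = a$residue_number[pidx],
    insertion_code = a$insertion_code[pidx],
    residue_name = a$residue_name[pidx],
    min_distance = dmin_atom,
    stringsAsFactors = FALSE
  )
  key <- paste(res$chain_id, res$residue_number, res$insertion_code)
  res <- res[order(key, res$min_distance), , drop = FALSE]
  res <- res[!duplicated(paste(res$chain_id, res$residue_number,
                               res$insertion_code)), , drop = FALSE]
  out <- res[res$min_distance <= cutoff, , drop = FALSE]
  out <- out[order(out$chain_id, out$residue_number, out$insertion_code), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
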