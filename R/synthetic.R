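## Deterministic synthetic fixtures: idealized alpha-helical peptides docked
## against idealized nucleic-acid strands or duplexes, and synthetic ddG
## datasets with a known generative model over computed features.  These
## emulate the geometry of small protein-NA complexes well enough to
## exercise every stage of the pipeline; they carry no physical energetics.

#' Specification of a toy protein-nucleic acid complex
#'
#' @param n_peptide_residues Peptide length (>= 3; default 8).
#' @param na_kind `"ssDNA"`, `"dsDNA"`, `"ssRNA"` or `"dsRNA"`.
#' @param n_nucleotides Nucleotides per strand (>= 2; default 6).
#' @param interface_gap Approximate minimum heavy-atom distance between
#'   peptide and nucleic acid, Angstrom (default 4).
#' @param seed Seed controlling the peptide and nucleotide sequences; the
#'   same spec always produces bit-identical PDB text.
#' @return A `ToySpec` list.
#' @export
toy_spec <- function(n_peptide_residues = 8, na_kind = "dsDNA",
                     n_nucleotides = 6, interface_gap = 4, seed = 1) {
  stopifnot(n_peptide_residues >= 3, n_nucleotides >= 2,
            na_kind %in% c("ssDNA", "dsDNA", "ssRNA", "dsRNA"),
            interface_gap > 0)
  structure(list(n_peptide_residues = n_peptide_residues, na_kind = na_kind,
                 n_nucleotides = n_nucleotides,
                 interface_gap = interface_gap, seed = seed),
            class = "ToySpec")
}

# helix backbone torsions and geometry
.HELIX <- list(phi = -57, psi = -47, omega = 180,
               b_n_ca = 1.46, b_ca_c = 1.52, b_c_n = 1.33, b_c_o = 1.23,
               a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
               a_ca_c_o = 120.5)

# idealized ladder parameters for the toy duplex; chosen so Watson-Crick
# partners pair unambiguously (N1-N3 = 2.9 A) while stacked neighbours stay
# clear of the pairing cutoff
.NA_GEOM <- list(rise = 4.0, twist_dna = 36, twist_rna = 32.7, wc_half = 1.45)

#' Generate a deterministic toy protein-nucleic acid complex
#'
#' Builds an ideal alpha-helical peptide (phi = -57, psi = -47) with
#' template side chains and a random (seed-determined) sequence, plus an
#' idealized nucleic-acid strand or duplex from planar base templates, and
#' places the peptide at the requested interface gap.
#'
#' @param spec A [toy_spec()].
#' @return List with `structure` (a `ComplexStructure`) and `pdb`
#'   (PDB-format lines).
#' @export
generate_toy_complex <- function(spec = toy_spec()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)

  rna <- spec$na_kind %in% c("ssRNA", "dsRNA")
  double <- spec$na_kind %in% c("dsDNA", "dsRNA")
  alphabet <- if (rna) c("A", "C", "G", "U") else c("DA", "DC", "DG", "DT")
  na_seq <- sample(alphabet, spec$n_nucleotides, replace = TRUE)
  pep_seq <- sample(.AA3, spec$n_peptide_residues, replace = TRUE)

  nuc <- .build_na(na_seq, rna, double)
  pep <- .build_helix(pep_seq)
  pep <- .dock_peptide(pep, nuc, spec$interface_gap)

  atoms <- rbind(pep, nuc)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  st <- structure(list(atoms = atoms, chains = .classify_chains(atoms),
                       id = sprintf("toy-%s-seed%d", spec$na_kind, spec$seed)),
                  class = "ComplexStructure")
  list(structure = st, pdb = write_structure(st))
}

.atom_rows <- function(coords, names, resname, chain, resno) {
  data.frame(serial = 0L, name = names, element = .infer_element(names),
             residue_name = resname, chain_id = chain,
             residue_number = resno, insertion_code = "",
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occupancy = 1, altloc = "", het = FALSE,
             stringsAsFactors = FALSE)
}

.build_helix <- function(seq3, chain = "A") {
  g <- .HELIX
  rows <- list()
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_along(seq3)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(g$b_n_ca, 0, 0)
      th <- (180 - g$a_n_ca_c) * pi / 180
      C <- CA + g$b_ca_c * c(cos(th), sin(th), 0)
    } else {
      N <- .place_atom(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n, g$psi)
      CA <- .place_atom(prevCA, prevC, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- .place_atom(prevC, N, CA, g$b_ca_c, g$a_n_ca_c, g$phi)
    }
    O <- .place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, g$psi + 180)
    placed <- .build_side_chain(seq3[i], list(N = N, CA = CA, C = C))
    nm <- c("N", "CA", "C", "O", .side_chain_atom_names(seq3[i]))
    placed$O <- O
    xyz <- do.call(rbind, placed[nm])
    rows[[i]] <- .atom_rows(xyz, nm, seq3[i], chain, i)
    prevN <- N; prevCA <- CA; prevC <- C
  }
  do.call(rbind, rows)
}

.build_na <- function(na_seq, rna, double) {
  g <- .NA_GEOM
  twist <- if (rna) g$twist_rna else g$twist_dna
  rows <- list()
  for (i in seq_along(na_seq)) {
    R <- .rotz(twist * (i - 1))
    shift <- c(0, 0, g$rise * (i - 1))
    xyz1 <- .nucleotide_coords(na_seq[i], rna)
    c1 <- t(R %*% t(xyz1)) + matrix(shift, nrow(xyz1), 3, byrow = TRUE)
    rows[[length(rows) + 1L]] <- .atom_rows(c1, rownames(xyz1), na_seq[i],
                                            "B", i)
    if (double) {
      comp <- .COMPLEMENT[[na_seq[i]]]
      xyz2 <- .nucleotide_coords(comp, rna)
      xyz2[, 1] <- -xyz2[, 1]  # mirror onto the +x side of the pair frame
      c2 <- t(R %*% t(xyz2)) + matrix(shift, nrow(xyz2), 3, byrow = TRUE)
      rows[[length(rows) + 1L]] <- .atom_rows(c2, rownames(xyz2), comp,
                                              "C", i)
    }
  }
  do.call(rbind, rows)
}

# translate the peptide along +x until its minimum heavy-atom distance to
# the nucleic acid approximates the requested gap
.dock_peptide <- function(pep, nuc, gap) {
  pxyz <- as.matrix(pep[, c("x", "y", "z")])
  nxyz <- as.matrix(nuc[, c("x", "y", "z")])
  # centre the peptide beside the nucleic acid, then slide along x
  pxyz <- sweep(pxyz, 2, colMeans(pxyz))
  target <- colMeans(nxyz) + c(max(nxyz[, 1]) - min(nxyz[, 1]) + 30, 0, 0)
  pxyz <- sweep(pxyz, 2, target, "+")
  for (it in 1:12) {
    d <- min(.cross_dist(pxyz, nxyz))
    if (abs(d - gap) < 0.05) break
    pxyz[, 1] <- pxyz[, 1] - (d - gap)
  }
  pep$x <- pxyz[, 1]; pep$y <- pxyz[, 2]; pep$z <- pxyz[, 3]
  pep
}

#' Generate a synthetic ddG dataset with a known generative model
#'
#' Samples mutation constructs on interface residues of the supplied toy
#' complexes, computes their feature vectors with the package pipeline and
#' draws `ddg = sum(coefficients * features) + N(0, noise_sigma)`.  The
#' generative parameters are returned so recovery experiments can compare
#' against ground truth.
#'
#' @param complexes List of `ComplexStructure`s (e.g. from
#'   [generate_toy_complex()]).
#' @param effect_spec Named numeric vector: feature name -> coefficient.
#' @param noise_sigma Gaussian noise level (kcal/mol).
#' @param n_records Number of records to draw.
#' @param seed Seed for sampling and noise.
#' @param multi_fraction Fraction of records drawn as 2-3-point constructs
#'   (their features aggregate the single-point parts; default 0).
#' @param config A [feature_config()].
#' @param interface_cutoff Residues with any heavy atom within this distance
#'   of the nucleic acid are mutable sites (8 A).
#' @return List: `records` (data frame with `complex_id`, `construct`,
#'   `ddg`, `na_kind`, `provenance`, `group_id`), `features` (n x schema
#'   matrix), `generative` (the parameters used).
#' @export
generate_synthetic_dataset <- function(complexes, effect_spec,
                                       noise_sigma = 0.2, n_records = 500,
                                       seed = 1, multi_fraction = 0,
                                       config = feature_config(),
                                       interface_cutoff = 8.0) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  schema <- feature_schema(config)
  if (!all(names(effect_spec) %in% schema)) {
    stop("effect_spec names outside the feature schema: ",
         paste(setdiff(names(effect_spec), schema), collapse = ", "))
  }

  ctx <- lapply(complexes, function(st) {
    ir <- interface_residues(st, interface_cutoff)
    if (nrow(ir) == 0L) stop("no interface residues in complex ", st$id)
    list(st = st, interface = ir, na_type = detect_na_type(st))
  })

  cache <- new.env(parent = emptyenv())
  single_features <- function(ci, row, mut) {
    key <- paste(ci, row$chain_id, row$residue_number, mut)
    if (!is.null(cache[[key]])) return(cache[[key]])
    st <- ctx[[ci]]$st
    spec <- list(chain_id = row$chain_id, wt = aa3to1(row$residue_name),
                 residue_number = row$residue_number,
                 insertion_code = row$insertion_code, mut = mut)
    mut_st <- naive_mutant(st, spec)
    fv <- assemble_features(st, mut_st, spec, ctx[[ci]]$na_type, config)
    cache[[key]] <- fv
    fv
  }

  feats <- matrix(NA_real_, n_records, length(schema),
                  dimnames = list(NULL, schema))
  rec <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    ci <- sample(length(ctx), 1)
    ir <- ctx[[ci]]$interface
    n_sites <- if (stats::runif(1) < multi_fraction && nrow(ir) >= 2)
      sample(2:min(3, nrow(ir)), 1) else 1L
    sites <- ir[sample(nrow(ir), n_sites), , drop = FALSE]
    fvs <- list(); con <- character(n_sites)
    for (s in seq_len(n_sites)) {
      row <- sites[s, , drop = FALSE]
      wt1 <- aa3to1(row$residue_name)
      mut <- sample(setdiff(.AA1, wt1), 1)
      fvs[[s]] <- single_features(ci, row, mut)
      con[s] <- sprintf("%s %s%d%s", row$chain_id, wt1,
                        row$residue_number, mut)
    }
    fv <- if (n_sites == 1L) fvs[[1]] else aggregate_multi(fvs)
    feats[r, ] <- as.numeric(fv)
    ddg <- sum(effect_spec * fv[names(effect_spec)]) +
      stats::rnorm(1, 0, noise_sigma)
    rec[[r]] <- data.frame(
      complex_id = ctx[[ci]]$st$id,
      construct = paste(con, collapse = ";"),
      ddg = ddg, na_kind = ctx[[ci]]$na_type$kind,
      provenance = "experimental", group_id = ctx[[ci]]$st$id,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  list(records = records, features = feats,
       generative = list(effect_spec = effect_spec,
                         noise_sigma = noise_sigma, seed = seed,
                         multi_fraction = multi_fraction))
}
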