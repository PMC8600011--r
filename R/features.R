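## Feature assembly for one mutation: graph-based signatures (wild +
## mutant-minus-wild), substitution-matrix scores, vibrational-entropy
## change, interaction counts and deltas, nucleic-acid-type binaries and the
## site-to-interface distance.  Multiple-point constructs aggregate the
## vectors of their single-point parts.

#' Feature-extraction configuration
#'
#' @param signature A [signature_config()].
#' @param interaction_scope Scope for interaction counting: `"site"`
#'   (contacts of the mutated residue, inter- and intra-molecular; default)
#'   or `"inter"` (whole protein-nucleic interface).
#' @param interaction A [interaction_config()].
#' @param enm_cutoff,enm_mode Elastic-network settings for the
#'   vibrational-entropy feature (10 A, all-heavy-atom nodes).
#' @param stability_ddg Optional user-supplied predicted protein-stability
#'   change (kcal/mol) exported as `opt:stability_ddg`; imputed as 0 when
#'   absent.
#' @return A `FeatureConfig` list.
#' @export
feature_config <- function(signature = signature_config(),
                           interaction_scope = c("site", "inter"),
                           interaction = interaction_config(),
                           enm_cutoff = 10,
                           enm_mode = c("heavy", "calpha"),
                           stability_ddg = NULL) {
  structure(list(signature = signature,
                 interaction_scope = match.arg(interaction_scope),
                 interaction = interaction,
                 enm_cutoff = enm_cutoff,
                 enm_mode = match.arg(enm_mode),
                 stability_ddg = stability_ddg),
            class = "FeatureConfig")
}

#' The fixed feature schema
#'
#' @param config A [feature_config()].
#' @return Character vector of feature names in canonical order:
#'   `sig:*` wild-type signature counts, `dsig:*` mutant-minus-wild
#'   signature differences, `sub:*` substitution scores, `nma:delta_s_vib`,
#'   `int:<type>:wt` and `int:<type>:delta` for the 13 interaction types,
#'   `na:is_rna`, `na:is_double`, `geo:min_dist_na`, `opt:stability_ddg`.
#' @export
feature_schema <- function(config = feature_config()) {
  c(signature_names(config$signature, "sig"),
    signature_names(config$signature, "dsig"),
    paste0("sub:", names(substitution_matrices())),
    "nma:delta_s_vib",
    paste0("int:", interaction_types(), ":wt"),
    paste0("int:", interaction_types(), ":delta"),
    "na:is_rna", "na:is_double", "geo:min_dist_na", "opt:stability_ddg")
}

#' Load the substitution matrices used for mutation scoring
#'
#' Three 20x20 matrices indexed `[wild-type, mutant]`: BLOSUM62 (from
#' Biostrings), and two packaged property-difference matrices derived from
#' the Kyte-Doolittle hydropathy scale and from residue volumes
#' (score = property(mutant) - property(wild-type)).
#'
#' @param paths Optional named character vector of whitespace-delimited
#'   20x20 matrix files (row/column names are one-letter codes) replacing
#'   the defaults.
#' @return Named list of matrices.
#' @export
substitution_matrices <- function(paths = NULL) {
  if (!is.null(paths)) {
    out <- lapply(paths, .read_submat)
    names(out) <- names(paths)
    return(out)
  }
  if (!is.null(.pkg_env$submats)) return(.pkg_env$submats)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b62 <- e$BLOSUM62[.AA1, .AA1]
  hyd <- .read_submat(system.file("extdata", "submat_hydropathy.txt",
                                  package = "nabind", mustWork = TRUE))
  vol <- .read_submat(system.file("extdata", "submat_volume.txt",
                                  package = "nabind", mustWork = TRUE))
  out <- list(blosum62 = b62, hydropathy = hyd, volume = vol)
  .pkg_env$submats <- out
  out
}

.read_submat <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  if (!all(.AA1 %in% rownames(m)) || !all(.AA1 %in% colnames(m))) {
    stop("substitution matrix incomplete over the 20 standard amino acids: ",
         path)
  }
  m[.AA1, .AA1]
}

#' Substitution-matrix scores for one amino-acid exchange
#'
#' @param wt,mut One-letter amino-acid codes.
#' @param matrices Named list of 20x20 matrices
#'   (default [substitution_matrices()]).
#' @return Named numeric vector `sub:<matrix>` with `scores[wt, mut]`.
#' @export
substitution_features <- function(wt, mut, matrices = substitution_matrices()) {
  if (!(wt %in% .AA1) || !(mut %in% .AA1)) {
    stop("validation error: non-standard amino acid letter: ", wt, "/", mut)
  }
  out <- vapply(matrices, function(m) m[wt, mut], numeric(1))
  names(out) <- paste0("sub:", names(matrices))
  out
}

#' Build a naive mutant structure by template side-chain replacement
#'
#' The mutated residue's side chain is replaced by an idealized template
#' rotamer anchored on the wild-type N/CA/C (and CB when both wild-type and
#' mutant have one); backbone atoms are untouched.  Mutation to glycine
#' removes the side chain.  No energetic refinement is performed; externally
#' built mutant structures can be supplied anywhere a mutant is accepted.
#'
#' @param structure Wild-type `ComplexStructure`.
#' @param mutation List or one-row data frame with `chain_id`, `wt`,
#'   `residue_number`, optional `insertion_code`, `mut` (one-letter codes).
#' @return Mutant `ComplexStructure`.
#' @export
naive_mutant <- function(structure, mutation) {
  m <- as.list(mutation)
  icode <- m$insertion_code %||% ""
  idx <- .residue_atoms(structure, m$chain_id, m$residue_number, icode)
  a <- structure$atoms
  found3 <- a$residue_name[idx[1]]
  found1 <- aa3to1(found3)
  if (is.na(found1) || found1 != m$wt) {
    stop(sprintf(
      "validation error: wild-type mismatch at %s %s%s: expected %s, found %s",
      m$chain_id, m$residue_number, icode, m$wt, found3))
  }
  if (m$wt == m$mut) return(structure)
  target3 <- aa1to3(m$mut)
  if (is.na(target3)) {
    stop("validation error: non-standard mutant amino acid: ", m$mut)
  }

  backbone <- c("N", "CA", "C", "O", "OXT")
  keep_idx <- idx[a$name[idx] %in% backbone]
  need <- c("N", "CA", "C")
  if (!all(need %in% a$name[keep_idx])) {
    stop("mutated residue lacks backbone atoms N/CA/C")
  }
  placed <- list()
  for (nm in need) {
    k <- keep_idx[a$name[keep_idx] == nm][1]
    placed[[nm]] <- c(a$x[k], a$y[k], a$z[k])
  }
  sc_names <- .side_chain_atom_names(target3)
  if ("CB" %in% sc_names) {
    wild_cb <- idx[a$name[idx] == "CB"]
    if (length(wild_cb) == 1L) {
      placed[["CB"]] <- c(a$x[wild_cb], a$y[wild_cb], a$z[wild_cb])
    }
  }
  placed <- .build_side_chain(target3, placed)

  new_rows <- NULL
  if (length(sc_names) > 0L) {
    xyz <- do.call(rbind, placed[sc_names])
    new_rows <- data.frame(
      serial = 0L,
      name = sc_names,
      element = .infer_element(sc_names),
      residue_name = target3,
      chain_id = m$chain_id,
      residue_number = m$residue_number,
      insertion_code = icode,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, altloc = "", het = FALSE,
      stringsAsFactors = FALSE
    )
  }
  bb <- a[keep_idx, , drop = FALSE]
  bb$residue_name <- target3
  before <- a[seq_len(nrow(a)) < min(idx), , drop = FALSE]
  after <- a[seq_len(nrow(a)) > max(idx), , drop = FALSE]
  atoms <- rbind(before, bb, new_rows, after)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chains = structure$chains,
                 id = paste0(structure$id, ":", m$chain_id, m$wt,
                             m$residue_number, icode, m$mut)),
            class = "ComplexStructure")
}

#' Assemble the feature vector for one single-point mutation
#'
#' @param wild Wild-type `ComplexStructure`.
#' @param mutant Mutant `ComplexStructure` (e.g. from [naive_mutant()] or an
#'   externally refined model).
#' @param mutation Single mutation as in [naive_mutant()].
#' @param na_type A `NucleicAcidType` (from [detect_na_type()]).
#' @param config A [feature_config()].
#' @return Named numeric vector following [feature_schema()], with the
#'   schema fingerprint in attribute `schema_hash`.
#' @export
assemble_features <- function(wild, mutant, mutation,
                              na_type = detect_na_type(wild),
                              config = feature_config()) {
  m <- as.list(mutation)
  icode <- m$insertion_code %||% ""
  if (length(.nucleic_atom_idx(wild)) == 0L) {
    stop("no-NA error: cannot featurize a complex without a nucleic chain")
  }
  sig <- mutation_signatures(wild, mutant, m$chain_id, m$residue_number,
                             icode, config$signature)
  subs <- substitution_features(m$wt, m$mut)
  nma <- vibrational_entropy_change(wild, mutant, cutoff = config$enm_cutoff,
                                    mode = config$enm_mode)
  site <- list(chain_id = m$chain_id, residue_number = m$residue_number,
               insertion_code = icode)
  ints <- interaction_delta(wild, mutant, scope = config$interaction_scope,
                            site = site, config = config$interaction)
  geo <- min_distance_to_na(wild, m$chain_id, m$residue_number, icode)

  v <- c(as.numeric(sig$wild), as.numeric(sig$delta), as.numeric(subs),
         nma, as.numeric(ints$wild), as.numeric(ints$delta),
         na_type$is_rna, na_type$is_double, geo$distance,
         config$stability_ddg %||% 0)
  schema <- feature_schema(config)
  names(v) <- schema
  attr(v, "schema_hash") <- .schema_hash(schema)
  v
}

#' Aggregate single-point feature vectors into a multi-point vector
#'
#' @param singles List of feature vectors with identical schemas.
#' @param mode `"auto"` (default; counts and deltas are summed, scores,
#'   distances and binaries averaged), `"mean"` or `"sum"` applied to every
#'   feature.
#' @return Aggregated feature vector under the same schema.
#' @export
aggregate_multi <- function(singles, mode = c("auto", "mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(length(singles) >= 1L)
  nm <- names(singles[[1]])
  for (s in singles) {
    if (!identical(names(s), nm)) stop("contract error: schema mismatch")
  }
  M <- do.call(rbind, lapply(singles, as.numeric))
  if (mode == "mean") out <- colMeans(M)
  else if (mode == "sum") out <- colSums(M)
  else {
    sum_mask <- grepl("^(sig|dsig|int|nma):", nm)
    out <- ifelse(sum_mask, colSums(M), colMeans(M))
  }
  names(out) <- nm
  attr(out, "schema_hash") <- attr(singles[[1]], "schema_hash")
  out
}
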