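## Graph-based structural signatures: cumulative distributions of pairwise
## distances between pharmacophore-class pairs in the mutation-site
## environment (cutoff scanning matrix).

#' Signature configuration
#'
#' @param environment_radius Radius (A) of the residue environment around the
#'   mutation site (default 10).
#' @param d_min,d_max,d_step Distance grid (A): cumulative cutoffs are
#'   `d_min + d_step, ..., d_max` (defaults 0, 10, 2, i.e. cutoffs
#'   2, 4, 6, 8, 10).
#' @return A `SignatureConfig` list.
#' @export
signature_config <- function(environment_radius = 10, d_min = 0,
                             d_max = 10, d_step = 2) {
  stopifnot(d_min >= 0, d_min < d_max, d_step > 0, environment_radius > 0)
  structure(list(environment_radius = environment_radius,
                 d_min = d_min, d_max = d_max, d_step = d_step),
            class = "SignatureConfig")
}

.signature_cutoffs <- function(config) {
  seq(config$d_min + config$d_step, config$d_max, by = config$d_step)
}

# all unordered class pairs (including same-class) in canonical order
.signature_class_pairs <- function() {
  cls <- pharmacophore_classes()
  n <- length(cls)
  pairs <- list()
  for (i in seq_len(n)) for (j in i:n) {
    pairs[[length(pairs) + 1L]] <- c(cls[i], cls[j])
  }
  pairs
}

#' Names of the signature vector entries, in canonical order
#' @param config A [signature_config()].
#' @param prefix Name prefix, default `"sig"`.
#' @return Character vector `"<prefix>:<classA>:<classB>:<=d"`.
#' @export
signature_names <- function(config = signature_config(), prefix = "sig") {
  cuts <- .signature_cutoffs(config)
  unlist(lapply(.signature_class_pairs(), function(p) {
    sprintf("%s:%s:%s:<=%g", prefix, p[1], p[2], cuts)
  }))
}

#' Atoms in the structural environment of a residue
#'
#' All heavy atoms (protein and nucleic) within `radius` of any atom of the
#' site residue, including the site residue's own atoms.
#'
#' @param structure A `ComplexStructure`.
#' @param chain_id,residue_number,insertion_code Site residue.
#' @param radius Environment radius in Angstrom.
#' @return Integer vector of row indices into `structure$atoms`.
#' @export
residue_environment <- function(structure, chain_id, residue_number,
                                insertion_code = "", radius = 10) {
  site <- .residue_atoms(structure, chain_id, residue_number, insertion_code)
  d <- .cross_dist(.coords(structure), .coords(structure, site))
  which(apply(d, 1, min) <= radius)
}

#' Compute a graph-based signature over a labelled atom environment
#'
#' Entry (pair i:j, cutoff d) counts unordered atom pairs (a, b), a != b,
#' with a carrying class i, b carrying class j and distance at most d.  An
#' atom with several labels contributes to every matching class pair; a pair
#' matching a class pair through both orientations is still counted once.
#'
#' @param structure A `ComplexStructure`.
#' @param env_idx Atom indices of the environment (see
#'   [residue_environment()]); may be empty.
#' @param labels Pharmacophore labels for all atoms of `structure`
#'   (see [assign_pharmacophores()]).
#' @param config A [signature_config()].
#' @return Named integer vector (`SignatureVector`), ordering as
#'   [signature_names()]; counts are non-decreasing across cutoffs within
#'   each class pair.
#' @export
compute_signature <- function(structure, env_idx, labels,
                              config = signature_config()) {
  cuts <- .signature_cutoffs(config)
  pairs <- .signature_class_pairs()
  out <- integer(length(pairs) * length(cuts))
  names(out) <- signature_names(config)
  n <- length(env_idx)
  if (n == 0L) return(out)

  lab <- labels[env_idx]
  if (any(vapply(lab, length, integer(1)) == 0L)) {
    stop("contract violation: unlabelled atom in environment")
  }
  cls <- pharmacophore_classes()
  member <- vapply(cls, function(cl) {
    vapply(lab, function(l) cl %in% l, logical(1))
  }, logical(n))
  member <- matrix(member, nrow = n, dimnames = list(NULL, cls))

  D <- .cross_dist(.coords(structure, env_idx), .coords(structure, env_idx))
  upper <- upper.tri(D)

  k <- 0L
  for (p in pairs) {
    mi <- member[, p[1]]
    mj <- member[, p[2]]
    sel <- (outer(mi, mj, "&") | outer(mj, mi, "&")) & upper
    dd <- D[sel]
    out[k + seq_along(cuts)] <- vapply(cuts, function(cc)
      sum(dd <= cc), numeric(1))
    k <- k + length(cuts)
  }
  storage.mode(out) <- "integer"
  out
}

#' Wild-type and difference signatures for one mutation
#'
#' Computes the signature of the wild-type site environment and the
#' difference (mutant minus wild-type) signature of the same site in the
#' mutant structure.
#'
#' @param wild,mutant `ComplexStructure`s sharing the site residue.
#' @param chain_id,residue_number,insertion_code Site residue.
#' @param config A [signature_config()].
#' @return List with `wild` and `delta` signature vectors.
#' @export
mutation_signatures <- function(wild, mutant, chain_id, residue_number,
                                insertion_code = "",
                                config = signature_config()) {
  r <- config$environment_radius
  lw <- assign_pharmacophores(wild)
  lm <- assign_pharmacophores(mutant)
  ew <- residue_environment(wild, chain_id, residue_number, insertion_code, r)
  em <- residue_environment(mutant, chain_id, residue_number, insertion_code, r)
  sw <- compute_signature(wild, ew, lw, config)
  sm <- compute_signature(mutant, em, lm, config)
  list(wild = sw, delta = sm - sw)
}
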