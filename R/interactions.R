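## Geometric classification of atomic interactions into thirteen types:
## clash, covalent, vdw, vdw_clash, hbond, weak_hbond, proximal,
## halogen_bond, aromatic, ionic, carbonyl, hydrophobic, metal.
## All thresholds live in one configuration block; criteria are distance
## based (structures carry no hydrogens), with a donor-angle test applied
## where a covalently bonded antecedent of the donor exists.

.INTERACTION_TYPES <- c("clash", "covalent", "vdw", "vdw_clash", "hbond",
                        "weak_hbond", "proximal", "halogen_bond", "aromatic",
                        "ionic", "carbonyl", "hydrophobic", "metal")

#' The thirteen interaction types, in canonical order
#' @return Character vector.
#' @export
interaction_types <- function() .INTERACTION_TYPES

# van der Waals radii (A)
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                ZN = 1.39, MG = 1.73, CA = 2.31, MN = 1.97, FE = 1.94,
                "NA" = 2.27, K = 2.75, CU = 1.40, NI = 1.63, CO = 1.92,
                SE = 1.90)
# covalent radii (A)
.COV_RADII <- c(C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05,
                F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
                ZN = 1.22, MG = 1.41, CA = 1.76, MN = 1.39, FE = 1.32,
                "NA" = 1.66, K = 2.03, CU = 1.32, NI = 1.24, CO = 1.26,
                SE = 1.20)
.METALS <- c("ZN", "MG", "CA", "MN", "FE", "NA", "K", "CU", "NI", "CO")
.HALOGENS <- c("CL", "BR", "I")

#' Interaction classifier configuration (thresholds in Angstrom)
#'
#' @param max_dist Candidate pair cutoff (5.5).
#' @param covalent_tol Added to the covalent-radius sum (0.4).
#' @param clash_tol Subtracted from the vdW-radius sum (0.5).
#' @param vdw_tol Added to the vdW-radius sum (0.5).
#' @param hbond_dist Donor-acceptor distance (3.5); `hbond_angle` minimum
#'   antecedent-donor-acceptor angle in degrees (90).
#' @param weak_hbond_dist Carbon-donor to acceptor distance (3.8).
#' @param ionic_dist Positive-negative distance (4.0).
#' @param aromatic_dist Ring-centroid distance (5.0).
#' @param hydrophobic_dist Hydrophobic carbon pair distance (4.5).
#' @param carbonyl_dist Carbonyl oxygen to carbonyl carbon (3.6).
#' @param halogen_dist Halogen to acceptor (3.5).
#' @param metal_dist Metal to O/N/S (2.8).
#' @param proximal_dist Fallback contact distance (5.0).
#' @return List of thresholds.
#' @export
interaction_config <- function(max_dist = 5.5, covalent_tol = 0.4,
                               clash_tol = 0.5, vdw_tol = 0.5,
                               hbond_dist = 3.5, hbond_angle = 90,
                               weak_hbond_dist = 3.8, ionic_dist = 4.0,
                               aromatic_dist = 5.0, hydrophobic_dist = 4.5,
                               carbonyl_dist = 3.6, halogen_dist = 3.5,
                               metal_dist = 2.8, proximal_dist = 5.0) {
  as.list(environment())
}

# aromatic ring definitions for centroid computation
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
.BASE_RING_PUR <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
.BASE_RING_PYR <- c("N1", "C2", "N3", "C4", "C5", "C6")

# carbonyl groups: oxygen names and the carbon each is bonded to
.CARBONYL_O <- c("O", "OXT", "OD1", "OE1", "O2", "O4", "O6")
.CARBONYL_C <- c("C", "CG", "CD", "C2", "C4", "C6")

#' Classify interatomic interactions in a complex
#'
#' Every heavy-atom pair within `config$max_dist` between the two scope sets
#' is assigned all matching types; `proximal` is assigned when a pair within
#' `proximal_dist` matches nothing else.  Aromatic contacts are counted
#' between ring centroids (one record per ring pair).
#'
#' @param structure A `ComplexStructure`.
#' @param scope `"inter"` (protein vs nucleic atoms), `"site"` (atoms of the
#'   residue given in `site` vs all other atoms) or `"all"`.
#' @param site For `scope = "site"`: list with `chain_id`, `residue_number`
#'   and optionally `insertion_code`.
#' @param labels Pharmacophore labels (computed if `NULL`).
#' @param config An [interaction_config()].
#' @return Data frame with columns `atom_a`, `atom_b` (row indices into
#'   `structure$atoms`), `type`, `distance`; zero rows is a valid result.
#' @export
compute_interactions <- function(structure,
                                 scope = c("inter", "site", "all"),
                                 site = NULL, labels = NULL,
                                 config = interaction_config()) {
  scope <- match.arg(scope)
  a <- structure$atoms
  if (is.null(labels)) labels <- assign_pharmacophores(structure)

  if (scope == "inter") {
    prot <- which(a$chain_id %in%
                    names(structure$chains)[structure$chains == "protein"])
    nuc <- .nucleic_atom_idx(structure)
    set_a <- prot; set_b <- nuc
  } else if (scope == "site") {
    if (is.null(site)) stop("scope 'site' requires a site residue")
    set_a <- .residue_atoms(structure, site$chain_id, site$residue_number,
                            site$insertion_code %||% "")
    set_b <- setdiff(seq_len(nrow(a)), set_a)
  } else {
    set_a <- seq_len(nrow(a)); set_b <- seq_len(nrow(a))
  }
  if (length(set_a) == 0L || length(set_b) == 0L) {
    return(.empty_interactions())
  }

  D <- .cross_dist(.coords(structure, set_a), .coords(structure, set_b))
  cand <- which(D <= config$max_dist, arr.ind = TRUE)
  ii <- set_a[cand[, 1]]
  jj <- set_b[cand[, 2]]
  dd <- D[cand]
  # drop self pairs, same-residue pairs, and duplicate unordered pairs
  keep <- ii != jj &
    !(a$chain_id[ii] == a$chain_id[jj] &
      a$residue_number[ii] == a$residue_number[jj] &
      a$insertion_code[ii] == a$insertion_code[jj])
  ii <- ii[keep]; jj <- jj[keep]; dd <- dd[keep]
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  dup <- duplicated(paste(ii, jj))
  ii <- ii[!dup]; jj <- jj[!dup]; dd <- dd[!dup]

  bonded <- .bonded_neighbours(structure, config)
  rows <- .classify_pairs(structure, ii, jj, dd, labels, bonded, config)

  # aromatic: ring-centroid contacts between the scope sides
  rows <- rbind(rows, .aromatic_contacts(structure, set_a, set_b, config))
  rownames(rows) <- NULL
  rows
}

.empty_interactions <- function() {
  data.frame(atom_a = integer(), atom_b = integer(),
             type = character(), distance = numeric(),
             stringsAsFactors = FALSE)
}

# adjacency list of covalently bonded heavy atoms (distance criterion)
.bonded_neighbours <- function(structure, config) {
  xyz <- .coords(structure)
  n <- nrow(xyz)
  rc <- .COV_RADII[structure$atoms$element]
  rc[is.na(rc)] <- 0.77
  D <- .cross_dist(xyz, xyz)
  thr <- outer(rc, rc, "+") + config$covalent_tol
  adj <- D <= thr & D > 0.1
  adj
}

.classify_pairs <- function(structure, ii, jj, dd, labels, bonded, config) {
  a <- structure$atoms
  out_i <- integer(0); out_j <- integer(0)
  out_t <- character(0); out_d <- numeric(0)
  add <- function(i, j, type, d) {
    out_i <<- c(out_i, i); out_j <<- c(out_j, j)
    out_t <<- c(out_t, type); out_d <<- c(out_d, d)
  }
  rv <- .VDW_RADII[a$element]; rv[is.na(rv)] <- 1.70
  rc <- .COV_RADII[a$element]; rc[is.na(rc)] <- 0.77
  xyz <- .coords(structure)

  for (k in seq_along(ii)) {
    i <- ii[k]; j <- jj[k]; d <- dd[k]
    li <- labels[[i]]; lj <- labels[[j]]
    ei <- a$element[i]; ej <- a$element[j]
    matched <- FALSE

    if (d <= rc[i] + rc[j] + config$covalent_tol) {
      add(i, j, "covalent", d); matched <- TRUE
    } else {
      vsum <- rv[i] + rv[j]
      if (d < vsum - config$clash_tol) {
        add(i, j, "clash", d); matched <- TRUE
      } else if (d < vsum) {
        add(i, j, "vdw_clash", d); matched <- TRUE
      } else if (d <= vsum + config$vdw_tol) {
        add(i, j, "vdw", d); matched <- TRUE
      }
    }

    # hydrogen bond (donor-acceptor, optional antecedent angle)
    if (d <= config$hbond_dist) {
      ok <- (.is_donor(li) && .is_acceptor(lj) &&
               .donor_angle_ok(xyz, bonded, i, j, config)) ||
            (.is_donor(lj) && .is_acceptor(li) &&
               .donor_angle_ok(xyz, bonded, j, i, config))
      if (ok) { add(i, j, "hbond", d); matched <- TRUE }
    }
    # weak (carbon-donor) hydrogen bond
    if (d <= config$weak_hbond_dist &&
        ((ei == "C" && .is_acceptor(lj)) || (ej == "C" && .is_acceptor(li)))) {
      add(i, j, "weak_hbond", d); matched <- TRUE
    }
    # ionic
    if (d <= config$ionic_dist &&
        (("positive" %in% li && "negative" %in% lj) ||
         ("negative" %in% li && "positive" %in% lj) ||
         ("positive" %in% li && "phosphate" %in% lj && ej == "O") ||
         ("phosphate" %in% li && ei == "O" && "positive" %in% lj))) {
      add(i, j, "ionic", d); matched <- TRUE
    }
    # hydrophobic
    if (d <= config$hydrophobic_dist && ei == "C" && ej == "C" &&
        "hydrophobic" %in% li && "hydrophobic" %in% lj) {
      add(i, j, "hydrophobic", d); matched <- TRUE
    }
    # carbonyl (dipole-dipole): C=O oxygen to a carbonyl carbon
    if (d <= config$carbonyl_dist &&
        ((a$name[i] %in% .CARBONYL_O && a$name[j] %in% .CARBONYL_C) ||
         (a$name[j] %in% .CARBONYL_O && a$name[i] %in% .CARBONYL_C))) {
      add(i, j, "carbonyl", d); matched <- TRUE
    }
    # halogen bond
    if (d <= config$halogen_dist &&
        ((ei %in% .HALOGENS && .is_acceptor(lj)) ||
         (ej %in% .HALOGENS && .is_acceptor(li)))) {
      add(i, j, "halogen_bond", d); matched <- TRUE
    }
    # metal coordination
    if (d <= config$metal_dist &&
        ((ei %in% .METALS && ej %in% c("O", "N", "S")) ||
         (ej %in% .METALS && ei %in% c("O", "N", "S")))) {
      add(i, j, "metal", d); matched <- TRUE
    }
    if (!matched && d <= config$proximal_dist) {
      add(i, j, "proximal", d)
    }
  }
  data.frame(atom_a = out_i, atom_b = out_j, type = out_t, distance = out_d,
             stringsAsFactors = FALSE)
}

.is_donor <- function(l) "donor" %in% l
.is_acceptor <- function(l) {
  any(c("acceptor", "phosphate") %in% l)
}

# antecedent-donor-acceptor angle >= hbond_angle when an antecedent exists;
# distance-only otherwise (no hydrogens present)
.donor_angle_ok <- function(xyz, bonded, donor, acceptor, config) {
  ante <- which(bonded[donor, ])
  ante <- setdiff(ante, acceptor)
  if (length(ante) == 0L) return(TRUE)
  v1 <- xyz[acceptor, ] - xyz[donor, ]
  ok <- vapply(ante, function(q) {
    v2 <- xyz[q, ] - xyz[donor, ]
    cosang <- sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi >= config$hbond_angle
  }, logical(1))
  all(ok)
}

# ring centroids of aromatic residues and nucleobases
.ring_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain_id, a$residue_number, a$insertion_code)
  out <- list()
  for (res_key in unique(key)) {
    idx <- which(key == res_key)
    rn <- a$residue_name[idx[1]]
    ring <- NULL
    if (rn %in% names(.RING_ATOMS)) ring <- .RING_ATOMS[[rn]]
    else if (rn %in% .NUC_PURINE) ring <- .BASE_RING_PUR
    else if (rn %in% .NUC_PYRIMIDINE) ring <- .BASE_RING_PYR
    if (is.null(ring)) next
    ridx <- idx[a$name[idx] %in% ring]
    if (length(ridx) < 3L) next
    out[[length(out) + 1L]] <- list(
      idx = ridx,
      centroid = colMeans(.coords(structure, ridx))
    )
  }
  out
}

.aromatic_contacts <- function(structure, set_a, set_b, config) {
  rings <- .ring_table(structure)
  if (length(rings) < 2L) return(.empty_interactions())
  in_a <- vapply(rings, function(r) any(r$idx %in% set_a), logical(1))
  in_b <- vapply(rings, function(r) any(r$idx %in% set_b), logical(1))
  rows <- .empty_interactions()
  for (p in seq_along(rings)) for (q in seq_along(rings)) {
    if (p >= q) next
    if (!((in_a[p] && in_b[q]) || (in_a[q] && in_b[p]))) next
    d <- .vnorm(rings[[p]]$centroid - rings[[q]]$centroid)
    if (d <= config$aromatic_dist) {
      rows <- rbind(rows, data.frame(
        atom_a = min(rings[[p]]$idx[1], rings[[q]]$idx[1]),
        atom_b = max(rings[[p]]$idx[1], rings[[q]]$idx[1]),
        type = "aromatic", distance = d, stringsAsFactors = FALSE))
    }
  }
  rows
}

#' Per-type interaction counts
#'
#' @param records Data frame from [compute_interactions()].
#' @return Named integer vector over [interaction_types()].
#' @export
interaction_counts <- function(records) {
  counts <- integer(length(.INTERACTION_TYPES))
  names(counts) <- .INTERACTION_TYPES
  if (nrow(records) > 0L) {
    tab <- table(factor(records$type, levels = .INTERACTION_TYPES))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Interaction-count changes between wild-type and mutant complexes
#'
#' @param wild,mutant `ComplexStructure`s sharing the nucleic chains.
#' @param scope,site,config As in [compute_interactions()]; when
#'   `scope = "site"` the mutated residue must exist in both structures.
#' @return List with `wild`, `mutant` and `delta` (mutant minus wild) counts
#'   per interaction type.
#' @export
interaction_delta <- function(wild, mutant, scope = "site", site = NULL,
                              config = interaction_config()) {
  if (identical(scope, "site") && !is.null(site)) {
    # contract: the mutated residue must be present in the mutant
    .residue_atoms(mutant, site$chain_id, site$residue_number,
                   site$insertion_code %||% "")
  }
  cw <- interaction_counts(compute_interactions(wild, scope, site,
                                                config = config))
  cm <- interaction_counts(compute_interactions(mutant, scope, site,
                                                config = config))
  list(wild = cw, mutant = cm, delta = cm - cw)
}
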