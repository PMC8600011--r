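# Shared fixtures and independent brute-force oracles.  Fixtures are built
# in code (no stored data); toy complexes are memoized per test run.

.fixture_env <- new.env()

toy <- function(kind = "dsDNA", seed = 1, n_pep = 8, n_nt = 6, gap = 4) {
  key <- paste(kind, seed, n_pep, n_nt, gap)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_toy_complex(
      toy_spec(n_pep, kind, n_nt, gap, seed))
  }
  .fixture_env[[key]]
}

# apply a rigid rotation (deg about z, then y) and translation
rigid_move <- function(st, zdeg = 30, ydeg = 60, shift = c(5, -3, 11)) {
  th <- zdeg * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ph <- ydeg * pi / 180
  Ry <- matrix(c(cos(ph), 0, -sin(ph), 0, 1, 0, sin(ph), 0, cos(ph)), 3, 3)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(Rz %*% Ry)
  xyz <- sweep(xyz, 2, shift, "+")
  st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
  st
}

# build a minimal ComplexStructure from an atom table (chains classified
# from residue names, serials renumbered)
manual_structure <- function(atoms, id = "manual") {
  atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$insertion_code)) atoms$insertion_code <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  st <- structure(list(atoms = atoms, chains = NULL, id = id),
                  class = "ComplexStructure")
  st$chains <- nabind:::.classify_chains(atoms)
  st
}

atom_row <- function(name, res, chain, resno, x, y, z, element = NULL) {
  data.frame(serial = 0L, name = name,
             element = element %||% toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1)),
             residue_name = res, chain_id = chain, residue_number = resno,
             insertion_code = "", x = x, y = y, z = z,
             occupancy = 1, altloc = "", het = FALSE,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- independent signature oracle -----------------------------------------
# naive O(n^2 * classes * bins) counter, written independently of
# compute_signature: explicit loops over atom pairs and label sets
oracle_signature <- function(st, env_idx, labels, config = signature_config()) {
  cuts <- seq(config$d_min + config$d_step, config$d_max, by = config$d_step)
  cls <- pharmacophore_classes()
  out <- numeric(0)
  nm <- character(0)
  xyz <- as.matrix(st$atoms[env_idx, c("x", "y", "z")])
  lab <- labels[env_idx]
  n <- length(env_idx)
  for (i in seq_along(cls)) for (j in i:length(cls)) {
    counts <- numeric(length(cuts))
    if (n >= 2) {
      for (a in 1:(n - 1)) for (b in (a + 1):n) {
        match_pair <- (cls[i] %in% lab[[a]] && cls[j] %in% lab[[b]]) ||
                      (cls[j] %in% lab[[a]] && cls[i] %in% lab[[b]])
        if (!match_pair) next
        d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
        for (k in seq_along(cuts)) if (d <= cuts[k]) counts[k] <- counts[k] + 1
      }
    }
    out <- c(out, counts)
    nm <- c(nm, sprintf("sig:%s:%s:<=%g", cls[i], cls[j], cuts))
  }
  names(out) <- nm
  out
}

## ---- independent interaction oracle ---------------------------------------
# straight-line re-implementation of the documented geometric criteria with
# its own radii copies and per-pair loops; counts per type
oracle_interaction_counts <- function(st, scope = "site", site = NULL,
                                      labels = NULL) {
  if (is.null(labels)) labels <- assign_pharmacophores(st)
  cfg <- interaction_config()
  a <- st$atoms
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
  cov <- c(C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)

  if (scope == "inter") {
    pa <- which(st$chains[a$chain_id] == "protein")
    pb <- which(st$chains[a$chain_id] == "nucleic")
  } else {
    pa <- which(a$chain_id == site$chain_id &
                  a$residue_number == site$residue_number)
    pb <- setdiff(seq_len(n), pa)
  }
  # covalent adjacency for donor-angle checks
  bonded <- function(i) {
    out <- integer(0)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      ra <- cov[a$element[i]]; if (is.na(ra)) ra <- 0.77
      rb <- cov[a$element[j]]; if (is.na(rb)) rb <- 0.77
      if (d > 0.1 && d <= ra + rb + 0.4) out <- c(out, j)
    }
    out
  }
  angle_ok <- function(donor, acc) {
    ante <- setdiff(bonded(donor), acc)
    if (length(ante) == 0) return(TRUE)
    for (q in ante) {
      v1 <- xyz[acc, ] - xyz[donor, ]
      v2 <- xyz[q, ] - xyz[donor, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < 90) return(FALSE)
    }
    TRUE
  }
  is_acc <- function(l) any(c("acceptor", "phosphate") %in% l)

  counts <- stats::setNames(integer(13), interaction_types())
  seen <- character(0)
  for (i in pa) for (j in pb) {
    if (i == j) next
    key <- paste(min(i, j), max(i, j))
    if (key %in% seen) next
    if (a$chain_id[i] == a$chain_id[j] &&
        a$residue_number[i] == a$residue_number[j] &&
        a$insertion_code[i] == a$insertion_code[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > 5.5) next
    seen <- c(seen, key)
    li <- labels[[i]]; lj <- labels[[j]]
    ei <- a$element[i]; ej <- a$element[j]
    rvi <- vdw[ei]; if (is.na(rvi)) rvi <- 1.70
    rvj <- vdw[ej]; if (is.na(rvj)) rvj <- 1.70
    rci <- cov[ei]; if (is.na(rci)) rci <- 0.77
    rcj <- cov[ej]; if (is.na(rcj)) rcj <- 0.77
    hit <- FALSE
    if (d <= rci + rcj + 0.4) { counts["covalent"] <- counts["covalent"] + 1; hit <- TRUE }
    else if (d < rvi + rvj - 0.5) { counts["clash"] <- counts["clash"] + 1; hit <- TRUE }
    else if (d < rvi + rvj) { counts["vdw_clash"] <- counts["vdw_clash"] + 1; hit <- TRUE }
    else if (d <= rvi + rvj + 0.5) { counts["vdw"] <- counts["vdw"] + 1; hit <- TRUE }
    if (d <= 3.5 &&
        (("donor" %in% li && is_acc(lj) && angle_ok(i, j)) ||
         ("donor" %in% lj && is_acc(li) && angle_ok(j, i)))) {
      counts["hbond"] <- counts["hbond"] + 1; hit <- TRUE
    }
    if (d <= 3.8 && ((ei == "C" && is_acc(lj)) || (ej == "C" && is_acc(li)))) {
      counts["weak_hbond"] <- counts["weak_hbond"] + 1; hit <- TRUE
    }
    if (d <= 4.0 &&
        (("positive" %in% li && "negative" %in% lj) ||
         ("negative" %in% li && "positive" %in% lj) ||
         ("positive" %in% li && "phosphate" %in% lj && ej == "O") ||
         ("positive" %in% lj && "phosphate" %in% li && ei == "O"))) {
      counts["ionic"] <- counts["ionic"] + 1; hit <- TRUE
    }
    if (d <= 4.5 && ei == "C" && ej == "C" &&
        "hydrophobic" %in% li && "hydrophobic" %in% lj) {
      counts["hydrophobic"] <- counts["hydrophobic"] + 1; hit <- TRUE
    }
    co <- c("O", "OXT", "OD1", "OE1", "O2", "O4", "O6")
    cc <- c("C", "CG", "CD", "C2", "C4", "C6")
    if (d <= 3.6 && ((a$name[i] %in% co && a$name[j] %in% cc) ||
                     (a$name[j] %in% co && a$name[i] %in% cc))) {
      counts["carbonyl"] <- counts["carbonyl"] + 1; hit <- TRUE
    }
    if (d <= 3.5 && ((ei %in% c("CL", "BR", "I") && is_acc(lj)) ||
                     (ej %in% c("CL", "BR", "I") && is_acc(li)))) {
      counts["halogen_bond"] <- counts["halogen_bond"] + 1; hit <- TRUE
    }
    mets <- c("ZN", "MG", "CA", "MN", "FE", "NA", "K", "CU", "NI", "CO")
    if (d <= 2.8 && ((ei %in% mets && ej %in% c("O", "N", "S")) ||
                     (ej %in% mets && ei %in% c("O", "N", "S")))) {
      counts["metal"] <- counts["metal"] + 1; hit <- TRUE
    }
    if (!hit && d <= 5.0) counts["proximal"] <- counts["proximal"] + 1
  }
  # aromatic ring-centroid pairs across the two sides
  rings <- list()
  ringdefs <- list(PHE = c("CG","CD1","CD2","CE1","CE2","CZ"),
                   TYR = c("CG","CD1","CD2","CE1","CE2","CZ"),
                   TRP = c("CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
                   HIS = c("CG","ND1","CD2","CE1","NE2"))
  purines <- c("DA","DG","A","G"); pyrs <- c("DC","DT","DU","C","T","U")
  reskey <- paste(a$chain_id, a$residue_number, a$insertion_code)
  for (rk in unique(reskey)) {
    idx <- which(reskey == rk)
    rn <- a$residue_name[idx[1]]
    def <- ringdefs[[rn]]
    if (is.null(def) && rn %in% purines)
      def <- c("N1","C2","N3","C4","C5","C6","N7","C8","N9")
    if (is.null(def) && rn %in% pyrs) def <- c("N1","C2","N3","C4","C5","C6")
    if (is.null(def)) next
    ridx <- idx[a$name[idx] %in% def]
    if (length(ridx) >= 3)
      rings[[length(rings) + 1]] <- list(idx = ridx,
                                         c = colMeans(xyz[ridx, , drop = FALSE]))
  }
  if (length(rings) >= 2) {
    for (p in seq_along(rings)) for (q in seq_along(rings)) {
      if (p >= q) next
      pa_hit <- any(rings[[p]]$idx %in% pa); pb_hit <- any(rings[[p]]$idx %in% pb)
      qa_hit <- any(rings[[q]]$idx %in% pa); qb_hit <- any(rings[[q]]$idx %in% pb)
      if (!((pa_hit && qb_hit) || (qa_hit && pb_hit))) next
      if (sqrt(sum((rings[[p]]$c - rings[[q]]$c)^2)) <= 5.0)
        counts["aromatic"] <- counts["aromatic"] + 1
    }
  }
  counts
}

# brute-force minimum residue-to-NA distance
oracle_min_dist <- function(st, chain, resno) {
  a <- st$atoms
  ridx <- which(a$chain_id == chain & a$residue_number == resno)
  nidx <- which(st$chains[a$chain_id] == "nucleic")
  best <- Inf
  for (i in ridx) for (j in nidx) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d < best) best <- d
  }
  best
}
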