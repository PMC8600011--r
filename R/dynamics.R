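## Anisotropic elastic-network normal mode analysis of the complex and the
## vibrational-entropy change upon mutation.  Nodes are either C-alpha
## (protein) plus P (nucleic) atoms, or all heavy atoms; springs of uniform
## stiffness connect node pairs within a cutoff.  Only entropy differences
## between wild-type and mutant enter the feature vector, so the entropy is
## expressed in model units.

#' Build an anisotropic elastic network for a complex
#'
#' @param structure A `ComplexStructure`.
#' @param cutoff Spring cutoff in Angstrom (default 10).
#' @param mode Node selection: `"calpha"` (protein C-alpha + nucleic P) or
#'   `"heavy"` (all heavy atoms).
#' @param gamma Spring constant (model units, default 1).
#' @return An `ElasticNetwork`: list with `nodes` (coordinate matrix),
#'   `hessian` (3N x 3N symmetric), `cutoff`, `gamma`, `n_springs`.
#' @export
build_enm <- function(structure, cutoff = 10, mode = c("calpha", "heavy"),
                      gamma = 1) {
  mode <- match.arg(mode)
  a <- structure$atoms
  if (mode == "calpha") {
    cls <- structure$chains[a$chain_id]
    sel <- (cls == "protein" & a$name == "CA") |
           (cls == "nucleic" & a$name == "P")
    nodes <- .coords(structure)[sel, , drop = FALSE]
  } else {
    nodes <- .coords(structure)
  }
  n <- nrow(nodes)
  if (n < 2L) stop("elastic network needs at least 2 nodes")

  D <- .cross_dist(nodes, nodes)
  H <- matrix(0, 3 * n, 3 * n)
  n_springs <- 0L
  for (i in seq_len(n - 1L)) {
    js <- which(D[i, ] <= cutoff & seq_len(n) > i)
    for (j in js) {
      dv <- nodes[j, ] - nodes[i, ]
      d2 <- sum(dv * dv)
      if (d2 < 1e-12) next
      blk <- -gamma * tcrossprod(dv) / d2
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      H[ri, rj] <- H[ri, rj] + blk
      H[rj, ri] <- H[rj, ri] + blk
      H[ri, ri] <- H[ri, ri] - blk
      H[rj, rj] <- H[rj, rj] - blk
      n_springs <- n_springs + 1L
    }
  }
  if (n_springs == 0L) warning("elastic network has no springs")
  structure(list(nodes = nodes, hessian = H, cutoff = cutoff, gamma = gamma,
                 n_springs = n_springs),
            class = "ElasticNetwork")
}

#' Normal modes of an elastic network
#'
#' @param enm An [build_enm()] result.
#' @param zero_tol Eigenvalues below `zero_tol * max(eigenvalue)` are treated
#'   as rigid-body (zero) modes.
#' @return An `NMAResult`: list with `eigenvalues` (ascending), `n_zero`,
#'   `s_vib` where `s_vib = -0.5 * sum(log(lambda))` over nonzero modes.
#' @export
enm_modes <- function(enm, zero_tol = 1e-8) {
  ev <- eigen(enm$hessian, symmetric = TRUE, only.values = TRUE)$values
  ev <- rev(ev)              # ascending
  ev[ev < 0] <- 0            # numerical noise on the PSD spectrum
  lmax <- max(ev)
  if (lmax <= 0) {
    nz <- numeric(0)
  } else {
    nz <- ev[ev > zero_tol * lmax]
  }
  n_zero <- length(ev) - length(nz)
  # disconnected networks leave extra zero modes; entropy uses nonzero only
  if (length(nz) == 0L) {
    s <- NA_real_
    warning("elastic network has no nonzero modes")
  } else {
    s <- -0.5 * sum(log(nz))
  }
  structure(list(eigenvalues = ev, n_zero = n_zero, s_vib = s),
            class = "NMAResult")
}

#' Vibrational-entropy change upon mutation
#'
#' Builds elastic networks for the wild-type and mutant complexes on the same
#' node-selection rule and returns `s_vib(mutant) - s_vib(wild)`.  Under
#' C-alpha/P coarse-graining a side-chain replacement leaves the network
#' unchanged, so the default for featurization is the all-heavy-atom mode.
#'
#' @param wild,mutant `ComplexStructure`s.
#' @param cutoff Spring cutoff in Angstrom.
#' @param mode `"heavy"` (default) or `"calpha"`.
#' @param require_equal_nodes For `"calpha"`: error when the coarse-grained
#'   node counts differ (a point mutation must not change them).
#' @return Scalar `delta_s_vib` (model units).
#' @export
vibrational_entropy_change <- function(wild, mutant, cutoff = 10,
                                       mode = c("heavy", "calpha"),
                                       require_equal_nodes = (mode[1] == "calpha")) {
  mode <- match.arg(mode)
  if (require_equal_nodes) {
    ew <- build_enm(wild, cutoff, mode)
    em <- build_enm(mutant, cutoff, mode)
    if (nrow(ew$nodes) != nrow(em$nodes)) {
      stop(sprintf("node count mismatch: wild %d vs mutant %d",
                   nrow(ew$nodes), nrow(em$nodes)))
    }
    return(enm_modes(em)$s_vib - enm_modes(ew)$s_vib)
  }
  .svib_cached(mutant, cutoff, mode) - .svib_cached(wild, cutoff, mode)
}

# memoized s_vib; repeated featurization of mutations on one wild-type
# complex recomputes the wild spectrum only once.  The key fingerprints the
# coordinates, so structures edited in place are still recomputed.
.svib_cached <- function(structure, cutoff, mode) {
  xyz <- .coords(structure)
  key <- paste(structure$id, nrow(xyz), sprintf("%.4f", sum(xyz)),
               cutoff, mode)
  if (is.null(.pkg_env$svib)) .pkg_env$svib <- new.env(parent = emptyenv())
  hit <- .pkg_env$svib[[key]]
  if (!is.null(hit)) return(hit)
  val <- enm_modes(build_enm(structure, cutoff, mode))$s_vib
  # bounded cache
  if (length(ls(.pkg_env$svib)) > 2000L) {
    rm(list = ls(.pkg_env$svib), envir = .pkg_env$svib)
  }
  .pkg_env$svib[[key]] <- val
  val
}
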