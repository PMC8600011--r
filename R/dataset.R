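## Affinity-record handling: mutation-string grammar, Kd -> ddG conversion,
## reverse-mutation augmentation, direction/neutral labelling, hot-spot
## labelling, additive-vs-synergistic classification and dataset CSV I/O.
##
## Sign convention throughout: ddG = dG(wild-type) - dG(mutant), in
## kcal/mol; negative values destabilize (reduce affinity).

# gas constant, kcal/(mol K)
.R_KCAL <- 1.98720425e-3

#' Parse a mutation construct string
#'
#' Grammar: `CONSTRUCT := SPEC (';' SPEC)*`;
#' `SPEC := CHAIN ' ' WT NUM[ICODE] MUT`, e.g. `"A R45G"` or
#' `"A R45G;A K50A"` for a double mutant.  Whitespace around `';'` is
#' tolerated.
#'
#' @param text Construct string.
#' @return A `MutationConstruct`: data frame with columns `chain_id`, `wt`,
#'   `residue_number`, `insertion_code`, `mut`, one row per point mutation.
#' @export
parse_mutation_string <- function(text) {
  if (is.null(text) || !nzchar(trimws(text))) {
    stop("parse error: empty mutation string")
  }
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  specs <- lapply(seq_along(parts), function(i) {
    p <- parts[i]
    m <- regmatches(p, regexec(
      "^([A-Za-z0-9]) ([A-Z])([0-9]+)([A-Za-z]?)([A-Z])$", p))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("parse error in mutation %d ('%s'): expected 'CHAIN WTnumMUT'",
                   i, p))
    }
    icode <- m[5]
    # a trailing lowercase letter before the mutant code is an insertion code;
    # uppercase insertion codes cannot be distinguished from the mutant letter
    # and must use the explicit column form of the dataset CSV
    data.frame(chain_id = m[2], wt = m[3],
               residue_number = as.integer(m[4]),
               insertion_code = toupper(icode), mut = m[6],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, specs)
  bad <- !(out$wt %in% .AA1) | !(out$mut %in% .AA1)
  if (any(bad)) {
    stop("validation error: non-standard amino acid in ",
         paste(parts[bad], collapse = ", "))
  }
  if (any(out$wt == out$mut)) {
    stop("validation error: wild-type equals mutant in ",
         paste(parts[out$wt == out$mut], collapse = ", "))
  }
  key <- paste(out$chain_id, out$residue_number, out$insertion_code)
  if (anyDuplicated(key)) {
    stop("validation error: duplicate site in construct: ", text)
  }
  class(out) <- c("MutationConstruct", "data.frame")
  out
}

#' Format a MutationConstruct back into its string form
#' @param construct A `MutationConstruct`.
#' @return Construct string, e.g. `"A R45G;A K50A"`.
#' @export
format_mutation_string <- function(construct) {
  paste(sprintf("%s %s%d%s%s", construct$chain_id, construct$wt,
                construct$residue_number,
                tolower(construct$insertion_code), construct$mut),
        collapse = ";")
}

#' Convert dissociation constants to a binding ddG
#'
#' `dG = R T ln(Kd)`, so
#' `ddG = dG_wt - dG_mut = R T ln(kd_wt / kd_mut)` with
#' R = 1.98720425e-3 kcal/(mol K).
#'
#' @param kd_wt,kd_mut Dissociation constants in molar; must be positive.
#' @param temperature Kelvin (default 298.15).
#' @return ddG in kcal/mol.
#' @export
kd_to_ddg <- function(kd_wt, kd_mut, temperature = 298.15) {
  if (any(kd_wt <= 0) || any(kd_mut <= 0)) {
    stop("domain error: Kd must be positive")
  }
  .R_KCAL * temperature * log(kd_wt / kd_mut)
}

#' Augment a dataset with hypothetical reverse mutations
#'
#' ddG is a state function, so the mutant-to-wild-type change is the exact
#' negation of the forward change.  Reverse records are appended only for
#' forward single-point records with `ddg >= -2` kcal/mol (inclusive):
#' strongly destabilizing mutations imply structural changes a modelled
#' mutant cannot be trusted to capture.  Reverse records keep the forward
#' record's group so cross-validation never separates the pair.
#'
#' @param dataset Data frame with at least `complex_id`, `construct`, `ddg`,
#'   `group_id` (see [read_affinity_csv()]); multi-point rows are passed
#'   through unaugmented.
#' @param ddg_min Reverse-eligibility threshold (-2 kcal/mol, inclusive).
#' @return Dataset with appended reverse rows: `provenance = "reverse"`,
#'   negated ddg, wild-type/mutant letters swapped in the construct,
#'   `partner` giving the forward row index.
#' @export
augment_with_reverse <- function(dataset, ddg_min = -2.0) {
  ds <- dataset
  if (is.null(ds$provenance)) ds$provenance <- "experimental"
  ds$partner <- NA_integer_
  is_single <- !grepl(";", ds$construct, fixed = TRUE)
  eligible <- which(is_single & ds$provenance == "experimental" &
                      ds$ddg >= ddg_min)
  if (length(eligible) == 0L) return(ds)
  rev_rows <- ds[eligible, , drop = FALSE]
  rev_rows$ddg <- -rev_rows$ddg
  rev_rows$provenance <- "reverse"
  rev_rows$partner <- eligible
  rev_rows$construct <- vapply(rev_rows$construct, function(s) {
    con <- parse_mutation_string(s)
    tmp <- con$wt; con$wt <- con$mut; con$mut <- tmp
    format_mutation_string(con)
  }, character(1))
  out <- rbind(ds, rev_rows)
  rownames(out) <- NULL
  out
}

#' Label the direction of an affinity change
#'
#' @param ddg Numeric vector, kcal/mol.
#' @param band Half-width of the neutral band (0.5 kcal/mol; both
#'   boundaries neutral).
#' @return Character vector: `"increasing"` (ddg > band), `"neutral"`
#'   (|ddg| <= band) or `"decreasing"` (ddg < -band).
#' @export
label_direction <- function(ddg, band = 0.5) {
  stopifnot(all(is.finite(ddg)))
  ifelse(ddg > band, "increasing",
         ifelse(ddg < -band, "decreasing", "neutral"))
}

#' Hot-spot labelling for alanine-scanning records
#'
#' Follows the alanine-scanning benchmark convention: only single-point
#' mutations to alanine are classifiable; a residue is a hot-spot when its
#' alanine mutation has `ddg <= cutoff`.
#'
#' @param construct Construct strings.
#' @param ddg kcal/mol.
#' @param cutoff Hot-spot threshold, kcal/mol (common choices: -2 or -1).
#' @return Character vector: `"hot-spot"`, `"non-hot-spot"` or
#'   `"not-applicable"` (multi-point or non-alanine records).
#' @export
label_hotspot <- function(construct, ddg, cutoff = -2.0) {
  vapply(seq_along(construct), function(i) {
    if (grepl(";", construct[i], fixed = TRUE)) return("not-applicable")
    con <- parse_mutation_string(construct[i])
    if (con$mut != "A") return("not-applicable")
    if (ddg[i] <= cutoff) "hot-spot" else "non-hot-spot"
  }, character(1))
}

#' Classify a multiple-point mutation as additive or synergistic
#'
#' Compares the construct's ddG with the sum of its single-point components:
#' `D = |ddg_multi - sum(ddg_singles)|`.  Additive when `D < 0.2` kcal/mol
#' (absolute criterion) or `D < 0.10 * |sum(ddg_singles)|` (relative
#' criterion; the denominator is the summed single effects).
#'
#' @param multi_ddg ddG of the multi-point construct (kcal/mol).
#' @param single_ddgs ddGs of all its single-point components.
#' @param criterion `"abs_0.2"` or `"rel_10pct"`.
#' @return `"additive"` or `"synergistic"`.
#' @export
classify_additivity <- function(multi_ddg, single_ddgs,
                                criterion = c("abs_0.2", "rel_10pct")) {
  criterion <- match.arg(criterion)
  if (length(single_ddgs) < 1L || any(!is.finite(single_ddgs))) {
    stop("not-classifiable: missing single-point components")
  }
  s <- sum(single_ddgs)
  D <- abs(multi_ddg - s)
  additive <- if (criterion == "abs_0.2") D < 0.2 else D < 0.10 * abs(s)
  if (additive) "additive" else "synergistic"
}

#' Read / write the affinity dataset CSV
#'
#' Columns: `complex_id`, `construct` (mutation-string grammar), `ddg`
#' (kcal/mol), `na_kind` (ssDNA/dsDNA/ssRNA/dsRNA), optional `provenance`,
#' `group_id`, `kd_wt`, `kd_mut`, `temperature`.  Records with Kd columns
#' but no ddg are converted via [kd_to_ddg()].  A missing `group_id`
#' defaults to the complex id, keeping every complex (and every
#' forward/reverse pair) within one cross-validation group.
#'
#' @param path CSV file path.
#' @return Data frame of affinity records.
#' @export
read_affinity_csv <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex_id", "construct")
  if (!all(need %in% names(ds))) {
    stop("dataset CSV must contain columns: ", paste(need, collapse = ", "))
  }
  if (is.null(ds$ddg)) ds$ddg <- NA_real_
  if (!is.null(ds$kd_wt) && !is.null(ds$kd_mut)) {
    temp <- if (is.null(ds$temperature)) rep(298.15, nrow(ds)) else
      ifelse(is.na(ds$temperature), 298.15, ds$temperature)
    fill <- is.na(ds$ddg) & !is.na(ds$kd_wt) & !is.na(ds$kd_mut)
    ds$ddg[fill] <- kd_to_ddg(ds$kd_wt[fill], ds$kd_mut[fill], temp[fill])
  }
  if (any(!is.finite(ds$ddg))) stop("dataset contains non-finite ddg values")
  if (is.null(ds$provenance)) ds$provenance <- "experimental"
  if (is.null(ds$group_id)) ds$group_id <- ds$complex_id
  invisible(lapply(ds$construct, parse_mutation_string))  # validate grammar
  ds
}

#' @rdname read_affinity_csv
#' @param dataset Data frame of affinity records.
#' @export
write_affinity_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
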