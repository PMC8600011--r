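## Pharmacophore atom typing.  Protein atoms carry one or more of seven
## physicochemical classes (aromatic, hydrophobic, negative, positive,
## donor, acceptor, neutral); nucleic-acid atoms carry exactly one component
## class (phosphate, sugar, base_purine or base_pyrimidine).  The protein
## table ships as a plain-text resource and can be replaced by the user.

.PROTEIN_CLASSES <- c("aromatic", "hydrophobic", "negative", "positive",
                      "donor", "acceptor", "neutral")
.NA_CLASSES <- c("phosphate", "sugar", "base_purine", "base_pyrimidine")

#' The eleven pharmacophore classes, in canonical order
#' @return Character vector of class names.
#' @export
pharmacophore_classes <- function() c(.PROTEIN_CLASSES, .NA_CLASSES)

# cached packaged table
.pkg_env <- new.env(parent = emptyenv())

#' Load a pharmacophore lookup table
#'
#' @param path Path to a CSV with columns `residue`, `atom`, `classes`
#'   (classes separated by `|`).  Default is the table packaged with the
#'   package, which covers every heavy atom of the 20 standard amino acids.
#' @return Data frame with columns residue, atom, classes.
#' @export
load_pharmacophore_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_env$pharma_table)) return(.pkg_env$pharma_table)
    path <- system.file("extdata", "pharmacophore_protein.csv",
                        package = "nabind", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .pkg_env$pharma_table <- tab
    return(tab)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# phosphate atoms by name convention; primed atoms are sugar
.PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O5'", "O3'")

#' Assign pharmacophore classes to every atom of a complex
#'
#' Protein atoms are looked up in the packaged residue/atom table; atoms
#' absent from the table receive `neutral`.  Nucleic-acid atoms are labelled
#' by atom-name convention: P/OP1/OP2/OP3/O5'/O3' are `phosphate`, other
#' primed atoms are `sugar`, base atoms are `base_purine` or
#' `base_pyrimidine` according to the residue.  Labels depend only on
#' residue and atom names, never on coordinates.
#'
#' @param structure A `ComplexStructure`.
#' @param table Optional replacement protein table
#'   (see [load_pharmacophore_table()]).
#' @return List of character vectors, one per atom, each a subset of
#'   [pharmacophore_classes()].
#' @export
assign_pharmacophores <- function(structure, table = NULL) {
  tab <- if (is.null(table)) load_pharmacophore_table() else table
  a <- structure$atoms
  cls <- structure$chains[a$chain_id]
  key <- paste(a$residue_name, a$name)
  tab_key <- paste(tab$residue, tab$atom)
  hit <- match(key, tab_key)

  labels <- vector("list", nrow(a))
  unknown <- character(0)
  for (i in seq_len(nrow(a))) {
    if (cls[i] == "nucleic" || a$residue_name[i] %in% .NUC_ALL) {
      labels[[i]] <- .na_atom_class(a$name[i], a$residue_name[i])
    } else if (!is.na(hit[i])) {
      labels[[i]] <- strsplit(tab$classes[hit[i]], "|", fixed = TRUE)[[1]]
    } else {
      labels[[i]] <- "neutral"
      unknown <- c(unknown, a$residue_name[i])
    }
  }
  if (length(unknown) > 0L) {
    message("pharmacophore: atoms of non-standard residue(s) ",
            paste(unique(unknown), collapse = ", "), " labelled neutral")
  }
  labels
}

.na_atom_class <- function(name, residue_name) {
  if (name %in% .PHOSPHATE_ATOMS) return("phosphate")
  if (grepl("'", name, fixed = TRUE)) return("sugar")
  if (residue_name %in% .NUC_PURINE) return("base_purine")
  if (residue_name %in% .NUC_PYRIMIDINE) return("base_pyrimidine")
  "sugar"  # unknown nucleotide fallback: treat as backbone
}
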