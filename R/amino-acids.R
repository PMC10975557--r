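# Canonical 18-amino-acid dictionary and reference intake distribution.
# Shares are percentages of total dietary amino acids; the canonical order
# is the conventional reporting order (isoleucine ... serine).

.aa_codebook <- function() {
  tibble::tibble(
    amino_acid = c(
      "isoleucine", "leucine", "lysine", "methionine", "cysteine",
      "phenylalanine", "tyrosine", "threonine", "tryptophan", "valine",
      "histidine", "arginine", "alanine", "aspartic acid", "glutamic acid",
      "glycine", "proline", "serine"
    ),
    abbrev = c(
      "ILE", "LEU", "LYS", "MET", "CYS", "PHE", "TYR", "THR", "TRP",
      "VAL", "HIS", "ARG", "ALA", "ASP", "GLU", "GLY", "PRO", "SER"
    )
  )
}

#' Canonical amino-acid labels
#'
#' The 18 dietary amino acids distinguished by the food-composition database
#' underlying the intake estimates, in canonical reporting order. All package
#' outputs report components in this order regardless of the pivot ordering
#' used internally.
#'
#' @return A tibble with columns `amino_acid` (full name) and `abbrev`
#'   (three-letter code, `ILE` ... `SER`).
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() .aa_codebook()

#' Reference amino-acid intake distribution
#'
#' Summary of the dietary amino-acid composition (percent of total amino
#' acids) in a population of Japanese adolescents: per-component geometric
#' means, arithmetic means, and standard deviations. These values calibrate
#' the default synthetic-cohort generator ([generator_config()]) and provide
#' the reference point used in worked examples.
#'
#' @return A tibble with columns `amino_acid`, `abbrev`, `geometric_mean`,
#'   `arithmetic_mean`, `sd` (all share columns in percent of total amino
#'   acids).
#' @export
#' @examples
#' aa_reference()
aa_reference <- function() {
  out <- .aa_codebook()
  out$geometric_mean <- c(
    4.56, 8.24, 6.85, 2.47, 1.55, 4.66, 3.66, 4.10, 1.23, 5.39,
    3.47, 5.65, 4.99, 9.36, 18.68, 4.21, 6.10, 4.84
  )
  out$arithmetic_mean <- c(
    4.56, 8.24, 6.85, 2.47, 1.55, 4.66, 3.66, 4.10, 1.23, 5.39,
    3.47, 5.64, 4.99, 9.36, 18.68, 4.21, 6.10, 4.84
  )
  out$sd <- c(
    0.10, 0.18, 0.43, 0.09, 0.10, 0.09, 0.07, 0.10, 0.03, 0.13,
    0.23, 0.36, 0.27, 0.36, 0.90, 0.30, 0.55, 0.13
  )
  out
}

#' Side-chain groups of amino acids
#'
#' Partition of the 18 amino acids by side-chain class: branched-chain
#' (BCAA), aromatic, sulfur, and all others. Used by the grouped
#' (amalgamated) 4-part analysis.
#'
#' @return A named list of character vectors of component abbreviations,
#'   together forming a partition of `amino_acids()$abbrev`.
#' @export
#' @examples
#' aa_groups()
aa_groups <- function() {
  list(
    BCAA     = c("ILE", "LEU", "VAL"),
    aromatic = c("PHE", "TYR", "TRP"),
    sulfur   = c("MET", "CYS"),
    other    = c("LYS", "THR", "HIS", "ARG", "ALA", "ASP", "GLU", "GLY",
                 "PRO", "SER")
  )
}

# Resolve user-supplied component labels (abbreviations or full names, any
# case) to canonical abbreviations. Errors on unknown labels.
.aa_normalize <- function(labels) {
  cb <- .aa_codebook()
  idx <- match(toupper(labels), cb$abbrev)
  full <- match(tolower(labels), cb$amino_acid)
  idx[is.na(idx)] <- full[is.na(idx)]
  if (anyNA(idx)) {
    abort(paste0(
      "unknown amino-acid label(s): ",
      paste(labels[is.na(idx)], collapse = ", ")
    ))
  }
  cb$abbrev[idx]
}

# Locate the composition columns of a cohort table, accepting abbreviations
# or full names; returns the actual column names in canonical order.
.aa_find_columns <- function(data, cols = NULL) {
  cb <- .aa_codebook()
  if (is.null(cols)) {
    nm <- names(data)
    hit_ab <- nm[toupper(nm) %in% cb$abbrev]
    hit_full <- nm[tolower(nm) %in% cb$amino_acid]
    cols <- union(hit_ab, hit_full)
    if (length(cols) == 0L) {
      abort("no amino-acid share columns found in `data`")
    }
  }
  key <- .aa_normalize(cols)
  cols[order(match(key, cb$abbrev))]
}
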