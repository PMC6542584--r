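# Filtering and canonicalization of de novo peptide lists before comparison.
#
# Degraded shell proteomes are matched under two equivalence classes:
# isoleucine/leucine (isobaric, indistinguishable by standard MS/MS) and
# deamidation (N -> D, Q -> E; +0.984 Da), which is pervasive in ancient
# samples and frequently reported by de novo engines as the converted
# residue. Mapping the residues, rather than tracking annotations, makes
# matching insensitive to whichever convention produced the list.

#' Filter a peptide table on ALC score
#'
#' Removes rows whose Average of Local Confidence (ALC) falls below the
#' threshold. The threshold is inclusive: `alc == min_alc` is retained.
#'
#' @param t a `peptide_table`.
#' @param min_alc minimum ALC percentage (default 50).
#' @return the filtered `peptide_table`, order preserved.
#' @export
filter_alc <- function(t, min_alc = 50) {
  validate_peptide_table(t)
  out <- t[t$alc >= min_alc, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(t)
  out
}

#' Remove contaminant-derived peptides
#'
#' Drops every peptide whose canonical form (I/L equivalence only) is a
#' substring of any contaminant sequence under the same equivalence.
#' Substring matching is deliberately enzyme-agnostic and conservative:
#' a cRAP-style contaminant removes all of its subsequences regardless of
#' how they were generated.
#'
#' @param t a `peptide_table`.
#' @param contaminants a `reference_set` of contaminant sequences.
#' @return the filtered `peptide_table`.
#' @export
filter_contaminants <- function(t, contaminants) {
  validate_peptide_table(t)
  validate_reference_set(contaminants)
  if (nrow(t) == 0 || nrow(contaminants) == 0) return(t)
  cont <- chartr("I", "L", contaminants$sequence)
  pep <- chartr("I", "L", t$peptide)
  hit <- vapply(pep, function(p) {
    any(vapply(cont, function(s) grepl(p, s, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  out <- t[!hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(t)
  out
}

#' Canonicalize a peptide or protein sequence
#'
#' Applies the matching equivalence classes: I -> L when `il_equiv`, and the
#' deamidation products N -> D, Q -> E when `deam_tolerant`. Idempotent and
#' deterministic; with both flags off it is the identity.
#'
#' @param x character vector of uppercase standard-alphabet sequences.
#' @param il_equiv collapse I and L (default `TRUE`).
#' @param deam_tolerant collapse N/D and Q/E (default `TRUE`).
#' @return character vector of canonical sequences.
#' @export
canonicalize <- function(x, il_equiv = TRUE, deam_tolerant = TRUE) {
  ok <- is_standard_seq(x)
  if (!all(ok)) {
    stop2("non-standard residue in sequence '", x[!ok][1], "'")
  }
  if (il_equiv) x <- chartr("I", "L", x)
  if (deam_tolerant) x <- chartr("NQ", "DE", x)
  x
}

#' Collapse a sample's peptides to unique canonical sequences
#'
#' Builds the unique canonical peptide list used by list-similarity scoring
#' and reference matching: one record per distinct canonical string of length
#' at least `min_len`, with the number of collapsed observations and the
#' maximum ALC among them.
#'
#' @param t a `peptide_table`.
#' @param sample_id sample to collapse; must be present in `t`.
#' @param min_len minimum canonical peptide length (default 6; shorter
#'   strings match references by chance).
#' @param il_equiv,deam_tolerant equivalence settings, see [canonicalize()].
#' @return a `canonical_peptides` data.frame with columns `canonical`,
#'   `source_count`, `max_alc`; the sample id is kept in the
#'   `"sample_id"` attribute.
#' @export
collapse_peptides <- function(t, sample_id, min_len = 6, il_equiv = TRUE,
                              deam_tolerant = TRUE) {
  validate_peptide_table(t)
  if (!sample_id %in% t$sample_id) {
    stop2("unknown sample_id: ", sample_id)
  }
  rows <- t[t$sample_id == sample_id, , drop = FALSE]
  canon <- canonicalize(rows$peptide, il_equiv, deam_tolerant)
  keep <- nchar(canon) >= min_len
  canon <- canon[keep]
  alc <- rows$alc[keep]
  if (length(canon) == 0) {
    out <- data.frame(canonical = character(), source_count = integer(),
                      max_alc = numeric())
  } else {
    first <- !duplicated(canon)
    out <- data.frame(
      canonical = canon[first],
      source_count = as.integer(table(canon)[canon[first]]),
      max_alc = vapply(canon[first],
                       function(p) max(alc[canon == p]), numeric(1)),
      row.names = NULL
    )
  }
  attr(out, "sample_id") <- sample_id
  class(out) <- c("canonical_peptides", "data.frame")
  out
}

# Accept either a canonical_peptides data.frame or a bare character vector.
canonical_strings <- function(peps) {
  if (is.data.frame(peps)) {
    if (!"canonical" %in% names(peps)) {
      stop2("expected a 'canonical' column")
    }
    peps$canonical
  } else {
    as.character(peps)
  }
}
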