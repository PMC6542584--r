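# Substitution-tolerant mapping of canonical peptides onto reference
# proteins, per-residue coverage, tiered protein calls, and substitution
# calling with explicit ambiguity symbols.
#
# The placement rule is a deliberately hard-edged reconstruction of
# score-based substitution-tolerant search: a peptide is first placed at
# every exact substring occurrence across the reference set; only if it has
# no exact placement anywhere is a single internal mismatch allowed.
# Mismatches are forbidden at the first and last residue (terminal residues
# are the least reliable in de novo data) and for peptides shorter than
# `min_sub_len`. This keeps the search exhaustive, deterministic and
# testable against a brute-force oracle.

#' Place canonical peptides onto reference proteins
#'
#' @param peps a `canonical_peptides` data.frame (see [collapse_peptides()])
#'   or a character vector of canonical peptide strings.
#' @param refs a `reference_set`; sequences are canonicalized internally with
#'   the same equivalence settings as the peptides were.
#' @param max_subst maximum substitutions per peptide (0 or 1, default 1).
#' @param il_equiv,deam_tolerant equivalence settings used when the peptides
#'   were canonicalized, see [canonicalize()].
#' @param min_sub_len substitution tolerance is disabled for peptides shorter
#'   than this (default 6).
#' @return a data.frame with one row per placement: `peptide`, `entry_id`,
#'   `start`, `end` (1-based inclusive), `n_subst`, `sub_pos`, `sub_ref`,
#'   `sub_obs` (reference coordinates; `NA` when exact), and `unique`
#'   (`TRUE` iff all retained placements of that peptide lie in one entry).
#'   Rows are ordered by peptide, then mismatch count, leftmost start and
#'   entry input order.
#' @export
place_peptides <- function(peps, refs, max_subst = 1, il_equiv = TRUE,
                           deam_tolerant = TRUE, min_sub_len = 6) {
  validate_reference_set(refs)
  if (nrow(refs) == 0) stop2("empty reference set")
  if (!max_subst %in% c(0, 1)) stop2("max_subst must be 0 or 1")
  pep <- unique(canonical_strings(peps))
  seqs <- canonicalize(refs$sequence, il_equiv, deam_tolerant)
  empty <- data.frame(peptide = character(), entry_id = character(),
                      start = integer(), end = integer(),
                      n_subst = integer(), sub_pos = integer(),
                      sub_ref = character(), sub_obs = character(),
                      unique = logical())
  if (length(pep) == 0) return(empty)

  # Exact matching against one concatenated subject ('#' separator), then
  # map hit offsets back to entries.
  sep_cat <- paste(seqs, collapse = "#")
  offsets <- cumsum(c(0L, nchar(seqs) + 1L))[seq_along(seqs)]
  seq_ints <- lapply(seqs, utf8ToInt)

  rows <- vector("list", length(pep))
  for (k in seq_along(pep)) {
    p <- pep[k]
    n <- nchar(p)
    hits <- gregexpr(p, sep_cat, fixed = TRUE)[[1]]
    placements <- NULL
    if (hits[1] != -1L) {
      entry_idx <- findInterval(hits, offsets + 1L)
      start <- as.integer(hits - offsets[entry_idx])
      placements <- data.frame(
        peptide = p, entry_id = refs$entry_id[entry_idx],
        start = start, end = start + n - 1L,
        n_subst = 0L, sub_pos = NA_integer_,
        sub_ref = NA_character_, sub_obs = NA_character_,
        entry_order = entry_idx
      )
    } else if (max_subst >= 1 && n >= min_sub_len) {
      p_int <- utf8ToInt(p)
      sub_rows <- list()
      for (e in seq_along(seqs)) {
        L <- length(seq_ints[[e]])
        if (L < n) next
        # all length-n windows of the reference as a matrix, one row per
        # offset; internal single mismatches only
        w <- stats::embed(seq_ints[[e]], n)[, n:1, drop = FALSE]
        mism <- w != matrix(p_int, nrow(w), n, byrow = TRUE)
        cand <- which(rowSums(mism) == 1L)
        for (s in cand) {
          j <- which(mism[s, ])
          if (j == 1L || j == n) next
          sub_rows[[length(sub_rows) + 1L]] <- data.frame(
            peptide = p, entry_id = refs$entry_id[e],
            start = s, end = s + n - 1L, n_subst = 1L,
            sub_pos = s + j - 1L,
            sub_ref = intToUtf8(w[s, j]),
            sub_obs = substr(p, j, j),
            entry_order = e
          )
        }
      }
      if (length(sub_rows) > 0) placements <- do.call(rbind, sub_rows)
    }
    if (!is.null(placements)) {
      placements <- placements[order(placements$n_subst, placements$start,
                                     placements$entry_order), , drop = FALSE]
      placements$unique <- length(unique(placements$entry_id)) == 1L
      rows[[k]] <- placements
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$entry_order <- NULL
  rownames(out) <- NULL
  out
}

#' Per-residue coverage of reference proteins in one sample
#'
#' Depth is incremented once per placement per covered position; coverage is
#' the percentage of positions with depth of at least 1 (position presence,
#' not depth-weighted). Multi-mapping peptides contribute to the coverage of
#' all their entries but to the unique-peptide count of none.
#'
#' @param placements output of [place_peptides()].
#' @param refs the `reference_set` the placements refer to.
#' @param sample_id sample label recorded in each profile.
#' @return a list of coverage profiles, one per reference entry (including
#'   entries with no placements), each a list with `entry_id`, `sample_id`,
#'   `depth` (integer vector), `alt` (data.frame `pos`, `res` of mismatch
#'   observations), `coverage_pct`, `n_unique_peptides`, `n_peptides`.
#' @export
compute_coverage <- function(placements, refs, sample_id) {
  validate_reference_set(refs)
  bad <- !placements$entry_id %in% refs$entry_id
  if (any(bad)) {
    stop2("placement refers to unknown entry ", placements$entry_id[bad][1])
  }
  lens <- stats::setNames(nchar(refs$sequence), refs$entry_id)
  if (nrow(placements) > 0 &&
      any(placements$start < 1 | placements$end > lens[placements$entry_id])) {
    stop2("placement outside sequence bounds")
  }
  lapply(seq_len(nrow(refs)), function(i) {
    id <- refs$entry_id[i]
    L <- lens[[id]]
    depth <- integer(L)
    pl <- placements[placements$entry_id == id, , drop = FALSE]
    for (j in seq_len(nrow(pl))) {
      idx <- pl$start[j]:pl$end[j]
      depth[idx] <- depth[idx] + 1L
    }
    alt <- pl[pl$n_subst == 1L, c("sub_pos", "sub_obs"), drop = FALSE]
    names(alt) <- c("pos", "res")
    rownames(alt) <- NULL
    list(entry_id = id,
         sample_id = sample_id,
         depth = depth,
         alt = alt,
         coverage_pct = 100 * sum(depth >= 1L) / L,
         n_unique_peptides = length(unique(pl$peptide[pl$unique])),
         n_peptides = length(unique(pl$peptide)))
  })
}

#' Tiered protein calls from coverage profiles
#'
#' A protein is called at the stringent tier when supported by at least
#' `stringent_min` unique peptides, at the relaxed tier when supported by at
#' least `relaxed_min` (reports flag relaxed-only calls with an asterisk),
#' and is absent otherwise.
#'
#' @param profiles list of coverage profiles from [compute_coverage()].
#' @param stringent_min unique peptides for a stringent call (default 2).
#' @param relaxed_min unique peptides for a relaxed call (default 1).
#' @return a data.frame: `entry_id`, `sample_id`, `tier`
#'   (`"stringent"`/`"relaxed"`/`"absent"`), `n_unique_peptides`,
#'   `coverage_pct`.
#' @export
call_proteins <- function(profiles, stringent_min = 2, relaxed_min = 1) {
  if (relaxed_min > stringent_min) {
    stop2("relaxed_min must not exceed stringent_min")
  }
  n_uni <- vapply(profiles, `[[`, integer(1), "n_unique_peptides")
  tier <- ifelse(n_uni >= stringent_min, "stringent",
                 ifelse(n_uni >= relaxed_min, "relaxed", "absent"))
  data.frame(entry_id = vapply(profiles, `[[`, "", "entry_id"),
             sample_id = vapply(profiles, `[[`, "", "sample_id"),
             tier = tier,
             n_unique_peptides = n_uni,
             coverage_pct = vapply(profiles, `[[`, numeric(1), "coverage_pct"),
             row.names = NULL)
}

#' Call amino-acid substitutions against the reference
#'
#' Per reference position, in canonical residue space: `'-'` where depth is
#' zero; the reference residue where every covering observation agrees with
#' it; an alternative residue where at least `min_support` observations
#' report that residue and no observation reports a different alternative;
#' `'?'` otherwise (ambiguous).
#'
#' @param profiles coverage profiles from [compute_coverage()] (one or more
#'   samples).
#' @param refs the `reference_set`.
#' @param min_support concordant alternative observations required for a
#'   substitution call (default 2).
#' @param il_equiv,deam_tolerant equivalence settings, must match those used
#'   for placement.
#' @return a data.frame: `entry_id`, `sample_id`, `position`, `symbol`,
#'   `support` (covering observations behind the symbol).
#' @export
call_substitutions <- function(profiles, refs, min_support = 2,
                               il_equiv = TRUE, deam_tolerant = TRUE) {
  validate_reference_set(refs)
  canon <- stats::setNames(canonicalize(refs$sequence, il_equiv, deam_tolerant),
                           refs$entry_id)
  out <- lapply(profiles, function(pr) {
    ref_res <- strsplit(canon[[pr$entry_id]], "")[[1]]
    L <- length(ref_res)
    symbol <- character(L)
    support <- integer(L)
    alt_by_pos <- split(pr$alt$res, factor(pr$alt$pos, levels = seq_len(L)))
    for (p in seq_len(L)) {
      d <- pr$depth[p]
      if (d == 0L) {
        symbol[p] <- "-"
        next
      }
      alts <- alt_by_pos[[p]]
      if (length(alts) == 0) {
        symbol[p] <- ref_res[p]
        support[p] <- d
      } else {
        tab <- table(alts)
        if (length(tab) == 1L && tab[[1]] >= min_support) {
          symbol[p] <- names(tab)[1]
          support[p] <- tab[[1]]
        } else {
          symbol[p] <- "?"
          support[p] <- length(alts)
        }
      }
    }
    data.frame(entry_id = pr$entry_id, sample_id = pr$sample_id,
               position = seq_len(L), symbol = symbol, support = support)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Render a substitution grid for selected samples and positions
#'
#' Produces the publication-style alignment summary: one row per sample, one
#' column per reference position, cells holding `'-'` (uncovered), `'?'`
#' (ambiguous) or a residue.
#'
#' @param sub_table output of [call_substitutions()].
#' @param entry_id reference entry to report on.
#' @param samples sample ids (row order of the grid).
#' @param positions 1-based reference positions (column order).
#' @return a character matrix with `samples` as rownames and `positions` as
#'   colnames.
#' @export
alignment_report <- function(sub_table, entry_id, samples, positions) {
  tab <- sub_table[sub_table$entry_id == entry_id, , drop = FALSE]
  if (nrow(tab) == 0) stop2("no substitution rows for entry ", entry_id)
  if (any(!positions %in% tab$position)) {
    stop2("unknown position ", setdiff(positions, tab$position)[1],
          " for entry ", entry_id)
  }
  grid <- matrix("-", length(samples), length(positions),
                 dimnames = list(samples, as.character(positions)))
  for (s in samples) {
    rows <- tab[tab$sample_id == s, , drop = FALSE]
    if (nrow(rows) == 0) next
    m <- match(positions, rows$position)
    grid[s, ] <- rows$symbol[m]
  }
  grid
}
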