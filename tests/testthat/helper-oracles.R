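# Independent brute-force oracles. These deliberately share no code with
# the implementation: cleavage sites are found by a character loop and
# fragments / placements by exhaustive enumeration.

oracle_sites <- function(sequence, enzyme) {
  ch <- strsplit(sequence, "")[[1]]
  after <- if (enzyme == "trypsin") c("K", "R") else
    c("A", "V", "S", "G", "L", "I")
  sites <- integer(0)
  for (i in seq_len(length(ch) - 1)) {
    if (ch[i] %in% after && !(enzyme == "trypsin" && ch[i + 1] == "P")) {
      sites <- c(sites, i)
    }
  }
  sites
}

# every substring whose boundaries are cleavage sites or termini and whose
# interior contains at most max_missed cleavage sites (counted explicitly;
# the interior count is monotone in the end boundary, so the scan can stop
# once it exceeds max_missed)
oracle_digest <- function(sequence, enzyme, max_missed) {
  n <- nchar(sequence)
  sites <- oracle_sites(sequence, enzyme)
  boundary <- unique(c(0, sites, n))
  starts <- ends <- missed <- integer(0)
  for (a in seq_along(boundary)) {
    i <- boundary[a] + 1
    if (i > n) next
    for (b in seq_along(boundary)) {
      j <- boundary[b]
      if (j < i) next
      interior <- sum(sites >= i & sites < j)
      if (interior > max_missed) break
      starts <- c(starts, i); ends <- c(ends, j)
      missed <- c(missed, interior)
    }
  }
  out <- data.frame(peptide = substring(sequence, starts, ends),
                    start = starts, end = ends, missed = missed)
  out[order(out$start, out$end), , drop = FALSE]
}

# exhaustive (entry, offset, mismatch-pattern) placement scan mirroring the
# documented rule: exact placements first; otherwise exactly one internal
# mismatch, only for peptides of length >= min_sub_len
oracle_place <- function(pep, canon_seqs, entry_ids, max_subst = 1,
                         min_sub_len = 6) {
  n <- nchar(pep)
  pch <- strsplit(pep, "")[[1]]
  exact <- NULL
  onemm <- NULL
  for (e in seq_along(canon_seqs)) {
    sch <- strsplit(canon_seqs[e], "")[[1]]
    L <- length(sch)
    if (L < n) next
    for (s in 1:(L - n + 1)) {
      mism <- which(sch[s:(s + n - 1)] != pch)
      if (length(mism) == 0) {
        exact <- rbind(exact, data.frame(entry_id = entry_ids[e], start = s,
                                         n_subst = 0, sub_pos = NA))
      } else if (length(mism) == 1 && mism != 1 && mism != n) {
        onemm <- rbind(onemm, data.frame(entry_id = entry_ids[e], start = s,
                                         n_subst = 1,
                                         sub_pos = s + mism - 1))
      }
    }
  }
  if (!is.null(exact)) return(exact)
  if (max_subst >= 1 && n >= min_sub_len && !is.null(onemm)) return(onemm)
  NULL
}

random_peptide <- function(n) {
  paste(sample(shellome:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}
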