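# Database-independent comparison at the spectrum level: cosine similarity
# between fragment spectra with greedy 1:1 peak pairing, aggregated to a
# sample-level score. Kept interface-compatible with the peptide-level
# similarity pathway so the two routes can be cross-checked.

#' Cosine similarity between two fragment spectra
#'
#' Peaks are paired greedily 1:1 in order of ascending m/z difference within
#' `frag_tol`; the score is the sum of paired intensity products over the
#' product of the full intensity norms, so unmatched peaks penalise the
#' score. Invariant to uniform intensity scaling of either spectrum.
#'
#' @param a,b `spectrum_record` objects (non-empty).
#' @param frag_tol fragment m/z tolerance in Da (default 0.02).
#' @return a list with `cosine` (in \[0, 1\]) and `n_matched_peaks`.
#' @export
cosine_score <- function(a, b, frag_tol = 0.02) {
  if (length(a$mz) == 0 || length(b$mz) == 0) stop2("empty spectrum")
  # candidate pairs within tolerance (peaks are sorted ascending)
  cand_i <- integer(0); cand_j <- integer(0)
  lo <- findInterval(a$mz - frag_tol, b$mz) + 1L
  hi <- findInterval(a$mz + frag_tol, b$mz)
  for (i in seq_along(a$mz)) {
    if (lo[i] <= hi[i]) {
      js <- lo[i]:hi[i]
      cand_i <- c(cand_i, rep.int(i, length(js)))
      cand_j <- c(cand_j, js)
    }
  }
  num <- 0
  n_matched <- 0L
  if (length(cand_i) > 0) {
    o <- order(abs(a$mz[cand_i] - b$mz[cand_j]))
    used_a <- logical(length(a$mz))
    used_b <- logical(length(b$mz))
    for (k in o) {
      i <- cand_i[k]; j <- cand_j[k]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- used_b[j] <- TRUE
        num <- num + a$intensity[i] * b$intensity[j]
        n_matched <- n_matched + 1L
      }
    }
  }
  denom <- sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2))
  list(cosine = if (denom == 0) 0 else min(1, num / denom),
       n_matched_peaks = n_matched)
}

#' Sample-level spectral similarity
#'
#' For each spectrum of one sample, candidate spectra of the other sample
#' are those within `prec_tol` of its precursor m/z; the spectrum counts as
#' matched when its best cosine among candidates reaches `min_cos`. The
#' score is the mean of the two directed matched fractions, so it is
#' symmetric and equals 1 when the lists are identical.
#'
#' @param A,B non-empty lists of `spectrum_record` objects.
#' @param prec_tol precursor m/z tolerance in Da (default 1.5).
#' @param min_cos cosine threshold for a qualifying match (default 0.7).
#' @param frag_tol fragment tolerance passed to [cosine_score()].
#' @return a real in \[0, 1\].
#' @export
sample_spectral_similarity <- function(A, B, prec_tol = 1.5, min_cos = 0.7,
                                       frag_tol = 0.02) {
  if (length(A) == 0 || length(B) == 0) stop2("empty spectrum list")
  directed <- function(X, Y) {
    prec <- vapply(Y, `[[`, numeric(1), "precursor_mz")
    o <- order(prec)
    prec <- prec[o]
    Y <- Y[o]
    matched <- vapply(X, function(x) {
      lo <- findInterval(x$precursor_mz - prec_tol, prec) + 1L
      hi <- findInterval(x$precursor_mz + prec_tol, prec)
      if (lo > hi) return(FALSE)
      for (j in lo:hi) {
        if (cosine_score(x, Y[[j]], frag_tol)$cosine >= min_cos) return(TRUE)
      }
      FALSE
    }, logical(1))
    mean(matched)
  }
  (directed(A, B) + directed(B, A)) / 2
}
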