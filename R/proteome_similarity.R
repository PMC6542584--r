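# Database-independent proteome comparison: peptide-list similarity,
# similarity -> distance conversion, classical (Torgerson) MDS, taxon
# attribution and shared-protein adjacency weights.
#
# The similarity score is computed on unique canonical peptide strings. The
# default is the overlap coefficient |A n B| / min(|A|, |B|), which is robust
# to the large size asymmetry between sparse archaeological peptide lists
# and rich reference digests; the Jaccard index is provided as an option.

#' Similarity between two peptide lists
#'
#' @param a,b non-empty sets of canonical peptides (`canonical_peptides`
#'   data.frames or character vectors).
#' @param mode `"overlap"` (default): intersection over the smaller set
#'   size; `"jaccard"`: intersection over union.
#' @return a real in \[0, 1\]; symmetric in its arguments.
#' @export
pepmatch_score <- function(a, b, mode = c("overlap", "jaccard")) {
  mode <- match.arg(mode)
  a <- unique(canonical_strings(a))
  b <- unique(canonical_strings(b))
  if (length(a) == 0 || length(b) == 0) {
    stop2("pepmatch_score is undefined for an empty peptide set")
  }
  inter <- length(intersect(a, b))
  if (mode == "overlap") inter / min(length(a), length(b))
  else inter / length(union(a, b))
}

#' All-pairwise similarity matrix over samples
#'
#' @param samples named list mapping sample id to its canonical peptide set;
#'   at least two samples, all non-empty.
#' @param mode see [pepmatch_score()].
#' @return a `similarity_matrix`: list with `labels`, `s` (square matrix,
#'   unit diagonal, symmetric, entries in \[0, 1\]) and `n_intersect`
#'   (raw intersection counts, used for attribution tie-breaks).
#' @export
build_similarity_matrix <- function(samples, mode = c("overlap", "jaccard")) {
  mode <- match.arg(mode)
  if (length(samples) < 2) stop2("need at least two samples")
  if (is.null(names(samples)) || anyDuplicated(names(samples))) {
    stop2("samples must be uniquely named")
  }
  sets <- lapply(samples, function(x) unique(canonical_strings(x)))
  sizes <- lengths(sets)
  if (any(sizes == 0)) {
    stop2("sample '", names(samples)[sizes == 0][1], "' has no peptides")
  }
  n <- length(sets)
  labels <- names(samples)
  s <- diag(1, n)
  ni <- diag(sizes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      ni[i, j] <- ni[j, i] <- inter
      s[i, j] <- s[j, i] <-
        if (mode == "overlap") inter / min(sizes[i], sizes[j])
        else inter / (sizes[i] + sizes[j] - inter)
    }
  }
  dimnames(s) <- dimnames(ni) <- list(labels, labels)
  structure(list(labels = labels, s = s, n_intersect = ni),
            class = "similarity_matrix")
}

#' Convert similarity to distance
#'
#' Elementwise `d = 1 - s`. The result need not satisfy the triangle
#' inequality; [classical_mds()] handles that by eigenvalue clamping and by
#' reporting stress.
#'
#' @param sm a `similarity_matrix`.
#' @return a `distance_matrix`: list with `labels` and `d`.
#' @export
to_distance <- function(sm) {
  if (!inherits(sm, "similarity_matrix")) stop2("expected a similarity_matrix")
  d <- 1 - sm$s
  diag(d) <- 0
  structure(list(labels = sm$labels, d = d), class = "distance_matrix")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres `-D^2 / 2`, eigendecomposes, retains the top `k`
#' eigenvalues (negative ones, which arise for non-Euclidean input, are
#' clamped to zero) and scales the eigenvectors by the square roots.
#' Kruskal's stress-1 between the input and embedded distances is reported
#' so distortion can be judged; embedding orientation is arbitrary, so
#' downstream comparisons should use embedded distances, not coordinates.
#'
#' @param dm a `distance_matrix`.
#' @param k embedding dimension (default 2); must not exceed the number of
#'   samples.
#' @return an `mds_embedding`: list with `labels`, `coords` (n x k matrix),
#'   `eigenvalues` (retained, clamped) and `stress1`.
#' @export
classical_mds <- function(dm, k = 2) {
  if (!inherits(dm, "distance_matrix")) stop2("expected a distance_matrix")
  d <- dm$d
  n <- nrow(d)
  if (k < 1 || k > n) stop2("k must be between 1 and the number of samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d * d) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- pmax(e$values[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda), nrow = k)
  rownames(coords) <- dm$labels
  lower <- lower.tri(d)
  delta <- as.matrix(stats::dist(coords))
  denom <- sum(d[lower]^2)
  stress1 <- if (denom == 0) 0 else
    sqrt(sum((d[lower] - delta[lower])^2) / denom)
  structure(list(labels = dm$labels, coords = coords,
                 eigenvalues = lambda, stress1 = stress1),
            class = "mds_embedding")
}

#' Rank reference samples by similarity to a query
#'
#' References are ranked by similarity score, descending; ties are broken by
#' the larger raw peptide-intersection count, then by the order of
#' `reference_ids`. A top score of zero is flagged as `no_signal`.
#'
#' @param query query sample id (must not be among the references).
#' @param sm a `similarity_matrix` containing query and references.
#' @param reference_ids reference sample ids.
#' @param ref_meta optional data.frame with columns `sample_id`, `taxon`,
#'   `clade`, merged into the ranking.
#' @return a data.frame ranked best-first: `reference_id`, `score`,
#'   `n_intersect`, `rank`, plus `taxon`/`clade` when `ref_meta` is given;
#'   attribute `"no_signal"` is `TRUE` when the top score is 0.
#' @export
attribute_sample <- function(query, sm, reference_ids, ref_meta = NULL) {
  if (!inherits(sm, "similarity_matrix")) stop2("expected a similarity_matrix")
  if (query %in% reference_ids) {
    stop2("query '", query, "' is among the reference ids")
  }
  missing <- setdiff(c(query, reference_ids), sm$labels)
  if (length(missing) > 0) {
    stop2("not in similarity matrix: ", paste(missing, collapse = ", "))
  }
  score <- sm$s[query, reference_ids]
  inter <- sm$n_intersect[query, reference_ids]
  o <- order(-score, -inter, seq_along(reference_ids))
  out <- data.frame(reference_id = reference_ids[o],
                    score = unname(score[o]),
                    n_intersect = unname(inter[o]),
                    rank = seq_along(o))
  if (!is.null(ref_meta)) {
    m <- match(out$reference_id, ref_meta$sample_id)
    out$taxon <- ref_meta$taxon[m]
    out$clade <- ref_meta$clade[m]
  }
  attr(out, "no_signal") <- out$score[1] == 0
  out
}

#' Shared-protein adjacency weights between query and reference samples
#'
#' Reconstructs the chord-diagram quantities used to visualise which
#' reference proteins are shared between archaeological (query) and
#' reference shell proteomes. Detection means a call tier other than
#' `"absent"`. `shared_ids` are entries detected in at least one query and
#' at least one reference sample. Per reference sample, the segment weight
#' sums, over its detected shared entries, the mean query coverage of that
#' entry; per (query, reference) pair the band counts entries detected in
#' both and the query segment sums the query's unique-peptide support for
#' them.
#'
#' @param query_calls,ref_calls protein-call data.frames from
#'   [call_proteins()] covering the query and reference samples (computed
#'   against a common reference set).
#' @return a list with `shared_ids`, `ref_segment` (named numeric, one per
#'   reference sample) and `pairs` (data.frame `query`, `reference`, `band`,
#'   `query_segment`).
#' @export
adjacency_weights <- function(query_calls, ref_calls) {
  if (length(intersect(query_calls$entry_id, ref_calls$entry_id)) == 0) {
    stop2("query and reference calls share no reference entries")
  }
  qdet <- query_calls[query_calls$tier != "absent", , drop = FALSE]
  rdet <- ref_calls[ref_calls$tier != "absent", , drop = FALSE]
  shared <- sort(intersect(unique(qdet$entry_id), unique(rdet$entry_id)))
  q_samples <- sort(unique(query_calls$sample_id))
  r_samples <- sort(unique(ref_calls$sample_id))
  # mean query coverage per shared entry, over query samples detecting it
  mean_cov <- vapply(shared, function(id) {
    mean(qdet$coverage_pct[qdet$entry_id == id])
  }, numeric(1))
  ref_segment <- vapply(r_samples, function(r) {
    ids <- intersect(rdet$entry_id[rdet$sample_id == r], shared)
    sum(mean_cov[ids])
  }, numeric(1))
  pairs <- do.call(rbind, lapply(q_samples, function(q) {
    qids <- qdet[qdet$sample_id == q, , drop = FALSE]
    do.call(rbind, lapply(r_samples, function(r) {
      rids <- intersect(rdet$entry_id[rdet$sample_id == r], shared)
      both <- intersect(intersect(qids$entry_id, rids), shared)
      data.frame(query = q, reference = r, band = length(both),
                 query_segment =
                   sum(qids$n_unique_peptides[qids$entry_id %in% both]))
    }))
  }))
  rownames(pairs) <- NULL
  list(shared_ids = shared, ref_segment = ref_segment, pairs = pairs)
}
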