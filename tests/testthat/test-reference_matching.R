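test_that("placement: exact substring, single substitution, multi-mapping", {
  refs <- make_refs("AAGAGAA", entry_id = "ref1")
  pl <- place_peptides("GAGA", refs)
  expect_equal(pl$start, 3)
  expect_equal(pl$end, 6)
  expect_equal(pl$n_subst, 0)
  expect_true(pl$unique)

  # one internal mismatch when no exact placement exists
  pl <- place_peptides("GASA", refs, min_sub_len = 4)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$start, 3)
  expect_equal(pl$n_subst, 1)
  expect_equal(pl$sub_pos, 5)
  expect_equal(pl$sub_ref, "G")
  expect_equal(pl$sub_obs, "S")

  # substitution tolerance disabled below min_sub_len (default 6)
  expect_equal(nrow(place_peptides("GASA", refs)), 0)

  # multi-mapping peptide: placements in both entries, unique = FALSE
  refs2 <- make_refs(c("WWPEPTLDEHH", "KKPEPTLDEMM"), c("e1", "e2"))
  pl <- place_peptides("PEPTLDE", refs2)
  expect_equal(sort(pl$entry_id), c("e1", "e2"))
  expect_false(any(pl$unique))

  expect_error(place_peptides("GAGA", refs[0, ]), "empty reference")
})

test_that("exact placements suppress mismatch placements entirely", {
  # peptide exact in e1; an internal 1-mismatch hit exists in e2 but must
  # not appear
  refs <- make_refs(c("HHWFYPKDCMHH", "HHWFYPADCMHH"), c("e1", "e2"))
  pl <- place_peptides("WFYPKDCM", refs)
  expect_equal(unique(pl$entry_id), "e1")
  expect_true(all(pl$n_subst == 0))
  expect_true(all(pl$unique))
})

test_that("placement agrees with the exhaustive oracle on random instances", {
  set.seed(101)
  for (trial in 1:40) {
    n_entries <- sample(1:3, 1)
    seqs <- replicate(n_entries, random_peptide(sample(30:120, 1)))
    ids <- sprintf("e%d", seq_len(n_entries))
    refs <- make_refs(seqs, ids)
    canon <- canonicalize(seqs)
    # half the trials plant a (possibly mutated) substring, half are random
    if (trial %% 2 == 0) {
      src <- sample(n_entries, 1)
      n <- sample(6:15, 1)
      s <- sample(nchar(canon[src]) - n + 1, 1)
      pep <- substr(canon[src], s, s + n - 1)
      if (runif(1) < 0.5) {
        at <- sample(n, 1)
        substr(pep, at, at) <- sample(shellome:::AA_ALPHABET, 1)
      }
      pep <- canonicalize(pep)
    } else {
      pep <- canonicalize(random_peptide(sample(6:15, 1)))
    }
    got <- place_peptides(pep, refs)
    want <- oracle_place(pep, canon, ids)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      key <- function(d) sort(paste(d$entry_id, d$start, d$n_subst,
                                    ifelse(is.na(d$sub_pos), 0, d$sub_pos)))
      expect_equal(key(got), key(want))
    }
  }
})

test_that("coverage counts position presence; depth counts placements", {
  refs <- make_refs(strrep("W", 10), "r1")
  pl <- data.frame(peptide = c("a", "b"), entry_id = "r1",
                   start = c(1, 7), end = c(5, 10), n_subst = 0L,
                   sub_pos = NA_integer_, sub_ref = NA_character_,
                   sub_obs = NA_character_, unique = TRUE)
  pr <- compute_coverage(pl, refs, "S1")[[1]]
  expect_equal(pr$coverage_pct, 90)
  expect_equal(sum(pr$depth >= 1), 9)

  pl2 <- pl
  pl2$start <- c(1, 1); pl2$end <- c(5, 5)
  pr2 <- compute_coverage(pl2, refs, "S1")[[1]]
  expect_equal(pr2$coverage_pct, 50)
  expect_equal(pr2$depth[1:5], rep(2L, 5))

  pr0 <- compute_coverage(pl[0, ], refs, "S1")[[1]]
  expect_equal(pr0$coverage_pct, 0)
  expect_equal(pr0$n_peptides, 0)

  pl_bad <- pl
  pl_bad$end[2] <- 11
  expect_error(compute_coverage(pl_bad, refs, "S1"), "bounds")
})

test_that("coverage_pct equals the positional definition on random panels", {
  set.seed(55)
  refs <- make_refs(random_peptide(80), "r1")
  for (rep in 1:10) {
    k <- sample(1:12, 1)
    start <- sample(1:70, k, replace = TRUE)
    end <- pmin(80, start + sample(5:12, k, replace = TRUE))
    pl <- data.frame(peptide = sprintf("p%d", seq_len(k)), entry_id = "r1",
                     start = start, end = end, n_subst = 0L,
                     sub_pos = NA_integer_, sub_ref = NA_character_,
                     sub_obs = NA_character_, unique = TRUE)
    pr <- compute_coverage(pl, refs, "S")[[1]]
    covered <- unique(unlist(Map(seq, start, end)))
    expect_equal(pr$coverage_pct, 100 * length(covered) / 80)
  }
})

test_that("protein calls are tiered by unique-peptide support", {
  mk <- function(n_uni) list(entry_id = "e", sample_id = "s",
                             depth = integer(0), alt = NULL,
                             coverage_pct = 10, n_unique_peptides = n_uni,
                             n_peptides = n_uni)
  calls <- call_proteins(list(mk(2L), mk(1L), mk(0L), mk(7L)))
  expect_equal(calls$tier, c("stringent", "relaxed", "absent", "stringent"))
  calls5 <- call_proteins(list(mk(2L), mk(4L)), stringent_min = 5)
  expect_equal(calls5$tier, c("relaxed", "relaxed"))
})

test_that("substitution calls follow the dash / residue / question-mark rules", {
  refs <- make_refs("WWWWAWWWWKWWWWW", "r1")  # canonical == itself
  # obs: pos 5 'S' twice (concordant alternative), pos 10 'T' once
  pl <- data.frame(
    peptide = c("p1", "p2", "p3"), entry_id = "r1",
    start = c(3, 4, 8), end = c(7, 9, 12), n_subst = 1L,
    sub_pos = c(5L, 5L, 10L), sub_ref = c("A", "A", "K"),
    sub_obs = c("S", "S", "T"), unique = TRUE)
  prof <- compute_coverage(pl, refs, "S1")
  st <- call_substitutions(prof, refs)
  sym <- st$symbol[match(1:15, st$position)]
  expect_equal(sym[5], "S")           # >= 2 concordant alternatives
  expect_equal(sym[10], "?")          # single-support alternative
  expect_equal(sym[1], "-")           # uncovered
  expect_equal(sym[15], "-")
  expect_equal(sym[4], "W")           # covered, agrees with reference
  expect_equal(st$support[st$position == 5], 2L)

  # conflicting alternatives at one position are ambiguous regardless of count
  pl$sub_obs <- c("S", "T", "T")
  st2 <- call_substitutions(compute_coverage(pl, refs, "S1"), refs)
  expect_equal(st2$symbol[st2$position == 5], "?")
})

test_that("raising min_support never increases residue substitution calls", {
  set.seed(77)
  refs <- make_refs(random_peptide(60), "r1")
  n_calls <- function(ms) {
    k <- 15
    pl <- data.frame(peptide = sprintf("p%d", 1:k), entry_id = "r1",
                     start = sample(1:50, k, TRUE), n_subst = 1L,
                     unique = TRUE)
    pl$end <- pl$start + 8
    pl$sub_pos <- pl$start + sample(1:7, k, TRUE)
    pl$sub_ref <- "X"
    pl$sub_obs <- sample(c("G", "G", "A"), k, TRUE)
    st <- call_substitutions(compute_coverage(pl, refs, "S"), refs, ms)
    sum(!st$symbol %in% c("-", "?") &
          st$symbol != strsplit(canonicalize(refs$sequence), "")[[1]][st$position])
  }
  set.seed(42); a <- n_calls(1)
  set.seed(42); b <- n_calls(2)
  set.seed(42); c3 <- n_calls(3)
  expect_gte(a, b)
  expect_gte(b, c3)
})

test_that("alignment report renders the sample x position grid", {
  refs <- make_refs("WWWWAWWWWW", "r1")
  pl <- data.frame(peptide = "p1", entry_id = "r1", start = 3, end = 8,
                   n_subst = 1L, sub_pos = 5L, sub_ref = "A", sub_obs = "S",
                   unique = TRUE)
  prof_a <- compute_coverage(rbind(pl, pl), refs, "sampleA")
  prof_b <- compute_coverage(pl[0, ], refs, "sampleB")
  st <- call_substitutions(c(prof_a, prof_b), refs)
  grid <- alignment_report(st, "r1", c("sampleA", "sampleB"), c(2, 5, 9))
  expect_equal(dim(grid), c(2, 3))
  expect_equal(grid["sampleA", ], c("2" = "-", "5" = "S", "9" = "-"))
  expect_equal(unname(grid["sampleB", ]), rep("-", 3))  # uncovered sample
  expect_error(alignment_report(st, "r1", "sampleA", 99), "unknown position")

  # TSV round trip preserves the grid
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(grid, path, sep = "\t", quote = FALSE)
  back <- as.matrix(utils::read.delim(path, row.names = 1,
                                      check.names = FALSE,
                                      colClasses = "character"))
  expect_equal(back, grid)
})

test_that("deamidation tolerance never decreases placed peptides", {
  panel <- small_panel(seed = 23)
  cfg <- synthetic_config(n_proteins_per_taxon = 3, p_deam = 0.5,
                          p_err = 0, p_survive = 0.5, seed = 23)
  sim <- degrade_sample(panel$refs, "taxon02", cfg, "q_deam")
  placed_rows <- function(deam) {
    canon <- canonicalize(sim$table$peptide, TRUE, deam)
    pl <- place_peptides(unique(canon), panel$refs, deam_tolerant = deam)
    sum(canon %in% pl$peptide)
  }
  expect_gte(placed_rows(TRUE), placed_rows(FALSE))
})
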