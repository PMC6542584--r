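test_that("trypsin digestion follows the cleavage rule", {
  d0 <- digest("MKRAPKGFRS", "trypsin", 0)
  expect_setequal(d0$peptide, c("MK", "R", "APK", "GFR", "S"))
  d1 <- digest("MKRAPKGFRS", "trypsin", 1)
  expect_setequal(setdiff(d1$peptide, d0$peptide),
                  c("MKR", "RAPK", "APKGFR", "GFRS"))
  # proline blocks cleavage: KP is not a site
  expect_setequal(digest("AKPAK", "trypsin", 0)$peptide, c("AKPAK"))
  # no cleavage sites: whole sequence as one peptide
  expect_equal(digest("WHWHWH", "trypsin", 0)$peptide, "WHWHWH")
  expect_error(digest("MKR", "pepsin", 0), "unknown enzyme")
})

test_that("digestion agrees with the brute-force oracle", {
  set.seed(61)
  for (trial in 1:30) {
    s <- random_peptide(sample(10:120, 1))
    for (enz in c("trypsin", "elastase")) {
      mm <- sample(0:2, 1)
      got <- digest(s, enz, mm)
      want <- oracle_digest(s, enz, mm)
      key <- function(d) sort(paste(d$start, d$end, d$missed))
      expect_equal(key(got), key(want))
      expect_equal(sort(got$peptide), sort(want$peptide))
    }
  }
})

test_that("reference generation: RLC sharing, divergence, determinism", {
  cfg <- synthetic_config(seed = 5)
  p1 <- generate_references(cfg)
  p2 <- generate_references(cfg)
  expect_identical(p1$refs, p2$refs)        # same seed, same panel

  # RLC blocks used by a protein template recur verbatim in every taxon
  used <- p1$truth$rlc_pool[vapply(p1$truth$rlc_pool, function(b)
    any(grepl(b, p1$refs$sequence[1], fixed = TRUE)), logical(1))]
  for (b in used) {
    # every block of taxon01's first protein recurs in every taxon's copy
    expect_true(all(vapply(p1$truth$taxa, function(t) {
      grepl(b, p1$refs$sequence[p1$refs$entry_id == paste0(t, "_p01")],
            fixed = TRUE)
    }, logical(1))))
  }

  # mu = 0: all taxa identical up to ids; mu > 0: they differ
  cfg0 <- synthetic_config(mu = 0, seed = 5)
  p0 <- generate_references(cfg0)
  seqs_by_taxon <- split(p0$refs$sequence[!p0$refs$is_marker],
                         p0$refs$taxon[!p0$refs$is_marker])
  expect_true(all(vapply(seqs_by_taxon, identical,
                         logical(1), y = seqs_by_taxon[[1]])))
  seqs_mu <- split(p1$refs$sequence[!p1$refs$is_marker],
                   p1$refs$taxon[!p1$refs$is_marker])
  expect_false(identical(seqs_mu[[1]], seqs_mu[[2]]))

  # markers: one per clade, carried with the clade label
  markers <- p1$refs[p1$refs$is_marker, ]
  expect_setequal(markers$clade, c("freshwater", "marine"))
})

test_that("degradation: no-noise limit, forced deamidation, determinism", {
  # hydrolysis_penalty = 1 so survival is genuinely certain at p_survive = 1
  cfg <- synthetic_config(n_proteins_per_taxon = 2, p_survive = 1,
                          p_deam = 0, p_err = 0, hydrolysis_penalty = 1,
                          seed = 17)
  panel <- generate_references(cfg)
  sim <- degrade_sample(panel$refs, "taxon01", cfg, "noiseless")
  # output is exactly the in-range digest of the source proteome
  own <- panel$refs[panel$refs$taxon == "taxon01" & !panel$refs$is_marker, ]
  marker <- panel$refs[panel$refs$is_marker &
                         panel$refs$clade == "freshwater", ]
  expected <- unlist(lapply(c(own$sequence, marker$sequence), function(s) {
    unlist(lapply(cfg$enzymes, function(e)
      digest(s, e, cfg$max_missed_cleavages)$peptide))
  }))
  expected <- expected[nchar(expected) >= 6 & nchar(expected) <= 30]
  expect_setequal(sim$table$peptide, expected)
  expect_equal(nrow(sim$table), length(expected))

  cfg_deam <- synthetic_config(n_proteins_per_taxon = 2, p_survive = 1,
                               p_deam = 1, p_err = 0, seed = 17)
  sim_d <- degrade_sample(panel$refs, "taxon01", cfg_deam, "alldeam")
  expect_false(any(grepl("[NQ]", sim_d$table$peptide)))
  # every conversion is annotated in mods
  has_deam <- vapply(seq_len(nrow(sim_d$table)), function(i) {
    any(shellome:::parse_mods(sim_d$table$mods[i])$kind == "deamidation")
  }, logical(1))
  expect_equal(has_deam, sim_d$truth$provenance$n_deamidated > 0)

  sim2 <- degrade_sample(panel$refs, "taxon01", cfg, "noiseless")
  expect_identical(sim$table, sim2$table)   # same (seed, sample_id) stream

  cfg0 <- synthetic_config(p_survive = 0, seed = 17)
  expect_error(degrade_sample(panel$refs, "taxon01", cfg0, "dead"),
               "insufficient peptides")
  expect_error(degrade_sample(panel$refs, "nosuch", cfg, "x"),
               "not present")
})

test_that("expected surviving peptide count tracks p_survive", {
  cfg <- synthetic_config(n_proteins_per_taxon = 3, p_deam = 0, p_err = 0,
                          p_survive = 0.4, hydrolysis_penalty = 1, seed = 37)
  panel <- generate_references(cfg)
  n_total <- degrade_sample(panel$refs, "taxon01",
                            synthetic_config(n_proteins_per_taxon = 3,
                                             p_survive = 1, p_deam = 0,
                                             p_err = 0, seed = 37),
                            "all")$truth$n_survived
  counts <- vapply(1:8, function(i) {
    degrade_sample(panel$refs, "taxon01", cfg,
                   paste0("surv", i))$truth$n_survived
  }, numeric(1))
  expected <- 0.4 * n_total
  sd_binom <- sqrt(n_total * 0.4 * 0.6)
  expect_lt(abs(mean(counts) - expected), 3 * sd_binom / sqrt(8))
})

test_that("two-enzyme union coverage is at least single-enzyme coverage", {
  panel <- small_panel(seed = 41)
  for (s in panel$refs$sequence[1:4]) {
    cov_for <- function(enzymes) {
      d <- do.call(rbind, lapply(enzymes, function(e) digest(s, e, 2)))
      d <- d[nchar(d$peptide) >= 6 & nchar(d$peptide) <= 30, ]
      length(unique(unlist(Map(seq, d$start, d$end))))
    }
    both <- cov_for(c("trypsin", "elastase"))
    expect_gte(both, cov_for("trypsin"))
    expect_gte(both, cov_for("elastase"))
  }
})

test_that("theoretical spectra have exact fragment masses and counts", {
  t <- make_table("S1", "AG")
  sp <- emit_spectra(t, charge = 1)[[1]]
  expect_equal(length(sp$mz), 2)                  # 2(n-1) peaks
  expect_equal(sort(sp$mz), c(72.04439, 76.03930), tolerance = 5e-4)
  expect_equal(sp$precursor_mz, 147.07642, tolerance = 5e-4)

  t8 <- make_table("S1", "ACDEFGHK")
  sp8 <- emit_spectra(t8)[[1]]
  expect_equal(length(sp8$mz), 14)

  # deamidation annotation on a still-N residue shifts peaks by +0.98402
  tN <- make_table("S1", "ANGGGK", mods = "2:deamidation")
  tD <- make_table("S1", "ADGGGK")
  expect_equal(emit_spectra(tN)[[1]]$precursor_mz,
               emit_spectra(tD)[[1]]$precursor_mz, tolerance = 1e-4)

  # identical input gives byte-identical MGF
  f1 <- withr::local_tempfile(fileext = ".mgf")
  f2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(emit_spectra(t8), f1)
  write_mgf(emit_spectra(t8), f2)
  expect_identical(readLines(f1), readLines(f2))
})
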