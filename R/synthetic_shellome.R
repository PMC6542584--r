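# Ground-truthed simulation of shell matrix proteomes and their diagenetic
# degradation.
#
# The generator reproduces the structural confound that makes shell-proteome
# attribution hard: repeated low-complexity (RLC) blocks -- poly-Ala runs,
# (GA)n repeats, Gly-rich stretches -- are shared verbatim across all taxa
# and therefore carry no taxonomic signal, while taxon-specific unique
# segments diverge from a common ancestor by per-site substitution.
# Degradation then applies in-silico trypsin/elastase digestion, peptide
# loss biased against hydrolysis-prone (Ser/Asp/Asn/Glu-rich) peptides,
# per-site deamidation, and occasional de novo sequencing error.

#' Build a validated simulation configuration
#'
#' @param n_taxa number of taxa (default 4, split evenly into a
#'   `"freshwater"` and a `"marine"` clade).
#' @param n_proteins_per_taxon proteins per taxon besides the clade marker
#'   (default 6).
#' @param rlc_pool_size number of RLC blocks in the shared pool (default 12).
#' @param mu per-site substitution probability for taxon divergence in
#'   non-RLC regions (default 0.05).
#' @param clades character vector of clade labels, one per taxon; `NULL`
#'   splits taxa evenly into freshwater/marine.
#' @param enzymes subset of `c("trypsin", "elastase")`.
#' @param max_missed_cleavages maximum missed cleavages (default 2).
#' @param len_range retained peptide length range (default 6..30).
#' @param p_survive per-peptide diagenetic survival probability
#'   (default 0.3, an "ancient" setting; use ~0.8 for modern shells).
#' @param hydrolysis_penalty survival multiplier (< 1) for peptides with
#'   more than half their residues in \{S, D, N, E\} (default 0.3).
#' @param p_deam per-site N/Q deamidation probability (default 0.3).
#' @param p_err per-peptide de novo error probability (default 0.05).
#' @param alc_model named vector `mean_good`, `mean_err`, `spread` for the
#'   ALC score distribution (defaults 82 / 62 / 8).
#' @param seed mandatory integer master seed; every stochastic operation
#'   draws from a stream derived from `(seed, sample_id)`.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_taxa = 4, n_proteins_per_taxon = 6,
                             rlc_pool_size = 12, mu = 0.05, clades = NULL,
                             enzymes = c("trypsin", "elastase"),
                             max_missed_cleavages = 2,
                             len_range = c(6, 30),
                             p_survive = 0.3, hydrolysis_penalty = 0.3,
                             p_deam = 0.3, p_err = 0.05,
                             alc_model = c(mean_good = 82, mean_err = 62,
                                           spread = 8),
                             seed) {
  if (missing(seed) || is.null(seed)) stop2("seed is mandatory")
  if (n_taxa < 1) stop2("n_taxa must be >= 1")
  probs <- c(mu = mu, p_survive = p_survive, p_deam = p_deam, p_err = p_err,
             hydrolysis_penalty = hydrolysis_penalty)
  if (any(probs < 0 | probs > 1)) {
    stop2("probability out of [0, 1]: ", names(probs)[probs < 0 | probs > 1][1])
  }
  if (!all(enzymes %in% c("trypsin", "elastase")) || length(enzymes) == 0) {
    stop2("enzymes must be a non-empty subset of trypsin/elastase")
  }
  if (len_range[1] < 1 || len_range[2] < len_range[1]) {
    stop2("invalid len_range")
  }
  if (is.null(clades)) {
    clades <- rep(c("freshwater", "marine"),
                  times = c(ceiling(n_taxa / 2), floor(n_taxa / 2)))
  }
  if (length(clades) != n_taxa) stop2("clades must have one label per taxon")
  if (rlc_pool_size == 0 && length(unique(clades)) == 0) {
    stop2("nothing distinguishes taxa")
  }
  structure(list(n_taxa = n_taxa,
                 n_proteins_per_taxon = n_proteins_per_taxon,
                 rlc_pool_size = rlc_pool_size, mu = mu, clades = clades,
                 enzymes = enzymes,
                 max_missed_cleavages = max_missed_cleavages,
                 len_range = len_range, p_survive = p_survive,
                 hydrolysis_penalty = hydrolysis_penalty,
                 p_deam = p_deam, p_err = p_err, alc_model = alc_model,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

random_seq <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

rlc_block <- function(kind) {
  switch(kind,
         polyA = strrep("A", sample(5:15, 1)),
         GA = strrep("GA", sample(3:8, 1)),
         Grich = paste(sample(c("G", "A", "S"), sample(8:20, 1),
                              replace = TRUE, prob = c(0.7, 0.15, 0.15)),
                       collapse = ""))
}

mutate_seq <- function(s, mu) {
  if (mu <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < mu
  for (i in which(hit)) {
    ch[i] <- sample(setdiff(AA_ALPHABET, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate a ground-truthed multi-taxon reference proteome panel
#'
#' Builds a pool of RLC blocks reused verbatim across all taxa, interleaved
#' with taxon-specific unique segments derived from a shared random ancestor
#' by per-site substitution at rate `mu`. One clade-specific marker protein
#' (an independent, RLC-free sequence) is emitted per clade, carried only by
#' that clade's taxa. Deterministic given the configuration seed.
#'
#' @param cfg a `synthetic_config`.
#' @return a list: `refs` (a `reference_set`; marker entries have
#'   `is_marker = TRUE` and their `taxon` field set to the clade label) and
#'   `truth` (taxa, taxon -> clade map, per-template segment map with
#'   `rlc`/`unique` types, marker ids).
#' @export
generate_references <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$rlc_pool_size == 0 && length(cfg$clades) == 0) {
    stop2("nothing distinguishes taxa")
  }
  set.seed(derive_seed(cfg$seed, "references"))
  taxa <- sprintf("taxon%02d", seq_len(cfg$n_taxa))
  clade_of <- stats::setNames(cfg$clades, taxa)

  pool <- if (cfg$rlc_pool_size > 0) {
    vapply(seq_len(cfg$rlc_pool_size), function(i) {
      rlc_block(c("polyA", "GA", "Grich")[(i - 1) %% 3 + 1])
    }, "")
  } else character(0)

  # protein templates: alternating unique segments and shared RLC blocks;
  # the same template (same RLC blocks, same ancestor unique segments) is
  # instantiated for every taxon
  templates <- lapply(seq_len(cfg$n_proteins_per_taxon), function(j) {
    n_rlc <- if (length(pool) > 0) sample(4:6, 1) else 0
    blocks <- list()
    seg <- list()
    pos <- 0L
    for (b in seq_len(n_rlc + 1)) {
      u <- random_seq(sample(25:60, 1))
      blocks[[length(blocks) + 1]] <- list(type = "unique", seq = u)
      seg[[length(seg) + 1]] <- data.frame(
        type = "unique", start = pos + 1L, end = pos + nchar(u))
      pos <- pos + nchar(u)
      if (b <= n_rlc) {
        r <- pool[[sample(length(pool), 1)]]
        blocks[[length(blocks) + 1]] <- list(type = "rlc", seq = r)
        seg[[length(seg) + 1]] <- data.frame(
          type = "rlc", start = pos + 1L, end = pos + nchar(r))
        pos <- pos + nchar(r)
      }
    }
    list(blocks = blocks, segments = do.call(rbind, seg))
  })

  rows <- list()
  for (t in taxa) {
    for (j in seq_along(templates)) {
      s <- paste(vapply(templates[[j]]$blocks, function(b) {
        if (b$type == "unique") mutate_seq(b$seq, cfg$mu) else b$seq
      }, ""), collapse = "")
      rows[[length(rows) + 1]] <- data.frame(
        entry_id = sprintf("%s_p%02d", t, j),
        description = sprintf("synthetic shell matrix protein %d of %s", j, t),
        taxon = t, clade = clade_of[[t]], is_marker = FALSE, sequence = s)
    }
  }
  marker_ids <- character(0)
  for (cl in unique(cfg$clades)) {
    id <- paste0("marker_", cl)
    marker_ids <- c(marker_ids, id)
    rows[[length(rows) + 1]] <- data.frame(
      entry_id = id,
      description = sprintf("synthetic clade marker protein (%s)", cl),
      taxon = cl, clade = cl, is_marker = TRUE,
      sequence = random_seq(240))
  }
  df <- do.call(rbind, rows)
  refs <- new_reference_set(df$entry_id, df$description, df$taxon, df$clade,
                            df$is_marker, df$sequence)
  validate_reference_set(refs)
  segments <- do.call(rbind, lapply(seq_along(templates), function(j) {
    s <- templates[[j]]$segments
    s$template <- j
    s
  }))
  list(refs = refs,
       truth = list(taxa = taxa, clade_of = as.list(clade_of),
                    segments = segments, marker_ids = marker_ids,
                    rlc_pool = pool))
}

cleavage_sites <- function(chars, enzyme) {
  n <- length(chars)
  if (n < 2) return(integer(0))
  idx <- seq_len(n - 1)
  if (enzyme == "trypsin") {
    idx[chars[idx] %in% c("K", "R") & chars[idx + 1] != "P"]
  } else if (enzyme == "elastase") {
    idx[chars[idx] %in% c("A", "V", "S", "G", "L", "I")]
  } else {
    stop2("unknown enzyme: ", enzyme)
  }
}

#' In-silico proteolytic digestion
#'
#' Trypsin cleaves after K or R except before P; elastase cleaves after
#' A, V, S, G, L or I (the broad specificity convention used by search
#' engines). All products with at most `max_missed` missed cleavages are
#' emitted with their 1-based coordinates.
#'
#' @param sequence uppercase protein sequence.
#' @param enzyme `"trypsin"` or `"elastase"`.
#' @param max_missed maximum missed cleavages (default 0).
#' @return a data.frame: `peptide`, `start`, `end`, `missed`.
#' @export
digest <- function(sequence, enzyme, max_missed = 0) {
  if (!is_standard_seq(sequence)) stop2("non-standard residue in sequence")
  chars <- strsplit(sequence, "")[[1]]
  bounds <- c(0L, cleavage_sites(chars, enzyme), length(chars))
  out <- list()
  for (a in seq_len(length(bounds) - 1)) {
    for (b in (a + 1):min(a + 1 + max_missed, length(bounds))) {
      out[[length(out) + 1]] <- c(bounds[a] + 1L, bounds[b], b - a - 1L)
    }
  }
  m <- do.call(rbind, out)
  data.frame(peptide = substring(sequence, m[, 1], m[, 2]),
             start = m[, 1], end = m[, 2], missed = m[, 3])
}

apply_denovo_error <- function(pep) {
  # near-isobaric confusions, then uniform single-residue swap as fallback
  iso <- list(c("N", "GG"), c("GG", "N"), c("Q", "AG"), c("AG", "Q"))
  cand <- Filter(function(p) grepl(p[1], pep, fixed = TRUE), iso)
  if (length(cand) > 0 && stats::runif(1) < 0.5) {
    p <- cand[[sample(length(cand), 1)]]
    hits <- gregexpr(p[1], pep, fixed = TRUE)[[1]]
    at <- hits[sample(length(hits), 1)]
    list(peptide = paste0(substr(pep, 1, at - 1), p[2],
                          substr(pep, at + nchar(p[1]), nchar(pep))),
         type = paste0(p[1], ">", p[2]), pos = as.integer(at))
  } else {
    at <- sample(nchar(pep), 1)
    old <- substr(pep, at, at)
    new <- sample(setdiff(AA_ALPHABET, old), 1)
    substr(pep, at, at) <- new
    list(peptide = pep, type = paste0(old, ">", new), pos = at)
  }
}

#' Simulate a degraded archaeological sample from a reference panel
#'
#' Digests every protein of the source taxon (plus its clade marker) with
#' the configured enzymes, keeps peptides in the configured length range,
#' applies Bernoulli survival (reduced by `hydrolysis_penalty` for peptides
#' with > 50% of residues in \{S, D, N, E\}), then de novo sequencing error
#' (probability `p_err` per peptide: a near-isobaric confusion N<->GG /
#' Q<->AG when applicable, otherwise a random single-residue swap), then
#' per-site deamidation (N -> D, Q -> E with probability `p_deam`, recorded
#' in the `mods` column), and draws ALC scores (lower mean for error-bearing
#' peptides). Deterministic given `(cfg$seed, sample_id)`.
#'
#' @param refs a `reference_set` from [generate_references()] (or
#'   compatible).
#' @param source_taxon taxon whose proteome is sampled; must be in `refs`.
#' @param cfg a `synthetic_config`.
#' @param sample_id sample label (default `"sample1"`); also seeds the
#'   per-sample RNG stream.
#' @param plant_subst optional data.frame `entry_id`, `pos`, `alt`: amino
#'   acid substitutions planted into the source copy of the reference
#'   before digestion (ground truth for substitution-recovery tests).
#' @return a list: `table` (a `peptide_table`) and `truth`
#'   (source taxon, planted substitutions with reference residues,
#'   per-peptide provenance, digest/survival counts, noise parameters).
#' @export
degrade_sample <- function(refs, source_taxon, cfg, sample_id = "sample1",
                           plant_subst = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_reference_set(refs)
  own <- refs[refs$taxon == source_taxon & !refs$is_marker, , drop = FALSE]
  if (nrow(own) == 0) stop2("source_taxon '", source_taxon,
                            "' not present in reference set")
  clade <- unique(own$clade)
  markers <- refs[refs$is_marker & refs$clade %in% clade, , drop = FALSE]
  source <- rbind(own, markers)

  planted <- NULL
  if (!is.null(plant_subst) && nrow(plant_subst) > 0) {
    planted <- plant_subst
    planted$ref_res <- NA_character_
    for (i in seq_len(nrow(plant_subst))) {
      j <- match(plant_subst$entry_id[i], source$entry_id)
      if (is.na(j)) stop2("plant_subst entry not in source proteome: ",
                          plant_subst$entry_id[i])
      p <- plant_subst$pos[i]
      planted$ref_res[i] <- substr(source$sequence[j], p, p)
      substr(source$sequence[j], p, p) <- plant_subst$alt[i]
    }
  }

  set.seed(derive_seed(cfg$seed, sample_id))
  frags <- do.call(rbind, lapply(seq_len(nrow(source)), function(i) {
    do.call(rbind, lapply(cfg$enzymes, function(enz) {
      d <- digest(source$sequence[i], enz, cfg$max_missed_cleavages)
      d$entry_id <- source$entry_id[i]
      d$enzyme <- enz
      d
    }))
  }))
  len <- nchar(frags$peptide)
  frags <- frags[len >= cfg$len_range[1] & len <= cfg$len_range[2], ,
                 drop = FALSE]
  n_inrange <- nrow(frags)

  # hydrolysis-prone peptides (polar S/D/N/E-rich) survive less often
  frac_polar <- vapply(strsplit(frags$peptide, ""), function(ch) {
    mean(ch %in% c("S", "D", "N", "E"))
  }, numeric(1))
  p_keep <- cfg$p_survive * ifelse(frac_polar > 0.5,
                                   cfg$hydrolysis_penalty, 1)
  keep <- stats::runif(nrow(frags)) < p_keep
  frags <- frags[keep, , drop = FALSE]
  if (nrow(frags) == 0) {
    stop2("insufficient peptides: no peptides survived simulation for ",
          "sample '", sample_id, "' (p_survive = ", cfg$p_survive, ")")
  }

  n <- nrow(frags)
  peptide <- frags$peptide
  mods <- character(n)
  err_type <- rep(NA_character_, n)
  err_pos <- rep(NA_integer_, n)
  n_deam <- integer(n)
  for (i in seq_len(n)) {
    p <- peptide[i]
    if (stats::runif(1) < cfg$p_err) {
      e <- apply_denovo_error(p)
      p <- e$peptide
      err_type[i] <- e$type
      err_pos[i] <- e$pos
    }
    ch <- strsplit(p, "")[[1]]
    deam_at <- which(ch %in% c("N", "Q") & stats::runif(length(ch)) < cfg$p_deam)
    if (length(deam_at) > 0) {
      ch[deam_at] <- ifelse(ch[deam_at] == "N", "D", "E")
      p <- paste(ch, collapse = "")
      mods[i] <- format_mods(deam_at, rep("deamidation", length(deam_at)))
      n_deam[i] <- length(deam_at)
    }
    peptide[i] <- p
  }
  is_err <- !is.na(err_type)
  alc <- stats::rnorm(n,
                      mean = ifelse(is_err, cfg$alc_model[["mean_err"]],
                                    cfg$alc_model[["mean_good"]]),
                      sd = cfg$alc_model[["spread"]])
  alc <- round(pmin(100, pmax(0, alc)), 1)

  table <- new_peptide_table(
    sample_id = rep(sample_id, n), peptide = peptide, alc = alc,
    mods = mods, charge = sample(2:3, n, replace = TRUE),
    enzyme = frags$enzyme)
  validate_peptide_table(table)
  provenance <- data.frame(peptide = peptide, entry_id = frags$entry_id,
                           start = frags$start, end = frags$end,
                           enzyme = frags$enzyme, missed = frags$missed,
                           n_deamidated = n_deam,
                           error_type = err_type, error_pos = err_pos)
  list(table = table,
       truth = list(sample_id = sample_id, source_taxon = source_taxon,
                    planted_substitutions = planted,
                    provenance = provenance,
                    n_digested_in_range = n_inrange,
                    n_survived = n,
                    noise = list(p_survive = cfg$p_survive,
                                 hydrolysis_penalty = cfg$hydrolysis_penalty,
                                 p_deam = cfg$p_deam, p_err = cfg$p_err,
                                 seed = cfg$seed)))
}

RESIDUE_MASS <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565
DEAMIDATION_DELTA <- 0.98402

#' Emit theoretical fragment spectra for a peptide table
#'
#' Generates singly charged monoisotopic b- and y-ion m/z values for every
#' backbone cleavage (2(n-1) peaks for an n-residue peptide), with unit
#' intensities and precursor m/z `[M + zH]/z`. Deamidation annotations add
#' +0.98402 Da at their site when the annotated residue is still N/Q;
#' annotations on already-converted D/E residues add nothing (the residue
#' mass carries the shift). Deterministic.
#'
#' @param table a `peptide_table`.
#' @param charge precursor charge (default 1).
#' @return a list of `spectrum_record` objects, one per table row.
#' @export
emit_spectra <- function(table, charge = 1) {
  validate_peptide_table(table)
  lapply(seq_len(nrow(table)), function(i) {
    pep <- table$peptide[i]
    n <- nchar(pep)
    if (n < 2) stop2("row ", i, ": peptide too short for fragmentation")
    m <- unname(RESIDUE_MASS[strsplit(pep, "")[[1]]])
    md <- parse_mods(table$mods[i])
    deam <- md$pos[md$kind == "deamidation"]
    if (length(deam) > 0) {
      still_nq <- substring(pep, deam, deam) %in% c("N", "Q")
      m[deam[still_nq]] <- m[deam[still_nq]] + DEAMIDATION_DELTA
    }
    b <- cumsum(m)[seq_len(n - 1)] + PROTON_MASS
    y <- cumsum(rev(m))[seq_len(n - 1)] + WATER_MASS + PROTON_MASS
    new_spectrum(sprintf("%s_%05d", table$sample_id[i], i),
                 (sum(m) + WATER_MASS + charge * PROTON_MASS) / charge,
                 charge, c(b, y), rep(1, 2 * (n - 1)))
  })
}
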