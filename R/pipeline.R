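# Orchestration: the full attribution analysis (prep -> match -> similarity
# -> MDS -> adjacency -> attribution -> report) and the simulation workflow,
# as plain functions and as a subcommand CLI. Every pipeline value is the
# output of the corresponding standalone operation on the same inputs; the
# pipeline adds no code paths of its own.

default_thresholds <- function() {
  list(min_alc = 50, min_len = 6, stringent_min = 2, relaxed_min = 1,
       min_support = 2, max_subst = 1, il_equiv = TRUE, deam_tolerant = TRUE)
}

#' Run the full attribution analysis
#'
#' Reads query and reference-sample peptide tables, filters (ALC,
#' contaminants), collapses to canonical peptide sets, builds the pairwise
#' similarity matrix, embeds it by classical MDS, places peptides on the
#' reference proteins, makes tiered protein calls and substitution calls,
#' computes shared-protein adjacency weights, and ranks reference samples
#' per query. All intermediate tables are written to `out_dir` as TSV, plus
#' a machine-readable `report.json`; the report body is deterministic given
#' inputs and configuration.
#'
#' @param config a named list (or path to a JSON file) with entries:
#'   `queries` (peptide table TSV; every sample id in it is a query),
#'   `references` (peptide table TSV of reference-shell samples),
#'   `reference_fasta` (reference proteins for matching),
#'   `contaminants` (optional FASTA), `ref_meta` (optional TSV mapping
#'   reference `sample_id` to `taxon`/`clade`; defaults to sample id as
#'   taxon), `out_dir`, `mode` (`"overlap"`/`"jaccard"`), `k` (MDS
#'   dimension, default 2), `seed` (recorded; the analysis itself is
#'   deterministic), and any of the thresholds `min_alc`, `min_len`,
#'   `stringent_min`, `relaxed_min`, `min_support`, `max_subst`,
#'   `il_equiv`, `deam_tolerant`.
#' @return the report, invisibly: a list with per-query attributions,
#'   protein calls, substitution grid, MDS coordinates and a provenance
#'   block.
#' @export
run_attribute <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (key in c("queries", "references", "reference_fasta", "out_dir")) {
    if (is.null(config[[key]])) stop2("config lacks required entry '", key, "'")
  }
  th <- utils::modifyList(default_thresholds(),
                          config[intersect(names(config),
                                           names(default_thresholds()))])
  mode <- if (is.null(config$mode)) "overlap" else config$mode
  k <- if (is.null(config$k)) 2 else config$k
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop2("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  qt <- stage("read", read_peptide_table(config$queries))
  rt <- stage("read", read_peptide_table(config$references))
  refs <- stage("read", read_fasta(config$reference_fasta))
  contaminants <- if (!is.null(config$contaminants)) {
    stage("read", read_fasta(config$contaminants))
  } else NULL

  query_ids <- unique(qt$sample_id)
  ref_ids <- unique(rt$sample_id)
  if (length(query_ids) < 1 || length(ref_ids) < 2) {
    stop2("need at least 1 query and 2 reference samples")
  }
  prep <- function(t) {
    t <- filter_alc(t, th$min_alc)
    if (!is.null(contaminants)) t <- filter_contaminants(t, contaminants)
    t
  }
  qt <- stage("prep", prep(qt))
  rt <- stage("prep", prep(rt))
  starved <- setdiff(c(query_ids, ref_ids),
                     unique(c(qt$sample_id, rt$sample_id)))
  if (length(starved) > 0) {
    stop2("insufficient peptides: sample '", starved[1],
          "' has no peptides after filtering")
  }
  all_t <- rbind(qt, rt)
  class(all_t) <- class(qt)
  sets <- lapply(stats::setNames(nm = c(query_ids, ref_ids)), function(s) {
    collapse_peptides(all_t, s, th$min_len, th$il_equiv, th$deam_tolerant)
  })
  empty <- names(sets)[vapply(sets, nrow, integer(1)) == 0]
  if (length(empty) > 0) {
    stop2("insufficient peptides: sample '", empty[1],
          "' has no peptides after filtering")
  }

  sm <- stage("similarity", build_similarity_matrix(sets, mode))
  dm <- to_distance(sm)
  emb <- stage("mds", classical_mds(dm, k))

  ref_meta <- if (!is.null(config$ref_meta)) {
    utils::read.delim(config$ref_meta, stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = ref_ids, taxon = ref_ids,
               clade = rep("unknown", length(ref_ids)))
  }
  attributions <- lapply(stats::setNames(nm = query_ids), function(q) {
    attribute_sample(q, sm, ref_ids, ref_meta)
  })

  match_sample <- function(s) {
    pl <- place_peptides(sets[[s]], refs, th$max_subst, th$il_equiv,
                         th$deam_tolerant, th$min_len)
    compute_coverage(pl, refs, s)
  }
  q_profiles <- stage("match", unlist(lapply(query_ids, match_sample),
                                      recursive = FALSE))
  r_profiles <- stage("match", unlist(lapply(ref_ids, match_sample),
                                      recursive = FALSE))
  q_calls <- call_proteins(q_profiles, th$stringent_min, th$relaxed_min)
  r_calls <- call_proteins(r_profiles, th$stringent_min, th$relaxed_min)
  subs <- call_substitutions(q_profiles, refs, th$min_support,
                             th$il_equiv, th$deam_tolerant)
  adj <- stage("adjacency", adjacency_weights(q_calls, r_calls))

  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_matrix(sm$s, file.path(out_dir, "similarity.tsv"))
  write_matrix(dm$d, file.path(out_dir, "distance.tsv"))
  coords <- data.frame(sample_id = emb$labels, emb$coords)
  names(coords) <- c("sample_id", paste0("dim", seq_len(k)))
  wt(coords, "mds.tsv")
  attr_tab <- do.call(rbind, lapply(query_ids, function(q) {
    cbind(query = q, attributions[[q]])
  }))
  wt(attr_tab, "attribution.tsv")
  calls_tab <- rbind(cbind(role = "query", q_calls),
                     cbind(role = "reference", r_calls))
  calls_tab$flag <- ifelse(calls_tab$tier == "relaxed", "*", "")
  wt(calls_tab, "protein_calls.tsv")
  wt(subs, "substitutions.tsv")
  wt(adj$pairs, "adjacency_pairs.tsv")
  wt(data.frame(reference = names(adj$ref_segment),
                segment = unname(adj$ref_segment)),
     "adjacency_ref_segments.tsv")

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config[order(names(config))], cfg_path,
                       auto_unbox = TRUE, pretty = TRUE)
  report <- list(
    queries = query_ids, references = ref_ids,
    attributions = lapply(attributions, function(a) {
      list(top_hit = a$reference_id[1], top_taxon = a$taxon[1],
           top_score = a$score[1],
           no_signal = isTRUE(attr(a, "no_signal")),
           ranking = a)
    }),
    protein_calls = calls_tab,
    mds = list(coords = coords, eigenvalues = emb$eigenvalues,
               stress1 = emb$stress1),
    adjacency = adj,
    provenance = list(package_version =
                        as.character(utils::packageVersion("shellome")),
                      config = config,
                      config_digest = unname(tools::md5sum(cfg_path)),
                      seed = config$seed,
                      thresholds = th, mode = mode, k = k))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Simulate a reference panel and degraded query samples to disk
#'
#' Writes the reference FASTA, one peptide-table TSV and truth JSON per
#' simulated query sample, optional MGF spectra, and a manifest with MD5
#' checksums of every emitted file. Identical configuration and seed yield
#' identical manifests.
#'
#' @param cfg a `synthetic_config`.
#' @param out_dir output directory.
#' @param samples_per_taxon simulated query samples per taxon (default 3).
#' @param spectra also emit MGF fragment spectra (default `FALSE`).
#' @param force allow writing into a non-empty directory (default `FALSE`).
#' @return the manifest data.frame (`file`, `md5`), invisibly.
#' @export
run_simulate <- function(cfg, out_dir, samples_per_taxon = 3,
                         spectra = FALSE, force = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop2("output directory not empty (use force = TRUE): ", out_dir)
  }
  if (cfg$n_taxa == 1) {
    warning("n_taxa = 1: attribution on this panel is trivially degenerate")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- generate_references(cfg)
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  fa <- file.path(out_dir, "references.fasta")
  write_fasta(panel$refs, fa)
  emit(fa)
  tj <- file.path(out_dir, "references_truth.json")
  jsonlite::write_json(panel$truth, tj, auto_unbox = TRUE, pretty = TRUE)
  emit(tj)

  for (taxon in panel$truth$taxa) {
    for (s in seq_len(samples_per_taxon)) {
      sid <- sprintf("%s_s%d", taxon, s)
      sim <- degrade_sample(panel$refs, taxon, cfg, sample_id = sid)
      tsv <- file.path(out_dir, paste0(sid, ".tsv"))
      write_peptide_table(sim$table, tsv)
      emit(tsv)
      tr <- file.path(out_dir, paste0(sid, "_truth.json"))
      jsonlite::write_json(sim$truth, tr, auto_unbox = TRUE, pretty = TRUE)
      emit(tr)
      if (spectra) {
        mgf <- file.path(out_dir, paste0(sid, ".mgf"))
        write_mgf(emit_spectra(sim$table), mgf)
        emit(mgf)
      }
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# --- command-line interface ---------------------------------------------

cli_parse <- function(args) {
  opts <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(opts = opts, positional = positional)
}

cli_log <- function(...) message("[shellome] ", ...)

#' Command-line entry point
#'
#' Subcommands: `simulate`, `prep`, `match`, `similarity`, `mds`,
#' `adjacency`, `spectra`, `attribute`, `report`. Run via
#' `Rscript -e 'quit(status = shellome::shellome_cli())' -- <subcommand> ...`
#' or the wrapper script in `inst/cli/`. Flags mirror the [run_attribute()]
#' config keys; `--config file.json` supplies defaults that individual flags
#' override.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return an integer exit status: 0 success, 2 input error,
#'   3 insufficient-data outcome.
#' @export
shellome_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: shellome <subcommand> [--flag value ...]",
    "subcommands: simulate prep match similarity mds adjacency spectra",
    "             attribute report", sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(2L)
  }
  parsed <- cli_parse(args[-1])
  opts <- parsed$opts
  sub <- args[1]
  t0 <- proc.time()[["elapsed"]]
  status <- tryCatch({
    switch(sub,
      simulate = {
        cfg <- synthetic_config(
          n_taxa = as.integer(opts$n_taxa %||% 4),
          p_survive = as.numeric(opts$p_survive %||% 0.3),
          p_deam = as.numeric(opts$p_deam %||% 0.3),
          p_err = as.numeric(opts$p_err %||% 0.05),
          mu = as.numeric(opts$mu %||% 0.05),
          seed = as.integer(opts$seed %||% 1))
        run_simulate(cfg, opts$out %||% stop2("--out required"),
                     samples_per_taxon = as.integer(opts$samples %||% 3),
                     spectra = isTRUE(opts$spectra) ||
                       identical(opts$spectra, "true"),
                     force = isTRUE(opts$force))
        0L
      },
      prep = {
        t <- read_peptide_table(opts$`in` %||% stop2("--in required"))
        t <- filter_alc(t, as.numeric(opts$min_alc %||% 50))
        if (!is.null(opts$contaminants)) {
          t <- filter_contaminants(t, read_fasta(opts$contaminants))
        }
        write_peptide_table(t, opts$out %||% stop2("--out required"))
        0L
      },
      match = {
        t <- read_peptide_table(opts$`in` %||% stop2("--in required"))
        refs <- read_fasta(opts$refs %||% stop2("--refs required"))
        calls <- do.call(rbind, lapply(unique(t$sample_id), function(s) {
          peps <- collapse_peptides(t, s,
                                    as.integer(opts$min_len %||% 6))
          pl <- place_peptides(peps, refs,
                               as.integer(opts$max_subst %||% 1))
          call_proteins(compute_coverage(pl, refs, s),
                        as.integer(opts$stringent_min %||% 2),
                        as.integer(opts$relaxed_min %||% 1))
        }))
        utils::write.table(calls, opts$out %||% stop2("--out required"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      similarity = {
        t <- read_peptide_table(opts$`in` %||% stop2("--in required"))
        sets <- lapply(stats::setNames(nm = unique(t$sample_id)), function(s)
          collapse_peptides(t, s, as.integer(opts$min_len %||% 6)))
        sm <- build_similarity_matrix(sets, opts$mode %||% "overlap")
        write_matrix(sm$s, opts$out %||% stop2("--out required"))
        0L
      },
      mds = {
        s <- read_matrix(opts$`in` %||% stop2("--in required"))
        sm <- structure(list(labels = rownames(s), s = s,
                             n_intersect = s * 0), class = "similarity_matrix")
        emb <- classical_mds(to_distance(sm), as.integer(opts$k %||% 2))
        out <- data.frame(sample_id = emb$labels, emb$coords)
        utils::write.table(out, opts$out %||% stop2("--out required"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cli_log("stress1 = ", format(emb$stress1, digits = 4))
        0L
      },
      adjacency = {
        q <- utils::read.delim(opts$query_calls %||%
                                 stop2("--query_calls required"))
        r <- utils::read.delim(opts$ref_calls %||%
                                 stop2("--ref_calls required"))
        adj <- adjacency_weights(q, r)
        utils::write.table(adj$pairs, opts$out %||% stop2("--out required"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      spectra = {
        t <- read_peptide_table(opts$`in` %||% stop2("--in required"))
        write_mgf(emit_spectra(t, as.integer(opts$charge %||% 1)),
                  opts$out %||% stop2("--out required"))
        0L
      },
      attribute = {
        config <- if (!is.null(opts$config)) {
          jsonlite::read_json(opts$config, simplifyVector = TRUE)
        } else list()
        flags <- opts[setdiff(names(opts), "config")]
        config[names(flags)] <- flags
        report <- run_attribute(config)
        for (q in report$queries) {
          a <- report$attributions[[q]]
          cli_log(q, " -> ", a$top_hit, " (score ",
                  format(a$top_score, digits = 4),
                  if (a$no_signal) ", NO SIGNAL" else "", ")")
        }
        0L
      },
      report = {
        path <- file.path(opts$dir %||% stop2("--dir required"), "report.json")
        rep <- jsonlite::read_json(path, simplifyVector = TRUE)
        for (q in rep$queries) {
          a <- rep$attributions[[q]]
          cli_log(q, " -> ", a$top_hit, " (score ",
                  format(a$top_score, digits = 4), ")")
        }
        0L
      },
      {
        message(usage)
        2L
      })
  }, error = function(e) {
    msg <- conditionMessage(e)
    cli_log("error: ", msg)
    if (grepl("insufficient", msg)) 3L else 2L
  })
  cli_log(sub, " finished in ",
          format(proc.time()[["elapsed"]] - t0, digits = 3), "s")
  status
}

`%||%` <- function(a, b) if (is.null(a)) b else a
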