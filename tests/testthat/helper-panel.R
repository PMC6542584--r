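# Shared fixtures, built in code.

make_table <- function(sample_id, peptide, alc = 90, mods = "", charge = 2L,
                       enzyme = "trypsin") {
  n <- length(peptide)
  shellome:::new_peptide_table(
    sample_id = rep_len(sample_id, n), peptide = peptide,
    alc = rep_len(alc, n), mods = rep_len(mods, n),
    charge = rep_len(charge, n), enzyme = rep_len(enzyme, n))
}

make_refs <- function(sequence, entry_id = sprintf("r%d", seq_along(sequence)),
                      taxon = "unknown", clade = "unknown",
                      is_marker = FALSE) {
  shellome:::new_reference_set(
    entry_id = entry_id,
    description = entry_id,
    taxon = rep_len(taxon, length(sequence)),
    clade = rep_len(clade, length(sequence)),
    is_marker = rep_len(is_marker, length(sequence)),
    sequence = sequence)
}

make_spectrum <- function(mz, intensity = rep(1, length(mz)),
                          precursor = 500, id = "s1", charge = 2L) {
  shellome:::new_spectrum(id, precursor, charge, mz, intensity)
}

# small panel + per-taxon "modern shell" reference peptide lists, used by
# several test files; kept small for speed
small_panel <- function(seed = 11, n_proteins = 3) {
  cfg <- synthetic_config(n_proteins_per_taxon = n_proteins, seed = seed)
  panel <- generate_references(cfg)
  ref_cfg <- synthetic_config(n_proteins_per_taxon = n_proteins,
                              p_survive = 0.8, p_deam = 0.05, p_err = 0.05,
                              seed = seed)
  refsets <- lapply(stats::setNames(nm = panel$truth$taxa), function(t) {
    sim <- degrade_sample(panel$refs, t, ref_cfg, paste0("ref_", t))
    collapse_peptides(sim$table, paste0("ref_", t))
  })
  list(cfg = cfg, ref_cfg = ref_cfg, refs = panel$refs,
       truth = panel$truth, refsets = refsets)
}
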