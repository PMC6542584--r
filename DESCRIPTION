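Package: shellome
Title: Taxonomic Attribution of Degraded Mollusc Shell Proteomes
Version: 0.1.0
Authors@R:
    person("Shellome", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for attributing degraded ("ancient") mollusc shell matrix
    proteomes to taxa when database coverage is poor. Implements
    database-independent peptide-list similarity scoring with classical
    multidimensional scaling, substitution-tolerant placement of de novo
    peptides onto reference proteins, coverage-based tiered marker-protein
    calls, amino-acid substitution detection with explicit ambiguity symbols,
    fragment-spectrum cosine similarity, and a ground-truthed simulator of
    degraded shell proteomes (in-silico trypsin/elastase digestion,
    hydrolysis-biased peptide loss, deamidation, de novo sequencing error)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
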