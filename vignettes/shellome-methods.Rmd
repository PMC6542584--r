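---
title: "Methods: attributing degraded shell proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing degraded shell proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellome)
```

## The analytical problem

Shell matrix proteins occluded in mollusc biominerals are the only
sequence-bearing molecules that survive in worked shell ornaments, but they
are an awkward analyte: concentrations are low, public databases cover only
a few dozen genera, a large fraction of every shell proteome is repeated
low-complexity (RLC) sequence shared across distant taxa, and diagenesis
both removes peptides (hydrolysis, biased towards polar Ser/Asp-rich
stretches) and rewrites them chemically (deamidation of Asn and Gln,
+0.984 Da). `shellome` implements an attribution pipeline built around
these constraints, and a simulator that reproduces them so that the
pipeline's claims are testable end to end.

## Canonicalization: matching under chemical equivalence

All matching happens on *canonical* residue strings: I→L (isobaric,
indistinguishable in standard MS/MS) and, by default, N→D / Q→E. Mapping
the deamidation products instead of tracking modification annotations makes
matching insensitive to whether an upstream de novo engine reports `N` with
a deamidation flag or `D` directly, and to whether the conversion happened
in the burial environment or in the lab. Both maps are idempotent, so
canonicalization is safely applied to peptides and references alike. The
cost is a small loss of specificity (true D/E and converted N/Q become
indistinguishable), accepted deliberately for ancient samples where
deamidation is pervasive; both flags are exposed if a user works with
fresh material.

Peptide lists are filtered before comparison: ALC (mean per-residue de novo
confidence) at an inclusive threshold of 50 %, the convention for de novo
data of this kind; contaminants removed by substring matching (under I/L
equivalence only) against a cRAP-style FASTA — deliberately enzyme-agnostic
and conservative; and canonical peptides shorter than 6 residues dropped,
since shorter strings match references by chance.

## Peptide-list similarity and MDS

The database-independent route scores two samples' unique canonical peptide
sets with the overlap coefficient

$$S(A,B) = \frac{|A \cap B|}{\min(|A|,|B|)}$$

The functional form of the original peptide-list comparison tools in this
field is generally unpublished; the overlap coefficient is this package's
own choice, made because archaeological lists are one to two orders of
magnitude smaller than reference digests, and Jaccard-style union
normalisation would let reference richness, not shared signal, dominate.
The Jaccard index is available as `mode = "jaccard"`, and the choice is
isolated behind the single function `pepmatch_score()`.

`D = 1 − S` is generally non-metric (triangle-inequality violations are
expected), so the embedding uses classical Torgerson scaling — double-centre
−½D², eigendecompose, clamp negative eigenvalues to zero, scale
eigenvectors by √λ — rather than iterative metric optimisation, and always
reports Kruskal's stress-1 so users can judge distortion. On genuinely
Euclidean input the procedure is exact (the test suite checks recovery of
planted planar configurations to 1e-6). Embedding orientation is
arbitrary; tests and downstream comparisons use embedded *distances*,
never raw coordinates.

Attribution ranks reference samples by similarity to the query, breaking
ties by raw intersection count and then input order; a top score of zero is
flagged `no_signal` rather than silently reported.

## Substitution-tolerant placement

Reference-based matching places each canonical peptide at every exact
substring occurrence across the reference set. Only when a peptide has no
exact placement anywhere does the search allow exactly one mismatch, and
then only: for peptides of ≥ 6 residues, and never at the first or last
residue (terminal residues are the least reliably called in de novo data,
and terminal "substitutions" would otherwise be spuriously common). The
published substitution-tolerant searches in this space are score-based and
closed; this hard-edged rule trades recall for a search that is exhaustive,
deterministic, and verifiable against a brute-force oracle — which the test
suite does on hundreds of random instances.

"Unique peptide" means: all retained placements fall in one reference
entry. This is entry-level, not taxon-level, uniqueness — a peptide shared
by two entries of the same taxon supports neither uniquely. Multi-mapping
peptides still contribute to coverage everywhere they place. Coverage is
position presence (percentage of residues with depth ≥ 1), not
depth-weighted.

Protein calls are tiered purely by unique-peptide support: stringent at
≥ 2, relaxed at ≥ 1 (asterisk-flagged in reports), absent otherwise.
Search-engine protein scores (e.g. −10lgP) cannot be reproduced outside
the engine that defines them, so coverage is reported alongside the tier
instead of folding into it.

Substitution calls per reference position follow the alignment-table
conventions: `-` where depth is zero; the reference residue where all
observations agree; an alternative residue only with ≥ 2 concordant
alternative observations and no conflicting alternative; `?` otherwise.
Raising `min_support` can only reduce residue calls (tested as a
monotonicity property).

## Spectrum-level route

`cosine_score()` pairs peaks greedily 1:1 by ascending m/z difference
within 0.02 Da and normalises by full intensity norms, so unmatched peaks
penalise the score; greedy pairing (not optimal assignment) is
deterministic and adequate at these tolerances. Sample-level similarity is
the symmetrised fraction of spectra with a qualifying match (cosine ≥ 0.7
among precursors within 1.5 Da). The 0.02 Da fragment and 1.5 Da precursor
tolerances are Orbitrap-plausible defaults; the thresholds are exposed.
This route exists as a cross-check: the acceptance suite requires its
taxon ranking to agree with the peptide-level route's top hit in ≥ 90 % of
simulated replicates.

## What the simulator emulates — and what it does not

`generate_references()` builds the confound that motivates the whole
design: a pool of RLC blocks (poly-A runs of 5–15, (GA)₃₋₈ repeats,
G-rich stretches of 8–20 residues) reused *verbatim* across all taxa,
interleaved with 25–60-residue unique segments derived from one shared
random ancestor by per-site substitution at rate `mu` (default 0.05 between
taxa). One RLC-free marker protein per clade is carried only by that
clade's taxa. `degrade_sample()` then digests with trypsin (after K/R, not
before P) and elastase (after A/V/S/G/L/I, the broad search-engine
convention — the narrower literature variants are configurable via the
code's residue set) at ≤ 2 missed cleavages, keeps 6–30-mers, and applies:

* **survival** — Bernoulli at `p_survive` (0.3 for "ancient" queries, 0.8
  for "modern" reference shells; the field reports no quantitative loss
  rates, so these are calibration settings chosen once), multiplied by
  `hydrolysis_penalty` (0.3) when > 50 % of residues are S/D/N/E —
  hydrolysis-prone, polar stretches;
* **de novo error** — probability 0.05 per peptide: a near-isobaric
  confusion (N↔GG, Q↔AG) when applicable, otherwise a uniform
  single-residue swap; error is applied *before* deamidation so that at
  `p_deam = 1` no N/Q can survive in the output;
* **deamidation** — per-site N→D/Q→E at `p_deam` (0.3 for ancient
  samples), applied in the sequence and annotated in `mods`;
* **ALC scores** — Gaussian, mean 82 (clean) / 62 (error-bearing),
  sd 8, clamped to [0, 100].

Every emitted peptide carries provenance (source protein, coordinates,
applied noise), and all randomness flows from a stream derived from
`(seed, sample_id)`, so each sample is independently reproducible.

The simulator does **not** model retention time, peak intensities, isotope
envelopes, chimeric spectra, or racemization (which has no sequence-level
representation). A green end-to-end test therefore establishes that the
pipeline's logic resolves taxa despite shared RLC content, deamidation and
sequencing error at the stated rates — not that it would perform
identically on any particular instrument's output.

## Numerical and degenerate-input choices

* Matrix TSVs are written with 6 significant digits; round trips agree
  within 1e-6.
* MDS on an all-zero distance matrix returns coincident points with
  stress 0 (the zero-denominator case is defined, not NaN).
* Empty peptide sets reject `pepmatch_score()` (the score is undefined)
  and empty post-filter samples abort the pipeline with an explicit
  "insufficient peptides" outcome (CLI exit code 3) rather than a silent
  zero.
* Placement ties are ordered (fewest mismatches, leftmost start, entry
  input order), making reports byte-stable.
* Fragment m/z uses monoisotopic residue masses with +0.98402 Da applied
  for deamidation annotations only when the annotated residue is still
  N/Q — annotations on already-converted D/E add nothing, since the
  residue mass itself carries the shift.

## Scale of the validation runs

The acceptance suite runs the stated scales (200-instance oracle
comparisons, 100 attribution replicates, 50 marker samples). The spectral
concordance check uses 20 replicates on a reduced panel (2 proteins per
taxon, query spectra capped at 120 per replicate): spectrum-level
comparison is quadratic in practice and the reduced panel keeps the run
inside its time budget without changing the property being tested.

## Known limitations

* Exact canonical matching only: the equivalence classes carry all the
  fuzziness, so a peptide with two real substitutions relative to the
  reference is never placed.
* Entry-level uniqueness means paralogue-rich reference sets depress
  unique-peptide counts and can demote genuinely present proteins to the
  relaxed tier.
* The overlap coefficient saturates when one list nearly contains the
  other; attribution between two near-identical reference taxa then rests
  on the intersection-count tie-break.
* Tiering by unique peptides only is a documented deviation from
  engine-score-based practice and is not calibrated to any FDR.
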