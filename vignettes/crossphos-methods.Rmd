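---
title: "Methods: cross-species analysis of hormone-responsive phosphoproteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species analysis of hormone-responsive phosphoproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossphos)
```

# Overview

`crossphos` compares hormone-induced protein phosphorylation across plant
species, starting from label-free quantification (LFQ) tables of localized
phosphopeptides and per-species proteome FASTA files. The motivating use
case is abscisic acid (ABA) signaling: seedlings of three species are
treated and sampled at 0, 15, 30 and 90 min with three biological
replicates, phosphopeptides are quantified by MS1 intensity, and the
question is which phosphorylation responses are conserved across species
and which are lineage-specific.

The pipeline has five analysis stages:

1. **Quantification I/O and dataset summaries** — readers for the TSV/FASTA
   interchange formats, enrichment efficiency, pS/pT/pY composition, and
   site-multiplicity distributions.
2. **Responsiveness calling** — a peptide is hormone-responsive when its
   abundance increases more than 2-fold with Student's t-test p < 0.05 at
   at least one post-treatment timepoint.
3. **Motif enrichment** — iterative motif-x style search over 13-residue
   windows centered on responsive phosphosites against a whole-proteome
   S/T/Y background.
4. **Ortholog mapping** — OrthoMCL-style group catalogue plus lowest-E-value
   best-hit assignment for species absent from the catalogue.
5. **Conservation accounting** — per-reference conservation matrices,
   three-set Venn regions of responsive ortholog groups, and alignment-based
   classification of individual phosphosites.

A seeded synthetic-data generator with planted ground truth stands in for
the deposited raw data, so every stage is testable offline.

# Responsiveness model

For each peptide and each tested timepoint $t \in \{15, 30, 90\}$ min
against the 0 min baseline:

* **Fold change** is the ratio of linear-scale replicate means, keeping the
  field's convention of quoting fold changes on the natural scale; a
  baseline mean of zero or fewer than 2 usable replicates on either side
  makes the timepoint *not testable*.
* **p-value** is a two-sided, unpaired, pooled-variance Student's t-test on
  log2 abundances. Log2 stabilizes the multiplicative error of LFQ
  intensities; the pooled (classical) form is used because that is what
  "Student's t-test" denotes, with Welch available via
  `stat_config(var_equal = FALSE)`. Degenerate variance is resolved by
  convention: equal means give p = 1, unequal means give p = 0.
* The peptide is **responsive** iff some tested timepoint passes both
  *strict* gates (FC > 2 and p < 0.05). Only increases are called; decreases
  are visible in the output table but excluded from conservation analysis.
* No multiple-testing correction is applied by default (the decision rule
  is a raw p < 0.05 gate); Benjamini-Hochberg is available via
  `stat_config(p_adjust = "BH")`.
* Missing abundances are never imputed and never treated as zero. A
  condition is usable with at least 2 of 3 replicates. A peptide with no
  testable timepoint is flagged `"insufficient data"` and can never be
  responsive.

A protein is responsive iff at least one of its phosphopeptides is. PCA QC
runs on the column-centered log2 matrix after dropping incomplete rows,
with a deterministic sign convention (the largest-magnitude loading of each
component is positive) so that repeated runs are identical.

# Motif enrichment

Foreground windows are the 6 residues on either side of each responsive
phosphosite (13-mers, `_`-padded at protein termini); the background is
every S/T/Y window of the species' full proteome — all catalogued proteins,
not only detected ones (configurable). S and T centers are pooled into one
S/T class, matching how such motifs are reported (e.g. `R-x-x-pS/pT`);
Y is searched separately.

Each candidate (offset, residue) pair is scored by the binomial upper tail
$P(X \ge k)$, $X \sim \mathrm{Bin}(n, p_0)$, where $k$ is the foreground
count, $n$ the number of foreground windows with a real (non-pad) residue
at that offset, and $p_0$ the frequency of the residue at that offset in
the current background (pads excluded). The most significant pair passing
$k > 10$ (strict) and $p < 10^{-6}$ is fixed; foreground and background are
reduced to matching windows; the search repeats. When no pair qualifies the
accumulated pairs are emitted as a motif, its windows leave the pool, the
background is restored, and the search restarts — so motifs partition the
foreground and each window is attributed to at most one motif. Ties are
broken by larger $k$, then smaller |offset|, then alphabetical residue; the
chain is total, making the procedure deterministic. Recomputing $p_0$ from
the *reduced* background at each step follows the canonical motif-x scheme.

# Ortholog mapping

The group catalogue is an OrthoMCL-style text file
(`OG7_0000009: ath|ACC osa|ACC ...`); each accession may belong to at most
one group. A species absent from the catalogue is assigned per protein by
similarity: hits with E-value strictly below $10^{-5}$ are considered and
the query inherits the group of the lowest-E subject (ties: higher bit
score, then lexicographically smallest accession).

Two interchangeable similarity backends feed the same rule. The internal
backend computes exact Smith-Waterman local alignments (BLOSUM62, affine
gaps 11/1, `X` scores 0) and converts raw scores with Karlin-Altschul
statistics, $\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ and
$E = mn\,2^{-\mathrm{bits}}$ with the standard gapped-BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$. Alternatively a 12-column BLAST tabular
file computed externally can be ingested. The internal backend is exact
and deterministic at the package's working scales; the tabular path exists
for proteome-scale searches where a heuristic search engine is preferable.
Alignment itself is delegated to `Biostrings::pairwiseAlignment`, whose
affine-gap convention (first gap residue costs open + extend) matches the
scoring used throughout; the test suite verifies it against independent
brute-force dynamic-programming oracles.

# Conservation accounting

For a reference species, each responsive protein either has an ortholog in
a target species (its group contains a member of that species) or not, and
the ortholog is itself responsive when the group contains a responsive
target-species protein. Both percentages are reported over the reference
species' responsive-protein count — matching the arithmetic conventionally
used with such matrices — to one decimal, rounding half away from zero.
At the group level, the three per-species responsive group sets yield the
seven regions of a three-set Venn diagram, tagged A (all three), B/C/D
(exactly two) and E/F/G (species-specific), plus pairwise overlap
percentages relative to each reference species' total.

Site-level conservation transfers a 1-based phosphosite coordinate through
a pairwise global (Needleman-Wunsch) alignment between ortholog partners,
using the same scoring as the local aligner. Pairwise alignment is used
instead of a multiple alignment because the classification compares *pairs*
of sites; within a group containing paralogs the partner with the highest
alignment bit score is taken and recorded. The traceback tie-break is the
aligner backend's deterministic convention. Categories:

* `conserved-responsive` — maps onto a responsive phosphosite;
* `conserved-residue-only` — maps onto S/T/Y that is not responsive;
* `position-not-conserved` — maps onto a gap or a non-phosphorylatable
  residue;
* `unalignable` — alignment bit score below the floor (default 25 bits,
  configurable), below which coordinate transfer is not trusted.

# Synthetic data and what it does (not) emulate

`generator_config()` defaults define the reference study conditions used by
the acceptance checks: 200 ortholog families evolved from founder proteins
(250-400 aa, proteome-like residue frequencies); a founder species, a
partner at 10% substitution divergence and a held-out species at 15%
divergence (both with rate-0.003 geometric indels, length cap 5, chosen so
coordinate mappings stay unambiguous); 40 unrelated decoy proteins per
species; 2000 phosphopeptides per species sampled from a tryptic-like
digest (cut after K/R, not before P; fragment lengths 9-35); 10% planted
responders at 4-fold from a random onset timepoint onward; log2 replicate
noise SD 0.1; pS/pT/pY mix 88/11.7/0.3 and site multiplicity 78.7/17.3/4.0
(the composition reported for such datasets); an `R` planted at offset -3
of 60% of responsive first sites; 5% missing cells; and 36 site families
planting cross-species site pairs that cycle through the three observable
conservation categories.

Design details worth knowing:

* Phosphosite residues are written into the protein sequences (at interior
  fragment offsets, so the -3 motif slot stays inside the peptide), and
  peptide sequences are sliced from the edited proteome, keeping proteome
  and tables perfectly consistent.
* Digest fragments covering a planted site pair are reserved for that pair:
  the general sampler cannot phosphorylate or motif-edit those positions,
  and the planted pair peptides are exempt from missing-value injection, so
  the planted category is actually realized in the emitted data. The
  planted pairs are the fixture's controlled contrast; stochastic dropout
  belongs to the rest of the table.
* Everything derives from the mandatory seed: the same seed gives
  byte-identical bundles, and the truth JSON suffices to score every
  recovery test without re-deriving.

What the generator does **not** emulate: acquisition-order and batch
effects, intensity-dependent missingness (an MNAR option is deliberately
left out of the defaults), site-localization ambiguity, shared peptides
between proteins, paralog families within a species, and real kinase-motif
grammar beyond the single planted motif. Passing the recovery tests
therefore shows the *decision rules* are implemented correctly under
controlled conditions, not that the pipeline is robust to every pathology
of real LFQ data.

# Numerical choices

* Percent rounding is half away from zero everywhere (`round_half_out()`):
  efficiencies as integer percent, distributions and rates to one decimal.
* The binomial tail uses `stats::pbinom`, stable for large $n$; the t-test
  uses `stats::t.test` with the degenerate-variance conventions wrapped
  around it.
* Problem sizes in the test suite: oracle equivalence on 200 random pairs
  of length ≤ 30 per aligner; binomial oracle on 1000 random triples; null
  calibration on a 1000-peptide null bundle; motif null specificity on 200
  seeded foregrounds of 500 windows; end-to-end recovery on the default
  200-family/2000-peptide bundle. These sizes make every distributional
  check well-powered while keeping a full run desk-scale.

# Known limitations

* The internal aligner is exact but quadratic; for real proteomes
  (tens of thousands of proteins) the tabular backend with an external
  search engine is the practical route.
* Group-level accounting inherits OrthoMCL's paralog lumping: overlap
  figures describe ortholog groups, not genes. Counts are per reference
  protein (a group with several responsive members contributes each of
  them), recorded in the output metadata.
* Whether a peptide-count is peptide sequences or peptide+site combinations
  is a dataset convention; the package counts table rows and counts each
  localized site once in residue/multiplicity summaries, taking the table
  as already site-localized.
* GO enrichment is intentionally out of scope; the pipeline exports plain
  accession lists suitable for external enrichment tools.
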