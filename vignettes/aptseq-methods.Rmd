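---
title: "Methods: joint aptamer and transcriptome deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint aptamer and transcriptome deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement this package models

Polyadenylated DNA aptamers bound to cell surfaces are captured by the same
poly-T bead primers as mRNA in a droplet barcoding run (Drop-seq-style
beads: a 12 nt cell barcode followed by an 8 nt UMI on read 1).  A single
sequencing library therefore mixes two read populations — aptamer
constructs (`flank5 + core + flank3 + poly-A`, under 200 bp) and cDNA
fragments — that share barcodes and UMIs and must be separated *in
silico*.  `aptseq` implements that separation and everything downstream of
it: cell calling, aptamer demultiplexing, transcript equivalence-class
counting, species-mixing coordinates, an SVD summary of the aptamer
profiles, and the qPCR standard-curve analysis used to validate aptamer
binding in bulk.

## Pipeline stages and their contracts

**Barcode extraction and cell calling.**  Read 1 is sliced positionally
(`barcode = read1[1..12]`, `umi = read1[13..20]` under the defaults).
Barcode abundance is tallied exactly, with no error correction and no
merging of near-identical barcodes; barcodes containing `N` are ordinary
distinct strings and fall below the threshold naturally.  Cells are the
barcodes with read count *strictly above* `min_barcode_count` (default
2000) — the wording "above" is implemented as `>`, and the threshold is
configurable.

**Aptamer demultiplexing.**  For each panel member, three overlapping
20-mers are taken from the construct at 0-based offsets `0`,
`floor((L - 20) / 2)` and `L - 20`.  The positions of the three query
20-mers within the construct are not dictated by the assay; spreading them
evenly across the construct (including both ends) maximises coverage and
is the package default, with `query_length` and `n_queries` exposed.  A
query matches a read if some window of the payload is within Hamming
distance 1 (substitutions only; indels are outside the matcher's
contract).  Reads matched by queries of two or more aptamers are set
aside as ambiguous rather than double-counted; reads matched by none are
passed to the transcript side.  Matching is forward-strand by default
because the simulated library is stranded; a reverse-complement toggle
exists for unstranded inputs.  Counts are distinct-UMI counts per (cell,
aptamer) under exact string identity — no directional or network UMI
correction is applied, so UMI collisions undercount molecules by an
enumerable amount (see the generator below).

**Transcript quantification.**  Rather than shelling out to an external
quantifier, the package carries a minimal k-mer pseudoaligner with the
same equivalence-class semantics: the compatibility set of a read is the
intersection of the transcript sets of all its indexed k-mers, unindexed
k-mers are skipped, and equal sets share one equivalence-class
identifier.  This keeps the stage fully testable against a brute-force
oracle at desk scale.  `k = 21` is the package default — a standard
odd k-mer size long enough that random 21-mers essentially never collide
in a toy reference — and is configurable.  No skipping heuristics,
expectation-maximisation, or gene-level aggregation are performed: counts
stop at equivalence classes, which is all the downstream display needs.
Reads already assigned (or ambiguous) on the aptamer side are excluded
from pseudoalignment so aptamer sequence cannot leak into equivalence
classes.

Cells are kept when their total distinct-UMI count is *at least*
`min_cell_umis` (default 4500) — "a minimum of" is implemented as `>=`,
deliberately different from the strict barcode threshold, following each
phrase's plain reading.  For display, the `top_n_features = 200` classes
with the highest across-cell sample variance of raw counts are selected;
variance is computed on raw counts because the selection feeds a
histogram of counts, and ties break lexicographically by feature id so
the selection is deterministic.

**Barnyard coordinates.**  Each equivalence class inherits the unique
species of its member transcripts, or `AMBIGUOUS` when they span species.
Per cell, counts are summed over each species' unambiguous classes;
`purity` is the larger share and `frac_a` (species A's share of assigned
counts) is the conventional display ordering key, drawn in decreasing
order.  A cell with no unambiguous counts gets `NA` rather than a number.

**SVD profile and colour mapping.**  The cell-by-aptamer matrix of the
filtered cells is column mean-centred and decomposed by full SVD.  Which
normalisation should precede centring is genuinely open (per cell, per
aptamer, log, or none), and the choice is consequential.  With per-cell
proportion scaling, a clean two-population mixture yields a centred
matrix whose mean structure is exactly rank one: the two population
indicators are perfectly anticorrelated after centring, so component 1
absorbs the entire between-type contrast and component 2 degenerates to
within-population sampling noise — the second component is then *not*
dominated by the type-B aptamer.  Raw-count centring instead preserves
per-cell staining-intensity variation, which is strong and
population-specific in this assay: type-A cells vary along their bound
trio (TD05/TD08/TE02), type-B cells along sgc8a.  Those two within-type
variation directions, plus the between-type contrast, give the
decomposition its documented two-component structure — a first component
with dominant, same-signed loadings on the trio and a second dominated by
sgc8a.  The pipeline therefore defaults to `normalization = "none"`, with
`"proportion"` and `"log"` available as configuration.

Sign conventions of an SVD are arbitrary, so each right singular vector
is oriented with its largest-magnitude loading positive, making results
reproducible run to run.  The colour table maps channel 1 (cyan) to the
min-max rescaled amplitude along component 1 and channel 2 (magenta) to
the rescaled *negated* amplitude along component 2: "inverse amplitude"
is read as sign inversion, because a reciprocal is undefined at amplitude
zero.  A note on "anticorrelated eigenvectors": per-cell amplitudes along
two singular vectors of a centred matrix are orthogonal by construction,
so their Pearson correlation is identically zero; the anticorrelation
that the two components express is that cells high in the trio signal are
low in sgc8a and vice versa, and the test suite asserts it on exactly
that quantity (correlation of the two group signals across cells,
required below −0.5 on simulated two-type data).

**qPCR.**  Under `C(n) = C0 * b^n`, observed Ct is regressed on log10 of
the known starting concentration (the standard-curve convention; the
regression orientation is configurable in principle but OLS of Ct on
log-concentration is what the replicate structure supports).  The slope
is `-1/log10(b)` and the intercept encodes the detection concentration
`C(n_Ct)`.  Unknowns are inverted per replicate and averaged; the
headline uncertainty combines the Bessel-corrected sample standard
deviation of the replicate estimates with the delta-method propagation of
the fit-parameter covariance, summed in quadrature — the two components
are also reported separately, since the combination rule is a package
choice.  The assay's detection limit is modelled as a maximum cycle
(default 40): any replicate Ct at or beyond it flags the estimate, and
enrichment ratios involving flagged estimates are reported as undefined
rather than numbers.

## The synthetic-data generator

Because the assay's real sequencing data are not publicly deposited, the
generator is the package's source of verifiable inputs, and its defaults
define the conditions under which the pipeline is validated:

* **Mixture.**  100 cells, 60 type A : 40 type B, from two species; type
  A expresses only species-A transcripts and vice versa, 6500 mean mRNA
  molecules per cell spread uniformly over 20 transcripts of length
  300 nt per species.
* **Panel.**  Eight aptamers.  TD05, TD08 and TE02 bind type A strongly
  (mean 150 molecules per cell), TD09 moderately (50), sgc8a binds type B
  (150), TC01 and TE17 are background (1), and sgc3b is absent (0,
  below detection).  Per-cell aptamer copy numbers are illustrative —
  the assay does not fix an absolute scale — and only their qualitative
  pattern matters to the structure tests.
* **Staining variability.**  Each cell carries a log-normal staining
  efficiency (`sdlog = 0.4`, roughly ±50% spread) multiplying its aptamer
  means.  This models cell-to-cell variation in staining and washing; it
  is applied to aptamer counts only, not mRNA capture, and it is what
  makes the two SVD components identifiable (see above).
* **Counts and depth.**  Molecule counts are Poisson with the configured
  means; each molecule is sequenced `Poisson(reads_per_molecule = 2)`
  times, so about 86% of molecules are observed and each cell yields
  roughly 5400–5800 distinct transcript UMIs — comfortably above the
  4500 filter.
* **Reads.**  Read 2 is the 3'-most 60 nt window of the transcript
  (poly-A capture geometry) or the 5' prefix of the aptamer construct;
  substitution errors are applied to the payload at
  `per_base_error_rate` (no indels, matching the matcher's contract;
  barcode and UMI bases are left clean, consistent with the pipeline's
  no-error-correction first pass).  UMIs are uniform random 8-mers with
  collisions allowed, so ground-truth comparisons must (and do) account
  for collision undercounting.  Ambient reads (default 5% of the
  library) carry barcodes belonging to no cell.
* **Reference sharing.**  A configurable fraction of transcripts
  (default 10%) receives a 50 nt window copied from another transcript,
  so multi-transcript and cross-species (ambiguous) equivalence classes
  genuinely occur.

What the generator does *not* emulate: quality-score structure, PCR
chimeras and duplicates beyond UMI multiplicity, indels, bead doublets,
barcode synthesis errors, droplet occupancy statistics, and any
sequence-dependent capture bias.  Passing tests on this generator
therefore demonstrate the correctness of the pipeline's logic under its
stated model, not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Matching and pseudoalignment are exact algorithms with no tolerances;
  both are verified against exhaustive oracles (sliding-window Hamming;
  per-k-mer set intersection) on ten thousand mixed payloads.
* SVD orthonormality and reconstruction are asserted at 1e-8; singular
  values are cross-checked against an independent eigendecomposition of
  the Gram matrix.
* Noiseless qPCR curves must invert to the generating parameters within
  1e-9 relative error; under Ct noise of 0.2 cycles the Monte-Carlo
  study (6 dilutions x 3 replicates, 500 repeats) requires the recovered
  amplification rate to be unbiased within three standard errors and the
  ±2-sd intervals to reach nominal coverage up to Monte-Carlo tolerance
  (the acceptance bound 0.92 is 0.954 minus about three binomial
  standard errors at 500 repeats, fixed before the study was run).
* Degenerate inputs fail loudly: empty Ct lists, rank-deficient standard
  curves, all-zero matrices, constructs shorter than the query length,
  transcripts shorter than k, and configs referencing unknown panel or
  reference entries are all errors; constant colour-map amplitudes warn
  and return 0.5.

## Problem sizes

The validation study uses 100 cells, ~690,000 molecules and ~1.45 million
read pairs, which the full pipeline processes in a couple of minutes on a
single core; the oracle-agreement and Monte-Carlo studies use 10,000
payloads/reads and 500 repeats respectively.  These sizes were chosen so
that every stage, including the exhaustive oracles, runs comfortably on a
laptop while leaving no stage untested at realistic per-cell depth.

## Known limitations

* Equivalence-class granularity depends entirely on the reference; toy
  references produce far fewer classes than a full transcriptome index,
  so class counts are not comparable across references.
* "Unique transcript reads" is interpreted as UMI-collapsed mapped reads;
  other definitions (e.g. position-aware deduplication) would shift the
  cell filter.
* The demultiplexer's one-mismatch Hamming window does not model indels;
  reads with an indel inside every query window are lost.
* No barcode error correction is attempted anywhere, by design; bead
  synthesis errors in real data would fragment cells into satellite
  barcodes below the retention threshold.
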