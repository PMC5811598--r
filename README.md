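# aptseq

Joint deconvolution of polyadenylated aptamer surface tags and mRNA from
droplet-barcoded single-cell sequencing reads.

## The problem

Aptamers — short DNA sequences that fold into epitope-binding structures —
can stain cell surfaces like antibodies do, but their sequence *is* the
detection tag: append a poly-A tail and they are captured, barcoded and
sequenced by the same poly-T bead chemistry as mRNA.  One droplet
barcoding run (Drop-seq-style beads: 12 nt cell barcode + 8 nt UMI on
read 1) then yields a single library in which aptamer reads and cDNA reads
share cell barcodes and UMIs and must be separated computationally.
`aptseq` is for analysts of such combined surface-profiling +
transcriptome experiments.  It provides:

* **Cell calling** — exact barcode tallies with no error correction;
  barcodes with read count strictly above a threshold (default 2000) are
  retained as cells.
* **Aptamer demultiplexing** — for each panel member, three overlapping
  20-mer queries over the construct `flank5+core+flank3`; a read belongs
  to an aptamer if some window of its payload is within Hamming distance
  1 of a query (ties between aptamers are discarded as ambiguous), and
  counts are distinct-UMI counts per cell and aptamer.
* **Transcript quantification** — a minimal k-mer pseudoaligner
  (default k = 21) that maps each read to a transcript *equivalence
  class*: the intersection of the transcript sets of its indexed k-mers.
  Cells need at least 4500 distinct transcript UMIs (inclusive) to pass;
  the 200 most variable classes are selected for display.
* **Barnyard coordinates** — per-cell counts over species-unambiguous
  classes, with purity and the decreasing species-A-fraction display
  ordering.
* **SVD profile** — the mean-centred cell-by-aptamer matrix is
  decomposed; per-cell amplitudes along the first two right singular
  vectors drive a cyan/magenta colour mapping (channel 2 uses the negated
  amplitude) for overlay on the barnyard plot.
* **qPCR analysis** — standard curves under `C(n) = C0·bⁿ` fitted by
  ordinary least squares of Ct on log10 concentration (slope
  `−1/log10 b`); unknown concentrations inverted per replicate with
  uncertainty that combines the Bessel-corrected replicate spread and
  delta-method propagation of the fit covariance; below-detection
  flagging and cell/supernatant enrichment ratios.
* **A synthetic-data generator** — ground-truth two-species cell
  mixtures, paired FASTQ reads and qPCR traces with known parameters, so
  every stage above is verifiable without external data.

## Worked example

Simulate the default study — 100 cells (60 type A : 40 type B, two
species), the eight-aptamer panel in which TD05/TD08/TE02 bind type A and
sgc8a binds type B, ~6500 transcript molecules per cell, zero sequencing
error — and run the full pipeline on the resulting FASTQ pair:

```r
library(aptseq)

panel <- default_panel()
reference <- generate_reference(20, 300, shared_fraction = 0.1, seed = 100)
config <- default_simulation_config(panel, reference,
                                    per_base_error_rate = 0, rng_seed = 101)

truth <- simulate_cells(config, panel, reference)
simulate_reads(truth, reference, panel, config,
               "reads_R1.fastq.gz", "reads_R2.fastq.gz")

res <- run_aptseq("reads_R1.fastq.gz", "reads_R2.fastq.gz", panel, reference)

length(res$retained_barcodes)
#> [1] 100
nrow(res$cells_kept)
#> [1] 100
summary(res$barnyard$purity)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max. 
#>       1       1       1       1       1       1 
res$decomposition
#> Profile decomposition: 100 cells x 8 aptamers
#> Singular values: 1366, 382, 85.46, 73.83, 53.88 ...
#> Leading loadings:
#>          PC1   PC2
#> TC01   0.000 0.012
#> TD05   0.496 0.250
#> TD08   0.509 0.279
#> TD09   0.169 0.072
#> TE02   0.501 0.264
#> TE17   0.000 0.003
#> sgc3b  0.000 0.000
#> sgc8a -0.464 0.886
```

All 100 true barcodes clear the 2000-read retention threshold and the
4500-UMI cell filter; every cell's transcriptome is species-pure
(purity 1), as expected at zero sequencing error.  The decomposition
shows the assay's signature structure: component 1 carries dominant,
same-signed loadings on the type-A trio TD05/TD08/TE02, and component 2
is dominated by the type-B aptamer sgc8a.  `res$colors` holds the
cyan/magenta channels per cell and `res$barnyard` the species
coordinates:

```r
head(res$barnyard[order(-res$barnyard$frac_a)], 3)
#>         barcode count_a count_b purity frac_a
#> 1: TCTTTTGGGCGT    5694       0      1      1
#> 2: GCTTAGTTCCCT    5715       0      1      1
#> 3: GAATGTTGACTA    5645       0      1      1
```

A thin command-line wrapper with `simulate`, `count`, `run` and `qpcr`
subcommands is installed at `inst/cli/aptseq.R`.

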