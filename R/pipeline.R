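# End-to-end deconvolution: FASTQ pair in, per-cell aptamer and transcript
# matrices, barnyard coordinates, SVD profile and colour table out.

#' Run the full aptamer + transcriptome deconvolution pipeline
#'
#' Executes the complete workflow on a paired FASTQ library: parse reads and
#' extract barcodes/UMIs; tabulate and retain high-count barcodes (strictly
#' above `min_barcode_count` reads); demultiplex aptamer reads by
#' mismatch-tolerant 20-mer matching and collapse them to a cell x aptamer
#' UMI matrix; pseudoalign the remaining reads (aptamer-assigned and
#' ambiguous reads are excluded so aptamer sequence cannot contaminate the
#' transcript equivalence classes) and collapse to a cell x equivalence-class
#' matrix; apply the inclusive `min_cell_umis` cell filter; select the most
#' variable classes for display; compute barnyard coordinates from the
#' species-unambiguous classes; and decompose the aptamer matrix of the
#' filtered cells by SVD with the two-channel colour mapping.
#'
#' @param fastq1,fastq2 Paired FASTQ paths (read 1 = barcode + UMI,
#'   read 2 = payload).
#' @param panel An [aptamer_panel].
#' @param reference A `transcript_reference`.
#' @param barcode_length,umi_length Read-1 layout (defaults 12 and 8).
#' @param min_barcode_count Barcode retention threshold, strict (default
#'   2000).
#' @param min_cell_umis Cell filter on total transcript UMIs, inclusive
#'   (default 4500).
#' @param k Pseudoaligner k-mer size (default 21).
#' @param top_n_features Number of most-variable equivalence classes kept
#'   for display (capped at the number available; default 200).
#' @param max_mismatch,query_length,n_queries Demultiplexer settings
#'   (defaults 1, 20, 3).
#' @param normalization Normalisation before SVD centring (default
#'   `"none"`; see [normalize_and_center]).
#' @param reverse_complement Also match reverse-complemented payloads
#'   (default `FALSE`).
#'
#' @return A list with elements `barcode_table`, `retained_barcodes`,
#'   `parsed` (the barcoded reads), `assignments`, `aptamer_counts`,
#'   `ec_counts`, `ec_table`, `cells_kept` (filtered equivalence-class
#'   matrix), `aptamer_counts_kept`, `top_features`, `barnyard`,
#'   `decomposition`, `colors`.
#' @export
run_aptseq <- function(fastq1, fastq2, panel, reference,
                       barcode_length = 12L, umi_length = 8L,
                       min_barcode_count = 2000L, min_cell_umis = 4500L,
                       k = 21L, top_n_features = 200L,
                       max_mismatch = 1L, query_length = 20L, n_queries = 3L,
                       normalization = "none",
                       reverse_complement = FALSE) {
  pairs <- read_fastq_pairs(fastq1, fastq2)
  parsed <- parse_read_pairs(pairs, barcode_length = barcode_length,
                             umi_length = umi_length)
  barcode_table <- count_barcodes(parsed)
  retained <- select_barcodes(barcode_table, min_barcode_count)

  queries <- build_queries(panel, query_length, n_queries)
  assignments <- match_reads(parsed, queries, max_mismatch,
                             reverse_complement)
  aptamer_counts <- collapse_umis(parsed, assignments, retained, panel$name)

  index <- build_kmer_index(reference, k)
  is_tx <- assignments$status == "unassigned"
  aln <- pseudoalign(parsed$payload[is_tx], index)
  ec <- rep(NA_character_, nrow(parsed))
  ec[is_tx] <- aln$ec
  ec_counts <- count_ec_umis(parsed, ec, retained, aln$ec_table$ec)

  cells_kept <- filter_cells(ec_counts, min_cell_umis)
  top_features <- top_variable_features(
    cells_kept, min(top_n_features, ncol(cells_kept)))
  barnyard <- barnyard_coordinates(cells_kept, aln$ec_table)

  apt_kept <- aptamer_counts[rownames(cells_kept), , drop = FALSE]
  attr(apt_kept, "feature_kind") <- "aptamer"
  centered <- normalize_and_center(apt_kept, normalization)
  decomposition <- svd_profile(centered)
  colors <- color_map(decomposition)

  list(barcode_table = barcode_table, retained_barcodes = retained,
       parsed = parsed, assignments = assignments,
       aptamer_counts = aptamer_counts, ec_counts = ec_counts,
       ec_table = aln$ec_table, cells_kept = cells_kept,
       aptamer_counts_kept = apt_kept, top_features = top_features,
       barnyard = barnyard, decomposition = decomposition, colors = colors)
}
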