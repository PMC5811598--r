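# Transcript quantification: k-mer pseudoalignment to equivalence classes,
# UMI-collapsed counting, the cell filter, variance-based feature selection,
# and species-mixing (barnyard) coordinates.

#' Build a k-mer index over a reference transcriptome
#'
#' Every k-mer of every transcript is recorded with the complete set of
#' transcripts containing it.
#'
#' @param reference A `transcript_reference` (see [generate_reference]).
#' @param k K-mer size (default 21; must not exceed any transcript length).
#' @return A list of class `kmer_index`: `k`, `map` (environment mapping
#'   k-mer string to an integer vector of transcript indices), `ids`,
#'   `species`, `sequences`.
#' @export
build_kmer_index <- function(reference, k = 21L) {
  seqs <- reference$sequences
  if (any(nchar(seqs) < k)) {
    stop("all transcripts must be at least as long as k = ", k)
  }
  dt <- data.table::rbindlist(lapply(seq_along(seqs), function(t) {
    s <- seqs[[t]]
    n <- nchar(s) - k + 1L
    data.table::data.table(kmer = substring(s, 1:n, k:(k + n - 1L)), tx = t)
  }))
  dt <- unique(dt)
  map <- list2env(lapply(split(dt$tx, dt$kmer), sort), hash = TRUE)
  structure(list(k = as.integer(k), map = map, ids = reference$ids,
                 species = reference$species, sequences = unname(seqs)),
            class = "kmer_index")
}

#' Pseudoalign read payloads to equivalence classes
#'
#' The compatibility set of a read is the intersection of the transcript
#' sets of all its indexed k-mers; k-mers absent from the index (including
#' any containing non-ACGT characters) are skipped.  A read is unmapped if
#' none of its k-mers is indexed or the intersection is empty.  Equal
#' compatibility sets share one equivalence-class identifier (assigned in
#' order of first appearance).
#'
#' @param payloads Character vector of read-2 sequences, or a data.table
#'   from [parse_read_pairs].
#' @param index A `kmer_index` from [build_kmer_index].
#' @return A list: `ec` (character vector, one equivalence-class id per
#'   read, `NA` for unmapped reads) and `ec_table` (data.table with `ec`,
#'   `transcripts` (list column of transcript ids), `species` — the unique
#'   species of the member transcripts, else `"AMBIGUOUS"`).
#' @export
pseudoalign <- function(payloads, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.data.frame(payloads)) payloads <- payloads$payload
  res <- cpp_pseudoalign(index$sequences, index$k, payloads)
  n_class <- length(res$classes)
  ec_ids <- sprintf("EC%04d", seq_len(n_class))
  tx_sets <- lapply(res$classes, function(ix) index$ids[ix])
  sp <- vapply(tx_sets, function(tx) {
    u <- unique(index$species[tx])
    if (length(u) == 1L) u else "AMBIGUOUS"
  }, character(1))
  list(
    ec = ifelse(res$ec > 0L, ec_ids[pmax(res$ec, 1L)], NA_character_),
    ec_table = data.table::data.table(ec = ec_ids, transcripts = tx_sets,
                                      species = sp)
  )
}

#' Count distinct UMIs per cell and equivalence class
#'
#' @param reads A data.table from [parse_read_pairs] (columns `barcode`,
#'   `umi`), row-aligned with `ec`.
#' @param ec Character vector of equivalence-class ids per read (`NA` for
#'   unmapped reads), from [pseudoalign].
#' @param retained_barcodes Cell barcodes to keep (row order of the result).
#' @param ec_ids Column order (default: classes seen in `ec`).
#' @return An integer matrix (cells x equivalence classes) with
#'   `attr(,"feature_kind") == "ec"`.
#' @export
count_ec_umis <- function(reads, ec, retained_barcodes, ec_ids = NULL) {
  stopifnot(nrow(reads) == length(ec))
  if (is.null(ec_ids)) ec_ids <- sort(unique(ec[!is.na(ec)]))
  dt <- data.table::data.table(
    barcode = reads$barcode, umi = reads$umi, feature = ec
  )[!is.na(feature) & barcode %in% retained_barcodes]
  umi_count_matrix(dt, retained_barcodes, ec_ids, "ec")
}

#' Filter cells by total unique transcript reads
#'
#' Keeps cells whose total UMI count is at least `min_unique_reads`
#' ("a minimum of 4500" is read inclusively).
#'
#' @param matrix A cell x equivalence-class count matrix.
#' @param min_unique_reads Inclusive threshold (default 4500).
#' @return The row-restricted matrix (feature kind preserved).
#' @export
filter_cells <- function(matrix, min_unique_reads = 4500L) {
  kind <- attr(matrix, "feature_kind")
  out <- matrix[rowSums(matrix) >= min_unique_reads, , drop = FALSE]
  attr(out, "feature_kind") <- kind
  out
}

#' Select the most variable features
#'
#' Features are ranked by across-cell sample variance of their raw counts;
#' ties are broken by feature id in lexicographic order so the selection is
#' deterministic.
#'
#' @param matrix A cell x feature count matrix.
#' @param n Number of features to keep (default 200; must not exceed the
#'   number of features).
#' @return The column-restricted matrix, most variable feature first.
#' @export
top_variable_features <- function(matrix, n = 200L) {
  if (n > ncol(matrix)) {
    stop("n = ", n, " exceeds the number of features (", ncol(matrix), ")")
  }
  kind <- attr(matrix, "feature_kind")
  v <- apply(matrix, 2L, var)
  ord <- order(-v, colnames(matrix))
  out <- matrix[, ord[seq_len(n)], drop = FALSE]
  attr(out, "feature_kind") <- kind
  out
}

#' Per-cell species-mixing (barnyard) coordinates
#'
#' Sums each cell's UMI counts over the equivalence classes unambiguously
#' assigned to each of the two species (classes labelled `AMBIGUOUS` are
#' ignored).  `purity` is the larger species count divided by their sum
#' (`NA` when a cell has no unambiguous counts at all), and `frac_a` — the
#' first species' share of assigned counts — is the display ordering key
#' (cells are conventionally drawn in decreasing `frac_a`).
#'
#' @param matrix A cell x equivalence-class count matrix.
#' @param ec_species Named character vector mapping equivalence-class id to
#'   species label (or a `pseudoalign` `ec_table`).
#' @return A data.table: `barcode`, `count_a`, `count_b`, `purity`,
#'   `frac_a`, with species labels recorded in
#'   `attr(, "species_levels")` (first = species A).
#' @export
barnyard_coordinates <- function(matrix, ec_species) {
  if (is.data.frame(ec_species)) {
    ec_species <- setNames(ec_species$species, ec_species$ec)
  }
  sp <- ec_species[colnames(matrix)]
  levels <- sort(unique(sp[sp != "AMBIGUOUS" & !is.na(sp)]))
  if (length(levels) != 2L) {
    stop("expected exactly two unambiguous species labels, got ",
         length(levels))
  }
  a <- rowSums(matrix[, which(sp == levels[1L]), drop = FALSE])
  b <- rowSums(matrix[, which(sp == levels[2L]), drop = FALSE])
  tot <- a + b
  out <- data.table::data.table(
    barcode = rownames(matrix),
    count_a = a, count_b = b,
    purity = ifelse(tot > 0, pmax(a, b) / tot, NA_real_),
    frac_a = ifelse(tot > 0, a / tot, NA_real_)
  )
  data.table::setattr(out, "species_levels", levels)
  out
}
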