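# Aptamer demultiplexing: mismatch-tolerant 20-mer query matching against
# read payloads, followed by UMI-collapsed cell x aptamer counting.

#' Build 20-mer query sets for an aptamer panel
#'
#' For each aptamer, `n_queries` overlapping `query_length`-mers are taken
#' from the construct `flank5 + core + flank3`, evenly spread so that both
#' ends are covered: for the default three queries over a construct of
#' length L the start offsets are 0, floor((L - k) / 2) and L - k
#' (0-based).  When the construct length equals the query length all
#' queries collapse to a single distinct query.
#'
#' @param panel An [aptamer_panel] (or any data.frame with `name` and
#'   `construct` columns).
#' @param query_length Query length k in nucleotides (default 20).
#' @param n_queries Queries per aptamer (default 3).
#' @return A data.table with columns `aptamer`, `query_index`, `offset`
#'   (0-based start within the construct) and `query`; duplicate queries
#'   arising from degenerate constructs are dropped.
#' @export
#' @examples
#' build_queries(default_panel())
build_queries <- function(panel, query_length = 20L, n_queries = 3L) {
  stopifnot(n_queries >= 1L, query_length >= 1L)
  L <- nchar(panel$construct)
  if (any(L < query_length)) {
    stop("construct shorter than the query length: ",
         paste(panel$name[L < query_length], collapse = ", "))
  }
  qs <- lapply(seq_len(nrow(panel)), function(i) {
    off <- unique(floor((L[i] - query_length) *
                          seq(0, 1, length.out = n_queries)))
    data.table::data.table(
      aptamer = panel$name[i],
      query_index = seq_along(off),
      offset = as.integer(off),
      query = substr(rep(panel$construct[i], length(off)),
                     off + 1L, off + query_length)
    )
  })
  data.table::rbindlist(qs)
}

#' Match read payloads against aptamer query sets
#'
#' A query matches a payload if some window of the payload has Hamming
#' distance at most `max_mismatch` to it (substitutions only, no indels).
#' A read is assigned to an aptamer when at least one of its queries
#' matches and no other aptamer's query does; reads matched by two or more
#' aptamers are `ambiguous`, reads matched by none (including payloads
#' shorter than the query length) are `unassigned`.
#'
#' @param payloads Character vector of read-2 sequences, or a data.table
#'   from [parse_read_pairs] (its `payload` column is used).
#' @param queries A query table from [build_queries].
#' @param max_mismatch Maximum Hamming distance per window (default 1).
#' @param reverse_complement Also match the reverse complement of each
#'   payload (default `FALSE`; the simulated library is stranded).
#' @return A data.table with one row per read: `aptamer` (`NA` unless
#'   assigned), `status` (`assigned`/`ambiguous`/`unassigned`), and for
#'   assigned reads the matched `query_index`, `mismatches` (0 or 1 under
#'   the default) and 1-based `position` of the best match (fewest
#'   mismatches, then leftmost, then lowest query index).
#' @export
match_reads <- function(payloads, queries, max_mismatch = 1L,
                        reverse_complement = FALSE) {
  if (is.data.frame(payloads)) payloads <- payloads$payload
  apt_names <- unique(queries$aptamer)
  apt_of_query <- match(queries$aptamer, apt_names)
  res <- cpp_match_reads(payloads, queries$query, apt_of_query,
                         length(apt_names), as.integer(max_mismatch))
  if (reverse_complement) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(payloads)))
    res2 <- cpp_match_reads(rc, queries$query, apt_of_query,
                            length(apt_names), as.integer(max_mismatch))
    res <- merge_strand_matches(res, res2)
  }
  out <- data.table::data.table(
    aptamer = ifelse(res$aptamer > 0L, apt_names[pmax(res$aptamer, 1L)],
                     NA_character_),
    status = c("ambiguous", "unassigned", "assigned")[sign(res$aptamer) + 2L],
    query_index = res$query_index,
    mismatches = res$mismatches,
    position = res$position
  )
  out
}

# Combine forward and reverse-complement match results: union of matched
# aptamer sets; forward-strand details win when both strands match the
# same single aptamer.
merge_strand_matches <- function(fwd, rev) {
  both <- fwd$aptamer
  for (i in seq_along(both)) {
    f <- fwd$aptamer[i]
    r <- rev$aptamer[i]
    if (f == -1L || r == -1L || (f > 0L && r > 0L && f != r)) {
      both[i] <- -1L
    } else if (f == 0L && r > 0L) {
      both[i] <- r
      fwd$query_index[i] <- rev$query_index[i]
      fwd$mismatches[i] <- rev$mismatches[i]
      fwd$position[i] <- rev$position[i]
    }
  }
  fwd$aptamer <- both
  fwd
}

#' Collapse aptamer assignments to a cell x aptamer UMI count matrix
#'
#' The count for a (cell, aptamer) pair is the number of distinct UMI
#' strings among that cell's reads assigned to that aptamer (exact string
#' identity, no UMI error correction).  Ambiguous and unassigned reads
#' contribute nothing, as do reads from barcodes outside `retained_barcodes`.
#'
#' @param reads A data.table from [parse_read_pairs] (columns `barcode`,
#'   `umi`), row-aligned with `assignments`.
#' @param assignments A data.table from [match_reads].
#' @param retained_barcodes Character vector of cell barcodes to keep; sets
#'   the row order of the result.
#' @param aptamer_names Column order of the result (default: aptamers seen
#'   in `assignments`).
#' @return An integer matrix (cells x aptamers) with
#'   `attr(,"feature_kind") == "aptamer"`.
#' @export
collapse_umis <- function(reads, assignments, retained_barcodes,
                          aptamer_names = NULL) {
  stopifnot(nrow(reads) == nrow(assignments))
  if (is.null(aptamer_names)) {
    aptamer_names <- sort(unique(assignments$aptamer[!is.na(assignments$aptamer)]))
  }
  dt <- data.table::data.table(
    barcode = reads$barcode,
    umi = reads$umi,
    feature = assignments$aptamer
  )[assignments$status == "assigned" & barcode %in% retained_barcodes]
  umi_count_matrix(dt, retained_barcodes, aptamer_names, "aptamer")
}

# Shared distinct-UMI counting: dt has columns barcode, umi, feature.
umi_count_matrix <- function(dt, row_barcodes, col_features, kind) {
  m <- matrix(0L, nrow = length(row_barcodes), ncol = length(col_features),
              dimnames = list(row_barcodes, col_features))
  if (nrow(dt) > 0L) {
    agg <- dt[, .(count = data.table::uniqueN(umi)), by = .(barcode, feature)]
    m[cbind(match(agg$barcode, row_barcodes),
            match(agg$feature, col_features))] <- agg$count
  }
  attr(m, "feature_kind") <- kind
  m
}

#' Feature kind of a count matrix
#'
#' @param m A count matrix produced by [collapse_umis] or [count_ec_umis].
#' @return `"aptamer"` or `"ec"` (or `NULL` for plain matrices).
#' @export
feature_kind <- function(m) attr(m, "feature_kind")
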