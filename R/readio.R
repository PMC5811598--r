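# First-pass read handling: extract barcode and UMI from read 1, tabulate
# exact barcode multiplicities without any error correction, and retain
# high-count barcodes.

#' Read a paired FASTQ file pair
#'
#' @param fastq1,fastq2 Paths to the read-1 and read-2 FASTQ files
#'   (optionally gzipped).  Records are paired by position; ids are taken
#'   from read 1, truncated at the first whitespace.
#' @return A data.table with columns `read_id`, `read1`, `read2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2)) {
    stop("read-1 and read-2 files contain different numbers of records")
  }
  data.table::data.table(
    read_id = sub("\\s.*$", "", names(r1)),
    read1 = as.character(r1),
    read2 = as.character(r2)
  )
}

#' Parse read pairs into barcoded reads
#'
#' Positional extraction under the configured layout: the first
#' `barcode_length` bases of read 1 are the cell barcode and the following
#' `umi_length` bases the UMI; read 2 is kept unmodified as the payload.
#' Pairs whose read 1 is shorter than `barcode_length + umi_length`, or
#' whose payload is empty, are rejected (counted, not kept).
#'
#' @param read1,read2 Character vectors of equal length, or a data.table
#'   from [read_fastq_pairs] as the first argument.
#' @param read_id Optional read identifiers (generated when missing).
#' @param barcode_length,umi_length Layout lengths (defaults 12 and 8).
#' @return A data.table with columns `read_id`, `barcode`, `umi`, `payload`
#'   and attribute `n_rejected`, the number of rejected pairs.
#' @export
#' @examples
#' parse_read_pairs("ACGTACGTACGTAAAATTTT", "ACGT")
parse_read_pairs <- function(read1, read2 = NULL, read_id = NULL,
                             barcode_length = 12L, umi_length = 8L) {
  if (is.data.frame(read1)) {
    read_id <- read1$read_id
    read2 <- read1$read2
    read1 <- read1$read1
  }
  stopifnot(length(read1) == length(read2))
  if (is.null(read_id)) read_id <- paste0("read", seq_along(read1))
  need <- barcode_length + umi_length
  ok <- nchar(read1) >= need & nchar(read2) > 0L
  out <- data.table::data.table(
    read_id = read_id[ok],
    barcode = substr(read1[ok], 1L, barcode_length),
    umi = substr(read1[ok], barcode_length + 1L, need),
    payload = read2[ok]
  )
  data.table::setattr(out, "n_rejected", sum(!ok))
  out
}

#' Tabulate exact barcode abundance
#'
#' Exact multiplicity per distinct barcode string, in the spirit of a
#' first pass without any error correction: near-identical barcodes are
#' never merged, and barcodes containing N are ordinary distinct strings.
#'
#' @param reads A data.table from [parse_read_pairs], or a character vector
#'   of barcodes.
#' @return A data.table of class `barcode_table` with columns `barcode` and
#'   `count`, sorted by decreasing count (ties by barcode), and attribute
#'   `total_reads`.
#' @export
count_barcodes <- function(reads) {
  bc <- if (is.data.frame(reads)) reads$barcode else reads
  if (length(bc) == 0L) {
    tab <- data.table::data.table(barcode = character(0), count = integer(0))
  } else {
    tab <- data.table::data.table(barcode = bc)[, .(count = .N), by = barcode]
    data.table::setorder(tab, -count, barcode)
  }
  data.table::setattr(tab, "total_reads", length(bc))
  data.table::setattr(tab, "class", c("barcode_table", class(tab)))
  tab
}

#' Retain high-count barcodes
#'
#' Barcodes whose read count is strictly above `min_count` ("above 2000"
#' is read literally as a strict inequality).
#'
#' @param table A `barcode_table` from [count_barcodes].
#' @param min_count Threshold (default 2000).
#' @return Character vector of retained barcodes, in decreasing-count order.
#' @export
#' @examples
#' tab <- count_barcodes(rep(c("AAAA", "CCCC"), c(3, 1)))
#' select_barcodes(tab, min_count = 2)
select_barcodes <- function(table, min_count = 2000L) {
  if (min_count < 0L) stop("min_count must be non-negative")
  table$barcode[table$count > min_count]
}

#' Write a barcode count table as TSV
#'
#' @param table A `barcode_table`.
#' @param path Output TSV path.
#' @export
write_barcode_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}
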