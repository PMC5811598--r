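# Aptamer panel definition: each panel member is a short DNA aptamer whose
# sequenced construct is flank5 + core + flank3, followed by a poly-A tail
# that lets it hybridise to the same poly-T bead primers as mRNA.

#' Build an aptamer panel
#'
#' An aptamer panel describes the members of the staining library: the core
#' (binding) sequence, the constant flanking sequences used for amplification,
#' and the length of the appended poly-A tail.  The demultiplexer derives its
#' 20-mer queries from the construct `flank5 + core + flank3`.
#'
#' @param name Character vector of aptamer names.
#' @param core Character vector of core sequences (ACGT).
#' @param flank5,flank3 Character vectors of 5' and 3' flanking sequences.
#' @param polya_length Integer vector, poly-A tail length in nucleotides.
#' @param reported_target Optional character vector of reported protein
#'   targets (`NA` when unknown).
#'
#' @return A `data.frame` of class `aptamer_panel` with one row per aptamer
#'   and a `construct` column (`flank5 + core + flank3`).
#' @export
#' @examples
#' aptamer_panel("toy", strrep("ACGT", 10), "TTTTTTTTTT", "GGGGGGGGGG", 20)
aptamer_panel <- function(name, core, flank5, flank3, polya_length = 20L,
                          reported_target = NA_character_) {
  stopifnot(length(name) >= 1L, !anyDuplicated(name))
  p <- data.frame(
    name = as.character(name),
    core = toupper(core),
    flank5 = toupper(flank5),
    flank3 = toupper(flank3),
    polya_length = as.integer(polya_length),
    reported_target = as.character(reported_target),
    stringsAsFactors = FALSE
  )
  p$construct <- paste0(p$flank5, p$core, p$flank3)
  bad <- grepl("[^ACGT]", p$construct)
  if (any(bad)) {
    stop("panel sequences must be over {A,C,G,T}: ", paste(p$name[bad], collapse = ", "))
  }
  len <- nchar(p$construct)
  if (any(len < 20L | len >= 200L)) {
    stop("aptamer constructs must have length >= 20 and < 200")
  }
  if (any(p$polya_length < 0L)) stop("polya_length must be non-negative")
  class(p) <- c("aptamer_panel", "data.frame")
  p
}

#' Default eight-aptamer panel
#'
#' The panel used throughout the package examples and simulations: five
#' aptamers reported to bind Ramos-like B cells (TC01, TD05, TD08, TD09,
#' TE02) and three that do not (TE17, sgc3b, sgc8a; sgc8a binds 3T3-like
#' cells instead).  The core and flank sequences are synthetic stand-ins
#' generated once with a fixed random generator; they reproduce the panel's
#' combinatorial structure (distinct 40 nt cores, distinct 10 nt flanks),
#' not the published sequences.
#'
#' @return An [aptamer_panel] with eight members and a 20 nt poly-A tail.
#' @export
default_panel <- function() {
  aptamer_panel(
    name = c("TC01", "TD05", "TD08", "TD09", "TE02", "TE17", "sgc3b", "sgc8a"),
    core = c(
      "AGACTGCAGGGGATTACTATAAGGATTGTCCGCTGGCTCC",
      "ACTTCGTGTATAGCAAGTACCCCCCACGTACGGACTTGAG",
      "TTCGGCCTATGATGTTACTCCGTTCCGTCGACGAATATCG",
      "CCTTTTACACCAATGCGCAATCTATAAATACTTACCTTTA",
      "GAGGATGACGCCTAACACGAGAGTAATTAGCGCGGTCCAC",
      "TTGATCAATCCTATACACCCTATTCGGCCCCGAAATCGGA",
      "GGACGCTTCCTTGGTTGTTTATCGTTTATAATTAGCGTCG",
      "CCAGACATACACACCTCGGATAATGCACCTTGTTTAATCG"
    ),
    flank5 = c(
      "TAGGAGGAGA", "CTCGCTCGTA", "GTAGACCGAG", "TGATGGAATT",
      "AACATATCCA", "GTGCAGGACG", "AACGTACGTC", "ACCGCTTGAA"
    ),
    flank3 = c(
      "CAACTCGCTT", "CCGTAGTAGA", "GGATCGAACG", "CCACTAGTGC",
      "GCGATTAGGG", "AGACAACTTG", "GCTTATCAGG", "GAATGGTTGA"
    ),
    polya_length = 20L,
    reported_target = c(
      NA, "IgM heavy chain", NA, NA, NA, NA, "L-selectin", "PTK7"
    )
  )
}

#' Write / read an aptamer panel
#'
#' The on-disk representation is a FASTA file of the constructs plus a TSV
#' of metadata (name, flank coordinates within the construct, poly-A length,
#' reported target), so a panel survives a round trip through plain text.
#'
#' @param panel An [aptamer_panel].
#' @param fasta Path to the construct FASTA file.
#' @param meta Path to the metadata TSV file.
#' @return `write_panel` returns `panel` invisibly; `read_panel` returns an
#'   [aptamer_panel].
#' @export
write_panel <- function(panel, fasta, meta) {
  stopifnot(inherits(panel, "aptamer_panel"))
  seqs <- Biostrings::DNAStringSet(panel$construct)
  names(seqs) <- panel$name
  Biostrings::writeXStringSet(seqs, fasta)
  m <- data.frame(
    name = panel$name,
    flank5_length = nchar(panel$flank5),
    flank3_length = nchar(panel$flank3),
    polya_length = panel$polya_length,
    reported_target = panel$reported_target
  )
  utils::write.table(m, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' @rdname write_panel
#' @export
read_panel <- function(fasta, meta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  m <- utils::read.table(meta, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  m <- m[match(names(seqs), m$name), ]
  construct <- as.character(seqs)
  core <- substr(construct, m$flank5_length + 1L,
                 nchar(construct) - m$flank3_length)
  aptamer_panel(
    name = m$name,
    core = core,
    flank5 = substr(construct, 1L, m$flank5_length),
    flank3 = substr(construct, nchar(construct) - m$flank3_length + 1L,
                    nchar(construct)),
    polya_length = m$polya_length,
    reported_target = if ("reported_target" %in% names(m)) m$reported_target else NA
  )
}
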