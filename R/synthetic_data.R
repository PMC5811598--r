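# Synthetic-data generator: two-species cell mixtures, droplet-barcoded
# paired-end reads, and qPCR cycle-threshold traces with known ground truth.
# The generator is first-class, tested code: its defaults define the study
# conditions under which every downstream stage is verified.

#' Generate a two-species toy reference transcriptome
#'
#' Random transcript sequences for two species, with an optional fraction of
#' transcripts carrying a duplicated sub-sequence (copied from another,
#' possibly cross-species, transcript) so that multi-transcript equivalence
#' classes arise during pseudoalignment.
#'
#' @param n_transcripts_per_species Positive integer, transcripts per species.
#' @param transcript_length Positive integer, length of every transcript
#'   (must be at least `min_length`, the pseudoaligner k-mer size).
#' @param shared_fraction Fraction in \[0, 1\] of transcripts that receive a
#'   duplicated window from a donor transcript.
#' @param seed Integer seed; the reference is deterministic given the seed.
#' @param species Character vector of two species labels.
#' @param shared_window Length of the duplicated window (default 50 nt,
#'   comfortably above the default k-mer size of 21).
#' @param min_length Minimum admissible transcript length (default 21).
#'
#' @return A list of class `transcript_reference` with elements `sequences`
#'   (named character vector, ids of the form `speciesA|tx0001`), `species`
#'   (named character vector keyed by transcript id), and `ids`.
#' @export
#' @examples
#' ref <- generate_reference(4, 300, shared_fraction = 0, seed = 1)
#' length(ref$sequences)
generate_reference <- function(n_transcripts_per_species, transcript_length,
                               shared_fraction = 0, seed = 1L,
                               species = c("speciesA", "speciesB"),
                               shared_window = 50L, min_length = 21L) {
  if (n_transcripts_per_species < 1L || transcript_length < 1L) {
    stop("n_transcripts_per_species and transcript_length must be positive")
  }
  if (transcript_length < min_length) {
    stop("transcript_length must be at least ", min_length)
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]")
  }
  stopifnot(length(species) == 2L)
  set.seed(seed)
  n_total <- 2L * n_transcripts_per_species
  ids <- paste0(rep(species, each = n_transcripts_per_species), "|tx",
                formatC(seq_len(n_total), width = 4, flag = "0"))
  sp <- rep(species, each = n_transcripts_per_species)
  seqs <- vapply(seq_len(n_total), function(i) {
    paste(sample(c("A", "C", "G", "T"), transcript_length, replace = TRUE),
          collapse = "")
  }, character(1))
  w <- min(shared_window, transcript_length)
  n_shared <- round(shared_fraction * n_total)
  if (n_shared > 0L && n_total >= 2L) {
    recipients <- sample(n_total, n_shared)
    for (i in recipients) {
      donor <- sample(setdiff(seq_len(n_total), i), 1L)
      from <- sample(transcript_length - w + 1L, 1L)
      at <- sample(transcript_length - w + 1L, 1L)
      block <- substr(seqs[donor], from, from + w - 1L)
      substr(seqs[i], at, at + w - 1L) <- block
    }
  }
  names(seqs) <- ids
  names(sp) <- ids
  structure(list(sequences = seqs, species = sp, ids = ids),
            class = "transcript_reference")
}

#' Write / read a reference transcriptome
#'
#' Stored as FASTA with the species label encoded in the record id
#' (`speciesA|tx0001`).
#'
#' @param reference A `transcript_reference`.
#' @param fasta Path to a FASTA file.
#' @return `read_reference` returns a `transcript_reference`.
#' @export
write_reference <- function(reference, fasta) {
  seqs <- Biostrings::DNAStringSet(reference$sequences)
  names(seqs) <- reference$ids
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(reference)
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  sp <- sub("\\|.*$", "", ids)
  s <- as.character(seqs)
  names(s) <- ids
  names(sp) <- ids
  structure(list(sequences = s, species = sp, ids = ids),
            class = "transcript_reference")
}

#' Simulation configuration
#'
#' Parameters of the synthetic cell mixture.  The defaults (via
#' [default_simulation_config]) emulate the mixed-species experiment the
#' pipeline is designed for: a 60:40 mixture of two cell types from
#' different species stained with an eight-aptamer panel in which TD05,
#' TD08 and TE02 bind type A strongly, TD09 moderately, sgc8a binds type B,
#' and TC01/TE17/sgc3b are near zero everywhere.
#'
#' @param n_cells_per_type Named positive integer vector, cells per type.
#' @param species_of_type Named character vector mapping cell type to
#'   species label.
#' @param aptamer_binding Numeric matrix (cell types x aptamers) of mean
#'   bound molecules per cell.
#' @param transcript_expression Numeric matrix (cell types x transcripts) of
#'   mean molecules per cell.
#' @param barcode_length,umi_length Read-1 layout in nucleotides
#'   (defaults 12 and 8, the Drop-seq bead design).
#' @param per_base_error_rate Substitution probability per sequenced payload
#'   base, in \[0, 1\].
#' @param ambient_read_fraction Expected fraction of reads carrying barcodes
#'   that belong to no cell, in \[0, 1).
#' @param reads_per_molecule Mean sequenced copies per molecule (Poisson).
#' @param staining_scale_sdlog Log-normal standard deviation of the per-cell
#'   aptamer staining efficiency (0 disables; default 0.4).  Applied to the
#'   aptamer means only: it models cell-to-cell variability in staining and
#'   washing, not mRNA capture.
#' @param rng_seed Integer seed.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells_per_type, species_of_type,
                              aptamer_binding, transcript_expression,
                              barcode_length = 12L, umi_length = 8L,
                              per_base_error_rate = 0.001,
                              ambient_read_fraction = 0.05,
                              reads_per_molecule = 2,
                              staining_scale_sdlog = 0.4,
                              rng_seed = 1L) {
  types <- names(n_cells_per_type)
  if (is.null(types) || any(n_cells_per_type < 1L)) {
    stop("n_cells_per_type must be a named vector of positive integers")
  }
  if (!setequal(types, names(species_of_type))) {
    stop("species_of_type must name every cell type")
  }
  stopifnot(is.matrix(aptamer_binding), is.matrix(transcript_expression))
  if (!setequal(types, rownames(aptamer_binding)) ||
      !setequal(types, rownames(transcript_expression))) {
    stop("binding and expression matrices need one row per cell type")
  }
  if (any(aptamer_binding < 0) || any(transcript_expression < 0)) {
    stop("mean molecule counts must be non-negative")
  }
  if (per_base_error_rate < 0 || per_base_error_rate > 1) {
    stop("per_base_error_rate must be in [0, 1]")
  }
  if (ambient_read_fraction < 0 || ambient_read_fraction >= 1) {
    stop("ambient_read_fraction must be in [0, 1)")
  }
  if (reads_per_molecule <= 0) stop("reads_per_molecule must be positive")
  if (barcode_length < 1L || umi_length < 1L) {
    stop("barcode_length and umi_length must be positive")
  }
  structure(list(
    n_cells_per_type = setNames(as.integer(n_cells_per_type), types),
    species_of_type = species_of_type[types],
    aptamer_binding = aptamer_binding[types, , drop = FALSE],
    transcript_expression = transcript_expression[types, , drop = FALSE],
    barcode_length = as.integer(barcode_length),
    umi_length = as.integer(umi_length),
    per_base_error_rate = per_base_error_rate,
    ambient_read_fraction = ambient_read_fraction,
    reads_per_molecule = reads_per_molecule,
    staining_scale_sdlog = staining_scale_sdlog,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

#' Default study-condition configuration
#'
#' Binds the default binding pattern and a uniform expression profile to a
#' given panel and reference: type A cells express the first species'
#' transcripts, type B the second's, with `transcript_total` mean molecules
#' per cell spread uniformly over the expressed transcripts.  Per-cell
#' aptamer copy numbers are illustrative (the assay does not fix a scale):
#' strong binders average 150 molecules per cell, the moderate binder 50,
#' background 1, and sgc3b 0 (below detection).
#'
#' @param panel An [aptamer_panel] (default [default_panel]).
#' @param reference A `transcript_reference`.
#' @param n_cells_per_type Cells per type (default 60 type A, 40 type B).
#' @param transcript_total Mean total mRNA molecules per cell (default 6500).
#' @param ... Passed on to [simulation_config].
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(panel = default_panel(), reference,
                                      n_cells_per_type = c(typeA = 60L, typeB = 40L),
                                      transcript_total = 6500, ...) {
  types <- names(n_cells_per_type)
  stopifnot(length(types) == 2L)
  species <- unique(reference$species)
  stopifnot(length(species) == 2L)
  species_of_type <- setNames(species, types)

  binding <- matrix(0, nrow = 2L, ncol = nrow(panel),
                    dimnames = list(types, panel$name))
  strongA <- intersect(c("TD05", "TD08", "TE02"), panel$name)
  moderateA <- intersect("TD09", panel$name)
  strongB <- intersect("sgc8a", panel$name)
  background <- setdiff(panel$name, c(strongA, moderateA, strongB, "sgc3b"))
  binding[1L, strongA] <- 150
  binding[1L, moderateA] <- 50
  binding[1L, background] <- 1
  binding[1L, strongB] <- 5
  binding[2L, strongB] <- 150
  binding[2L, setdiff(panel$name, c(strongB, "sgc3b"))] <- 1

  expr <- matrix(0, nrow = 2L, ncol = length(reference$ids),
                 dimnames = list(types, reference$ids))
  for (i in 1:2) {
    own <- reference$ids[reference$species == species[i]]
    expr[i, own] <- transcript_total / length(own)
  }
  simulation_config(n_cells_per_type, species_of_type, binding, expr, ...)
}

#' Write / read a simulation configuration
#'
#' Serialised as YAML with keys mirroring the [simulation_config] fields.
#'
#' @param config A `simulation_config`.
#' @param path Path to a YAML file.
#' @return `read_simulation_config` returns a `simulation_config`.
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  x$n_cells_per_type <- as.list(config$n_cells_per_type)
  x$species_of_type <- as.list(config$species_of_type)
  x$aptamer_binding <- list(rows = rownames(config$aptamer_binding),
                            cols = colnames(config$aptamer_binding),
                            values = as.vector(config$aptamer_binding))
  x$transcript_expression <- list(rows = rownames(config$transcript_expression),
                                  cols = colnames(config$transcript_expression),
                                  values = as.vector(config$transcript_expression))
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  unpack <- function(m) {
    matrix(unlist(m$values), nrow = length(m$rows),
           dimnames = list(unlist(m$rows), unlist(m$cols)))
  }
  simulation_config(
    n_cells_per_type = setNames(unlist(x$n_cells_per_type),
                                names(x$n_cells_per_type)),
    species_of_type = setNames(unlist(x$species_of_type),
                               names(x$species_of_type)),
    aptamer_binding = unpack(x$aptamer_binding),
    transcript_expression = unpack(x$transcript_expression),
    barcode_length = x$barcode_length, umi_length = x$umi_length,
    per_base_error_rate = x$per_base_error_rate,
    ambient_read_fraction = x$ambient_read_fraction,
    reads_per_molecule = x$reads_per_molecule,
    staining_scale_sdlog = x$staining_scale_sdlog,
    rng_seed = x$rng_seed
  )
}

random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

unique_barcodes <- function(n, width, exclude = character(0), max_tries = 20L) {
  bc <- unique(setdiff(random_dna(n, width), exclude))
  tries <- 0L
  while (length(bc) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not draw ", n, " distinct barcodes of length ", width)
    }
    bc <- unique(setdiff(c(bc, random_dna(n - length(bc), width)), exclude))
  }
  bc[seq_len(n)]
}

#' Simulate a ground-truth cell population
#'
#' Draws per-cell molecule counts (Poisson with the configured means, the
#' aptamer means additionally scaled by a per-cell log-normal staining
#' efficiency), assigns each cell a unique random barcode, and labels every
#' molecule with a UMI drawn uniformly at random (collisions allowed; they
#' exercise deduplication undercounting downstream).
#'
#' @param config A [simulation_config].
#' @param panel An [aptamer_panel]; every aptamer named in the binding matrix
#'   must exist in the panel.
#' @param reference A `transcript_reference`; every transcript named in the
#'   expression matrix must exist in the reference.
#'
#' @return A list of class `apt_ground_truth`: `cells` (data.table with
#'   barcode, type, species, staining_scale), `molecules` (data.table with
#'   barcode, kind, feature, umi, one row per molecule), and realised count
#'   matrices `aptamer_counts` and `transcript_counts` (cells x features).
#' @export
simulate_cells <- function(config, panel, reference) {
  stopifnot(inherits(config, "simulation_config"))
  if (!all(colnames(config$aptamer_binding) %in% panel$name)) {
    stop("aptamer_binding names an aptamer absent from the panel")
  }
  if (!all(colnames(config$transcript_expression) %in% reference$ids)) {
    stop("transcript_expression names a transcript absent from the reference")
  }
  set.seed(config$rng_seed)
  types <- names(config$n_cells_per_type)
  cells <- data.table::data.table(
    type = rep(types, config$n_cells_per_type)
  )
  n <- nrow(cells)
  cells[, species := config$species_of_type[type]]
  cells[, barcode := unique_barcodes(n, config$barcode_length)]
  cells[, staining_scale := exp(rnorm(n, 0, config$staining_scale_sdlog))]

  draw_counts <- function(means, scale = rep(1, n)) {
    mu <- means[cells$type, , drop = FALSE] * scale
    cnt <- matrix(rpois(length(mu), mu), nrow = n,
                  dimnames = list(cells$barcode, colnames(means)))
    cnt
  }
  apt_counts <- draw_counts(config$aptamer_binding, cells$staining_scale)
  tx_counts <- draw_counts(config$transcript_expression)

  mol_table <- function(counts, kind) {
    idx <- which(counts > 0L, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      return(data.table::data.table(barcode = character(0), kind = character(0),
                                    feature = character(0)))
    }
    reps <- counts[idx]
    data.table::data.table(
      barcode = rep(rownames(counts)[idx[, 1L]], reps),
      kind = kind,
      feature = rep(colnames(counts)[idx[, 2L]], reps)
    )
  }
  molecules <- data.table::rbindlist(list(
    mol_table(apt_counts, "aptamer"),
    mol_table(tx_counts, "transcript")
  ))
  molecules[, umi := random_dna(.N, config$umi_length)]
  molecules[, molecule_id := seq_len(.N)]

  structure(list(cells = cells, molecules = molecules,
                 aptamer_counts = apt_counts, transcript_counts = tx_counts),
            class = "apt_ground_truth")
}

#' Write a ground-truth table
#'
#' One row per cell: barcode, type, species, then the realised per-aptamer
#' and per-transcript molecule counts.
#'
#' @param truth An `apt_ground_truth`.
#' @param path Path to a TSV file.
#' @export
write_ground_truth <- function(truth, path) {
  tab <- cbind(as.data.frame(truth$cells),
               as.data.frame(truth$aptamer_counts),
               as.data.frame(truth$transcript_counts))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  widths <- nchar(seqs)
  n_err <- rbinom(length(seqs), widths, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(widths[i], n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a ground truth
#'
#' Each molecule is emitted `Poisson(reads_per_molecule)` times.  Read 1
#' carries the cell barcode followed by the molecule's UMI; read 2 carries
#' the payload: for mRNA, the 3'-most window of the transcript (poly-A
#' capture geometry), for aptamers, the 5' prefix of
#' `flank5 + core + flank3 + poly-A`.  Substitution errors are applied to
#' the payload at `per_base_error_rate`; ambient reads carry barcodes that
#' belong to no cell.  Output is written as a valid 4-line-record FASTQ
#' pair, byte-identical for identical seeds.
#'
#' @param truth An `apt_ground_truth` from [simulate_cells].
#' @param reference The `transcript_reference` used to build the truth.
#' @param panel The [aptamer_panel] used to build the truth.
#' @param config The [simulation_config].
#' @param fastq1,fastq2 Output FASTQ paths (gzipped when ending in `.gz`).
#' @param read_length Read-2 length in nucleotides (default 60).
#' @param seed Seed for read emission (defaults to `config$rng_seed`).
#'
#' @return Invisibly, a list with `molecules` (the truth molecule table plus
#'   an `n_copies` column of emitted read counts), `n_reads`, `n_ambient`,
#'   `ambient_barcodes`, and the output paths.
#' @export
simulate_reads <- function(truth, reference, panel, config, fastq1, fastq2,
                           read_length = 60L, seed = config$rng_seed) {
  stopifnot(inherits(truth, "apt_ground_truth"))
  set.seed(seed)

  tx_payload <- substr(reference$sequences,
                       pmax(1L, nchar(reference$sequences) - read_length + 1L),
                       nchar(reference$sequences))
  apt_full <- paste0(panel$construct, strrep("A", panel$polya_length))
  apt_payload <- substr(apt_full, 1L, pmin(read_length, nchar(apt_full)))
  names(apt_payload) <- panel$name
  short <- nchar(apt_payload) < 20L
  if (any(short)) {
    warning("skipping aptamer payloads shorter than the 20 nt query window: ",
            paste(panel$name[short], collapse = ", "))
    apt_payload <- apt_payload[!short]
  }
  payload_of <- c(tx_payload, apt_payload)

  mols <- data.table::copy(truth$molecules)
  mols <- mols[kind == "transcript" | feature %in% names(apt_payload)]
  mols[, n_copies := rpois(.N, config$reads_per_molecule)]

  reads <- mols[n_copies > 0L,
                .(barcode = rep(barcode, n_copies),
                  umi = rep(umi, n_copies),
                  feature = rep(feature, n_copies))]
  n_real <- nrow(reads)

  f <- config$ambient_read_fraction
  n_amb <- if (f > 0 && n_real > 0L) {
    rbinom(1L, size = round(n_real / (1 - f)), prob = f)
  } else 0L
  amb_bc <- character(0)
  if (n_amb > 0L) {
    amb_bc <- random_dna(n_amb, config$barcode_length)
    clash <- amb_bc %in% truth$cells$barcode
    while (any(clash)) {
      amb_bc[clash] <- random_dna(sum(clash), config$barcode_length)
      clash <- amb_bc %in% truth$cells$barcode
    }
    ambient <- data.table::data.table(
      barcode = amb_bc,
      umi = random_dna(n_amb, config$umi_length),
      feature = sample(names(payload_of), n_amb, replace = TRUE)
    )
    reads <- data.table::rbindlist(list(reads, ambient))
  }

  n_reads <- nrow(reads)
  if (n_reads == 0L) stop("simulation produced no reads")
  ord <- sample.int(n_reads)
  reads <- reads[ord]
  read1 <- paste0(reads$barcode, reads$umi)
  read2 <- apply_substitutions(unname(payload_of[reads$feature]),
                               config$per_base_error_rate)
  ids <- paste0("read", seq_len(n_reads), ":", reads$barcode, ":", reads$umi)

  write_one <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, compress = grepl("\\.gz$", path), format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  }
  write_one(read1, fastq1)
  write_one(read2, fastq2)

  invisible(list(molecules = mols, n_reads = n_reads, n_ambient = n_amb,
                 ambient_barcodes = unique(amb_bc),
                 fastq1 = fastq1, fastq2 = fastq2, read_length = read_length))
}

#' Simulate qPCR cycle-threshold observations
#'
#' Under the amplification model `C(n) = C0 * b^n`, the threshold cycle at
#' which the detection concentration is reached is
#' `Ct = log(detection / C0) / log(b)`; observations add Gaussian noise.
#'
#' @param c0 Starting concentration (> 0, arbitrary but consistent units).
#' @param b Amplification rate per cycle (> 1; ideal PCR has b = 2).
#' @param detection_concentration Concentration at the detection threshold
#'   (>= `c0`).
#' @param ct_noise_sd Gaussian noise standard deviation in cycles.
#' @param n_replicates Number of replicate observations.
#' @param seed Integer seed.
#' @return Numeric vector of `n_replicates` Ct values.
#' @export
#' @examples
#' simulate_qpcr(1, 2, 1024, ct_noise_sd = 0, n_replicates = 1)  # exactly 10
simulate_qpcr <- function(c0, b, detection_concentration, ct_noise_sd = 0,
                          n_replicates = 3L, seed = 1L) {
  if (b <= 1) stop("amplification rate b must be > 1")
  if (c0 <= 0) stop("c0 must be positive")
  if (detection_concentration < c0) {
    stop("detection_concentration must be at least c0")
  }
  set.seed(seed)
  true_ct <- log(detection_concentration / c0) / log(b)
  true_ct + rnorm(n_replicates, 0, ct_noise_sd)
}
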