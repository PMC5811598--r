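# Small simulation fixtures shared across test files; everything is built
# in code at test time.

tiny_reference <- function(n = 4L, len = 300L, shared = 0, seed = 1L) {
  generate_reference(n, len, shared_fraction = shared, seed = seed)
}

tiny_config <- function(reference, n_a = 12L, n_b = 8L, error = 0,
                        ambient = 0, depth = 3, tx_total = 400,
                        seed = 7L, ...) {
  default_simulation_config(
    default_panel(), reference,
    n_cells_per_type = c(typeA = n_a, typeB = n_b),
    transcript_total = tx_total,
    per_base_error_rate = error,
    ambient_read_fraction = ambient,
    reads_per_molecule = depth,
    rng_seed = seed, ...
  )
}

# Simulate through to FASTQ, returning paths plus truth and emission record.
simulate_to_fastq <- function(config, panel = default_panel(),
                              reference, gz = FALSE) {
  truth <- simulate_cells(config, panel, reference)
  ext <- if (gz) ".fastq.gz" else ".fastq"
  f1 <- tempfile("r1_", fileext = ext)
  f2 <- tempfile("r2_", fileext = ext)
  sim <- simulate_reads(truth, reference, panel, config, f1, f2)
  list(truth = truth, sim = sim, fastq1 = f1, fastq2 = f2)
}
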