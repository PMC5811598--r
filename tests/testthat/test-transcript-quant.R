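test_that("build_kmer_index records every k-mer with its full transcript set", {
  # two identical transcripts: every k-mer maps to both
  ref <- list(sequences = c(`s|t1` = strrep("ACGTT", 10),
                            `s|t2` = strrep("ACGTT", 10)),
              species = c(`s|t1` = "s", `s|t2` = "s"),
              ids = c("s|t1", "s|t2"))
  class(ref) <- "transcript_reference"
  idx <- build_kmer_index(ref, k = 21)
  sets <- mget(ls(idx$map), envir = idx$map)
  expect_true(all(vapply(sets, identical, logical(1), c(1L, 2L))))

  # k-mer-disjoint transcripts: all singletons (checked brute force)
  ref2 <- tiny_reference(2, 120, shared = 0, seed = 5)
  idx2 <- build_kmer_index(ref2, k = 21)
  sets2 <- mget(ls(idx2$map), envir = idx2$map)
  expect_true(all(lengths(sets2) == 1L))

  # engineered sharing produces at least one multi-transcript k-mer
  ref3 <- tiny_reference(4, 300, shared = 0.5, seed = 2)
  idx3 <- build_kmer_index(ref3, k = 21)
  expect_true(any(lengths(mget(ls(idx3$map), envir = idx3$map)) >= 2L))

  short <- ref2
  short$sequences[1] <- "ACGT"
  expect_error(build_kmer_index(short, 21), "at least as long")
})

test_that("pseudoalign computes compatibility-set intersections", {
  ref <- tiny_reference(4, 300, shared = 0.5, seed = 6)
  idx <- build_kmer_index(ref, 21)
  oracle <- oracle_ec_fun(ref$sequences, 21)

  # verbatim unique region -> singleton class of the source transcript
  pay <- substr(ref$sequences[1], 1, 60)
  res <- pseudoalign(pay, idx)
  tx <- res$ec_table$transcripts[[match(res$ec[1], res$ec_table$ec)]]
  expect_identical(sort(match(tx, ref$ids)), oracle(pay))

  # random payload sharing no k-mer -> unmapped
  set.seed(3)
  repeat {
    rnd <- random_seq(1, 60)
    if (length(oracle(rnd)) == 0) break
  }
  expect_true(is.na(pseudoalign(rnd, idx)$ec[1]))

  # payload shorter than k -> unmapped
  expect_true(is.na(pseudoalign("ACGT", idx)$ec[1]))

  # equal compatibility sets share one identifier (memoization)
  two <- rep(substr(ref$sequences[2], 10, 80), 2)
  res2 <- pseudoalign(two, idx)
  expect_equal(res2$ec[1], res2$ec[2])
  expect_equal(nrow(res2$ec_table), 1L)
})

test_that("pseudoalign agrees with the brute-force oracle on random reads", {
  ref <- tiny_reference(5, 300, shared = 0.4, seed = 11)
  idx <- build_kmer_index(ref, 21)
  oracle <- oracle_ec_fun(ref$sequences, 21)
  set.seed(12)
  starts <- sample(240, 400, replace = TRUE)
  src <- sample(length(ref$sequences), 400, replace = TRUE)
  payloads <- c(
    substr(ref$sequences[src], starts, starts + 59),            # exact
    vapply(substr(ref$sequences[src[1:200]], starts[1:200], starts[1:200] + 59),
           function(s) plant_substitutions(s, 2), character(1)), # mutated
    random_seq(200, 60)                                          # random
  )
  res <- pseudoalign(payloads, idx)
  ec_sets <- lapply(res$ec_table$transcripts, function(tx) sort(match(tx, ref$ids)))
  names(ec_sets) <- res$ec_table$ec
  for (i in seq_along(payloads)) {
    want <- oracle(payloads[i])
    if (length(want) == 0) {
      expect_true(is.na(res$ec[i]))
    } else {
      expect_identical(ec_sets[[res$ec[i]]], want)
    }
  }
  # every mapped read belongs to exactly one class
  expect_true(all(is.na(res$ec) | res$ec %in% res$ec_table$ec))
})

test_that("species labels derive from class membership", {
  ref <- tiny_reference(2, 120, shared = 0, seed = 7)
  idx <- build_kmer_index(ref, 21)
  win <- substr(ref$sequences, nchar(ref$sequences) - 59, nchar(ref$sequences))
  res <- pseudoalign(win, idx)
  got_sp <- res$ec_table$species[match(res$ec, res$ec_table$ec)]
  expect_identical(got_sp, unname(ref$species))

  # a class spanning both species is AMBIGUOUS
  mixed <- list(sequences = c(`speciesA|t1` = strrep("ACGTT", 12),
                              `speciesB|t2` = strrep("ACGTT", 12)),
                species = c(`speciesA|t1` = "speciesA", `speciesB|t2` = "speciesB"),
                ids = c("speciesA|t1", "speciesB|t2"))
  class(mixed) <- "transcript_reference"
  resm <- pseudoalign(strrep("ACGTT", 8), build_kmer_index(mixed, 21))
  expect_equal(resm$ec_table$species, "AMBIGUOUS")
})

test_that("count_ec_umis collapses UMIs and ignores unmapped reads", {
  reads <- data.table::data.table(
    barcode = c("c1", "c1", "c1", "c2"),
    umi = c("u1", "u1", "u2", "u9"),
    payload = "x"
  )
  ec <- c("EC0001", "EC0001", "EC0001", NA)
  m <- count_ec_umis(reads, ec, c("c1", "c2"))
  expect_equal(m["c1", "EC0001"], 2L)
  expect_equal(m["c2", "EC0001"], 0L)
  expect_equal(feature_kind(m), "ec")
  m0 <- count_ec_umis(reads[0], character(0), c("c1"), "EC0001")
  expect_true(all(m0 == 0L))
})

test_that("filter_cells is inclusive at the threshold", {
  m <- matrix(c(4499L, 4500L, 9000L), ncol = 1,
              dimnames = list(c("a", "b", "c"), "EC1"))
  attr(m, "feature_kind") <- "ec"
  kept <- filter_cells(m, 4500)
  expect_equal(rownames(kept), c("b", "c"))
  expect_identical(filter_cells(m, 0), m)
  # commutes with row permutation
  perm <- m[c(3, 1, 2), , drop = FALSE]
  attr(perm, "feature_kind") <- "ec"
  expect_setequal(rownames(filter_cells(perm, 4500)), rownames(kept))
})

test_that("top_variable_features ranks by variance with lexicographic ties", {
  m <- cbind(const = rep(5L, 4), varying = c(0L, 10L, 0L, 10L))
  rownames(m) <- paste0("c", 1:4)
  top1 <- top_variable_features(m, 1)
  expect_equal(colnames(top1), "varying")

  tied <- matrix(rep(c(1L, 2L, 3L), 3), ncol = 3,
                 dimnames = list(paste0("c", 1:3), c("zz", "aa", "mm")))
  expect_equal(colnames(top_variable_features(tied, 2)), c("aa", "mm"))

  expect_error(top_variable_features(m, 3), "exceeds")

  # agrees with a brute-force variance ranking on random data
  set.seed(14)
  big <- matrix(rpois(20 * 30, rep(c(2, 40), each = 10 * 30)), nrow = 30)
  colnames(big) <- sprintf("f%02d", 1:20)
  rownames(big) <- sprintf("c%02d", 1:30)
  got <- colnames(top_variable_features(big, 5))
  v <- apply(big, 2, var)
  want <- names(sort(v, decreasing = TRUE))[1:5]
  expect_setequal(got, want)
  # commutes with column permutation
  perm <- big[, sample(ncol(big))]
  expect_setequal(colnames(top_variable_features(perm, 5)), got)
})

test_that("barnyard coordinates split counts by species and flag 0/0", {
  m <- matrix(c(10L, 0L, 5L,
                0L, 8L, 5L,
                0L, 0L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("cA", "cB", "cE"), c("EC1", "EC2", "EC3")))
  sp <- c(EC1 = "speciesA", EC2 = "speciesB", EC3 = "AMBIGUOUS")
  by <- barnyard_coordinates(m, sp)
  expect_equal(by$count_a, c(10, 0, 0))
  expect_equal(by$count_b, c(0, 8, 0))
  expect_equal(by$purity, c(1, 1, NA))
  expect_equal(by$frac_a, c(1, 0, NA))

  meq <- matrix(c(4L, 4L), nrow = 1, dimnames = list("c", c("EC1", "EC2")))
  expect_equal(barnyard_coordinates(meq, sp[1:2])$purity, 0.5)
})

test_that("zero-error species recovery: every mapped read matches its source", {
  ref <- tiny_reference(3, 200, shared = 0, seed = 15)
  cfg <- tiny_config(ref, n_a = 8, n_b = 6, tx_total = 200, seed = 37)
  out <- simulate_to_fastq(cfg, reference = ref)
  parsed <- parse_read_pairs(read_fastq_pairs(out$fastq1, out$fastq2))
  idx <- build_kmer_index(ref, 21)
  queries <- build_queries(default_panel())
  asn <- match_reads(parsed, queries)
  is_tx <- asn$status == "unassigned"
  res <- pseudoalign(parsed$payload[is_tx], idx)
  # map reads back to their source molecule via barcode+umi
  mol <- out$sim$molecules
  key <- paste(parsed$barcode[is_tx], parsed$umi[is_tx])
  src <- mol$feature[match(key, paste(mol$barcode, mol$umi))]
  known <- !is.na(src) & grepl("\\|", src)
  got_sp <- res$ec_table$species[match(res$ec[known], res$ec_table$ec)]
  expect_identical(got_sp, unname(ref$species[src[known]]))
})
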