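# Independent brute-force oracles, written against the raw definitions and
# kept free of the package's implementation paths.

# Exhaustive sliding-window Hamming matcher.  For each payload, every
# (window, query) pair is compared position by position; a read is assigned
# when queries of exactly one aptamer reach distance <= max_mismatch.
oracle_match <- function(payloads, queries_dt, max_mismatch = 1L) {
  qints <- lapply(queries_dt$query, utf8ToInt)
  qapt <- queries_dt$aptamer
  res <- lapply(payloads, function(x) {
    p <- utf8ToInt(x)
    n <- length(p)
    hit <- character(0)
    for (j in seq_along(qints)) {
      q <- qints[[j]]
      k <- length(q)
      if (n < k) next
      W <- matrix(p[outer(seq_len(k), 0:(n - k), `+`)], nrow = k)
      if (min(colSums(W != q)) <= max_mismatch) hit <- c(hit, qapt[j])
    }
    hit <- unique(hit)
    if (length(hit) == 0L) {
      list(status = "unassigned", aptamer = NA_character_)
    } else if (length(hit) > 1L) {
      list(status = "ambiguous", aptamer = NA_character_)
    } else {
      list(status = "assigned", aptamer = hit)
    }
  })
  data.frame(
    status = vapply(res, `[[`, character(1), "status"),
    aptamer = vapply(res, `[[`, character(1), "aptamer"),
    stringsAsFactors = FALSE
  )
}

# Brute-force equivalence-class oracle: recomputes per-k-mer transcript sets
# from the raw reference sequences and intersects them across the payload's
# indexed k-mers.  Returns a sorted integer vector of transcript indices
# (empty = unmapped).
oracle_ec_fun <- function(sequences, k) {
  tabs <- lapply(seq_along(sequences), function(t) {
    s <- sequences[[t]]
    n <- nchar(s) - k + 1L
    data.frame(kmer = substring(s, 1:n, k:(n + k - 1L)), tx = t)
  })
  kt <- unique(do.call(rbind, tabs))
  sets <- tapply(kt$tx, kt$kmer, function(v) sort(unique(v)))
  function(payload) {
    n <- nchar(payload) - k + 1L
    if (n < 1L) return(integer(0))
    km <- unique(substring(payload, 1:n, k:(n + k - 1L)))
    hits <- sets[names(sets) %in% km]
    if (length(hits) == 0L) return(integer(0))
    sort(Reduce(intersect, hits))
  }
}

# Distinct-UMI aggregation with base R only (independent of the package's
# data.table path): expected count matrix from a molecule table.
oracle_umi_matrix <- function(barcode, feature, umi, row_barcodes, col_features) {
  keep <- barcode %in% row_barcodes & feature %in% col_features
  m <- matrix(0L, length(row_barcodes), length(col_features),
              dimnames = list(row_barcodes, col_features))
  if (any(keep)) {
    key <- paste(barcode[keep], feature[keep], sep = "\r")
    cnt <- tapply(umi[keep], key, function(u) length(unique(u)))
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    m[cbind(match(vapply(parts, `[`, "", 1L), row_barcodes),
            match(vapply(parts, `[`, "", 2L), col_features))] <- as.integer(cnt)
  }
  m
}

# Plant exactly n substitutions at distinct random positions.
plant_substitutions <- function(seq, n) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), n)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

random_seq <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}
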