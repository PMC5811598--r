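# SVD decomposition of the cell x aptamer matrix and the two-channel
# colour mapping used to overlay aptamer profiles on the barnyard plot.

#' Normalise and mean-centre a count matrix
#'
#' Prepares a cell x aptamer count matrix for singular value decomposition.
#' Three normalisations are available before the aptamer columns are
#' mean-centred across cells:
#' \describe{
#'   \item{`proportion`}{each cell's counts divided by that cell's total
#'     (cells with total 0 are dropped and recorded);}
#'   \item{`log`}{`log1p` of the raw counts;}
#'   \item{`none`}{raw counts, centring only.}
#' }
#' The pipeline default is `none` (see [run_aptseq]): raw-count centring
#' preserves the per-cell staining-intensity variation that makes the two
#' population-specific components identifiable, whereas per-cell proportion
#' scaling collapses the two-population structure onto a single axis.
#'
#' @param matrix A cell x aptamer count matrix (at least 2 cells and 2
#'   aptamers with nonzero data).
#' @param method One of `"proportion"`, `"log"`, `"none"`.
#' @return A real-valued matrix with column means 0 (within 1e-12);
#'   attributes `normalization` (the method) and `dropped_cells` (barcodes
#'   removed for having total count 0 under `proportion`).
#' @export
normalize_and_center <- function(matrix,
                                 method = c("proportion", "log", "none")) {
  method <- match.arg(method)
  if (ncol(matrix) < 2L) stop("need at least 2 aptamers")
  dropped <- character(0)
  x <- matrix * 1.0
  if (method == "proportion") {
    tot <- rowSums(x)
    dropped <- rownames(x)[tot == 0]
    if (length(dropped) > 0L) {
      message("dropping ", length(dropped), " cell(s) with zero total count")
      x <- x[tot > 0, , drop = FALSE]
      tot <- tot[tot > 0]
    }
    x <- x / tot
  } else if (method == "log") {
    x <- log1p(x)
  }
  if (nrow(x) < 2L) stop("need at least 2 cells with nonzero counts")
  x <- scale(x, center = TRUE, scale = FALSE)
  attr(x, "scaled:center") <- NULL
  attr(x, "normalization") <- method
  attr(x, "dropped_cells") <- dropped
  x
}

#' Singular value decomposition of a centred profile matrix
#'
#' Full SVD of the centred cell x aptamer matrix.  The right singular
#' vectors ("eigenvectors" over aptamer space) describe how the aptamers
#' co-vary across cells; per-cell amplitudes are the projections of each
#' centred cell profile onto them.  Each right singular vector is oriented
#' so that its largest-magnitude loading is positive — SVD signs are
#' otherwise arbitrary, and this convention makes the decomposition
#' deterministic.
#'
#' @param centered A matrix from [normalize_and_center].
#' @return A list of class `profile_decomposition`: `loadings` (aptamers x
#'   components, orthonormal columns), `amplitudes` (cells x components),
#'   `singular_values` (non-increasing), `normalization`.
#' @export
svd_profile <- function(centered) {
  if (all(centered == 0)) stop("degenerate input: the centred matrix is zero")
  s <- svd(centered)
  v <- s$v
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  amplitudes <- centered %*% v
  dimnames(v) <- list(colnames(centered), paste0("PC", seq_len(ncol(v))))
  dimnames(amplitudes) <- list(rownames(centered), colnames(v))
  structure(list(loadings = v, amplitudes = amplitudes,
                 singular_values = s$d,
                 normalization = attr(centered, "normalization")),
            class = "profile_decomposition")
}

#' @export
print.profile_decomposition <- function(x, ...) {
  cat("Profile decomposition:", nrow(x$amplitudes), "cells x",
      nrow(x$loadings), "aptamers\n")
  cat("Singular values:",
      paste(signif(head(x$singular_values, 5), 4), collapse = ", "),
      if (length(x$singular_values) > 5) "...\n" else "\n")
  cat("Leading loadings:\n")
  print(round(x$loadings[, seq_len(min(2L, ncol(x$loadings))), drop = FALSE], 3))
  invisible(x)
}

#' Two-channel colour mapping from the first two components
#'
#' Channel 1 (cyan weight) is the min-max rescaled amplitude along the
#' first eigenvector; channel 2 (magenta weight) is the min-max rescaled
#' *negated* amplitude along the second ("inverse amplitude" read as sign
#' inversion — a reciprocal would be undefined at amplitude 0).  Both
#' channels lie in \[0, 1\]; a constant amplitude maps to 0.5 with a
#' warning.
#'
#' @param decomposition A `profile_decomposition` with at least two
#'   components.
#' @return A data.table: `barcode`, `channel1`, `channel2`.
#' @export
color_map <- function(decomposition) {
  amp <- decomposition$amplitudes
  if (ncol(amp) < 2L) stop("need at least 2 components for the colour map")
  rescale <- function(x, label) {
    r <- range(x)
    if (r[1] == r[2]) {
      warning("constant amplitude for ", label, "; channel set to 0.5")
      return(rep(0.5, length(x)))
    }
    (x - r[1]) / (r[2] - r[1])
  }
  data.table::data.table(
    barcode = rownames(amp),
    channel1 = rescale(amp[, 1L], "component 1"),
    channel2 = rescale(-amp[, 2L], "component 2")
  )
}
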