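# qPCR standard-curve fitting under C(n) = C0 * b^n, concentration
# estimation with propagated uncertainty, and cell-vs-supernatant
# enrichment summaries.

#' Fit a qPCR standard curve
#'
#' Under the amplification model `C(n) = C0 * b^n`, the threshold cycle
#' satisfies `log C(n_Ct) = log C0 + n_Ct * log b`, so regressing observed
#' Ct on log10 of the known starting concentration gives slope
#' `-1 / log10(b)` and an intercept encoding the detection concentration
#' `C(n_Ct)`.  The fit is ordinary least squares; the parameter covariance
#' of (intercept, slope) is retained for first-order uncertainty
#' propagation.
#'
#' @param concentration Known starting concentrations (> 0, at least two
#'   distinct values).
#' @param ct Observed threshold cycles, same length.
#' @return A list of class `standard_curve_fit`: `b` (amplification rate
#'   per cycle), `log10_detection` (log10 of the detection concentration),
#'   `intercept`, `slope`, `covariance` (2x2, intercept/slope),
#'   `residual_variance`, `n_points`.
#' @export
#' @examples
#' f <- fit_standard_curve(c(1, 4, 16), log2(1024 / c(1, 4, 16)))
#' f$b  # 2
fit_standard_curve <- function(concentration, ct) {
  stopifnot(length(concentration) == length(ct))
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (length(unique(concentration)) < 2L) {
    stop("rank-deficient design: need at least two distinct concentrations")
  }
  logc <- log10(concentration)
  fit <- lm(ct ~ logc)
  a <- unname(coef(fit)[1L])
  s <- unname(coef(fit)[2L])
  if (s >= 0) {
    warning("non-negative slope: implied amplification rate b <= 1; ",
            "the assay is not valid")
  }
  # suppress the noiseless-data "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  structure(list(
    b = 10^(-1 / s),
    log10_detection = -a / s,
    intercept = a,
    slope = s,
    covariance = suppressWarnings(vcov(fit)),
    residual_variance = sm$sigma^2,
    n_points = length(ct)
  ), class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf("qPCR standard curve (%d points): b = %.4f, detection = %.4g\n",
              x$n_points, x$b, 10^x$log10_detection))
  invisible(x)
}

#' Estimate a starting concentration from Ct replicates
#'
#' Inverts the fitted model per replicate, `C0 = C(n_Ct) / b^ct`, and
#' averages.  The reported standard deviation combines, in quadrature,
#' (i) the sample standard deviation of the replicate estimates with
#' Bessel's correction (n - 1 denominator) and (ii) first-order
#' (delta-method) propagation of the fit-parameter covariance through the
#' inversion.  With a single replicate component (i) is undefined and the
#' estimate is flagged `propagation_only`.
#'
#' @param ct Numeric vector of observed threshold cycles (at least one).
#' @param fit A `standard_curve_fit`.
#' @param max_cycles Detection-limit cutoff: a replicate Ct at or beyond
#'   this cycle flags the estimate `below_detection` (default 40).
#' @return A list of class `concentration_estimate`: `estimate`, `sd`,
#'   `sd_replicate`, `sd_fit`, `n_replicates`, `propagation_only`,
#'   `below_detection`.
#' @export
estimate_concentration <- function(ct, fit, max_cycles = 40) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  if (length(ct) < 1L) stop("need at least one Ct observation")
  a <- fit$intercept
  s <- fit$slope
  # per-replicate inversion: log10 C0 = (ct - a) / s
  conc <- 10^((ct - a) / s)
  est <- mean(conc)
  # delta method through the mean of the inversions
  ln10 <- log(10)
  dda <- mean(-ln10 / s * conc)
  dds <- mean(-ln10 * (ct - a) / s^2 * conc)
  grad <- c(dda, dds)
  var_fit <- drop(t(grad) %*% fit$covariance %*% grad)
  sd_fit <- sqrt(max(var_fit, 0))
  n <- length(ct)
  propagation_only <- n < 2L
  sd_rep <- if (propagation_only) NA_real_ else sd(conc)
  total <- sqrt(sum(c(if (!propagation_only) sd_rep^2 else 0, sd_fit^2)))
  structure(list(
    estimate = est, sd = total, sd_replicate = sd_rep, sd_fit = sd_fit,
    n_replicates = n, propagation_only = propagation_only,
    below_detection = any(ct >= max_cycles)
  ), class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("C0 = %.4g +/- %.3g (n = %d%s%s)\n", x$estimate, x$sd,
              x$n_replicates,
              if (x$propagation_only) ", propagation only" else "",
              if (x$below_detection) ", below detection" else ""))
  invisible(x)
}

#' Cell-fraction versus supernatant enrichment summary
#'
#' For each aptamer, tabulates the concentration estimated in the cellular
#' fraction and in the wash supernatant, their ratio (cells / supernatant),
#' and the first-order propagated uncertainty of the ratio.  The ratio is
#' undefined (`NA`) when the supernatant estimate is zero or either
#' estimate is below the detection limit.
#'
#' @param cell_estimates Named list of `concentration_estimate`s (cellular
#'   fraction), keyed by aptamer.
#' @param supernatant_estimates Named list of `concentration_estimate`s
#'   (supernatant), same names.
#' @return A data.table: `aptamer`, `cells`, `cells_sd`, `supernatant`,
#'   `supernatant_sd`, `ratio`, `ratio_sd`, `below_detection`.
#' @export
enrichment_summary <- function(cell_estimates, supernatant_estimates) {
  apt <- names(cell_estimates)
  stopifnot(!is.null(apt), setequal(apt, names(supernatant_estimates)))
  rows <- lapply(apt, function(a) {
    ce <- cell_estimates[[a]]
    se <- supernatant_estimates[[a]]
    below <- ce$below_detection || se$below_detection
    if (below || se$estimate == 0) {
      ratio <- NA_real_
      ratio_sd <- NA_real_
    } else {
      ratio <- ce$estimate / se$estimate
      ratio_sd <- abs(ratio) * sqrt((ce$sd / ce$estimate)^2 +
                                      (se$sd / se$estimate)^2)
    }
    data.table::data.table(
      aptamer = a, cells = ce$estimate, cells_sd = ce$sd,
      supernatant = se$estimate, supernatant_sd = se$sd,
      ratio = ratio, ratio_sd = ratio_sd, below_detection = below
    )
  })
  data.table::rbindlist(rows)
}

#' Read a qPCR sample table and run the full analysis
#'
#' The TSV must have columns `aptamer`, `sample_type` (one of `standard`,
#' `cells`, `supernatant`), `known_concentration` (standards only) and
#' `ct`.  For each aptamer the standards are fitted, the cell and
#' supernatant concentrations estimated, and the enrichment summarised.
#'
#' @param path Path to the TSV file.
#' @param max_cycles Detection-limit cutoff passed to
#'   [estimate_concentration].
#' @return A list: `fits` (named list of `standard_curve_fit`s),
#'   `enrichment` (the [enrichment_summary] table).
#' @export
analyze_qpcr_table <- function(path, max_cycles = 40) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("aptamer", "sample_type", "ct")
  if (!all(need %in% names(tab))) {
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  }
  fits <- list()
  cells <- list()
  sup <- list()
  for (a in unique(tab$aptamer)) {
    sub <- tab[tab$aptamer == a, ]
    std <- sub[sub$sample_type == "standard", ]
    if (nrow(std) < 2L) stop("aptamer ", a, " has fewer than 2 standards")
    fits[[a]] <- fit_standard_curve(std$known_concentration, std$ct)
    cells[[a]] <- estimate_concentration(
      sub$ct[sub$sample_type == "cells"], fits[[a]], max_cycles)
    sup[[a]] <- estimate_concentration(
      sub$ct[sub$sample_type == "supernatant"], fits[[a]], max_cycles)
  }
  list(fits = fits, enrichment = enrichment_summary(cells, sup))
}
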