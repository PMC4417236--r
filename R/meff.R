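#' Effective sample size of an ordered series via AR spectral density
#'
#' Fits an autoregressive model by Yule-Walker (order selected by AIC up to
#' `p_max`), evaluates the spectral density at frequency zero,
#' `S(0) = sigma_eps^2 / (1 - sum(phi_k))^2`, and returns
#' `ESS = n * s^2 / S(0)` where `s^2` is the sample variance of the series.
#' The 2*pi convention cancels between numerator and denominator, so the
#' result is convention-free. The result is clipped to `[1, n]`.
#'
#' @param series Ordered numeric series (e.g. one individual's local
#'   ancestry counts along a chromosome), length >= 10 and non-constant.
#' @param p_max Maximum AR order considered (default 20).
#' @return Effective sample size (numeric scalar) with attribute `order`
#'   (the AR order selected).
#' @export
spectral_ess <- function(series, p_max = 20) {
  n <- length(series)
  if (n < 10) stop("series too short (need >= 10 points)")
  if (stats::var(series) == 0) stop("degenerate series: constant values")
  fit <- stats::ar(series, aic = TRUE, order.max = min(p_max, n - 1),
                   method = "yule-walker")
  phi_sum <- if (fit$order > 0) sum(fit$ar) else 0
  s0 <- fit$var.pred / (1 - phi_sum)^2
  ess <- n * stats::var(series) / s0
  structure(min(max(ess, 1), n), order = fit$order)
}

#' Effective number of independent ancestry tests
#'
#' For each chromosome, computes the spectral-density effective sample size
#' of each individual's local-ancestry series along the map order (or of
#' the cohort-mean ancestry series when `mode = "pooled"`), aggregates
#' across individuals by the median (or mean), clips the chromosome value
#' to `[1, markers on chromosome]`, and sums over chromosomes. The
#' genome-wide significance threshold is `alpha / total`.
#'
#' @param ancestry African-allele count matrix.
#' @param map Marker map ordering the columns (`marker_id`, `chrom`,
#'   `genetic_pos`).
#' @param alpha Family-wise error rate (default 0.05).
#' @param agg `"median"` (default) or `"mean"` aggregation across
#'   individuals.
#' @param mode `"per_individual"` (default) or `"pooled"` (one ESS per
#'   chromosome from the cohort-mean series).
#' @param p_max Maximum AR order, passed to [spectral_ess()].
#' @return A list of class `meff_estimate`: `per_chromosome`
#'   (`data.frame` of `chrom`, `n_markers`, `meff`, `n_skipped`),
#'   `total_meff`, `threshold`, `alpha`.
#' @export
effective_tests <- function(ancestry, map, alpha = 0.05,
                            agg = c("median", "mean"),
                            mode = c("per_individual", "pooled"),
                            p_max = 20) {
  agg <- match.arg(agg)
  mode <- match.arg(mode)
  aggfun <- if (agg == "median") stats::median else mean
  chroms <- unique(map$chrom)
  rows <- lapply(chroms, function(ch) {
    cols <- map$marker_id[map$chrom == ch]
    if (length(cols) < 2) stop("need >= 2 markers per chromosome")
    A <- ancestry[, cols, drop = FALSE]
    if (mode == "pooled") {
      ess <- tryCatch(as.numeric(spectral_ess(colMeans(A), p_max)),
                      error = function(e) NA_real_)
      skipped <- if (is.na(ess)) 1L else 0L
      val <- ess
    } else {
      ess <- apply(A, 1, function(x) {
        tryCatch(as.numeric(spectral_ess(x, p_max)),
                 error = function(e) NA_real_)
      })
      skipped <- sum(is.na(ess))
      val <- if (all(is.na(ess))) NA_real_ else aggfun(ess, na.rm = TRUE)
    }
    if (is.na(val)) val <- 1               # fully degenerate chromosome
    data.frame(chrom = ch, n_markers = length(cols),
               meff = min(max(val, 1), length(cols)), n_skipped = skipped)
  })
  per_chrom <- do.call(rbind, rows)
  total <- sum(per_chrom$meff)
  structure(list(per_chromosome = per_chrom, total_meff = total,
                 threshold = genomewide_threshold(total, alpha),
                 alpha = alpha),
            class = "meff_estimate")
}

#' @export
print.meff_estimate <- function(x, ...) {
  cat("Effective number of independent ancestry tests\n")
  print(x$per_chromosome, row.names = FALSE)
  cat(sprintf("  total Meff: %.1f\n  genome-wide threshold (alpha = %g): %.3g\n",
              x$total_meff, x$alpha, x$threshold))
  invisible(x)
}

#' Genome-wide Bonferroni threshold from an effective test count
#'
#' @param meff Effective number of independent tests (>= 1).
#' @param alpha Family-wise error rate in (0, 1).
#' @return `alpha / meff`; e.g. 245 effective ancestry blocks at
#'   `alpha = 0.05` gives 2.04e-4.
#' @export
genomewide_threshold <- function(meff, alpha = 0.05) {
  if (any(meff < 1)) stop("meff must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / meff
}
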