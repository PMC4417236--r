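#' Per-individual global African ancestry
#'
#' Sums African-allele counts across markers and divides by twice the number
#' of markers, giving a proportion on \[0, 1\]. The per-marker reading
#' (divide by the marker count only, so the result is a mean allele count on
#' \[0, 2\]) is available via `scale = "per_marker"`.
#'
#' @param ancestry African-allele count matrix (individuals x markers).
#' @param scale `"proportion"` (default, divide by 2m) or `"per_marker"`
#'   (divide by m).
#' @return Named numeric vector of per-individual values, with the cohort
#'   mean attached as attribute `cohort_mean`.
#' @export
global_ancestry <- function(ancestry, scale = c("proportion", "per_marker")) {
  scale <- match.arg(scale)
  if (is.null(dim(ancestry)) || nrow(ancestry) == 0 || ncol(ancestry) == 0)
    stop("empty ancestry matrix")
  denom <- if (scale == "proportion") 2 * ncol(ancestry) else ncol(ancestry)
  out <- rowSums(ancestry) / denom
  attr(out, "cohort_mean") <- mean(out)
  out
}

#' Sample exclusion filter: missing phenotype and low African ancestry
#'
#' Removes individuals with a missing phenotype value or a global African
#' ancestry proportion below `min_afr`. An individual failing both criteria
#' is recorded once, with reason `missing_phenotype`.
#'
#' @param phenotypes Phenotype table with columns `individual_id` and `cac`.
#' @param global_anc Named vector of global African proportions (names are
#'   individual ids; must cover the phenotype table).
#' @param min_afr Minimum global African proportion (default 0.01).
#' @return A list with `kept` (ids in input order) and `excluded` (a
#'   `data.frame` of `individual_id`, `reason` in
#'   \{"missing_phenotype", "low_ancestry"\}).
#' @export
filter_individuals <- function(phenotypes, global_anc, min_afr = 0.01) {
  ids <- phenotypes$individual_id
  ga <- global_anc[ids]
  if (anyNA(names(ga)) || anyNA(ga))
    stop("global_anc must provide a value for every phenotyped individual")
  miss <- is.na(phenotypes$cac)
  low <- ga < min_afr
  reason <- ifelse(miss, "missing_phenotype",
                   ifelse(low, "low_ancestry", NA_character_))
  excluded <- data.frame(individual_id = ids[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(kept = ids[is.na(reason)], excluded = excluded)
}

## Hardy-Weinberg goodness-of-fit p-value from genotype counts (1 df).
.hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)           # monomorphic: nothing to test
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Marker quality filter: call rate, minor allele frequency, Hardy-Weinberg
#'
#' Removes markers with call rate below `call_rate_min`, minor allele
#' frequency below `maf_min` (monomorphic markers fail here), or a
#' Hardy-Weinberg 1-df chi-square goodness-of-fit p-value below `hwe_p_min`.
#' A marker failing several criteria is logged once; precedence is
#' call rate, then MAF, then HWE.
#'
#' @param genotypes Minor-allele count matrix in \{0,1,2,NA\}.
#' @param maf_min,hwe_p_min,call_rate_min Thresholds (defaults 0.01, 1e-6,
#'   0.99).
#' @return A list with `kept` (marker ids in input order) and `excluded`
#'   (`data.frame` of `marker_id`, `reason` in \{"call_rate","maf","hwe"\}),
#'   plus a `stats` data.frame of the per-marker quantities.
#' @export
filter_markers <- function(genotypes, maf_min = 0.01, hwe_p_min = 1e-6,
                           call_rate_min = 0.99) {
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("m", seq_len(ncol(genotypes)))
  n <- nrow(genotypes)
  call_rate <- colMeans(!is.na(genotypes))
  n0 <- colSums(genotypes == 0L, na.rm = TRUE)
  n1 <- colSums(genotypes == 1L, na.rm = TRUE)
  n2 <- colSums(genotypes == 2L, na.rm = TRUE)
  af <- (2 * n2 + n1) / (2 * pmax(n0 + n1 + n2, 1L))
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(genotypes)),
                function(j) .hwe_p(n0[j], n1[j], n2[j]), numeric(1))
  reason <- rep(NA_character_, ncol(genotypes))
  reason[!is.na(hwe) & hwe < hwe_p_min] <- "hwe"
  reason[maf < maf_min] <- "maf"
  reason[call_rate < call_rate_min] <- "call_rate"
  keep <- is.na(reason)
  list(
    kept = colnames(genotypes)[keep],
    excluded = data.frame(marker_id = colnames(genotypes)[!keep],
                          reason = reason[!keep], stringsAsFactors = FALSE),
    stats = data.frame(marker_id = colnames(genotypes),
                       call_rate = call_rate, maf = maf, hwe_p = hwe,
                       stringsAsFactors = FALSE)
  )
}
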