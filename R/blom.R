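#' Blom rank-based inverse-normal transformation within strata
#'
#' Within each stratum of size n, the value with (tie-averaged) rank r is
#' mapped to the standard-normal quantile at (r - 3/8) / (n + 1/4). Tied
#' values receive the mean of their tied ranks and hence a common
#' transformed value — important for zero-inflated scores such as CAC,
#' where around half the cohort is tied at zero. Missing values are left
#' missing and do not enter the ranking.
#'
#' @param values Numeric vector (e.g. raw CAC scores).
#' @param strata Optional vector of stratum labels (e.g. sex x age group);
#'   `NULL` treats all values as one stratum.
#' @return Numeric vector of transformed values, same length and order.
#' @examples
#' blom_transform(c(0, 0, 3, 10))
#' @export
blom_transform <- function(values, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", length(values))
  if (length(strata) != length(values))
    stop("values and strata must have the same length")
  out <- rep(NA_real_, length(values))
  for (s in unique(strata[!is.na(values)])) {
    idx <- which(strata == s & !is.na(values))
    n <- length(idx)
    if (n < 2)
      stop(sprintf("stratum '%s' has fewer than 2 non-missing values", s))
    r <- rank(values[idx], ties.method = "average")
    out[idx] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  }
  out
}

#' Sex-by-age-group stratum labels for phenotype transformation
#'
#' Default age bins follow conventional CAC reporting decades:
#' <30, 30-39, 40-49, 50-59, >=60.
#'
#' @param sex Character vector ("male"/"female").
#' @param age Numeric ages in years.
#' @param age_breaks Interior cut points of the age bins.
#' @return Character vector of stratum labels like `"male.[30,40)"`.
#' @export
phenotype_strata <- function(sex, age, age_breaks = c(30, 40, 50, 60)) {
  if (length(sex) != length(age)) stop("sex and age must align")
  bins <- cut(age, breaks = c(-Inf, age_breaks, Inf), right = FALSE)
  paste(sex, bins, sep = ".")
}

#' Add Blom-transformed scores to a phenotype table
#'
#' Applies [blom_transform()] to the `cac` column within sex x age-group
#' strata and appends columns `stratum` and `blom_score`. Age bins with
#' fewer than `min_stratum` non-missing values are merged with the adjacent
#' (next lower, else next higher) bin within the same sex, so sparse tails
#' of the age distribution cannot produce degenerate strata.
#'
#' @param phenotypes Phenotype table with `cac`, `age`, `sex`.
#' @param age_breaks Passed to [phenotype_strata()].
#' @param min_stratum Minimum non-missing values per stratum before merging.
#' @return The phenotype table with `stratum` and `blom_score` added.
#' @export
add_blom_score <- function(phenotypes, age_breaks = c(30, 40, 50, 60),
                           min_stratum = 5) {
  bins <- cut(phenotypes$age, breaks = c(-Inf, age_breaks, Inf),
              right = FALSE)
  bin_idx <- as.integer(bins)
  nb <- nlevels(bins)
  for (s in unique(phenotypes$sex)) {
    rows <- which(phenotypes$sex == s & !is.na(phenotypes$cac))
    repeat {
      cnt <- tabulate(bin_idx[rows], nbins = nb)
      present <- which(cnt > 0)
      small <- present[cnt[present] < min_stratum]
      if (length(small) == 0 || length(present) <= 1) break
      b <- small[1]
      lower <- present[present < b]
      target <- if (length(lower)) max(lower) else min(present[present > b])
      sel <- phenotypes$sex == s & bin_idx == b
      bin_idx[sel] <- target
    }
  }
  phenotypes$stratum <- paste(phenotypes$sex, bin_idx, sep = ".")
  phenotypes$blom_score <- blom_transform(phenotypes$cac, phenotypes$stratum)
  phenotypes
}
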