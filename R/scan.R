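#' Genome-wide mixed-model scan of phenotype on local ancestry
#'
#' For each marker, fits
#' `y = mu + beta * (African-allele count) + covariates + u + e`
#' with polygenic covariance `sigma_g^2 * 2 * kinship` and tests `beta`
#' with a Wald statistic (normal reference). The variance ratio is
#' estimated once by REML under the null model and held fixed across
#' markers; the residual scale is re-estimated per marker, so with an
#' identity relatedness matrix the scan reduces exactly to ordinary least
#' squares. Full per-marker REML is available via `reml_per_marker`.
#'
#' @param blom Named numeric vector of transformed phenotype values (names
#'   are individual ids), or a phenotype table carrying `individual_id` and
#'   `blom_score`.
#' @param ancestry African-allele count matrix; rows must cover the
#'   phenotyped individuals.
#' @param kinship Kinship matrix (coefficients phi; the model uses 2*phi).
#' @param covariates Optional numeric matrix of extra fixed effects (age and
#'   sex are normally absorbed by the stratified Blom transform and are not
#'   included by default).
#' @param map Optional marker map; if supplied, `chrom` and `bp_pos` are
#'   merged into the result.
#' @param reml_per_marker Re-estimate the variance ratio by REML for every
#'   marker (slow; default `FALSE`).
#' @return A `data.frame` of class `admix_scan` with columns `marker_id`,
#'   (`chrom`, `bp_pos`,) `beta`, `se`, `p`, `n_used`, and attributes `h2`
#'   and `sigma2` from the null fit. Markers with constant ancestry get
#'   `NA` estimates and are flagged in the `note` column.
#' @export
scan_local_ancestry <- function(blom, ancestry, kinship, covariates = NULL,
                                map = NULL, reml_per_marker = FALSE) {
  y <- .as_named_pheno(blom)
  ids <- names(y)
  if (!all(ids %in% rownames(ancestry)))
    stop("ancestry matrix missing phenotyped individuals")
  if (!all(ids %in% rownames(kinship)))
    stop("kinship matrix missing phenotyped individuals")
  A <- ancestry[ids, , drop = FALSE]
  K <- 2 * kinship[ids, ids, drop = FALSE]
  n <- length(y)
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must align with phenotype")
    X <- cbind(X, covariates)
  }

  null_fit <- fit_lmm_null(y, K, X)
  Ar <- crossprod(null_fit$U, A)              # rotate all markers at once

  m <- ncol(A)
  beta <- se <- p <- rep(NA_real_, m)
  note <- rep(NA_character_, m)
  const <- apply(A, 2, function(x) length(unique(x)) < 2)
  for (j in seq_len(m)) {
    if (const[j]) { note[j] <- "constant_ancestry"; next }
    if (reml_per_marker) {
      fitj <- fit_lmm_null(y, K, cbind(X, A[, j]))
      pcol <- ncol(fitj$Xr)
      g <- .gls_rot(fitj$Xr, fitj$yr, fitj$w)
      sig <- g$rss / (n - pcol)
      beta[j] <- g$beta[pcol]
      se[j] <- sqrt(g$XtWX_inv[pcol, pcol] * sig)
      p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
    } else {
      wres <- .lmm_wald(null_fit, Ar[, j])
      beta[j] <- wres["beta"]; se[j] <- wres["se"]; p[j] <- wres["p"]
      if (is.na(beta[j])) note[j] <- "singular_fit"
    }
  }

  out <- data.frame(marker_id = colnames(A), beta = beta, se = se, p = p,
                    n_used = n, note = note, stringsAsFactors = FALSE)
  if (!is.null(map)) {
    mi <- match(out$marker_id, map$marker_id)
    out$chrom <- map$chrom[mi]
    out$bp_pos <- map$bp_pos[mi]
    out$genetic_pos <- map$genetic_pos[mi]
    out <- out[, c("marker_id", "chrom", "bp_pos", "genetic_pos",
                   "beta", "se", "p", "n_used", "note")]
  }
  structure(out, h2 = null_fit$h2, sigma2 = null_fit$sigma2,
            class = c("admix_scan", "data.frame"))
}

## Accept either a named vector or a phenotype table with blom_score.
.as_named_pheno <- function(blom) {
  if (is.data.frame(blom)) {
    if (!all(c("individual_id", "blom_score") %in% names(blom)))
      stop("phenotype table needs 'individual_id' and 'blom_score'")
    keep <- !is.na(blom$blom_score)
    return(stats::setNames(blom$blom_score[keep], blom$individual_id[keep]))
  }
  if (is.null(names(blom))) stop("phenotype vector must be named by id")
  blom[!is.na(blom)]
}

#' Mixed-model test of phenotype on global ancestry
#'
#' Same kinship mixed model as [scan_local_ancestry()] with the global
#' African proportion as the single predictor, optionally stratified by
#' sex.
#'
#' @param blom Named phenotype vector or phenotype table (see
#'   [scan_local_ancestry()]).
#' @param global_anc Named vector of global African proportions.
#' @param kinship Kinship matrix.
#' @param by_sex Also fit within each sex.
#' @param sex Named character vector of sexes; required when
#'   `by_sex = TRUE`.
#' @return A `data.frame` with one row per stratum (`overall`, and `male` /
#'   `female` when requested): `stratum`, `beta`, `se`, `p`, `n_used`. A
#'   constant predictor yields `NA` with a warning; an absent sex stratum is
#'   skipped with a warning.
#' @export
scan_global_ancestry <- function(blom, global_anc, kinship, by_sex = FALSE,
                                 sex = NULL) {
  y <- .as_named_pheno(blom)
  one <- function(ids, label) {
    yy <- y[ids]
    g <- global_anc[ids]
    if (length(unique(g)) < 2) {
      warning(sprintf("global ancestry constant in stratum '%s'", label))
      return(data.frame(stratum = label, beta = NA, se = NA, p = NA,
                        n_used = length(ids)))
    }
    K <- 2 * kinship[ids, ids, drop = FALSE]
    nf <- fit_lmm_null(yy, K)
    gr <- drop(crossprod(nf$U, g))
    wres <- .lmm_wald(nf, gr)
    data.frame(stratum = label, beta = wres["beta"], se = wres["se"],
               p = wres["p"], n_used = length(ids))
  }
  out <- one(names(y), "overall")
  if (by_sex) {
    if (is.null(sex)) stop("by_sex = TRUE requires a named 'sex' vector")
    for (s in c("male", "female")) {
      ids <- names(y)[sex[names(y)] == s]
      if (length(ids) < 3) {
        warning(sprintf("sex stratum '%s' absent or too small; skipped", s))
        next
      }
      out <- rbind(out, one(ids, s))
    }
  }
  rownames(out) <- NULL
  out
}

#' Quartile comparison of local ancestry between extreme phenotype groups
#'
#' Compares mean African-allele counts at one marker between individuals in
#' the lowest and highest quartiles of the raw phenotype, using a pooled
#' two-sample t-test. With heavy ties at zero (more than 25% of CAC scores
#' are typically zero) the lower group is defined as the zero scores.
#'
#' @param cac_raw Numeric raw phenotype values.
#' @param anc_marker African-allele counts (0/1/2) at the marker, aligned
#'   with `cac_raw`.
#' @return A list: `t`, `p`, `mean_q1`, `mean_q3` (mean allele counts),
#'   `prop_q1`, `prop_q3` (same on the proportion scale), `n1`, `n3`.
#' @export
quartile_ancestry_test <- function(cac_raw, anc_marker) {
  if (length(cac_raw) != length(anc_marker)) stop("inputs must align")
  ok <- !is.na(cac_raw) & !is.na(anc_marker)
  cac <- cac_raw[ok]; anc <- anc_marker[ok]
  if (length(unique(cac)) < 2)
    stop("degenerate quartiles: phenotype is constant")
  qs <- stats::quantile(cac, c(0.25, 0.75), names = FALSE)
  if (mean(cac == 0) > 0.25) {
    lo <- cac == 0
  } else {
    lo <- cac <= qs[1]
  }
  hi <- cac >= qs[2]
  if (sum(lo) < 2 || sum(hi) < 2)
    stop("fewer than 2 individuals in a quartile group")
  x1 <- anc[lo]; x3 <- anc[hi]
  if (stats::var(x1) + stats::var(x3) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(x1, x3, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_q1 = mean(x1), mean_q3 = mean(x3),
       prop_q1 = mean(x1) / 2, prop_q3 = mean(x3) / 2,
       n1 = length(x1), n3 = length(x3))
}
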