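#' Composite linkage-disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of genotype dosage vectors (phase-free,
#' composite LD). Invariant to allele relabelling at either marker.
#'
#' @param genotypes_a,genotypes_b Dosage vectors in \{0,1,2\} (NA allowed;
#'   complete pairs are used).
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(genotypes_a, genotypes_b) {
  if (length(genotypes_a) != length(genotypes_b))
    stop("genotype vectors must have the same length (same individuals)")
  ok <- !is.na(genotypes_a) & !is.na(genotypes_b)
  a <- genotypes_a[ok]; b <- genotypes_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("monomorphic genotype vector")
  stats::cor(a, b)^2
}

#' Find the best LD proxy for an index SNP
#'
#' Searches typed markers within `window_bp` of the index SNP on the same
#' chromosome and returns the one maximising r-squared with the index-SNP
#' genotypes, provided it exceeds `r2_min`. A typed index SNP is its own
#' proxy with r-squared 1 (unless `exclude_index` is set, which mimics an
#' untyped index SNP).
#'
#' @param index_snp Marker id of the index SNP (must be in `map`).
#' @param genotypes Genotype matrix (individuals x typed markers).
#' @param map Marker map covering the index SNP and candidates.
#' @param r2_min Minimum acceptable r-squared (default 0.8).
#' @param window_bp Search window half-width in bp (default 500 kb).
#' @param index_genotypes Dosage vector for the index SNP when it is not a
#'   column of `genotypes`.
#' @param exclude_index Do not return the index SNP itself.
#' @return A list `proxy` (marker id or `NA` when no proxy clears the
#'   floor), `r2`, `n_candidates`.
#' @export
find_proxy <- function(index_snp, genotypes, map, r2_min = 0.8,
                       window_bp = 5e5, index_genotypes = NULL,
                       exclude_index = FALSE) {
  mi <- match(index_snp, map$marker_id)
  if (is.na(mi)) stop("index SNP not found in marker map")
  typed <- index_snp %in% colnames(genotypes)
  if (typed && !exclude_index)
    return(list(proxy = index_snp, r2 = 1, n_candidates = 1L))
  idx_g <- if (typed) genotypes[, index_snp] else index_genotypes
  if (is.null(idx_g))
    stop("index SNP is untyped; supply index_genotypes to compute LD")
  cand <- map$marker_id[map$chrom == map$chrom[mi] &
                        abs(map$bp_pos - map$bp_pos[mi]) <= window_bp &
                        map$marker_id != index_snp]
  cand <- intersect(cand, colnames(genotypes))
  if (length(cand) == 0)
    return(list(proxy = NA_character_, r2 = NA_real_, n_candidates = 0L))
  r2 <- vapply(cand, function(m) {
    tryCatch(ld_r2(idx_g, genotypes[, m]), error = function(e) NA_real_)
  }, numeric(1))
  best <- which.max(r2)
  if (length(best) == 0 || is.na(r2[best]) || r2[best] <= r2_min)
    return(list(proxy = NA_character_, r2 = NA_real_,
                n_candidates = length(cand)))
  list(proxy = cand[best], r2 = unname(r2[best]),
       n_candidates = length(cand))
}

#' Conditional adjustment for a candidate locus and regional re-scan
#'
#' Stage 1 regresses the transformed phenotype on the local African-allele
#' count at the index marker (kinship random effect included by default)
#' and takes the marginal residuals `y - X beta-hat`. Stage 2 re-runs the
#' local-ancestry mixed-model scan over the region's markers on those
#' residuals and compares the lead marker's p-value before and after
#' adjustment. Attenuation of the signal indicates the index locus may
#' account for the regional ancestry association.
#'
#' @param blom Named phenotype vector or phenotype table.
#' @param ancestry African-allele count matrix.
#' @param kinship Kinship matrix.
#' @param region A `target_region` from [delimit_region()].
#' @param index_marker Marker id whose local ancestry is conditioned on
#'   (the candidate SNP or its LD proxy).
#' @param keep_kinship_stage1 Include the kinship random effect in the
#'   stage-1 adjustment (default `TRUE`); `FALSE` gives a fixed-effects-only
#'   adjustment for sensitivity analysis.
#' @param signif_cut P-value cut used to declare the re-scanned lead
#'   non-significant (default 1e-3, the carry-forward cut).
#' @param proxy_r2 Optional r-squared of the proxy, recorded in the report.
#' @return A list of class `attenuation_report`: `region_chrom`,
#'   `lead_marker_id`, `index_marker`, `proxy_r2`, `p_before`, `p_after`,
#'   `attenuated` (`p_after > signif_cut`), `scan_after` (regional scan on
#'   residuals).
#' @export
condition_and_rescan <- function(blom, ancestry, kinship, region,
                                 index_marker, keep_kinship_stage1 = TRUE,
                                 signif_cut = 1e-3, proxy_r2 = NA_real_) {
  y <- .as_named_pheno(blom)
  ids <- names(y)
  if (!index_marker %in% colnames(ancestry))
    stop("index marker has no local-ancestry values")
  x_idx <- ancestry[ids, index_marker]
  if (length(unique(x_idx)) < 2)
    stop("local ancestry at the index marker is constant")

  reg_markers <- region$marker_ids
  A_reg <- ancestry[, reg_markers, drop = FALSE]

  ## p at the lead before adjustment
  scan_before <- scan_local_ancestry(y, A_reg, kinship)
  p_before <- scan_before$p[scan_before$marker_id == region$lead_marker_id]

  ## stage 1: adjust for index-marker ancestry
  X <- cbind(1, x_idx)
  if (keep_kinship_stage1) {
    K <- 2 * kinship[ids, ids, drop = FALSE]
    nf <- fit_lmm_null(y, K, X)
    resid <- drop(y - X %*% nf$beta)
  } else {
    resid <- stats::residuals(stats::lm.fit(X, y))
  }
  names(resid) <- ids

  ## stage 2: regional re-scan on the residuals
  scan_after <- scan_local_ancestry(resid, A_reg, kinship)
  p_after <- scan_after$p[scan_after$marker_id == region$lead_marker_id]

  structure(list(region_chrom = region$chrom,
                 lead_marker_id = region$lead_marker_id,
                 index_marker = index_marker,
                 proxy_r2 = proxy_r2,
                 p_before = p_before,
                 p_after = p_after,
                 attenuated = is.na(p_after) || p_after > signif_cut,
                 scan_after = scan_after),
            class = "attenuation_report")
}

#' @export
print.attenuation_report <- function(x, ...) {
  cat(sprintf(
    "Conditional adjustment (chr%s lead %s | index %s): p %.3g -> %.3g (%s)\n",
    x$region_chrom, x$lead_marker_id, x$index_marker,
    x$p_before, x$p_after,
    if (x$attenuated) "attenuated" else "not attenuated"))
  invisible(x)
}
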