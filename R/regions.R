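#' Carry forward lead markers from an ancestry scan
#'
#' Returns one lead marker per eventual target region: among markers with
#' `p < p_cut`, candidates are taken in order of increasing p and a
#' candidate is dropped if it falls inside the delimited region (see
#' [delimit_region()]) of a lead already accepted on the same chromosome.
#'
#' @param scan An `admix_scan` result with `chrom` and `bp_pos` columns.
#' @param p_cut Carry-forward threshold (default 1e-3).
#' @param drop The -log10(p) drop used to delimit each lead's envelope.
#' @return Character vector of lead marker ids (possibly empty), ordered by
#'   increasing p.
#' @export
carry_forward <- function(scan, p_cut = 1e-3, drop = 2.0) {
  if (!all(c("chrom", "bp_pos") %in% names(scan)))
    stop("scan must carry 'chrom' and 'bp_pos' (supply the map to the scan)")
  cand <- scan[!is.na(scan$p) & scan$p < p_cut, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  cand <- cand[order(cand$p), , drop = FALSE]
  leads <- character(0)
  claimed <- list()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]; bp <- cand$bp_pos[i]
    inside <- any(vapply(claimed, function(r) {
      r$chrom == ch && bp >= r$start_bp && bp <= r$end_bp
    }, logical(1)))
    if (inside) next
    reg <- delimit_region(scan, cand$marker_id[i], drop = drop)
    leads <- c(leads, cand$marker_id[i])
    claimed[[length(claimed) + 1L]] <- reg
  }
  leads
}

#' Delimit the target region around a lead marker
#'
#' Walks outward from the lead along the chromosome's map order and keeps
#' the maximal contiguous run of markers whose -log10(p) stays within
#' `drop` units of the lead's -log10(p). The outermost qualifying markers
#' are the region bounds; their p-values are reported as the boundary
#' p-values (lower-coordinate bound first).
#'
#' @param scan An `admix_scan` result with `chrom` and `bp_pos`.
#' @param lead_marker_id Marker id of the lead (must be in the scan).
#' @param drop Allowed drop in -log10(p) units (default 2.0).
#' @return A list of class `target_region`: `chrom`, `lead_marker_id`,
#'   `lead_p`, `start_bp`, `end_bp`, `start_marker`, `end_marker`,
#'   `boundary_p_lower`, `boundary_p_upper`, `marker_ids` (all markers in
#'   the region), and flags `at_chrom_edge` (one-sided region) and
#'   `spans_chromosome`.
#' @export
delimit_region <- function(scan, lead_marker_id, drop = 2.0) {
  i0 <- match(lead_marker_id, scan$marker_id)
  if (is.na(i0)) stop("lead marker not found in scan")
  ch <- scan$chrom[i0]
  sub <- scan[scan$chrom == ch & !is.na(scan$p), , drop = FALSE]
  sub <- sub[order(sub$bp_pos), , drop = FALSE]
  k0 <- match(lead_marker_id, sub$marker_id)
  lp <- -log10(sub$p)
  cut <- lp[k0] - drop
  lo <- k0
  while (lo > 1 && lp[lo - 1] >= cut) lo <- lo - 1
  hi <- k0
  while (hi < nrow(sub) && lp[hi + 1] >= cut) hi <- hi + 1
  structure(list(
    chrom = ch,
    lead_marker_id = lead_marker_id,
    lead_p = sub$p[k0],
    start_bp = sub$bp_pos[lo],
    end_bp = sub$bp_pos[hi],
    start_marker = sub$marker_id[lo],
    end_marker = sub$marker_id[hi],
    boundary_p_lower = sub$p[lo],
    boundary_p_upper = sub$p[hi],
    marker_ids = sub$marker_id[lo:hi],
    at_chrom_edge = (lo == 1 || hi == nrow(sub)),
    spans_chromosome = (lo == 1 && hi == nrow(sub))
  ), class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf(
    "Target region chr%s:%d-%d (lead %s, p = %.3g; boundary p = %.3g / %.3g)\n",
    x$chrom, x$start_bp, x$end_bp, x$lead_marker_id, x$lead_p,
    x$boundary_p_lower, x$boundary_p_upper))
  if (x$spans_chromosome) cat("  note: region spans the whole chromosome\n")
  else if (x$at_chrom_edge) cat("  note: region reaches a chromosome edge\n")
  invisible(x)
}

#' Ancestry informativeness (delta) of a marker
#'
#' The absolute allele-frequency difference of an index allele between the
#' two ancestral populations (African and European reference panels). A
#' marker is ancestry-informative when delta exceeds 0.2 (strictly, by
#' default).
#'
#' @param freq_afr,freq_eur Allele frequencies in \[0, 1\] (vectorised).
#' @return `abs(freq_afr - freq_eur)`.
#' @export
delta <- function(freq_afr, freq_eur) {
  if (any(freq_afr < 0 | freq_afr > 1 | freq_eur < 0 | freq_eur > 1,
          na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  abs(freq_afr - freq_eur)
}

#' Informative markers inside a target region
#'
#' @param region A [delimit_region()] result.
#' @param map Marker map with `freq_afr`, `freq_eur`, `chrom`, `bp_pos`.
#' @param delta_min Informativeness cutoff (default 0.2).
#' @param strict Use strictly greater than (`>`; default) or `>=`.
#' @return Character vector of informative marker ids inside the region.
#' @export
informative_markers <- function(region, map, delta_min = 0.2, strict = TRUE) {
  inside <- map$chrom == region$chrom &
    map$bp_pos >= region$start_bp & map$bp_pos <= region$end_bp
  ## round to 9 decimals so a printed delta of exactly 0.20 sits on the
  ## boundary rather than a float epsilon below it
  d <- round(delta(map$freq_afr[inside], map$freq_eur[inside]), 9)
  keep <- if (strict) d > delta_min else d >= delta_min
  map$marker_id[inside][keep]
}

#' Region-specific Bonferroni threshold
#'
#' Divides `alpha` by the number of ancestry-informative SNPs looked up in
#' the region and additionally by the number of regions considered, per the
#' two-stage Bonferroni correction.
#'
#' @param n_informative Number of informative (delta > 0.2) SNPs in the
#'   region (>= 1).
#' @param n_regions Number of regions considered (default 4).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / (n_informative * n_regions)`.
#' @export
regional_threshold <- function(n_informative, n_regions = 4, alpha = 0.05) {
  if (any(n_informative < 1)) stop("need at least one informative SNP")
  if (any(n_regions < 1)) stop("n_regions must be >= 1")
  alpha / (n_informative * n_regions)
}

#' Flag candidate driver SNPs in a target region
#'
#' Given externally obtained association p-values (e.g. from a published
#' meta-analysis) for the informative SNPs inside a region, flags SNPs
#' below the region-specific threshold as candidate drivers, and SNPs
#' within one order of magnitude of the threshold as suggestive.
#'
#' @param region A `target_region` with element `regional_threshold`
#'   attached (or pass `threshold`).
#' @param external `data.frame` with columns `snp`, `chrom`, `bp`, `p` (and
#'   optionally `effect`, `se`).
#' @param threshold Region-specific p-value threshold; defaults to
#'   `region$regional_threshold`.
#' @return The `external` table restricted to flagged SNPs, with a `status`
#'   column (`"driver"` or `"suggestive"`), ordered by p.
#' @export
flag_candidates <- function(region, external, threshold = NULL) {
  if (is.null(threshold)) threshold <- region$regional_threshold
  if (is.null(threshold)) stop("no regional threshold available")
  need <- c("snp", "chrom", "bp", "p")
  if (!all(need %in% names(external)))
    stop("external table needs columns: ", paste(need, collapse = ", "))
  out_of_region <- external$chrom != region$chrom |
    external$bp < region$start_bp | external$bp > region$end_bp
  if (any(out_of_region))
    stop("SNP(s) outside region bounds: ",
         paste(external$snp[out_of_region], collapse = ", "))
  status <- ifelse(external$p < threshold, "driver",
                   ifelse(external$p < 10 * threshold, "suggestive",
                          NA_character_))
  res <- external[!is.na(status), , drop = FALSE]
  res$status <- status[!is.na(status)]
  res[order(res$p), , drop = FALSE]
}
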