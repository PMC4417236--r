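#' Default pipeline configuration
#'
#' All tunables of the analysis pipeline with their standard defaults:
#' sample filter at 1% global African ancestry, marker filters (MAF 1%,
#' HWE 1e-6, call rate 0.99), Blom transform within sex x decade strata,
#' carry-forward at p < 1e-3, region delimitation at a 2.0-unit
#' -log10(p) drop, delta > 0.2 informativeness (strict), LD-proxy floor
#' r2 > 0.8 with a 500 kb window, and family-wise alpha 0.05.
#'
#' @param ... Overrides for any tunable; unknown names are an error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    alpha = 0.05,
    p_cut = 1e-3,
    drop = 2.0,
    delta_min = 0.2,
    delta_strict = TRUE,
    r2_min = 0.8,
    window_bp = 5e5,
    maf_min = 0.01,
    hwe_p_min = 1e-6,
    call_rate_min = 0.99,
    min_afr = 0.01,
    age_breaks = c(30, 40, 50, 60),
    meff_agg = "median",
    meff_mode = "per_individual",
    p_max = 20,
    by_sex = TRUE,
    run_conditional = FALSE,
    make_plot = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the admixture-mapping pipeline end to end
#'
#' Executes quality control (sample and marker filters), the stratified
#' Blom transform, pedigree kinship construction, the genome-wide
#' local-ancestry mixed-model scan, the global-ancestry test (overall and
#' by sex), effective-test estimation with the genome-wide threshold,
#' carry-forward and region delimitation, informative-marker counting with
#' region-specific thresholds, quartile ancestry comparisons at the leads,
#' and (optionally) conditional adjustment per region. Writes
#' tab-delimited result tables, a JSON run manifest and a Manhattan-style
#' plot to `out_dir`.
#'
#' @param cohort A `sim_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param out_dir Output directory; `NULL` skips all file output.
#' @param config A [pipeline_config()].
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic given the cohort).
#' @return A list of class `admix_pipeline` with elements `qc`, `phenotypes`,
#'   `scan`, `global`, `meff`, `leads`, `regions`, `quartile`,
#'   `conditional`, `config`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))

  ## --- QC ------------------------------------------------------------
  ganc <- global_ancestry(cohort$ancestry)
  ind_filter <- filter_individuals(cohort$phenotypes, ganc,
                                   min_afr = config$min_afr)
  kept_ids <- ind_filter$kept
  if (length(kept_ids) == 0) stop("qc: no individuals left after filtering")
  mrk_filter <- filter_markers(cohort$genotypes,
                               maf_min = config$maf_min,
                               hwe_p_min = config$hwe_p_min,
                               call_rate_min = config$call_rate_min)
  kept_markers <- mrk_filter$kept
  message(sprintf("qc: %d/%d individuals, %d/%d markers retained",
                  length(kept_ids), nrow(cohort$ancestry),
                  length(kept_markers), ncol(cohort$genotypes)))

  anc <- cohort$ancestry[kept_ids, kept_markers, drop = FALSE]
  map <- cohort$map[match(kept_markers, cohort$map$marker_id), ]
  phe <- cohort$phenotypes[match(kept_ids, cohort$phenotypes$individual_id), ]

  ## --- transform ------------------------------------------------------
  phe <- add_blom_score(phe, age_breaks = config$age_breaks)

  ## --- kinship + scans -------------------------------------------------
  phi <- kinship_from_pedigree(cohort$pedigree)[kept_ids, kept_ids]
  scan <- scan_local_ancestry(phe, anc, phi, map = map)
  sexv <- stats::setNames(phe$sex, phe$individual_id)
  glob <- scan_global_ancestry(phe, global_ancestry(anc), phi,
                               by_sex = config$by_sex, sex = sexv)

  ## --- effective tests -------------------------------------------------
  meff <- effective_tests(anc, map, alpha = config$alpha,
                          agg = config$meff_agg, mode = config$meff_mode,
                          p_max = config$p_max)

  ## --- regions ----------------------------------------------------------
  leads <- carry_forward(scan, p_cut = config$p_cut, drop = config$drop)
  n_regions <- max(length(leads), 1L)
  regions <- lapply(leads, function(ld) {
    reg <- delimit_region(scan, ld, drop = config$drop)
    inf <- informative_markers(reg, map, delta_min = config$delta_min,
                               strict = config$delta_strict)
    reg$n_informative <- length(inf)
    reg$informative_ids <- inf
    reg$regional_threshold <-
      if (length(inf)) regional_threshold(length(inf), n_regions,
                                          config$alpha) else NA_real_
    reg
  })
  names(regions) <- leads

  quart <- lapply(leads, function(ld) {
    quartile_ancestry_test(phe$cac, anc[phe$individual_id, ld])
  })
  names(quart) <- leads

  ## --- conditional (optional; conditions on each region's own lead) ----
  conditional <- NULL
  if (config$run_conditional && length(regions)) {
    conditional <- lapply(regions, function(reg) {
      condition_and_rescan(phe, anc, phi, reg, reg$lead_marker_id,
                           signif_cut = config$p_cut)
    })
  }

  result <- structure(
    list(qc = list(individuals = ind_filter, markers = mrk_filter,
                   global_ancestry = ganc),
         phenotypes = phe, scan = scan, global = glob, meff = meff,
         leads = leads, regions = regions, quartile = quart,
         conditional = conditional, config = config, seed = seed),
    class = "admix_pipeline")

  if (!is.null(out_dir)) .write_pipeline_outputs(result, map, out_dir)
  result
}

.write_pipeline_outputs <- function(result, map, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(result$scan), "scan.tsv")
  wt(result$qc$individuals$excluded, "excluded_individuals.tsv")
  wt(result$qc$markers$excluded, "excluded_markers.tsv")
  wt(result$meff$per_chromosome, "meff_per_chromosome.tsv")
  wt(result$global, "global_ancestry_tests.tsv")
  if (length(result$regions)) {
    regdf <- do.call(rbind, lapply(result$regions, function(r) {
      data.frame(chrom = r$chrom, lead_marker_id = r$lead_marker_id,
                 lead_p = r$lead_p, start_bp = r$start_bp,
                 end_bp = r$end_bp,
                 boundary_p_lower = r$boundary_p_lower,
                 boundary_p_upper = r$boundary_p_upper,
                 n_informative = r$n_informative,
                 regional_threshold = r$regional_threshold)
    }))
    wt(regdf, "regions.tsv")
  }
  manifest <- list(
    package = "admixscan",
    version = as.character(utils::packageVersion("admixscan")),
    r_version = R.version.string,
    seed = result$seed,
    parameters = unclass(result$config),
    n_analyzed = length(result$qc$individuals$kept),
    total_meff = result$meff$total_meff,
    genomewide_threshold = result$meff$threshold,
    leads = result$leads
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (isTRUE(result$config$make_plot)) {
    grDevices::png(file.path(out_dir, "manhattan.png"),
                   width = 1200, height = 500)
    plot_manhattan(result$scan, threshold = result$meff$threshold)
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' Manhattan-style plot of an ancestry scan
#'
#' @param scan An `admix_scan` with `chrom` and `bp_pos`.
#' @param threshold Optional genome-wide p-value threshold (horizontal
#'   line).
#' @param p_cut Optional carry-forward threshold (dashed line).
#' @return Invisibly, `NULL`; draws on the current device.
#' @export
plot_manhattan <- function(scan, threshold = NULL, p_cut = 1e-3) {
  ok <- !is.na(scan$p)
  chroms <- unique(scan$chrom)
  offset <- 0
  xs <- numeric(sum(ok)); cols <- integer(sum(ok))
  pos <- scan$bp_pos
  x_all <- rep(NA_real_, nrow(scan))
  for (i in seq_along(chroms)) {
    sel <- scan$chrom == chroms[i]
    x_all[sel] <- pos[sel] + offset
    offset <- offset + max(pos[sel]) + 1e6
  }
  colv <- ifelse(match(scan$chrom, chroms) %% 2 == 0, "grey40", "steelblue")
  graphics::plot(x_all[ok], -log10(scan$p[ok]), pch = 16, cex = 0.6,
                 col = colv[ok], xaxt = "n", xlab = "chromosome",
                 ylab = expression(-log[10](p)),
                 main = "Local-ancestry association scan")
  mid <- vapply(chroms, function(ch) mean(x_all[scan$chrom == ch],
                                          na.rm = TRUE), numeric(1))
  graphics::axis(1, at = mid, labels = chroms)
  if (!is.null(threshold))
    graphics::abline(h = -log10(threshold), col = "red")
  if (!is.null(p_cut))
    graphics::abline(h = -log10(p_cut), col = "red", lty = 2)
  invisible(NULL)
}

#' @export
print.admix_pipeline <- function(x, ...) {
  cat("Admixture-mapping pipeline result\n")
  cat(sprintf("  analyzed individuals: %d\n",
              length(x$qc$individuals$kept)))
  cat(sprintf("  markers scanned: %d\n", nrow(x$scan)))
  cat(sprintf("  total Meff: %.1f (genome-wide threshold %.3g)\n",
              x$meff$total_meff, x$meff$threshold))
  cat(sprintf("  carried-forward leads: %s\n",
              if (length(x$leads)) paste(x$leads, collapse = ", ")
              else "none"))
  invisible(x)
}
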