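## Shared fixture builders (everything generated in code).

## Small simulated cohort for fast end-to-end tests.
small_cohort <- function(seed = 11, n_families = 40, n_chrom = 2,
                         m_per_chrom = 25, causal = NULL, ...) {
  cfg <- sim_config(n_families = n_families, n_chromosomes = n_chrom,
                    n_markers_per_chrom = m_per_chrom,
                    causal_loci = causal, seed = seed, ...)
  simulate_cohort(cfg)
}

## Map with near-zero genetic distances (no recombination possible).
zero_distance_map <- function(m = 20) {
  data.frame(marker_id = sprintf("chr1_m%03d", seq_len(m)),
             chrom = 1,
             bp_pos = seq_len(m),
             genetic_pos = 50 + (seq_len(m) - 1) * 1e-9,
             freq_afr = rep(0.5, m), freq_eur = rep(0.5, m),
             stringsAsFactors = FALSE)
}

## Synthetic scan table from a -log10(p) profile on one chromosome.
scan_from_profile <- function(logp, chrom = 1) {
  data.frame(marker_id = sprintf("chr%d_m%03d", chrom, seq_along(logp)),
             chrom = chrom,
             bp_pos = seq_along(logp) * 1e5,
             beta = 0, se = 1,
             p = 10^(-logp),
             n_used = 100,
             stringsAsFactors = FALSE)
}

## Exhaustive-window oracle for region delimitation: the largest contiguous
## window containing the lead in which every marker satisfies the drop rule.
region_oracle <- function(logp, lead_idx, drop = 2.0) {
  cut <- logp[lead_idx] - drop
  best <- c(lead_idx, lead_idx)
  for (lo in seq_len(lead_idx)) {
    for (hi in lead_idx:length(logp)) {
      if (all(logp[lo:hi] >= cut) && (hi - lo) > (best[2] - best[1]))
        best <- c(lo, hi)
    }
  }
  best
}

## Three-generation pedigree used by the kinship tests.
three_gen_pedigree <- function() {
  data.frame(
    individual_id = c("gf", "gm", "f2", "c1", "c2", "sp", "g1", "g2"),
    father_id = c(NA, NA, NA, "gf", "gf", NA, "c1", "c1"),
    mother_id = c(NA, NA, NA, "gm", "gm", NA, "sp", "sp"),
    stringsAsFactors = FALSE
  )
}

## Gene-dropping Monte-Carlo estimate of kinship between two individuals:
## founders carry unique allele labels, alleles are dropped through the
## pedigree, and kinship is the probability that one allele sampled from
## each individual is identical by descent.
gene_drop_kinship <- function(pedigree, id_a, id_b, n_rep = 4000) {
  ids <- pedigree$individual_id
  fi <- match(pedigree$father_id, ids)
  mi <- match(pedigree$mother_id, ids)
  n <- length(ids)
  ia <- match(id_a, ids); ib <- match(id_b, ids)
  hits <- 0
  for (r in seq_len(n_rep)) {
    a1 <- a2 <- integer(n)
    lab <- 0L
    for (i in seq_len(n)) {        # pedigree rows ordered parents-first
      if (is.na(fi[i])) {
        a1[i] <- (lab <- lab + 1L)
        a2[i] <- (lab <- lab + 1L)
      } else {
        a1[i] <- if (stats::runif(1) < 0.5) a1[fi[i]] else a2[fi[i]]
        a2[i] <- if (stats::runif(1) < 0.5) a1[mi[i]] else a2[mi[i]]
      }
    }
    x <- if (stats::runif(1) < 0.5) a1[ia] else a2[ia]
    y <- if (stats::runif(1) < 0.5) a1[ib] else a2[ib]
    hits <- hits + (x == y)
  }
  hits / n_rep
}
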