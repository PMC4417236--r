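#' Configuration for the synthetic admixed-cohort simulator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' emulate a sibship-based African American cohort: 211 families of 2-4
#' genotyped siblings (expected total close to 622 before quality control),
#' mean individual African ancestry proportion around 0.85 (SD about 0.075,
#' matching reported per-sex standard deviations near 0.07-0.08), admixture
#' roughly 6 generations old, and a zero-inflated, right-skewed coronary
#' artery calcification (CAC) score that is higher in men and increases with
#' age.
#'
#' Ancestry along each chromosome follows a hybrid-isolation Markov model:
#' crossover events arise as a Poisson process at rate `g` per Morgan and at
#' each event the ancestral origin is redrawn as African with the
#' individual's own proportion `q`. `q` is drawn per founder from a Beta
#' distribution parameterised by `q_mean` and `q_sd`; offspring inherit
#' ancestry through simulated meioses (one crossover per Morgan, Haldane
#' model), so sibling ancestry is correlated through transmission.
#'
#' @param n_families Number of sibship families.
#' @param sib_weights Named numeric vector: probability of each sibship size
#'   (names are sizes). Default gives expected cohort size ~622 with 211
#'   families.
#' @param total_sibs Optional exact total number of siblings; sibship sizes
#'   are adjusted after sampling to hit this total exactly.
#' @param n_chromosomes,n_markers_per_chrom,chrom_length Map dimensions;
#'   `chrom_length` in Morgans.
#' @param g Generations since admixture (ancestry-switch rate per Morgan).
#' @param q_mean,q_sd Mean and SD of the founder African-ancestry proportion
#'   Beta distribution; must satisfy `q_sd^2 < q_mean * (1 - q_mean)`.
#' @param delta_frac Fraction of markers whose ancestral allele-frequency
#'   difference (delta) is drawn above the 0.2 informativeness cutoff.
#' @param causal_loci `NULL`, or a data.frame with columns `marker` (global
#'   marker index into the map) and `beta` (effect of one African allele on
#'   the latent phenotype scale; negative values encode a protective effect
#'   of African ancestry).
#' @param beta_age,beta_sex_male Latent-scale covariate effects (per year,
#'   and male vs female).
#' @param age_mean,age_sd,age_min Age distribution of siblings (years).
#' @param prop_male Probability that a sibling is male (cohort is ~1/3 male).
#' @param sigma_poly SD of the polygenic family effect (covariance
#'   `sigma_poly^2 * 2 * kinship`).
#' @param sigma_env SD of the independent residual.
#' @param zero_rate Target fraction of CAC scores equal to zero (latent
#'   threshold hurdle). Default 0.47 reproduces the reported ~38% zeros in
#'   men and ~51% in women at the default sex effect.
#' @param cac_shape,cac_scale Shape and scale of the positive part:
#'   `cac = cac_scale * expm1(cac_shape * (latent - threshold))`.
#' @param n_missing_pheno Number of siblings whose CAC is set missing (to
#'   exercise the missing-phenotype exclusion).
#' @param n_low_afr Number of siblings whose ancestry is overridden to be
#'   essentially European (`q = low_afr_q`), to exercise the low-ancestry
#'   exclusion.
#' @param low_afr_q African proportion used for the overridden individuals.
#' @param missing_geno_rate Per-entry genotype missingness probability.
#' @param include_parents If `TRUE`, parents appear in the ancestry/genotype
#'   matrices as well as the pedigree (they are never phenotyped).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_families = 211,
                       sib_weights = c("2" = 0.35, "3" = 0.35, "4" = 0.30),
                       total_sibs = NULL,
                       n_chromosomes = 4,
                       n_markers_per_chrom = 60,
                       chrom_length = 1.4,
                       g = 6,
                       q_mean = 0.85,
                       q_sd = 0.075,
                       delta_frac = 0.4,
                       causal_loci = NULL,
                       beta_age = 0.04,
                       beta_sex_male = 0.6,
                       age_mean = 30,
                       age_sd = 12,
                       age_min = 18,
                       prop_male = 0.34,
                       sigma_poly = 0.5,
                       sigma_env = 0.85,
                       zero_rate = 0.47,
                       cac_shape = 1.2,
                       cac_scale = 60,
                       n_missing_pheno = 0,
                       n_low_afr = 0,
                       low_afr_q = 0.004,
                       missing_geno_rate = 0,
                       include_parents = FALSE,
                       seed = 1L) {
  stopifnot(n_families >= 1, n_chromosomes >= 1, n_markers_per_chrom >= 2,
            chrom_length > 0)
  if (!(g > 0)) stop("generations since admixture 'g' must be > 0")
  if (q_mean <= 0 || q_mean >= 1) stop("q_mean must lie in (0, 1)")
  if (q_sd^2 >= q_mean * (1 - q_mean))
    stop("q_sd too large for a Beta distribution with this mean")
  if (low_afr_q <= 0 || low_afr_q >= 1) stop("low_afr_q must lie in (0, 1)")
  if (zero_rate < 0 || zero_rate >= 1) stop("zero_rate must lie in [0, 1)")
  if (delta_frac < 0 || delta_frac > 1) stop("delta_frac must lie in [0, 1]")
  if (is.null(names(sib_weights)) ||
      any(is.na(suppressWarnings(as.integer(names(sib_weights))))))
    stop("sib_weights must be named by integer sibship sizes")
  if (any(sib_weights < 0) || sum(sib_weights) <= 0)
    stop("sib_weights must be non-negative and sum to a positive value")
  if (!is.null(causal_loci)) {
    causal_loci <- as.data.frame(causal_loci)
    if (!all(c("marker", "beta") %in% names(causal_loci)))
      stop("causal_loci needs columns 'marker' and 'beta'")
    m_total <- n_chromosomes * n_markers_per_chrom
    if (any(causal_loci$marker < 1 | causal_loci$marker > m_total))
      stop("causal marker index out of range")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## Beta shape parameters from mean/sd
.q_beta_shapes <- function(q_mean, q_sd) {
  nu <- q_mean * (1 - q_mean) / q_sd^2 - 1
  c(shape1 = q_mean * nu, shape2 = (1 - q_mean) * nu)
}

#' Build a synthetic marker map
#'
#' Generates per-chromosome genetic positions (strictly increasing, cM),
#' physical positions (bp, 1 cM taken as 1 Mb), and African/European allele
#' frequencies with a configurable fraction of ancestry-informative markers
#' (delta > 0.2).
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `marker_id`, `chrom`, `bp_pos`,
#'   `genetic_pos` (cM), `freq_afr`, `freq_eur`.
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_markers_per_chrom
  len_cm <- config$chrom_length * 100
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    gpos <- sort(stats::runif(m, 0, len_cm))
    while (any(diff(gpos) <= 0)) gpos <- sort(stats::runif(m, 0, len_cm))
    p_afr <- stats::runif(m, 0.05, 0.95)
    hi <- stats::runif(m) < config$delta_frac
    d <- ifelse(hi, stats::runif(m, 0.25, 0.60), stats::runif(m, 0, 0.20))
    sgn <- ifelse(stats::runif(m) < 0.5, -1, 1)
    p_eur <- p_afr + sgn * d
    flip <- p_eur < 0 | p_eur > 1
    p_eur[flip] <- p_afr[flip] - sgn[flip] * d[flip]
    p_eur <- pmin(pmax(p_eur, 0), 1)
    data.frame(
      marker_id = sprintf("chr%d_m%03d", ch, seq_len(m)),
      chrom = ch,
      bp_pos = as.integer(round(gpos * 1e6)),
      genetic_pos = gpos,
      freq_afr = p_afr,
      freq_eur = p_eur,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, maps)
}

#' Build a sibship pedigree
#'
#' Two founder parents per family plus the sampled number of full siblings.
#' Parent sex is 1 (father) / 2 (mother); sibling sex is drawn Bernoulli.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex` ("male"/"female") and `role`
#'   ("parent"/"sib"). Founder parent ids are `NA` in `father_id`/`mother_id`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- as.integer(names(config$sib_weights))
  nf <- config$n_families
  counts <- sample(sizes, nf, replace = TRUE,
                   prob = config$sib_weights / sum(config$sib_weights))
  if (!is.null(config$total_sibs)) {
    tgt <- as.integer(config$total_sibs)
    if (tgt < nf * min(sizes) || tgt > nf * max(sizes))
      stop("total_sibs unreachable with the given sibship sizes")
    while (sum(counts) > tgt) {
      i <- sample(which(counts > min(sizes)), 1L)
      counts[i] <- counts[i] - 1L
    }
    while (sum(counts) < tgt) {
      i <- sample(which(counts < max(sizes)), 1L)
      counts[i] <- counts[i] + 1L
    }
  }
  rows <- lapply(seq_len(nf), function(f) {
    fam <- sprintf("F%03d", f)
    fa <- sprintf("%s_P1", fam)
    mo <- sprintf("%s_P2", fam)
    sibs <- sprintf("%s_S%d", fam, seq_len(counts[f]))
    data.frame(
      family_id = fam,
      individual_id = c(fa, mo, sibs),
      father_id = c(NA, NA, rep(fa, counts[f])),
      mother_id = c(NA, NA, rep(mo, counts[f])),
      sex = c("male", "female",
              ifelse(stats::runif(counts[f]) < config$prop_male,
                     "male", "female")),
      role = c("parent", "parent", rep("sib", counts[f])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

## Simulate founder haplotypes for one chromosome.
## q: vector of per-haplotype African proportions; gpos in cM.
## Returns 0/1 matrix (haplotypes x markers), 1 = African.
.sim_founder_haps <- function(q, gpos, g) {
  m <- length(gpos)
  nh <- length(q)
  d <- diff(gpos) / 100                       # Morgans
  p_switch <- 1 - exp(-g * d)
  H <- matrix(0L, nh, m)
  H[, 1] <- stats::rbinom(nh, 1L, q)
  for (k in seq_len(m - 1L)) {
    ev <- stats::runif(nh) < p_switch[k]
    redraw <- stats::rbinom(nh, 1L, q)
    H[, k + 1L] <- ifelse(ev, redraw, H[, k])
  }
  H
}

## One meiosis per child from a parent's two haplotypes (Haldane, rate 1/Morgan).
## h1, h2: (children x markers) matrices of the parent's haplotypes replicated
## per child row. Returns transmitted haplotype matrix.
.sim_meiosis <- function(h1, h2, gpos) {
  m <- length(gpos)
  n <- nrow(h1)
  d <- diff(gpos) / 100
  p_co <- 0.5 * (1 - exp(-2 * d))             # recombination fraction
  src <- stats::rbinom(n, 1L, 0.5)            # 0 -> h1, 1 -> h2
  out <- matrix(0L, n, m)
  out[, 1] <- ifelse(src == 0L, h1[, 1], h2[, 1])
  for (k in seq_len(m - 1L)) {
    co <- stats::runif(n) < p_co[k]
    src <- ifelse(co, 1L - src, src)
    out[, k + 1L] <- ifelse(src == 0L, h1[, k + 1L], h2[, k + 1L])
  }
  out
}

## Full ancestry simulation over the pedigree; returns haplotype matrices and
## per-individual realised African proportion.
.sim_ancestry_internal <- function(config, map = NULL, pedigree = NULL) {
  if (is.null(map)) map <- simulate_marker_map(config)
  if (is.null(pedigree)) pedigree <- simulate_pedigree(config)
  if (any(map$freq_afr < 0 | map$freq_afr > 1 |
          map$freq_eur < 0 | map$freq_eur > 1))
    stop("allele frequencies must lie in [0, 1]")
  bad <- tapply(map$genetic_pos, map$chrom, function(x) any(diff(x) <= 0))
  if (any(unlist(bad)))
    stop("genetic positions must be strictly increasing within chromosome")

  ids <- pedigree$individual_id
  n <- length(ids)
  m <- nrow(map)
  is_founder <- is.na(pedigree$father_id)
  founders <- which(is_founder)
  kids <- which(!is_founder)

  shapes <- .q_beta_shapes(config$q_mean, config$q_sd)
  qf <- stats::rbeta(length(founders), shapes[1], shapes[2])
  qf <- pmin(pmax(qf, 1e-6), 1 - 1e-6)

  hap1 <- matrix(0L, n, m, dimnames = list(ids, map$marker_id))
  hap2 <- matrix(0L, n, m, dimnames = list(ids, map$marker_id))
  fa_idx <- match(pedigree$father_id[kids], ids)
  mo_idx <- match(pedigree$mother_id[kids], ids)

  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    gpos <- map$genetic_pos[cols]
    hap1[founders, cols] <- .sim_founder_haps(qf, gpos, config$g)
    hap2[founders, cols] <- .sim_founder_haps(qf, gpos, config$g)
    hap1[kids, cols] <- .sim_meiosis(hap1[fa_idx, cols, drop = FALSE],
                                     hap2[fa_idx, cols, drop = FALSE], gpos)
    hap2[kids, cols] <- .sim_meiosis(hap1[mo_idx, cols, drop = FALSE],
                                     hap2[mo_idx, cols, drop = FALSE], gpos)
  }

  q_true <- stats::setNames(rep(NA_real_, n), ids)
  q_true[founders] <- qf
  list(map = map, pedigree = pedigree, hap1 = hap1, hap2 = hap2,
       founder_q = stats::setNames(qf, ids[founders]))
}

#' Simulate local-ancestry tracks for an admixed family cohort
#'
#' Founder haplotypes follow the hybrid-isolation Markov model (crossovers at
#' rate `g` per Morgan, ancestry redrawn Bernoulli(`q`) at each crossover);
#' offspring haplotypes are produced by meiosis from the parental haplotypes
#' with one crossover per Morgan. The returned matrix counts African alleles
#' (0/1/2) per individual and marker.
#'
#' @param config A [sim_config()].
#' @param map Optional pre-built marker map (see [simulate_marker_map()]).
#' @param pedigree Optional pre-built pedigree (see [simulate_pedigree()]).
#' @return An integer matrix (individuals x markers) with values in
#'   \{0,1,2\}, row names = individual ids, column names = marker ids, and
#'   attributes `map`, `pedigree` and `q_true` (realised per-individual
#'   global African proportion). Rows cover siblings only unless
#'   `config$include_parents` is `TRUE`.
#' @export
simulate_ancestry_tracks <- function(config, map = NULL, pedigree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim <- .sim_ancestry_internal(config, map, pedigree)
  counts <- sim$hap1 + sim$hap2
  keep <- if (config$include_parents) rep(TRUE, nrow(counts))
          else sim$pedigree$role == "sib"
  counts <- counts[keep, , drop = FALSE]
  structure(counts,
            map = sim$map,
            pedigree = sim$pedigree,
            q_true = rowSums(counts) / (2 * ncol(counts)))
}

#' Simulate genotypes given local ancestry and ancestral allele frequencies
#'
#' Each of the two alleles at a marker is drawn Bernoulli with the allele
#' frequency of the haplotype's local ancestral population, so the genotype
#' at a marker with `c` African alleles is
#' `Binom(c, freq_afr) + Binom(2 - c, freq_eur)`.
#'
#' @param ancestry Integer matrix of African-allele counts (individuals x
#'   markers), columns matching `map$marker_id`.
#' @param map Marker map with `freq_afr` and `freq_eur`.
#' @param seed Optional integer seed (omit to use the current RNG state).
#' @param missing_rate Per-entry missingness probability.
#' @return Integer matrix of minor-allele counts in \{0,1,2\} (with `NA`
#'   where missing), same dimnames as `ancestry`.
#' @export
simulate_genotypes <- function(ancestry, map, seed = NULL, missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(colnames(ancestry) == map$marker_id))
    stop("ancestry columns must match the marker map")
  if (any(map$freq_afr < 0 | map$freq_afr > 1 |
          map$freq_eur < 0 | map$freq_eur > 1))
    stop("allele frequencies must lie in [0, 1]")
  n <- nrow(ancestry)
  geno <- matrix(0L, n, ncol(ancestry), dimnames = dimnames(ancestry))
  for (j in seq_len(ncol(ancestry))) {
    cnt <- ancestry[, j]
    geno[, j] <- stats::rbinom(n, cnt, map$freq_afr[j]) +
                 stats::rbinom(n, 2L - cnt, map$freq_eur[j])
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(length(geno)) < missing_rate, n)
    geno[miss] <- NA_integer_
  }
  geno
}

#' Simulate zero-inflated phenotypes (CAC-like scores)
#'
#' The latent trait is
#' `beta_age * (age - age_mean) + beta_sex_male * male +
#'  sum(beta_j * African-allele count at causal locus j) +
#'  polygenic family effect + residual`,
#' with the polygenic effect drawn multivariate normal with covariance
#' `sigma_poly^2 * 2 * kinship`. Observed CAC is 0 below a latent threshold
#' (placed at the `zero_rate` quantile of the latent trait) and a monotone
#' exponential transform of the latent excess above it, giving a
#' zero-inflated, right-skewed score. A negative causal `beta` encodes a
#' protective effect of African ancestry.
#'
#' @param ancestry African-allele count matrix for the phenotyped
#'   individuals.
#' @param pedigree Pedigree containing (at least) those individuals.
#' @param config A [sim_config()].
#' @param seed Optional seed (omit to use the current RNG state).
#' @return A `data.frame` with columns `individual_id`, `cac`, `age`, `sex`
#'   and attribute `latent` (the latent trait, for diagnostics).
#' @export
simulate_phenotypes <- function(ancestry, pedigree, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(ancestry)
  ped_idx <- match(ids, pedigree$individual_id)
  if (anyNA(ped_idx)) stop("ancestry rows missing from pedigree")
  n <- length(ids)

  age <- pmax(config$age_min,
              stats::rnorm(n, config$age_mean, config$age_sd))
  sex <- pedigree$sex[ped_idx]
  male <- as.numeric(sex == "male")

  genetic <- numeric(n)
  if (!is.null(config$causal_loci)) {
    for (r in seq_len(nrow(config$causal_loci))) {
      j <- config$causal_loci$marker[r]
      if (j < 1 || j > ncol(ancestry)) stop("causal marker index out of range")
      genetic <- genetic + config$causal_loci$beta[r] * ancestry[, j]
    }
  }

  phi <- kinship_from_pedigree(pedigree)
  K <- 2 * phi[ids, ids, drop = FALSE]
  L <- chol(K + diag(1e-8, n))
  poly <- drop(crossprod(L, stats::rnorm(n))) * config$sigma_poly

  latent <- config$beta_age * (age - config$age_mean) +
    config$beta_sex_male * male + genetic + poly +
    stats::rnorm(n, 0, config$sigma_env)

  thr <- stats::quantile(latent, config$zero_rate, names = FALSE)
  cac <- ifelse(latent <= thr, 0,
                config$cac_scale * expm1(config$cac_shape * (latent - thr)))

  structure(
    data.frame(individual_id = ids, cac = cac, age = age, sex = sex,
               stringsAsFactors = FALSE),
    latent = latent
  )
}

#' Simulate a complete synthetic admixed family cohort
#'
#' Composes the marker map, pedigree, ancestry tracks, genotypes and
#' phenotypes into one index-consistent cohort object, together with a truth
#' record (causal loci, true effects, realised per-individual global African
#' proportion) sufficient to score parameter recovery. Optionally injects
#' missing phenotypes and near-European individuals so the downstream sample
#' filters can be exercised.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `ancestry`,
#'   `genotypes`, `pedigree`, `phenotypes`, `map`, `truth`.
#' @examples
#' cfg <- sim_config(n_families = 20, n_chromosomes = 2,
#'                   n_markers_per_chrom = 25, seed = 7)
#' coh <- simulate_cohort(cfg)
#' dim(coh$ancestry)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim <- .sim_ancestry_internal(config)
  ped <- sim$pedigree
  sib_rows <- which(ped$role == "sib")
  sib_ids <- ped$individual_id[sib_rows]

  counts <- sim$hap1 + sim$hap2

  ## optional override: force a subset of sibs to near-zero African ancestry
  low_ids <- character(0)
  if (config$n_low_afr > 0) {
    if (config$n_low_afr > length(sib_ids))
      stop("n_low_afr exceeds the number of siblings")
    low_ids <- sample(sib_ids, config$n_low_afr)
    chrom_cols <- split(seq_len(nrow(sim$map)),
                        factor(sim$map$chrom, levels = unique(sim$map$chrom)))
    for (id in low_ids) {
      ## rejection-sample so the realised global proportion is genuinely
      ## below the 1% exclusion boundary (ancestry blocks are lumpy, so a
      ## single draw at low q can still overshoot)
      for (try in 1:100) {
        row <- unlist(lapply(chrom_cols, function(cols) {
          gpos <- sim$map$genetic_pos[cols]
          .sim_founder_haps(config$low_afr_q, gpos, config$g) +
            .sim_founder_haps(config$low_afr_q, gpos, config$g)
        }), use.names = FALSE)
        if (sum(row) / (2 * length(row)) < 0.01) break
        if (try == 100) row <- rep(0L, length(row))
      }
      counts[id, ] <- row
    }
  }

  keep_ids <- if (config$include_parents) ped$individual_id else sib_ids
  ancestry <- counts[keep_ids, , drop = FALSE]
  genotypes <- simulate_genotypes(ancestry, sim$map,
                                  missing_rate = config$missing_geno_rate)
  pheno <- simulate_phenotypes(ancestry[sib_ids, , drop = FALSE], ped, config)
  if (config$include_parents) {
    parents <- setdiff(keep_ids, sib_ids)
    pheno <- rbind(pheno,
                   data.frame(individual_id = parents, cac = NA_real_,
                              age = NA_real_,
                              sex = ped$sex[match(parents, ped$individual_id)],
                              stringsAsFactors = FALSE))
    pheno <- pheno[match(keep_ids, pheno$individual_id), ]
    rownames(pheno) <- NULL
  }

  ## optional missing-phenotype injection (disjoint from the low-ancestry set)
  if (config$n_missing_pheno > 0) {
    pool <- setdiff(sib_ids, low_ids)
    if (config$n_missing_pheno > length(pool))
      stop("n_missing_pheno exceeds the number of eligible siblings")
    miss_ids <- sample(pool, config$n_missing_pheno)
    pheno$cac[pheno$individual_id %in% miss_ids] <- NA_real_
  }

  truth <- list(
    causal_loci = config$causal_loci,
    q_true = rowSums(ancestry) / (2 * ncol(ancestry)),
    founder_q = sim$founder_q,
    low_afr_ids = low_ids
  )
  structure(list(ancestry = ancestry, genotypes = genotypes,
                 pedigree = ped, phenotypes = pheno, map = sim$map,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic admixed cohort\n")
  cat(sprintf("  individuals (analysis set): %d\n", nrow(x$ancestry)))
  cat(sprintf("  families: %d\n", length(unique(x$pedigree$family_id))))
  cat(sprintf("  markers: %d on %d chromosome(s)\n",
              nrow(x$map), length(unique(x$map$chrom))))
  cat(sprintf("  mean global African proportion: %.3f\n",
              mean(x$truth$q_true)))
  invisible(x)
}
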