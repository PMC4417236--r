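test_that("ancestry entries stay in {0,1,2} and are reproducible under a seed", {
  coh1 <- small_cohort(seed = 21)
  coh2 <- small_cohort(seed = 21)
  expect_true(all(coh1$ancestry %in% 0:2))
  expect_true(all(coh1$genotypes %in% c(0:2, NA)))
  expect_identical(coh1$ancestry, coh2$ancestry)
  expect_identical(coh1$genotypes, coh2$genotypes)
  expect_identical(coh1$phenotypes, coh2$phenotypes)
})

test_that("zero genetic distance gives zero ancestry switches", {
  cfg <- sim_config(n_families = 30, n_chromosomes = 1,
                    n_markers_per_chrom = 20, seed = 5)
  anc <- simulate_ancestry_tracks(cfg, map = zero_distance_map(20))
  ## every row constant across markers
  expect_true(all(apply(anc, 1, function(x) length(unique(x)) == 1)))
})

test_that("degenerate ancestry proportion q = 1 yields all-African haplotypes", {
  set.seed(1)
  gpos <- seq(0, 100, length.out = 50)
  H <- admixscan:::.sim_founder_haps(rep(1, 200), gpos, g = 6)
  expect_true(all(H == 1L))
  H0 <- admixscan:::.sim_founder_haps(rep(0, 200), gpos, g = 6)
  expect_true(all(H0 == 0L))
})

test_that("observed switch rate matches the closed form g*L*2q(1-q)", {
  set.seed(42)
  gpos <- seq(0, 100, length.out = 200)       # 1 Morgan, dense map
  H <- admixscan:::.sim_founder_haps(rep(0.5, 4000), gpos, g = 6)
  mean_switches <- mean(rowSums(abs(t(diff(t(H)))) > 0))
  expect_lt(abs(mean_switches - 3.0), 0.15)

  ## independent event-counting oracle: simulate the redraw process at the
  ## event level (exponential waiting times) and count realised switches
  oracle <- replicate(4000, {
    n_ev <- stats::rpois(1, 6)                # events on 1 Morgan at rate g
    if (n_ev == 0) return(0)
    states <- c(stats::rbinom(1, 1, 0.5), stats::rbinom(n_ev, 1, 0.5))
    sum(diff(states) != 0)
  })
  expect_lt(abs(mean(oracle) - 3.0), 0.15)
  expect_lt(abs(mean_switches - mean(oracle)), 0.2)
})

test_that("per-marker African proportion is stationary at the cohort mean q", {
  coh <- small_cohort(seed = 31, n_families = 80)
  qbar <- mean(coh$truth$q_true)
  per_marker <- colMeans(coh$ancestry) / 2
  n <- nrow(coh$ancestry)
  mc_se <- sqrt(qbar * (1 - qbar) / (2 * n)) +
    stats::sd(coh$truth$q_true) / sqrt(n)    # q varies between individuals
  expect_true(all(abs(per_marker - qbar) < 6 * mc_se))
  expect_lt(abs(mean(per_marker) - qbar), 3 * mc_se)
})

test_that("mean switch count increases with generations since admixture", {
  switches <- function(g, seed) {
    set.seed(seed)
    gpos <- seq(0, 100, length.out = 150)
    H <- admixscan:::.sim_founder_haps(rep(0.85, 800), gpos, g = g)
    mean(rowSums(abs(t(diff(t(H)))) > 0))
  }
  for (s in 1:3) expect_gt(switches(20, s), switches(6, s))
})

test_that("siblings share local ancestry more than unrelated pairs", {
  coh <- small_cohort(seed = 77, n_families = 60)
  ped <- coh$pedigree
  sibs <- ped[ped$role == "sib", ]
  fam <- split(sibs$individual_id, sibs$family_id)
  fam <- fam[lengths(fam) >= 2]
  ## constant rows (all-African individuals) yield NA correlations; drop them
  sib_cor <- mean(suppressWarnings(vapply(fam, function(ids) {
    stats::cor(coh$ancestry[ids[1], ], coh$ancestry[ids[2], ])
  }, numeric(1))), na.rm = TRUE)
  set.seed(1)
  unrel <- suppressWarnings(replicate(100, {
    f2 <- sample(names(fam), 2)
    stats::cor(coh$ancestry[fam[[f2[1]]][1], ], coh$ancestry[fam[[f2[2]]][1], ])
  }))
  expect_gt(sib_cor, mean(unrel, na.rm = TRUE) + 0.1)
})

test_that("genotype frequencies follow the ancestry-weighted mixture", {
  set.seed(9)
  n <- 5000
  anc <- matrix(stats::rbinom(n, 2, 0.85), ncol = 1,
                dimnames = list(paste0("i", 1:n), "chr1_m001"))
  map <- data.frame(marker_id = "chr1_m001", chrom = 1, bp_pos = 1,
                    genetic_pos = 0.0, freq_afr = 0.48, freq_eur = 0.28)
  g <- simulate_genotypes(anc, map, seed = 10)
  expect_lt(abs(mean(g) / 2 - (0.85 * 0.48 + 0.15 * 0.28)), 0.015)

  ## ancestry-determined alleles
  map2 <- within(map, {freq_afr <- 1; freq_eur <- 0})
  anc2 <- matrix(c(0L, 1L, 2L), ncol = 1,
                 dimnames = list(c("a", "b", "c"), "chr1_m001"))
  expect_equal(as.vector(simulate_genotypes(anc2, map2, seed = 1)),
               c(0L, 1L, 2L))
  map3 <- within(map, {freq_afr <- 1; freq_eur <- 1})
  expect_true(all(simulate_genotypes(anc2, map3, seed = 1) == 2L))
})

test_that("zero-inflation hits the configured zero rate", {
  coh <- small_cohort(seed = 13, n_families = 150, n_chrom = 1,
                      m_per_chrom = 20, zero_rate = 0.5)
  expect_lt(abs(mean(coh$phenotypes$cac == 0) - 0.5), 0.02)
  expect_true(all(coh$phenotypes$cac >= 0))
  ## right skew of the nonzero part
  pos <- coh$phenotypes$cac[coh$phenotypes$cac > 0]
  expect_gt(mean(pos), stats::median(pos))
})

test_that("deterministic limit: no effects and no noise give a constant score", {
  coh <- small_cohort(seed = 2, n_families = 20, n_chrom = 1,
                      m_per_chrom = 15, sigma_poly = 0, sigma_env = 0,
                      beta_age = 0, beta_sex_male = 0, zero_rate = 0)
  expect_true(length(unique(coh$phenotypes$cac)) == 1)
})

test_that("cohort structure matches the configured design", {
  cfg <- sim_config(n_families = 211, total_sibs = 622, n_chromosomes = 2,
                    n_markers_per_chrom = 15, seed = 4)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$ancestry), 622)
  expect_equal(length(unique(coh$pedigree$family_id)), 211)
  ## two founder parents per family, un-phenotyped and out of the matrices
  expect_equal(sum(coh$pedigree$role == "parent"), 2 * 211)
  expect_false(any(coh$pedigree$individual_id[coh$pedigree$role == "parent"]
                   %in% rownames(coh$ancestry)))
  ## mean global African proportion near the configured 0.85
  expect_lt(abs(mean(coh$truth$q_true) - 0.85), 3 * 0.075 / sqrt(211))
  ## index consistency
  expect_identical(rownames(coh$ancestry), rownames(coh$genotypes))
  expect_identical(colnames(coh$ancestry), coh$map$marker_id)
  expect_identical(coh$phenotypes$individual_id, rownames(coh$ancestry))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(g = 0), "g")
  expect_error(sim_config(q_mean = 1.2), "q_mean")
  expect_error(sim_config(q_sd = 0.5), "q_sd")
  expect_error(sim_config(causal_loci = data.frame(marker = 1e6, beta = 1)),
               "out of range")
  cfg <- sim_config(n_families = 5, n_chromosomes = 1,
                    n_markers_per_chrom = 10, seed = 1)
  bad_map <- zero_distance_map(10)
  bad_map$genetic_pos <- rev(bad_map$genetic_pos)
  expect_error(simulate_ancestry_tracks(cfg, map = bad_map),
               "strictly increasing")
})
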