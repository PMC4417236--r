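test_that("with an identity relatedness matrix the scan is exactly OLS", {
  set.seed(2)
  n <- 80
  ids <- paste0("i", 1:n)
  anc <- matrix(stats::rbinom(n * 5, 2, 0.85), n, 5,
                dimnames = list(ids, paste0("m", 1:5)))
  y <- stats::setNames(stats::rnorm(n), ids)
  phi <- diag(0.5, n); dimnames(phi) <- list(ids, ids)
  scan <- scan_local_ancestry(y, anc, phi)
  for (j in 1:5) {
    ols <- summary(stats::lm(y ~ anc[, j]))$coefficients
    expect_equal(scan$beta[j], ols[2, 1], tolerance = 1e-10)
    expect_equal(scan$se[j], ols[2, 2], tolerance = 1e-10)
  }
})

test_that("flipping the ancestry coding flips the effect sign exactly", {
  coh <- small_cohort(seed = 19, n_families = 30, n_chrom = 1,
                      m_per_chrom = 10)
  phe <- add_blom_score(coh$phenotypes)
  phi <- kinship_from_pedigree(coh$pedigree)
  ids <- rownames(coh$ancestry)
  s1 <- scan_local_ancestry(phe, coh$ancestry, phi[ids, ids])
  s2 <- scan_local_ancestry(phe, 2L - coh$ancestry, phi[ids, ids])
  expect_equal(s1$beta, -s2$beta, tolerance = 1e-10)
  expect_equal(s1$se, s2$se, tolerance = 1e-10)
  expect_equal(s1$p, s2$p, tolerance = 1e-10)
})

test_that("REML optimum is never worse than the no-polygenic-variance fit", {
  for (s in 1:4) {
    coh <- small_cohort(seed = 100 + s, n_families = 25, n_chrom = 1,
                        m_per_chrom = 10, sigma_poly = c(0, 0.8)[1 + s %% 2])
    phe <- add_blom_score(coh$phenotypes)
    ids <- phe$individual_id
    K <- 2 * kinship_from_pedigree(coh$pedigree)[ids, ids]
    fit <- fit_lmm_null(stats::setNames(phe$blom_score, ids), K)
    expect_gte(fit$loglik, fit$loglik_h0 - 1e-8)
    expect_true(fit$h2 >= 0 && fit$h2 < 1)
  }
})

test_that("null scan p-values are calibrated and uniform", {
  ## real family structure in the kinship matrix, permuted phenotype,
  ## independent ancestry columns: each marker is a true null test
  coh <- small_cohort(seed = 55, n_families = 100, n_chrom = 1,
                      m_per_chrom = 10)
  phe <- add_blom_score(coh$phenotypes)
  ids <- phe$individual_id
  n <- length(ids)
  set.seed(77)
  y <- stats::setNames(sample(phe$blom_score), ids)
  anc <- matrix(stats::rbinom(n * 1000, 2, 0.85), n, 1000,
                dimnames = list(ids, sprintf("s%04d", 1:1000)))
  phi <- kinship_from_pedigree(coh$pedigree)[ids, ids]
  scan <- scan_local_ancestry(y, anc, phi)
  frac <- mean(scan$p < 0.05, na.rm = TRUE)
  band <- 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), band)
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a protective African-ancestry effect is recovered with correct sign", {
  res <- vapply(1:10, function(s) {
    coh <- small_cohort(seed = 500 + s, n_families = 100, n_chrom = 1,
                        m_per_chrom = 20,
                        causal = data.frame(marker = 10, beta = -0.3))
    phe <- add_blom_score(coh$phenotypes)
    ids <- phe$individual_id
    phi <- kinship_from_pedigree(coh$pedigree)[ids, ids]
    sc <- scan_local_ancestry(phe, coh$ancestry[, 10, drop = FALSE], phi)
    c(sc$beta, sc$se)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - (-0.3)), 2 * mean(res[2, ]))
  expect_lt(mean(res[1, ]), 0)
})

test_that("constant ancestry columns are flagged, not fatal", {
  set.seed(4)
  n <- 40; ids <- paste0("i", 1:n)
  anc <- cbind(const = rep(2L, n),
               ok = stats::rbinom(n, 2, 0.8))
  rownames(anc) <- ids
  y <- stats::setNames(stats::rnorm(n), ids)
  phi <- diag(0.5, n); dimnames(phi) <- list(ids, ids)
  scan <- scan_local_ancestry(y, anc, phi)
  expect_true(is.na(scan$p[1]))
  expect_equal(scan$note[1], "constant_ancestry")
  expect_false(is.na(scan$p[2]))
})

test_that("global-ancestry test finds a simulated male-only effect", {
  hits <- vapply(1:5, function(s) {
    set.seed(900 + s)
    n <- 400
    ids <- paste0("i", 1:n)
    sex <- stats::setNames(rep(c("male", "female"), n / 2), ids)
    ganc <- stats::setNames(pmin(pmax(stats::rnorm(n, 0.85, 0.075),
                                      0.02), 0.999), ids)
    y <- stats::setNames(
      ifelse(sex == "male", 4, 0) * (ganc - 0.85) + stats::rnorm(n), ids)
    phi <- diag(0.5, n); dimnames(phi) <- list(ids, ids)
    res <- scan_global_ancestry(y, ganc, phi, by_sex = TRUE, sex = sex)
    c(male = res$p[res$stratum == "male"] < 0.05,
      female = res$p[res$stratum == "female"] > 0.001)
  }, logical(2))
  expect_gte(sum(hits["male", ]), 4)
  expect_gte(sum(hits["female", ]), 4)
})

test_that("by-sex off equals the joint fit and constants are flagged", {
  set.seed(12)
  n <- 60; ids <- paste0("i", 1:n)
  ganc <- stats::setNames(stats::runif(n, 0.6, 0.95), ids)
  y <- stats::setNames(stats::rnorm(n), ids)
  phi <- diag(0.5, n); dimnames(phi) <- list(ids, ids)
  joint <- scan_global_ancestry(y, ganc, phi)
  expect_equal(nrow(joint), 1)
  expect_equal(joint$stratum, "overall")
  const <- stats::setNames(rep(0.8, n), ids)
  expect_warning(res <- scan_global_ancestry(y, const, phi), "constant")
  expect_true(is.na(res$p[1]))
})

test_that("quartile ancestry test matches the pooled-t closed form", {
  set.seed(30)
  cac <- c(rep(0, 30), stats::rexp(70, 1 / 50))
  anc <- stats::rbinom(100, 2, 0.85)
  res <- quartile_ancestry_test(cac, anc)
  ## independent textbook oracle
  lo <- anc[cac == 0]                        # >25% zeros -> zero group
  hi <- anc[cac >= stats::quantile(cac, 0.75)]
  sp <- sqrt(((length(lo) - 1) * stats::var(lo) +
              (length(hi) - 1) * stats::var(hi)) /
             (length(lo) + length(hi) - 2))
  t_oracle <- (mean(lo) - mean(hi)) / (sp * sqrt(1 / length(lo) + 1 / length(hi)))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$prop_q1, mean(lo) / 2)

  ## identical ancestry distributions give t = 0, p = 1
  res0 <- quartile_ancestry_test(c(0, 0, 1, 1, 9, 9, 10, 10),
                                 c(1, 2, 1, 2, 1, 2, 1, 2))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(quartile_ancestry_test(rep(5, 10), stats::rbinom(10, 2, 0.5)),
               "degenerate")
})

test_that("protective effect shows more African ancestry in the low-CAC quartile", {
  coh <- small_cohort(seed = 61, n_families = 120, n_chrom = 1,
                      m_per_chrom = 15,
                      causal = data.frame(marker = 8, beta = -0.6))
  res <- quartile_ancestry_test(coh$phenotypes$cac, coh$ancestry[, 8])
  expect_gt(res$mean_q1, res$mean_q3)
})
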