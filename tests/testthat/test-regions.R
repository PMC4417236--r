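test_that("carry-forward returns one lead per envelope", {
  ## nothing below the cut
  expect_length(carry_forward(scan_from_profile(c(1, 2, 2.5, 1))), 0)

  ## four clear peaks on distinct chromosomes -> four leads
  peaks <- do.call(rbind, lapply(1:4, function(ch) {
    scan_from_profile(c(0.5, 1, 4 + ch / 10, 1, 0.5), chrom = ch)
  }))
  leads <- carry_forward(peaks)
  expect_length(leads, 4)
  expect_equal(sort(unique(peaks$chrom[match(leads, peaks$marker_id)])), 1:4)

  ## two sub-threshold markers inside one 2.0-drop envelope -> single lead
  one_env <- scan_from_profile(c(1, 4.0, 4.5, 1))
  leads2 <- carry_forward(one_env)
  expect_equal(leads2, one_env$marker_id[3])   # the smaller p wins
})

test_that("region delimitation follows the -log10(p) drop rule", {
  sc <- scan_from_profile(c(1.0, 3.5, 5.0, 3.2, 0.5))
  reg <- delimit_region(sc, sc$marker_id[3])
  expect_equal(reg$start_marker, sc$marker_id[2])
  expect_equal(reg$end_marker, sc$marker_id[4])
  expect_equal(reg$boundary_p_lower, sc$p[2])
  expect_equal(reg$boundary_p_upper, sc$p[4])
  expect_true(reg$start_bp <= sc$bp_pos[3] && sc$bp_pos[3] <= reg$end_bp)

  ## flat profile spans the whole chromosome, flagged
  flat <- scan_from_profile(rep(3, 6))
  regf <- delimit_region(flat, flat$marker_id[2])
  expect_true(regf$spans_chromosome)
})

test_that("walking delimitation equals the exhaustive-window oracle", {
  set.seed(50)
  for (i in 1:100) {
    logp <- stats::runif(30, 0, 6)
    lead <- which.max(logp)
    sc <- scan_from_profile(logp)
    reg <- delimit_region(sc, sc$marker_id[lead])
    oracle <- region_oracle(logp, lead)
    expect_equal(match(reg$start_marker, sc$marker_id), oracle[1])
    expect_equal(match(reg$end_marker, sc$marker_id), oracle[2])
  }
})

test_that("regions nest with the drop parameter and survive order reversal", {
  set.seed(51)
  logp <- stats::runif(40, 0, 6)
  lead <- which.max(logp)
  sc <- scan_from_profile(logp)
  r1 <- delimit_region(sc, sc$marker_id[lead], drop = 1)
  r2 <- delimit_region(sc, sc$marker_id[lead], drop = 2.5)
  expect_true(r2$start_bp <= r1$start_bp && r1$end_bp <= r2$end_bp)

  ## reversing coordinates relabels the same region
  rev_sc <- sc[nrow(sc):1, ]
  rev_sc$bp_pos <- sc$bp_pos                  # mirror the coordinates
  r3 <- delimit_region(rev_sc, sc$marker_id[lead], drop = 1)
  expect_setequal(r3$marker_ids, r1$marker_ids)
})

test_that("delta is the absolute ancestral frequency difference", {
  expect_equal(delta(0.48, 0.28), 0.20)
  expect_equal(delta(0.44, 0.85), 0.41)
  expect_equal(delta(0.3, 0.3), 0)
  expect_equal(delta(0.1, 0.9), delta(0.9, 0.1))   # symmetric
  expect_true(all(delta(stats::runif(50), stats::runif(50)) <= 1))
  expect_error(delta(1.2, 0.5), "frequencies")
})

test_that("informative-marker filter honours the strict cutoff", {
  sc <- scan_from_profile(c(2.5, 4, 2.5))
  reg <- delimit_region(sc, sc$marker_id[2])
  map <- data.frame(marker_id = sc$marker_id, chrom = 1, bp_pos = sc$bp_pos,
                    genetic_pos = 1:3,
                    freq_afr = c(0.48, 0.44, 0.50),
                    freq_eur = c(0.28, 0.85, 0.10))
  ## delta = 0.20, 0.41, 0.40; the boundary delta = 0.20 is NOT informative
  expect_setequal(informative_markers(reg, map), sc$marker_id[2:3])
  expect_setequal(informative_markers(reg, map, strict = FALSE),
                  sc$marker_id[1:3])
})

test_that("regional thresholds implement the two-stage Bonferroni correction", {
  expect_equal(regional_threshold(1, 1), 0.05)
  ## exact algebra: threshold * n * n_regions == alpha
  for (n in c(3, 17, 416, 1838)) {
    expect_equal(regional_threshold(n, 4) * n * 4, 0.05)
  }
  expect_error(regional_threshold(0), "informative")
})

test_that("candidate flagging separates drivers, suggestive SNPs and noise", {
  sc <- scan_from_profile(c(1, 4, 4.5, 4, 1))
  reg <- delimit_region(sc, sc$marker_id[3])
  reg$regional_threshold <- 1e-5
  ext <- data.frame(snp = paste0("rs", 1:4), chrom = 1,
                    bp = c(2.0e5, 2.5e5, 3.0e5, 3.9e5),
                    p = c(0.5, 5e-6, 8e-5, 0.2))
  out <- flag_candidates(reg, ext)
  expect_equal(out$snp, c("rs2", "rs3"))
  expect_equal(out$status, c("driver", "suggestive"))
  ## all-null externals flag nothing
  ext0 <- within(ext, p <- rep(0.5, 4))
  expect_equal(nrow(flag_candidates(reg, ext0)), 0)
  ## a SNP outside the region bounds is rejected with a message
  ext_bad <- rbind(ext, data.frame(snp = "rs_out", chrom = 1, bp = 9e9,
                                   p = 0.1))
  expect_error(flag_candidates(reg, ext_bad), "rs_out")
})

test_that("a simulated driver SNP is flagged in most replicates", {
  sc <- scan_from_profile(c(1, 4, 4.5, 4, 1))
  reg <- delimit_region(sc, sc$marker_id[3])
  reg$regional_threshold <- regional_threshold(100, 4)   # 1.25e-4
  set.seed(52)
  hit <- replicate(50, {
    z <- c(stats::rnorm(9), stats::rnorm(1, 5.8))        # last SNP causal
    ext <- data.frame(snp = sprintf("rs%02d", 1:10), chrom = 1,
                      bp = seq(reg$start_bp, reg$end_bp, length.out = 10),
                      p = 2 * stats::pnorm(-abs(z)))
    out <- flag_candidates(reg, ext)
    "rs10" %in% out$snp[out$status == "driver"]
  })
  expect_gt(mean(hit), 0.8)
})
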