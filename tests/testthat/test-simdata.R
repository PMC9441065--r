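test_that("Balding-Nichols draws collapse to ancestral frequency at F = 0 and keep fixed sites fixed", {
  model <- population_model(populations = c("a", "b"), fst = c(0, 0.2),
                            copy_rho = c(a = 1e-6, b = 1e-6),
                            n_sites = 5L)
  fr <- draw_population_frequencies(model, seed = 1L,
                                    ancestral = c(0.3, 0, 1, 0.5, 0.02))
  expect_identical(fr$freq[, "a"], c(0.3, 0, 1, 0.5, 0.02))
  expect_identical(fr$freq[c(2, 3), "b"], c(0, 1))
})

test_that("Balding-Nichols moments match the closed form at F = 0.2", {
  # Var = p (1 - p) F, mean = p; checked by simulation at p = 0.5
  model <- population_model(populations = "a", fst = 0.2,
                            copy_rho = c(a = 1e-6), n_sites = 100000L)
  fr <- draw_population_frequencies(model, seed = 42L,
                                    ancestral = rep(0.5, 100000L))
  expect_equal(mean(fr$freq[, 1]), 0.5, tolerance = 0.01)
  expect_equal(stats::var(fr$freq[, 1]), 0.05, tolerance = 0.02)
})

test_that("degenerate differentiation (F = 1) and bad models are rejected", {
  expect_error(population_model(fst = 1), "\\[0, 1\\)")
  expect_error(population_model(fst = -0.1), "\\[0, 1\\)")
  expect_error(population_model(n_sites = 1L), "at least 2")
  expect_error(population_model(copy_rho = c(taurine = 0, indicine = 1e-6)),
               "positive")
})

test_that("haplotype pools: no switching and no mutation yield exact copies of earlier haplotypes", {
  freqs <- rep(0.5, 50)
  pos <- seq_len(50) * 1000L
  H <- simulate_haplotypes(freqs, n_haps = 12L, pos = pos,
                           copy_rho = 1e-300, mut_eps = 0,
                           n_founders = 4L, seed = 3L)
  for (j in 5:12) {
    matches <- apply(H[seq_len(j - 1), , drop = FALSE], 1,
                     function(r) all(r == H[j, ]))
    expect_true(any(matches))
  }
  expect_error(simulate_haplotypes(freqs, 1L, pos, 1e-6), "at least 2")
})

test_that("haplotype simulation is bit-identical under a fixed seed", {
  freqs <- runif(200, 0.1, 0.9)
  pos <- sort(sample.int(1e6, 200))
  a <- simulate_haplotypes(freqs, 30L, pos, copy_rho = 1e-6, seed = 9L)
  b <- simulate_haplotypes(freqs, 30L, pos, copy_rho = 1e-6, seed = 9L)
  expect_identical(a, b)
})

test_that("infinite switch rate drives inter-site r2 to the permuted-site baseline", {
  # mean r2 over seeds under copy_rho -> Inf vs the same panels with
  # site-decoupled (permuted) haplotype columns
  set.seed(1)
  r2_high <- numeric(0); r2_perm <- numeric(0)
  for (s in 1:25) {
    freqs <- rep(0.5, 40)
    pos <- seq_len(40) * 100L
    H <- simulate_haplotypes(freqs, 30L, pos, copy_rho = 10,
                             mut_eps = 0, n_founders = 10L, seed = s)
    cc <- suppressWarnings(cor(H))^2
    r2_high <- c(r2_high, cc[upper.tri(cc)])
    Hp <- apply(H, 2, sample)
    cp <- suppressWarnings(cor(Hp))^2
    r2_perm <- c(r2_perm, cp[upper.tri(cp)])
  }
  expect_equal(mean(r2_high, na.rm = TRUE), mean(r2_perm, na.rm = TRUE),
               tolerance = 0.01)
})

test_that("cohort genotypes are the site-wise sum of the two truth haplotypes", {
  model <- population_model(n_sites = 300L, chrom_length_bp = 1e6)
  sim <- simulate_pools(model, n_pool_haps = 20L, seed = 2L)
  coh <- simulate_cohort(model, sim$pools,
    spec = list(list(name = "mix", n = 6,
                     alpha = c(taurine = 0.5, indicine = 0.5))),
    seed = 4L)
  expect_identical(collapse_haplotypes(coh$truth)$geno, coh$genotypes$geno)
  expect_equal(nrow(coh$truth$haps), 2L * length(coh$truth$sample_ids))
  expect_identical(coh$observed$haps, coh$truth$haps)  # error_rate 0
})

test_that("pure admixture vectors copy exclusively from their own population pool", {
  # pool 'a' carries only allele 0, pool 'b' only allele 1; with no copying
  # mutation an alpha = (1, 0) cohort must be all-zero
  model <- population_model(populations = c("a", "b"), fst = c(0, 0),
                            copy_rho = c(a = 1e-6, b = 1e-6), mut_eps = 0,
                            n_sites = 100L, chrom_length_bp = 1e6)
  sim <- simulate_pools(model, n_pool_haps = 10L, seed = 5L)
  sim$pools$a$haps[] <- 0L
  sim$pools$b$haps[] <- 1L
  coh <- simulate_cohort(model, sim$pools,
    spec = list(list(name = "pure_a", n = 4, alpha = c(a = 1, b = 0))),
    seed = 6L)
  expect_true(all(coh$truth$haps == 0L))
})

test_that("two pure cohorts at F = 0.2 give a Hudson FST estimate near 0.2", {
  fst_hat <- numeric(3)
  for (s in 1:3) {
    model <- population_model(fst = 0.2, n_sites = 4000L,
                              chrom_length_bp = 5e6, n_founders = 100L)
    sim <- simulate_pools(model, n_pool_haps = 200L,
                          seed = herdimpute:::derive_seed(s, 21L))
    fst_hat[s] <- oracle_hudson_fst(sim$pools$taurine$haps,
                                    sim$pools$indicine$haps)
  }
  expect_equal(mean(fst_hat), 0.2, tolerance = 0.05)
})

test_that("exchangeable populations (F = 0) give FST estimates near zero", {
  fst_hat <- numeric(3)
  for (s in 1:3) {
    model <- population_model(fst = 0, n_sites = 3000L,
                              chrom_length_bp = 5e6, n_founders = 100L)
    sim <- simulate_pools(model, n_pool_haps = 200L,
                          seed = herdimpute:::derive_seed(s, 22L))
    fst_hat[s] <- oracle_hudson_fst(sim$pools$taurine$haps,
                                    sim$pools$indicine$haps)
  }
  expect_lt(abs(mean(fst_hat)), 0.02)
})

test_that("requested genotype missingness lands within binomial bounds", {
  model <- population_model(n_sites = 1000L, chrom_length_bp = 2e6)
  sim <- simulate_pools(model, n_pool_haps = 20L, seed = 7L)
  coh <- simulate_cohort(model, sim$pools,
    spec = list(list(name = "c", n = 10,
                     alpha = c(taurine = 1, indicine = 0))),
    missing_rate = 0.05, seed = 8L)
  n_calls <- length(coh$genotypes$geno)  # 10,000 calls
  frac <- mean(is.na(coh$genotypes$geno))
  half_width <- 2.58 * sqrt(0.05 * 0.95 / n_calls)
  expect_gt(frac, 0.05 - half_width)
  expect_lt(frac, 0.05 + half_width)
})

test_that("array schemes honour their site-eligibility postconditions", {
  model <- population_model(n_sites = 600L, chrom_length_bp = 3e6)
  sim <- simulate_pools(model, n_pool_haps = 40L, seed = 11L)
  coh <- simulate_cohort(model, sim$pools,
    spec = list(list(name = "taurine", n = 10,
                     alpha = c(taurine = 1, indicine = 0)),
                list(name = "indicine", n = 10,
                     alpha = c(taurine = 0, indicine = 1))),
    impact_spec = c(HIGH = 0.02, MODERATE = 0.05, LOW = 0.1), seed = 12L)
  n_poly <- sum(site_maf(coh$truth) > 0)
  full <- design_array(coh, "random", size = n_poly, seed = 1L)
  expect_equal(nrow(full), n_poly)
  expect_setequal(full$pos, coh$sites$pos[site_maf(coh$truth) > 0])

  uc <- design_array(coh, "uniform-common", size = 80,
                     discovery = "taurine", maf_threshold = 0.05, seed = 1L)
  disc <- subset_panel(coh$truth, "taurine")
  man_idx <- intersect_sites(coh$sites, uc)$idx_a
  expect_true(all(site_maf(disc)[man_idx] >= 0.05))

  fe <- design_array(coh, "functional-enriched", size = 60, seed = 1L)
  expect_equal(nrow(fe), 60)
  expect_error(design_array(coh, "random", size = n_poly + 1, seed = 1L),
               "exceeds eligible")
})

test_that("ascertainment bias: discovery-population MAF exceeds diverged-population MAF on the array", {
  lower_in_b <- 0
  for (s in 1:10) {
    model <- population_model(n_sites = 500L, chrom_length_bp = 3e6)
    sim <- simulate_pools(model, n_pool_haps = 40L,
                          seed = herdimpute:::derive_seed(s, 31L))
    coh <- simulate_cohort(model, sim$pools,
      spec = list(list(name = "taurine", n = 12,
                       alpha = c(taurine = 1, indicine = 0)),
                  list(name = "indicine", n = 12,
                       alpha = c(taurine = 0, indicine = 1))),
      seed = herdimpute:::derive_seed(s, 32L))
    man <- design_array(coh, "uniform-common", size = 60,
                        discovery = "taurine", seed = 1L)
    idx <- intersect_sites(coh$sites, man)$idx_a
    maf_a <- mean(site_maf(subset_panel(coh$truth, "taurine"))[idx])
    maf_b <- mean(site_maf(subset_panel(coh$truth, "indicine"))[idx])
    if (maf_b < maf_a) lower_in_b <- lower_in_b + 1
  }
  expect_gte(lower_in_b, 9)
})

test_that("impact annotation proportions and rare skew behave as specified", {
  sites <- variant_table("1", seq_len(10000L) * 100L)
  maf <- runif(10000, 0.005, 0.5)
  none <- annotate_impacts(sites, maf, c(HIGH = 0, MODERATE = 0, LOW = 0),
                           seed = 1L)
  expect_true(all(none == "NONE"))
  lab <- annotate_impacts(sites, maf, c(HIGH = 0.01), seed = 2L)
  n_high <- sum(lab == "HIGH")
  half_width <- 2.58 * sqrt(10000 * 0.01 * 0.99)
  expect_gt(n_high, 100 - half_width)
  expect_lt(n_high, 100 + half_width)
  expect_error(annotate_impacts(sites, maf, c(HIGH = -0.1), seed = 1L),
               "negative")
  # rare skew: HIGH median MAF below NONE median MAF across seeds
  med_high <- med_none <- numeric(5)
  for (s in 1:5) {
    l <- annotate_impacts(sites, maf, c(HIGH = 0.02, MODERATE = 0.05),
                          seed = s)
    med_high[s] <- median(maf[l == "HIGH"])
    med_none[s] <- median(maf[l == "NONE"])
  }
  expect_true(all(med_high < med_none))
})
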