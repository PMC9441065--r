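test_that("a single-template chain copies the reference haplotype everywhere", {
  H <- matrix(c(1L, 0L, 1L, 1L, 0L), nrow = 1)
  ref <- make_panel(rbind(H, H), pos = c(1L, 50L, 200L, 900L, 4000L))
  ref1 <- subset_sites(ref, 1:5)
  ref1$haps <- ref1$haps[1, , drop = FALSE]  # K = 1
  out <- impute_haplotype(c(1L), typed_idx = 1L, ref1,
                          ls_params(eps = 0.4, rho_scale = 1))
  expect_equal(out$allele_post, as.numeric(H[1, ]))
})

test_that("posteriors match exhaustive path enumeration on toy instances", {
  set.seed(70)
  p <- ls_params(eps = 0.05, rho_scale = 2e-4)
  H <- rbind(c(1L, 0L, 1L), c(0L, 1L, 1L))
  pos <- c(100L, 2000L, 7000L)
  obs <- c(1L, NA, 0L)
  ref <- make_panel(H, pos = pos)
  got <- impute_haplotype(obs[!is.na(obs)], which(!is.na(obs)), ref, p)
  want <- oracle_ls_allele_post(obs, H, pos, p)
  expect_equal(got$allele_post, want, tolerance = 1e-12)
})

test_that("a target present in the panel is recovered with high confidence", {
  set.seed(71)
  K <- 10L; m <- 40L
  H <- matrix(rbinom(K * m, 1, 0.5), nrow = K)
  pos <- sort(sample.int(1e6, m))
  ref <- make_panel(H, pos = pos)
  typed <- seq(1, m, by = 2)
  out <- impute_haplotype(H[3, typed], typed, ref,
                          ls_params(eps = 1e-6, rho_scale = 4e-6))
  untyped <- setdiff(seq_len(m), typed)
  agree <- abs(out$allele_post[untyped] - H[3, untyped])
  expect_true(all(agree < 0.01 | vapply(untyped, function(t)
    any(H[-3, t] != H[3, t]) == FALSE, logical(1))))
  expect_true(mean(abs(out$allele_post[untyped] - H[3, untyped]) < 0.01)
              > 0.95)
})

test_that("leave-one-out posterior equals the naive masked re-run exactly", {
  set.seed(72)
  K <- 6L; m <- 25L
  H <- matrix(rbinom(K * m, 1, 0.5), nrow = K)
  pos <- sort(sample.int(2e5, m))
  ref <- make_panel(H, pos = pos)
  typed <- sort(sample.int(m, 10))
  obs <- as.integer(rbinom(length(typed), 1, 0.5))
  p <- ls_params(eps = 0.02, rho_scale = 1e-4)
  fast <- impute_haplotype(obs, typed, ref, p)
  for (j in seq_along(typed)) {
    naive <- impute_haplotype(obs[-j], typed[-j], ref, p)
    expect_equal(fast$loo_post[j], naive$allele_post[typed[j]],
                 tolerance = 1e-12)
  }
})

test_that("posteriors stay normalized and dosages bounded in [0, 2]", {
  set.seed(73)
  K <- 20L; m <- 60L
  H <- matrix(rbinom(K * m, 1, runif(m)[rep(1:m, each = K)]), nrow = K)
  pos <- sort(sample.int(1e6, m))
  ref <- haplotype_panel(variant_table("1", pos), H)
  targets <- make_panel(H[1:4, , drop = FALSE], pos = pos)
  typed <- sort(sample.int(m, 20))
  res <- impute_cohort(subset_sites(targets, typed), ref, ls_params())
  expect_lt(res$max_norm_dev, 1e-9)
  expect_true(all(res$dosage >= 0 & res$dosage <= 2))
  expect_true(all(res$loo_dosage >= 0 & res$loo_dosage <= 2))
})

test_that("emission noise at 0.5 pushes dosages to the panel-frequency prior", {
  set.seed(74)
  K <- 30L; m <- 30L
  p_site <- runif(m, 0.2, 0.8)
  H <- matrix(rbinom(K * m, 1, p_site[rep(1:m, each = K)]), nrow = K)
  ref <- make_panel(H)
  targets <- make_panel(H[1:2, ])
  res <- impute_cohort(targets, ref, ls_params(eps = 0.4999))
  expect_equal(res$dosage[1, ], 2 * colMeans(H), tolerance = 0.01)
})

test_that("self-imputation with the truth in the panel recovers the truth", {
  sl <- study_slice(101)
  typed <- seq(1L, nrow(sl$ref$truth$sites), by = 5L)
  targets <- subset_sites(sl$ref$truth, typed)
  targets <- subset_samples(targets, 1:4)
  res <- impute_cohort(targets, sl$ref$truth, ls_params(eps = 1e-6))
  truth <- subset_samples(collapse_haplotypes(sl$ref$truth), 1:4)
  expect_equal(max(abs(res$dosage - truth$geno)), 0, tolerance = 0.01)
})

test_that("accuracy metrics follow their definitions and exclusions", {
  set.seed(75)
  m <- 6L; n <- 8L
  truth <- matrix(rbinom(n * m, 2, 0.5), n, m)
  truth[, 3] <- 1L  # monomorphic: undefined accuracy
  sites <- variant_table("1", seq_len(m) * 100L)
  res <- structure(list(
    sites = sites, dosage = truth + 0.0,
    loo_dosage = truth[, c(1, 2), drop = FALSE] + 0.0,
    typed_idx = c(1L, 2L), sample_ids = sprintf("S%d", 1:n)),
    class = "imputation_result")
  gm <- genotype_matrix(sites, truth)
  acc <- imputation_accuracy(res, gm)
  expect_equal(acc$er2[1:2], c(1, 1))
  expect_true(is.na(acc$dosage_r2[3]))
  expect_true(all(is.na(acc$er2[3:6])))
  expect_equal(acc$accuracy[4], 1)
})

test_that("null dosages give mean ER2 near 1/(n-1)", {
  set.seed(76)
  m <- 1000L; n <- 50L
  truth <- matrix(rbinom(n * m, 2L, 0.4), n, m)
  sites <- variant_table("1", seq_len(m) * 10L)
  res <- structure(list(
    sites = sites, dosage = matrix(runif(n * m, 0, 2), n, m),
    loo_dosage = matrix(runif(n * m, 0, 2), n, m),
    typed_idx = seq_len(m), sample_ids = sprintf("S%d", 1:n)),
    class = "imputation_result")
  acc <- imputation_accuracy(res, genotype_matrix(sites, truth))
  expect_equal(mean(acc$er2, na.rm = TRUE), 1 / (n - 1), tolerance = 0.3)
})

test_that("dosage R2 rises with reference panel size", {
  set.seed(77)
  means <- numeric(0)
  for (K_sam in c(5L, 20L, 60L)) {
    vals <- numeric(3)
    for (s in 1:3) {
      model <- population_model(n_sites = 600L, chrom_length_bp = 2e6)
      sim <- simulate_pools(model, n_pool_haps = 70L,
                            seed = herdimpute:::derive_seed(s, 80L))
      ref <- simulate_cohort(model, sim$pools,
        spec = list(list(name = "taurine", n = K_sam,
                         alpha = c(taurine = 1, indicine = 0))),
        seed = herdimpute:::derive_seed(s, 81L + K_sam))
      tgt <- simulate_cohort(model, sim$pools,
        spec = list(list(name = "taurine", n = 4,
                         alpha = c(taurine = 1, indicine = 0))),
        seed = herdimpute:::derive_seed(s, 82L))
      typed <- sort(sample.int(600L, 60L))
      res <- impute_cohort(subset_sites(tgt$truth, typed), ref$truth,
                           ls_params())
      acc <- imputation_accuracy(res, collapse_haplotypes(tgt$truth))
      vals[s] <- mean(acc$dosage_r2, na.rm = TRUE)
    }
    means <- c(means, mean(vals))
  }
  expect_true(all(diff(means) > 0))
})

test_that("two-step with identical grids and panels reduces to one-step", {
  set.seed(78)
  K <- 12L; m <- 40L
  H <- matrix(rbinom(K * m, 1, 0.5), nrow = K)
  pos <- sort(sample.int(5e5, m))
  ref <- make_panel(H, pos = pos)
  typed <- sort(sample.int(m, 15))
  tgt <- make_panel(matrix(rbinom(2 * length(typed), 1, 0.5), nrow = 2),
                    pos = pos[typed])
  tgt$sample_ids <- "T1"  # distinct from the panel's ids
  p <- ls_params(eps = 1e-6)
  one <- impute_cohort(tgt, ref, p)
  two <- two_step_impute(tgt, subset_sites(ref, typed), ref, p)
  expect_equal(two$dosage, one$dosage, tolerance = 1e-9)
})

test_that("target samples present in the intermediate panel are removed from it", {
  sl <- study_slice(102)
  sparse <- subset_sites(sl$ref$truth, sl$sparse_idx)
  sparse <- subset_samples(sparse, 1:2)      # ids overlap the reference
  dense <- subset_sites(sl$ref$truth, sl$dense_idx)
  expect_message(
    two_step_impute(sparse, dense, sl$ref$truth, ls_params()),
    "removing 2 target sample")
})

test_that("degenerate target inputs are rejected or warned", {
  H <- matrix(rbinom(8 * 10, 1, 0.5), nrow = 8)
  ref <- make_panel(H)
  bad <- make_panel(matrix(rbinom(2 * 3, 1, 0.5), nrow = 2),
                    pos = c(55L, 155L, 255L))  # positions not in ref
  expect_error(impute_cohort(bad, ref, ls_params()), "absent from the reference")
  expect_warning(impute_haplotype(integer(0), integer(0), ref, ls_params()),
                 "zero sites")
})
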