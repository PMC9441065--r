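# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written from the definitions (enumeration, brute
# force) and never call the code paths they check.

# --- Li-Stephens posterior by exhaustive path enumeration -------------------
# Enumerates all K^m template paths; prior = uniform start x product of
# transition factors ((1-s) + s/K to stay, s/K to move); likelihood =
# product of emissions at observed sites. Allele posterior at each site is
# the weight of paths whose template carries allele 1 there.
oracle_ls_allele_post <- function(obs, H, pos, params) {
  K <- nrow(H); m <- ncol(H)
  s <- pmax(1 - exp(-params$rho_scale * diff(pos) / K), params$min_switch)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
  w <- rep(1 / K, nrow(paths))
  if (m > 1) {
    for (t in 2:m) {
      same <- paths[, t] == paths[, t - 1]
      w <- w * ifelse(same, (1 - s[t - 1]) + s[t - 1] / K, s[t - 1] / K)
    }
  }
  for (t in seq_len(m)) {
    if (!is.na(obs[t])) {
      match <- H[cbind(paths[, t], t)] == obs[t]
      w <- w * ifelse(match, 1 - params$eps, params$eps)
    }
  }
  w <- w / sum(w)
  vapply(seq_len(m), function(t) {
    sum(w * H[cbind(paths[, t], t)])
  }, numeric(1))
}

# --- brute-force allele-pair classifier -------------------------------------
# Written as explicit set logic, independent of classify_pair's structure.
oracle_classify <- function(q_ref, q_alt, r_ref, r_alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  if (is.na(q_ref) || is.na(q_alt) || !(q_ref %in% bases) ||
      !(q_alt %in% bases) || q_ref == q_alt)
    return("NONBIALLELIC_DISCARDED")
  pair_sorted <- paste(sort(c(q_ref, q_alt)), collapse = "")
  if (pair_sorted %in% c("AT", "CG")) return("AMBIGUOUS_DISCARDED")
  if (is.na(r_ref) || is.na(r_alt)) return("ABSENT_DISCARDED")
  cand <- list(OK = c(q_ref, q_alt),
               SWAPPED = c(q_alt, q_ref),
               STRAND_FLIP = unname(comp[c(q_ref, q_alt)]),
               SWAPPED_AND_FLIP = unname(comp[c(q_alt, q_ref)]))
  for (nm in names(cand)) {
    if (identical(cand[[nm]], c(r_ref, r_alt))) return(nm)
  }
  "NONBIALLELIC_DISCARDED"
}

# --- Hudson-type FST from two haplotype pools -------------------------------
oracle_hudson_fst <- function(h1, h2) {
  p1 <- colMeans(h1); p2 <- colMeans(h2)
  n1 <- nrow(h1); n2 <- nrow(h2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

# --- quick builders ---------------------------------------------------------
# panel from a haplotype matrix (rows = haplotypes) at given positions
make_panel <- function(haps, pos = NULL, chrom = "1", ref = "A", alt = "G") {
  haps <- as.matrix(haps)
  m <- ncol(haps)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  sites <- variant_table(chrom, pos, ref = rep_len(ref, m),
                         alt = rep_len(alt, m))
  haplotype_panel(sites, haps)
}

# bare reference (sites + haplotype rows) for HMM tests with odd K
make_ref <- function(haps, pos = NULL, chrom = "1") {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (is.null(pos)) pos <- seq_len(ncol(haps)) * 1000L
  list(sites = variant_table(chrom, pos, ref = "A", alt = "G"), haps = haps)
}

make_gm <- function(geno, pos = NULL, qual = NA_real_, gq = NULL,
                    groups = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  sites <- variant_table("1", pos, ref = rep_len("A", m),
                         alt = rep_len("G", m), qual = qual)
  genotype_matrix(sites, geno, gq = gq, groups = groups)
}

# --- shared study slices ----------------------------------------------------
# One seeded realization of the desk-scale imputation study: diverged
# reference cohort, admixed targets, random dense and nested sparse arrays.
# Memoised so composition and two-step properties reuse the same cohorts.
.slice_cache <- new.env(parent = emptyenv())

study_slice <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.slice_cache[[key]])) return(.slice_cache[[key]])
  model <- population_model(n_sites = 1500L, chrom_length_bp = 5e6)
  ds <- function(stream) herdimpute:::derive_seed(seed, stream)
  sim <- simulate_pools(model, n_pool_haps = 60L, seed = ds(1L))
  ref <- simulate_cohort(model, sim$pools,
    spec = list(list(name = "taurine", n = 30,
                     alpha = c(taurine = 1, indicine = 0)),
                list(name = "indicine", n = 30,
                     alpha = c(taurine = 0, indicine = 1))),
    seed = ds(2L))
  tgt <- simulate_cohort(model, sim$pools,
    spec = list(list(name = "admixed", n = 8,
                     alpha = c(taurine = 0.5, indicine = 0.5))),
    seed = ds(3L))
  man <- design_array(tgt, "random", size = 150, seed = ds(4L))
  man_dense <- design_array(tgt, "random", size = 300, seed = ds(5L))
  dense_idx <- intersect_sites(ref$truth$sites, man_dense)$idx_a
  sparse_idx <- sort(withr::with_seed(ds(6L), sample(dense_idx, 30)))
  out <- list(model = model, sim = sim, ref = ref, tgt = tgt,
              manifest = man, dense_idx = dense_idx,
              sparse_idx = sparse_idx,
              truth = collapse_haplotypes(tgt$truth))
  .slice_cache[[key]] <- out
  out
}

# Larger slice for accuracy-by-MAF / impact-class experiments: targets typed
# from observed haplotypes (1% allele-flip error), random 500-site array.
maf_slice <- function(seed) {
  key <- paste0("m", seed)
  if (!is.null(.slice_cache[[key]])) return(.slice_cache[[key]])
  model <- population_model(n_sites = 2500L, chrom_length_bp = 8e6)
  ds <- function(stream) herdimpute:::derive_seed(seed, stream)
  sim <- simulate_pools(model, n_pool_haps = 80L, seed = ds(11L))
  ref <- simulate_cohort(model, sim$pools,
    spec = list(list(name = "taurine", n = 25,
                     alpha = c(taurine = 1, indicine = 0)),
                list(name = "indicine", n = 25,
                     alpha = c(taurine = 0, indicine = 1))),
    seed = ds(12L))
  tgt <- simulate_cohort(model, sim$pools,
    spec = list(list(name = "taurine", n = 9,
                     alpha = c(taurine = 1, indicine = 0)),
                list(name = "indicine", n = 9,
                     alpha = c(taurine = 0, indicine = 1)),
                list(name = "admixed", n = 7,
                     alpha = c(taurine = 0.5, indicine = 0.5))),
    error_rate = 0.01,
    impact_spec = c(HIGH = 0.02, MODERATE = 0.04, LOW = 0.1),
    seed = ds(13L))
  man <- design_array(tgt, "random", size = 500, seed = ds(14L))
  arr <- intersect_sites(ref$truth$sites, man)$idx_a
  targets <- subset_sites(tgt$observed, arr)
  res <- impute_cohort(targets, ref$truth, ls_params(eps = 0.01))
  acc <- imputation_accuracy(res, collapse_haplotypes(tgt$truth),
                             maf = site_maf(ref$truth), impact = tgt$impact)
  out <- list(acc = acc)
  .slice_cache[[key]] <- out
  out
}

# Spearman rank correlation of bin means against bin order
bin_trend <- function(values, bins) {
  bm <- tapply(values, bins, mean, na.rm = TRUE)
  ok <- !is.na(bm)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(seq_along(bm)[ok], bm[ok], method = "spearman")
}
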