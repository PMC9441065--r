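#' Population structure model for synthetic cohorts
#'
#' Describes the demographic scenario the simulator emulates: a set of
#' ancestral populations differentiated from a shared ancestral pool
#' (Balding-Nichols model, per-population F), per-population
#' haplotype-copying switch rates that set the LD-decay scale, a copying
#' mutation probability, and the chromosome layout. Pairwise differentiation
#' between populations i and j is approximately (F_i + F_j) / 2 under this
#' parameterization.
#'
#' @param populations character labels of the ancestral populations.
#' @param fst per-population differentiation from the ancestral pool, each
#'   in [0, 1). Named by population (recycled if scalar).
#' @param ancestral_freq_range range of the Uniform ancestral allele
#'   frequency distribution.
#' @param copy_rho per-bp template-switch rate of the haplotype-copying
#'   process, named by population. Lower values give longer shared segments
#'   and slower LD decay (taurine-like); higher values give faster decay
#'   (indicine-like).
#' @param mut_eps per-site copying mutation (allele flip) probability.
#' @param n_founders number of independent founder haplotypes seeding each
#'   population pool; controls the magnitude of background LD (small pool =
#'   strong LD, analogous to a small effective population size).
#' @param chrom_length_bp chromosome length in base pairs.
#' @param n_sites number of segregating sites to simulate.
#' @param chrom chromosome label.
#' @param seed default master seed carried with the model.
#' @return a validated \code{population_model} list.
#' @export
population_model <- function(populations = c("taurine", "indicine"),
                             fst = 0.2,
                             ancestral_freq_range = c(0.02, 0.98),
                             copy_rho = c(taurine = 1e-6, indicine = 4e-6),
                             mut_eps = 1e-3,
                             n_founders = 32L,
                             chrom_length_bp = 1e7,
                             n_sites = 20000L,
                             chrom = "1",
                             seed = 1L) {
  fst <- rep_len(fst, length(populations))
  names(fst) <- populations
  if (any(fst < 0 | fst >= 1))
    stop("fst values must lie in [0, 1); F = 1 is a degenerate Beta")
  if (is.null(names(copy_rho))) names(copy_rho) <- rep_len(populations, length(copy_rho))
  copy_rho <- copy_rho[populations]
  if (any(is.na(copy_rho)) || any(copy_rho <= 0))
    stop("copy_rho must be positive and named for every population")
  if (n_sites < 2) stop("n_sites must be at least 2")
  if (mut_eps < 0 || mut_eps >= 0.5) stop("mut_eps must be in [0, 0.5)")
  stopifnot(length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] >= 0, ancestral_freq_range[2] <= 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  structure(list(populations = populations, fst = fst,
                 ancestral_freq_range = ancestral_freq_range,
                 copy_rho = copy_rho, mut_eps = mut_eps,
                 n_founders = as.integer(n_founders),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 n_sites = as.integer(n_sites), chrom = as.character(chrom),
                 seed = as.integer(seed)),
            class = "population_model")
}

#' Cohort composition for the default study scenario
#'
#' Two ancestral populations at F = 0.2 and three cohorts: pure taurine,
#' pure indicine, and a 50:50 admixture, over one 10-Mb chromosome with
#' 20,000 sites; 100 reference and 50 target samples.
#'
#' @param n_sites,chrom_length_bp override the default chromosome layout.
#' @return list with elements \code{model}, \code{reference_spec} and
#'   \code{target_spec} (cohort specifications for
#'   \code{\link{simulate_cohort}}).
#' @export
default_scenario <- function(n_sites = 20000L, chrom_length_bp = 1e7) {
  model <- population_model(n_sites = n_sites,
                            chrom_length_bp = chrom_length_bp)
  ref <- list(
    list(name = "taurine", n = 50L, alpha = c(taurine = 1, indicine = 0)),
    list(name = "indicine", n = 50L, alpha = c(taurine = 0, indicine = 1))
  )
  tgt <- list(
    list(name = "taurine", n = 17L, alpha = c(taurine = 1, indicine = 0)),
    list(name = "indicine", n = 17L, alpha = c(taurine = 0, indicine = 1)),
    list(name = "admixed", n = 16L, alpha = c(taurine = 0.5, indicine = 0.5))
  )
  list(model = model, reference_spec = ref, target_spec = tgt)
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' Each site's ancestral frequency p is drawn Uniform on the model's range;
#' each population's frequency is then Beta(p (1 - F) / F, (1 - p)(1 - F) / F)
#' with that population's F. F = 0 collapses to the ancestral frequency
#' exactly; fixed ancestral sites (p = 0 or 1) stay fixed in every
#' population.
#'
#' @param model a \code{\link{population_model}}.
#' @param seed RNG seed (defaults to the model's).
#' @param ancestral optional vector of ancestral frequencies to use instead
#'   of drawing them.
#' @return list with \code{ancestral} (length n_sites) and \code{freq}
#'   (n_sites x n_populations matrix).
#' @export
draw_population_frequencies <- function(model, seed = model$seed,
                                        ancestral = NULL) {
  withr::with_seed(seed, {
    m <- model$n_sites
    if (is.null(ancestral)) {
      r <- model$ancestral_freq_range
      ancestral <- stats::runif(m, r[1], r[2])
    } else {
      stopifnot(length(ancestral) == m, all(ancestral >= 0 & ancestral <= 1))
    }
    freq <- matrix(NA_real_, m, length(model$populations),
                   dimnames = list(NULL, model$populations))
    for (k in seq_along(model$populations)) {
      f <- model$fst[k]
      if (f == 0) {
        freq[, k] <- ancestral
      } else {
        scale <- (1 - f) / f
        freq[, k] <- stats::rbeta(m, ancestral * scale, (1 - ancestral) * scale)
      }
      fixed <- ancestral == 0 | ancestral == 1
      freq[fixed, k] <- ancestral[fixed]
    }
    list(ancestral = ancestral, freq = freq)
  })
}

# Generate one mosaic haplotype over template rows 1..(j-1) of H, or over an
# explicit template pool. Switch probability per inter-site gap d is
# 1 - exp(-rho * d); the copied allele flips with probability mut_eps.
mosaic_over <- function(templates, pos, rho, mut_eps,
                        pick = NULL) {
  m <- length(pos)
  n_templ <- nrow(templates)
  sw <- c(TRUE, stats::runif(m - 1L) < (1 - exp(-rho * diff(pos))))
  seg <- cumsum(sw)
  if (is.null(pick)) {
    tmpl <- sample.int(n_templ, seg[m], replace = TRUE)
  } else {
    tmpl <- pick(seg[m])
  }
  hap <- templates[cbind(tmpl[seg], seq_len(m))]
  if (mut_eps > 0) {
    flip <- stats::runif(m) < mut_eps
    hap <- ifelse(flip, 1L - hap, hap)
  }
  as.integer(hap)
}

#' Simulate a population haplotype pool under the copying model
#'
#' The first \code{n_founders} haplotypes are drawn site-wise
#' Bernoulli(freq); every subsequent haplotype is a recombination mosaic of
#' the haplotypes generated before it, switching template at rate
#' \code{copy_rho} per bp and flipping the copied allele with probability
#' \code{mut_eps}. Marginal site frequencies are preserved in expectation
#' while shared segments generate distance-decaying LD.
#'
#' @param freqs per-site allele-1 frequencies for this population.
#' @param n_haps number of haplotypes to generate (>= 2).
#' @param pos site positions in bp (sorted).
#' @param copy_rho per-bp switch rate.
#' @param mut_eps copying mutation probability.
#' @param n_founders independent founder haplotypes (capped at n_haps).
#' @param seed RNG seed.
#' @return integer n_haps x n_sites 0/1 matrix.
#' @export
simulate_haplotypes <- function(freqs, n_haps, pos,
                                copy_rho, mut_eps = 1e-3,
                                n_founders = 16L, seed = 1L) {
  if (n_haps < 2) stop("n_haps must be at least 2")
  stopifnot(all(freqs >= 0 & freqs <= 1), length(pos) == length(freqs))
  m <- length(freqs)
  n_f <- min(as.integer(n_founders), as.integer(n_haps))
  withr::with_seed(seed, {
    H <- matrix(0L, n_haps, m)
    H[seq_len(n_f), ] <- matrix(
      stats::rbinom(n_f * m, 1L, rep(freqs, each = n_f)), n_f, m)
    if (n_haps > n_f) {
      for (j in (n_f + 1L):n_haps) {
        H[j, ] <- mosaic_over(H[seq_len(j - 1L), , drop = FALSE], pos,
                              copy_rho, mut_eps)
      }
    }
    H
  })
}

#' Simulate the shared site map and per-population haplotype pools
#'
#' Draws site positions uniformly without replacement, random ref/alt
#' alleles, ancestral and population frequencies, and a haplotype pool per
#' population.
#'
#' @param model a \code{\link{population_model}}.
#' @param n_pool_haps haplotypes per population pool.
#' @param seed master seed.
#' @return list with \code{sites} (a \code{\link{variant_table}}),
#'   \code{freq} (population frequency matrix), \code{ancestral}, and
#'   \code{pools} (named list of \code{\link{haplotype_panel}}s).
#' @export
simulate_pools <- function(model, n_pool_haps = 120L, seed = model$seed) {
  sites <- withr::with_seed(derive_seed(seed, 1L), {
    pos <- sort(sample.int(model$chrom_length_bp, model$n_sites))
    al <- draw_allele_pairs(model$n_sites)
    variant_table(model$chrom, pos, ref = al$ref, alt = al$alt)
  })
  fr <- draw_population_frequencies(model, seed = derive_seed(seed, 2L))
  pools <- vector("list", length(model$populations))
  names(pools) <- model$populations
  for (k in seq_along(model$populations)) {
    H <- simulate_haplotypes(fr$freq[, k], n_pool_haps, sites$pos,
                             copy_rho = model$copy_rho[k],
                             mut_eps = model$mut_eps,
                             n_founders = model$n_founders,
                             seed = derive_seed(seed, 10L + k))
    if (n_pool_haps %% 2L == 1L) H <- H[-n_pool_haps, , drop = FALSE]
    pools[[k]] <- haplotype_panel(
      sites, H,
      sample_ids = paste0(model$populations[k], "_P", seq_len(nrow(H) %/% 2L)),
      groups = rep(model$populations[k], nrow(H) %/% 2L))
  }
  list(sites = sites, freq = fr$freq, ancestral = fr$ancestral, pools = pools)
}

#' Simulate a (possibly admixed) cohort from population pools
#'
#' Each sampled haplotype is an ancestry mosaic: segment breakpoints follow
#' the same exponential switch process as the copying model (rate = the
#' admixture-weighted mean of the population switch rates), the ancestry of
#' each segment is drawn from the cohort's admixture proportions, and the
#' segment is copied from a random haplotype of that population's pool.
#' Genotypes are the site-wise sum of each sample's two truth haplotypes;
#' optional genotyping error (symmetric per-haplotype allele flip) and
#' missingness are injected into the genotype matrix only, leaving the truth
#' haplotypes clean.
#'
#' @param model a \code{\link{population_model}}.
#' @param pools named list of per-population \code{\link{haplotype_panel}}s
#'   sharing one site list (from \code{\link{simulate_pools}}).
#' @param spec list of cohort specifications, each a list with \code{name},
#'   \code{n} (samples) and \code{alpha} (named admixture proportions
#'   summing to 1).
#' @param missing_rate per-call missingness probability in the genotype
#'   matrix.
#' @param error_rate per-haplotype-call symmetric allele-flip probability.
#' @param impact_spec optional named proportions passed to
#'   \code{\link{annotate_impacts}}.
#' @param seed RNG seed.
#' @return a \code{simulated_cohort}: list with \code{truth} (clean phased
#'   \code{haplotype_panel} with cohort groups), \code{observed} (the same
#'   panel after error injection; equal to truth at error_rate 0),
#'   \code{genotypes} (\code{genotype_matrix} derived from the observed
#'   haplotypes, with QUAL/GQ fields populated), and \code{impact} (factor,
#'   or all-NONE when no spec given).
#' @export
simulate_cohort <- function(model, pools, spec, missing_rate = 0,
                            error_rate = 0, impact_spec = NULL, seed = 1L) {
  sites <- pools[[1]]$sites
  for (p in pools) {
    if (!identical(p$sites$pos, sites$pos) ||
        !identical(p$sites$chrom, sites$chrom))
      stop("pools must share one site list")
  }
  pops <- names(pools)
  for (cs in spec) {
    a <- cs$alpha[pops]
    if (any(is.na(a)) || abs(sum(a) - 1) > 1e-9)
      stop("admixture proportions for cohort '", cs$name,
           "' must be named over all populations and sum to 1")
    if (any(a < 0)) stop("negative admixture proportion")
  }
  m <- nrow(sites)
  n_total <- sum(vapply(spec, function(cs) as.integer(cs$n), integer(1)))
  pool_mats <- lapply(pools, function(p) p$haps)
  pool_sizes <- vapply(pool_mats, nrow, integer(1))

  withr::with_seed(seed, {
    H <- matrix(0L, 2L * n_total, m)
    groups <- character(n_total)
    ids <- character(n_total)
    row <- 0L
    si <- 0L
    for (cs in spec) {
      alpha <- cs$alpha[pops]
      rho_c <- sum(alpha * model$copy_rho[pops])
      for (i in seq_len(cs$n)) {
        si <- si + 1L
        groups[si] <- cs$name
        ids[si] <- paste0(cs$name, "_", i)
        for (h in 1:2) {
          row <- row + 1L
          # ancestry + template chosen jointly at each switch point
          sw <- c(TRUE, stats::runif(m - 1L) <
                    (1 - exp(-rho_c * diff(sites$pos))))
          seg <- cumsum(sw)
          n_seg <- seg[m]
          anc <- sample.int(length(pops), n_seg, replace = TRUE, prob = alpha)
          tmpl <- vapply(anc, function(k) sample.int(pool_sizes[k], 1L),
                         integer(1))
          alleles <- integer(m)
          for (k in seq_along(pops)) {
            in_k <- anc[seg] == k
            if (any(in_k))
              alleles[in_k] <- pool_mats[[k]][cbind(tmpl[seg][in_k],
                                                    which(in_k))]
          }
          if (model$mut_eps > 0) {
            flip <- stats::runif(m) < model$mut_eps
            alleles <- ifelse(flip, 1L - alleles, alleles)
          }
          H[row, ] <- alleles
        }
      }
    }
    truth <- haplotype_panel(sites, H, sample_ids = ids, groups = groups)

    # observed haplotypes: truth plus symmetric per-call allele flips; the
    # genotype matrix (and any array typing) derives from these
    obs_h <- H
    if (error_rate > 0) {
      flip <- matrix(stats::runif(length(obs_h)) < error_rate, nrow(obs_h))
      obs_h[flip] <- 1L - obs_h[flip]
    }
    odd <- seq(1L, nrow(obs_h), by = 2L)
    geno <- obs_h[odd, , drop = FALSE] + obs_h[odd + 1L, , drop = FALSE]
    if (missing_rate > 0) {
      geno[matrix(stats::runif(length(geno)) < missing_rate,
                  nrow(geno))] <- NA_integer_
    }
    # per-call genotype quality: mostly confident calls with a low-GQ tail
    gq <- matrix(stats::rpois(length(geno), 60L), nrow(geno))
    low <- matrix(stats::runif(length(geno)) < 0.03, nrow(geno))
    gq[low] <- sample(0:24, sum(low), replace = TRUE)
    gq <- pmin(gq, 99L)
    # per-site QUAL: log-normal, mostly above typical QC cut-offs
    sites_q <- sites
    sites_q$qual <- round(exp(stats::rnorm(m, log(500), 0.9)), 1)
    class(sites_q) <- class(sites)

    genotypes <- genotype_matrix(sites_q, geno, sample_ids = ids,
                                 groups = groups, gq = gq)
    impact <- if (is.null(impact_spec)) {
      factor(rep("NONE", m), levels = c("NONE", "LOW", "MODERATE", "HIGH"))
    } else {
      annotate_impacts(sites_q, site_maf(truth), impact_spec,
                       seed = derive_seed(seed, 77L))
    }
    observed <- haplotype_panel(sites, obs_h, sample_ids = ids,
                                groups = groups)
    structure(list(truth = truth, observed = observed,
                   genotypes = genotypes, sites = sites_q, impact = impact),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", length(x$truth$sample_ids), "samples x",
      nrow(x$sites), "sites\n")
  print(x$truth)
  invisible(x)
}

#' Design a genotyping-array manifest from a simulated cohort
#'
#' Emulates the main array ascertainment strategies: \code{uniform-common}
#' picks sites common (MAF >= \code{maf_threshold}) in a named discovery
#' population and spaces them for near-uniform bp coverage (the classic
#' European-discovery design whose informativeness drops in diverged
#' populations); \code{functional-enriched} picks impact-annotated sites
#' (including rare ones) plus a small common-variant backbone;
#' \code{random} samples polymorphic sites uniformly.
#'
#' @param cohort a \code{simulated_cohort}.
#' @param scheme one of \code{"uniform-common"}, \code{"functional-enriched"},
#'   \code{"random"}.
#' @param size number of array sites requested.
#' @param discovery discovery population/cohort label (required for
#'   \code{uniform-common}); MAF is evaluated in that group's haplotypes.
#' @param maf_threshold discovery-population MAF cut-off.
#' @param backbone_frac fraction of a functional-enriched array reserved for
#'   a common-variant backbone.
#' @param seed RNG seed (used by the random scheme and backbone draw).
#' @return an \code{array_manifest} data frame with TOP and FORWARD allele
#'   codings.
#' @export
design_array <- function(cohort, scheme = c("uniform-common",
                                            "functional-enriched", "random"),
                         size, discovery = NULL, maf_threshold = 0.05,
                         backbone_frac = 0.15, seed = 1L) {
  scheme <- match.arg(scheme)
  sites <- cohort$sites
  maf_all <- site_maf(cohort$truth)
  poly <- which(maf_all > 0)
  idx <- withr::with_seed(seed, {
    switch(scheme,
      "random" = {
        if (size > length(poly)) stop("requested size exceeds eligible sites")
        sort(sample(poly, size))
      },
      "uniform-common" = {
        if (is.null(discovery)) stop("uniform-common needs a discovery group")
        disc <- subset_samples(cohort$truth,
                               cohort$truth$groups == discovery)
        if (length(disc$sample_ids) == 0) stop("unknown discovery group")
        maf_d <- site_maf(disc)
        elig <- which(maf_d >= maf_threshold)
        if (size > length(elig)) stop("requested size exceeds eligible sites")
        # evenly spaced along the eligible (position-sorted) sites
        elig[unique(round(seq(1, length(elig), length.out = size)))]
      },
      "functional-enriched" = {
        func <- which(cohort$impact != "NONE" & maf_all > 0)
        n_backbone <- round(size * backbone_frac)
        n_func <- size - n_backbone
        if (n_func > length(func))
          stop("requested size exceeds eligible sites (",
               length(func), " impact-annotated)")
        chosen <- sample(func, n_func)
        common <- setdiff(which(maf_all >= maf_threshold), chosen)
        if (n_backbone > length(common))
          stop("requested size exceeds eligible sites")
        sort(c(chosen, sample(common, n_backbone)))
      })
  })
  manifest_from_sites(sites[idx, , drop = FALSE])
}

# Build a manifest (FORWARD = ref/alt as given; TOP = orientation with the
# A allele in {A, C}, the Illumina TOP/BOT convention for unambiguous SNPs).
manifest_from_sites <- function(sites) {
  a_fwd <- sites$ref
  b_fwd <- sites$alt
  flip <- !(a_fwd %in% c("A", "C"))
  a_top <- ifelse(flip, complement_allele(a_fwd), a_fwd)
  b_top <- ifelse(flip, complement_allele(b_fwd), b_fwd)
  array_manifest(data.frame(
    id = sites$id, chrom = sites$chrom, pos = sites$pos,
    alleleA_top = a_top, alleleB_top = b_top,
    alleleA_fwd = a_fwd, alleleB_fwd = b_fwd,
    stringsAsFactors = FALSE))
}

#' Array manifest constructor / validator
#'
#' @param df data frame with columns id, chrom, pos, alleleA_top,
#'   alleleB_top, alleleA_fwd, alleleB_fwd.
#' @return an \code{array_manifest}.
#' @export
array_manifest <- function(df) {
  need <- c("id", "chrom", "pos", "alleleA_top", "alleleB_top",
            "alleleA_fwd", "alleleB_fwd")
  if (!all(need %in% names(df))) stop("manifest missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$id)) stop("manifest ids must be unique")
  same <- df$alleleA_top == df$alleleA_fwd & df$alleleB_top == df$alleleB_fwd
  comp <- df$alleleA_top == complement_allele(df$alleleA_fwd) &
    df$alleleB_top == complement_allele(df$alleleB_fwd)
  if (!all(same | comp, na.rm = TRUE))
    stop("TOP and FORWARD codings are not complement-consistent")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("array_manifest", "data.frame")
  df
}

#' Assign functional-impact labels to sites
#'
#' Emulates effect-class annotation with the empirical skew of deleterious
#' variation: HIGH-impact labels are assigned preferentially to rare sites
#' with sampling weight proportional to 1/MAF (capped), while MODERATE and
#' LOW labels are spread uniformly over the remaining sites. Class counts
#' are binomial draws at the requested proportions; the remainder is NONE.
#'
#' @param sites a \code{\link{variant_table}} (row count sets the length).
#' @param maf per-site minor allele frequencies used for the HIGH weighting.
#' @param proportions named numeric, e.g. \code{c(HIGH = 0.01,
#'   MODERATE = 0.05, LOW = 0.1)}; must be non-negative and sum to <= 1.
#' @param seed RNG seed.
#' @param weight_cap cap on the 1/MAF weight.
#' @return factor with levels NONE, LOW, MODERATE, HIGH.
#' @export
annotate_impacts <- function(sites, maf, proportions, seed = 1L,
                             weight_cap = 100) {
  m <- nrow(sites)
  stopifnot(length(maf) == m)
  pr <- c(HIGH = 0, MODERATE = 0, LOW = 0)
  pr[names(proportions)] <- proportions
  if (any(pr < 0)) stop("negative impact proportions")
  if (sum(pr) > 1) stop("impact proportions must sum to at most 1")
  withr::with_seed(seed, {
    lab <- rep("NONE", m)
    n_high <- stats::rbinom(1L, m, pr["HIGH"])
    if (n_high > 0) {
      w <- pmin(1 / pmax(maf, 1e-3), weight_cap)
      hi <- sample.int(m, n_high, prob = w)
      lab[hi] <- "HIGH"
    }
    for (cls in c("MODERATE", "LOW")) {
      n_cls <- stats::rbinom(1L, m, pr[cls])
      free <- which(lab == "NONE")
      if (n_cls > length(free)) n_cls <- length(free)
      if (n_cls > 0) lab[sample(free, n_cls)] <- cls
    }
    factor(lab, levels = c("NONE", "LOW", "MODERATE", "HIGH"))
  })
}
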