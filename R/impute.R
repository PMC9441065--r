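#' Li-Stephens HMM parameters
#'
#' The haploid copying model used for imputation: the hidden state is the
#' reference template being copied; between adjacent grid sites separated
#' by d bp the chain switches template with probability
#' 1 - exp(-rho_scale * d / K) (K = reference haplotype count), choosing
#' the new template uniformly; at typed sites the emitted allele matches
#' the template with probability 1 - eps.
#'
#' @param eps emission mismatch probability, in (0, 0.5).
#' @param rho_scale population-scaled recombination factor (per bp). The
#'   default 4e-8 * Ne with Ne = 100 gives desk-scale switch rates; tune to
#'   the panel.
#' @param min_switch floor on the per-gap switch probability.
#' @return an \code{ls_params} list.
#' @export
ls_params <- function(eps = 1e-3, rho_scale = 4e-8 * 100, min_switch = 1e-9) {
  if (eps <= 0 || eps >= 0.5) stop("eps must be in (0, 0.5)")
  if (rho_scale <= 0) stop("rho_scale must be positive")
  structure(list(eps = eps, rho_scale = rho_scale, min_switch = min_switch),
            class = "ls_params")
}

# Scaled forward-backward over the full reference grid for one target
# haplotype. obs is the allele vector over ALL reference sites with NA at
# untyped sites (emission 1 there). Returns per-site allele-1 posteriors,
# leave-one-out allele posteriors at typed sites (emission at the site
# itself omitted: predictive forward x backward), and the worst deviation
# of the state posterior normalization from 1.
ls_forward_backward <- function(obs, H, pos, params) {
  K <- nrow(H)
  m <- ncol(H)
  eps <- params$eps
  typed <- which(!is.na(obs))
  if (K == 1L) {
    post <- as.numeric(H[1L, ])
    return(list(allele_post = post, loo_post = post[typed],
                typed_idx = typed, max_norm_dev = 0))
  }
  s <- pmax(1 - exp(-params$rho_scale * diff(pos) / K), params$min_switch)

  emis <- function(t) {
    if (is.na(obs[t])) rep(1, K)
    else ifelse(H[, t] == obs[t], 1 - eps, eps)
  }
  # forward pass; alpha[, t] normalized to sum 1 (includes emission at t)
  alpha <- matrix(0, K, m)
  pred <- matrix(0, K, m)  # predictive distribution before emission at t
  pred[, 1L] <- 1 / K
  a <- pred[, 1L] * emis(1L)
  alpha[, 1L] <- a / sum(a)
  for (t in seq_len(m - 1L)) {
    pr <- (1 - s[t]) * alpha[, t] + s[t] / K
    pred[, t + 1L] <- pr
    a <- pr * emis(t + 1L)
    alpha[, t + 1L] <- a / sum(a)
  }
  # backward pass, emitting posteriors on the fly
  allele_post <- numeric(m)
  loo_post <- rep(NA_real_, m)
  max_dev <- 0
  b <- rep(1, K)
  for (t in m:1L) {
    g <- alpha[, t] * b
    g <- g / sum(g)
    max_dev <- max(max_dev, abs(sum(g) - 1))
    allele_post[t] <- sum(g * H[, t])
    if (!is.na(obs[t])) {
      gl <- pred[, t] * b
      gl <- gl / sum(gl)
      loo_post[t] <- sum(gl * H[, t])
    }
    if (t > 1L) {
      eb <- emis(t) * b
      b <- (1 - s[t - 1L]) * eb + s[t - 1L] * mean(eb)
      b <- b / sum(b)
    }
  }
  list(allele_post = allele_post, loo_post = loo_post[typed],
       typed_idx = typed, max_norm_dev = max_dev)
}

#' Impute one haplotype against a reference panel
#'
#' Runs the haploid Li-Stephens forward-backward over the full reference
#' site grid, with emissions only at the typed sites, and returns the
#' posterior probability of allele 1 at every reference site plus the
#' leave-one-out posterior (the site's own emission masked) at each typed
#' site.
#'
#' @param target_alleles alleles of the target haplotype at the typed
#'   sites (0/1).
#' @param typed_idx indices of the typed sites within the reference grid.
#' @param reference a \code{\link{haplotype_panel}}.
#' @param params an \code{\link{ls_params}}.
#' @return list with \code{allele_post} (length = reference sites),
#'   \code{loo_post} (length = typed sites) and \code{max_norm_dev}.
#' @export
impute_haplotype <- function(target_alleles, typed_idx, reference,
                             params = ls_params()) {
  m <- nrow(reference$sites)
  typed_idx <- as.integer(typed_idx)
  if (any(typed_idx < 1 | typed_idx > m)) stop("typed sites outside grid")
  obs <- rep(NA_integer_, m)
  if (length(typed_idx) == 0L) {
    warning("target typed at zero sites; returning prior-only posteriors")
  } else {
    obs[typed_idx] <- as.integer(target_alleles)
  }
  ls_forward_backward(obs, reference$haps, reference$sites$pos, params)
}

#' Impute a phased cohort to the reference grid
#'
#' For each target haplotype the typed alleles are matched to the reference
#' grid by (chrom, pos); every target site must exist in the reference
#' after harmonization. Diploid dosage is the sum of the two haplotype
#' allele posteriors; the leave-one-out dosage at each typed site is the
#' sum of the two leave-one-out posteriors.
#'
#' @param targets a phased \code{\link{haplotype_panel}} typed at a subset
#'   of the reference sites.
#' @param reference the reference \code{\link{haplotype_panel}}.
#' @param params an \code{\link{ls_params}}.
#' @return an \code{imputation_result}: sites (reference grid), dosage
#'   (samples x sites, in [0, 2]), loo_dosage (samples x typed sites),
#'   typed_idx, sample_ids/groups, and the worst posterior normalization
#'   deviation seen.
#' @export
impute_cohort <- function(targets, reference, params = ls_params()) {
  if (nrow(targets$haps) == 0 || ncol(targets$haps) == 0)
    stop("empty target site set")
  ix <- intersect_sites(targets$sites, reference$sites)
  if (nrow(ix) < nrow(targets$sites)) {
    missing <- setdiff(seq_len(nrow(targets$sites)), ix$idx_a)
    stop("target sites absent from the reference grid after harmonization: ",
         paste(utils::head(paste0(targets$sites$chrom[missing], ":",
                                  targets$sites$pos[missing]), 5),
               collapse = ", "),
         if (length(missing) > 5) paste0(" (+", length(missing) - 5, " more)"))
  }
  typed_idx <- ix$idx_b
  m <- nrow(reference$sites)
  n_sam <- length(targets$sample_ids)
  dosage <- matrix(0, n_sam, m)
  loo <- matrix(0, n_sam, length(typed_idx))
  max_dev <- 0
  for (i in seq_len(n_sam)) {
    for (h in c(2L * i - 1L, 2L * i)) {
      res <- impute_haplotype(targets$haps[h, ix$idx_a], typed_idx,
                              reference, params)
      dosage[i, ] <- dosage[i, ] + res$allele_post
      loo[i, ] <- loo[i, ] + res$loo_post
      max_dev <- max(max_dev, res$max_norm_dev)
    }
  }
  structure(list(sites = reference$sites, dosage = dosage, loo_dosage = loo,
                 typed_idx = typed_idx, sample_ids = targets$sample_ids,
                 groups = targets$groups, params = params,
                 max_norm_dev = max_dev),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("imputation_result:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "sites (", length(x$typed_idx), "typed )\n")
  invisible(x)
}

#' Per-site imputation accuracy (ER2 and dosage R2)
#'
#' ER2 at each typed site is the squared Pearson correlation, across
#' samples, between true genotypes (0/1/2) and leave-one-out dosages;
#' dosage R2 at each untyped site is the squared correlation between true
#' genotypes and imputed dosages. Sites where either vector has zero
#' variance are flagged undefined (NA) and must be excluded from
#' aggregates, not zero-filled.
#'
#' @param result an \code{imputation_result}.
#' @param truth a \code{\link{genotype_matrix}} aligned to the result's
#'   sites and samples.
#' @param maf per-site MAF used for stratification (defaults to the truth
#'   MAF; reference-panel MAF is the conventional alternative).
#' @param impact optional per-site impact factor.
#' @return data frame with one row per site: chrom, pos, id, typed flag,
#'   maf, maf_bin, impact, er2, dosage_r2 and \code{accuracy} (ER2 where
#'   typed, dosage R2 otherwise).
#' @export
imputation_accuracy <- function(result, truth, maf = NULL, impact = NULL) {
  if (!identical(dim(truth$geno), dim(result$dosage)))
    stop("truth not aligned to result")
  m <- ncol(result$dosage)
  n <- nrow(result$dosage)
  er2 <- rep(NA_real_, m)
  dr2 <- rep(NA_real_, m)
  typed <- seq_len(m) %in% result$typed_idx
  if (n >= 2) {
    for (t in seq_along(result$typed_idx)) {
      site <- result$typed_idx[t]
      er2[site] <- squared_cor(truth$geno[, site], result$loo_dosage[, t])
    }
    for (site in which(!typed)) {
      dr2[site] <- squared_cor(truth$geno[, site], result$dosage[, site])
    }
  }
  if (is.null(maf)) maf <- site_maf(truth)
  data.frame(chrom = result$sites$chrom, pos = result$sites$pos,
             id = result$sites$id, typed = typed, maf = maf,
             maf_bin = maf_bin(maf),
             impact = if (is.null(impact)) factor(rep("NONE", m)) else impact,
             er2 = er2, dosage_r2 = dr2,
             accuracy = ifelse(typed, er2, dr2))
}

# Harden per-haplotype allele posteriors into 0/1 calls; ties at 0.5 go to
# the allele more frequent in the panel used for the step.
harden_posterior <- function(post, panel_freq, tol = 1e-12) {
  hard <- as.integer(post > 0.5)
  tie <- abs(post - 0.5) <= tol
  hard[tie] <- as.integer(panel_freq[tie] >= 0.5)
  hard
}

#' Two-step imputation: sparse array to dense array to sequence
#'
#' Step 1 imputes the sparse-typed targets to the dense-array site grid
#' against the intermediate panel (any sample also present in the targets
#' is removed from that panel first); each haplotype's posteriors are
#' hardened (posterior > 0.5, ties to the panel-major allele) into phased
#' dense genotypes. Step 2 imputes those dense haplotypes to the full grid
#' against the final panel. Site sets must be nested: sparse within dense
#' within full.
#'
#' @param targets phased \code{\link{haplotype_panel}} at the sparse sites.
#' @param intermediate dense-array \code{haplotype_panel} (the analogue of
#'   an HD-array reference cohort).
#' @param final full-density reference \code{haplotype_panel}.
#' @param params an \code{\link{ls_params}} used for both steps.
#' @param harden keep the default hardening of step-1 output; set FALSE to
#'   pass step-1 dosages rounded per haplotype anyway (sensitivity mode,
#'   equivalent here since the HMM consumes alleles).
#' @return the step-2 \code{imputation_result} (typed set = dense sites),
#'   with the step-1 result attached as attribute \code{step1}.
#' @export
two_step_impute <- function(targets, intermediate, final,
                            params = ls_params(), harden = TRUE) {
  key <- function(tab) paste(tab$chrom, tab$pos)
  if (!all(key(targets$sites) %in% key(intermediate$sites)))
    stop("sparse sites must be nested within dense sites")
  if (!all(key(intermediate$sites) %in% key(final$sites)))
    stop("dense sites must be nested within full sites")
  overlap <- intersect(intermediate$sample_ids, targets$sample_ids)
  if (length(overlap)) {
    message("two_step_impute: removing ", length(overlap),
            " target sample(s) from the intermediate panel")
    intermediate <- subset_samples(intermediate,
                                   !(intermediate$sample_ids %in% overlap))
    if (length(intermediate$sample_ids) == 0)
      stop("intermediate panel empty after removing target samples")
  }
  # step 1 at the haplotype level: posteriors accumulate into the diploid
  # step-1 result and are hardened per haplotype for phased step-2 input
  m_dense <- nrow(intermediate$sites)
  n_sam <- length(targets$sample_ids)
  dense_haps <- matrix(0L, 2L * n_sam, m_dense)
  ix <- intersect_sites(targets$sites, intermediate$sites)
  panel_freq <- alt_freq(intermediate)
  s1_dosage <- matrix(0, n_sam, m_dense)
  s1_loo <- matrix(0, n_sam, nrow(ix))
  for (i in seq_len(n_sam)) {
    for (k in 1:2) {
      h <- 2L * i - 2L + k
      res <- impute_haplotype(targets$haps[h, ix$idx_a], ix$idx_b,
                              intermediate, params)
      s1_dosage[i, ] <- s1_dosage[i, ] + res$allele_post
      s1_loo[i, ] <- s1_loo[i, ] + res$loo_post
      dense_haps[h, ] <- harden_posterior(res$allele_post, panel_freq)
    }
  }
  step1 <- structure(list(sites = intermediate$sites, dosage = s1_dosage,
                          loo_dosage = s1_loo, typed_idx = ix$idx_b,
                          sample_ids = targets$sample_ids,
                          groups = targets$groups, params = params,
                          max_norm_dev = NA_real_),
                     class = "imputation_result")
  dense_panel <- haplotype_panel(intermediate$sites, dense_haps,
                                 sample_ids = targets$sample_ids,
                                 groups = targets$groups)
  out <- impute_cohort(dense_panel, final, params)
  attr(out, "step1") <- step1
  out
}
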