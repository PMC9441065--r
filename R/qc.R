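#' Quality-control threshold sets
#'
#' Bundles the site, sample and relatedness cut-offs used in the three QC
#' regimes: array cohorts (call rate >= 0.90, MAF >= 0.01, sample
#' missingness <= 10%, duplicate kinship 0.40), WGS reference panels
#' (QUAL > 100, per-group site missingness <= 25%, call rate >= 0.75 with
#' GQ >= 25 masking, unrelated kinship 0.0625), or a custom combination.
#' Set any threshold to \code{NA} to disable that rule.
#'
#' @param site_maf_min minimum minor allele frequency.
#' @param site_call_rate_min minimum fraction of non-missing calls per site.
#' @param sample_missing_max maximum per-sample missing fraction.
#' @param site_missing_max maximum per-site missing fraction, evaluated per
#'   sample group when groups are available.
#' @param qual_min minimum site QUAL (strict: sites must exceed it).
#' @param gq_min calls below this genotype quality are set missing before
#'   the call-rate rules.
#' @param kinship_unrelated_max kinship above which a pair counts as
#'   related for pruning.
#' @param kinship_duplicate_max kinship above which a pair counts as a
#'   duplicate.
#' @return a \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(site_maf_min = 0.01, site_call_rate_min = 0.90,
                          sample_missing_max = 0.10, site_missing_max = NA,
                          qual_min = NA, gq_min = NA,
                          kinship_unrelated_max = 0.0625,
                          kinship_duplicate_max = 0.40) {
  th <- list(site_maf_min = site_maf_min,
             site_call_rate_min = site_call_rate_min,
             sample_missing_max = sample_missing_max,
             site_missing_max = site_missing_max,
             qual_min = qual_min, gq_min = gq_min,
             kinship_unrelated_max = kinship_unrelated_max,
             kinship_duplicate_max = kinship_duplicate_max)
  chk01 <- c("site_maf_min", "site_call_rate_min", "sample_missing_max",
             "site_missing_max")
  for (nm in chk01) {
    v <- th[[nm]]
    if (!is.na(v) && (v < 0 || v > 1)) stop(nm, " must be in [0, 1]")
  }
  structure(th, class = "qc_thresholds")
}

#' Preset QC regimes
#'
#' @param profile "array" (genotyping-array cohort QC), "wgs-panel"
#'   (sequence reference-panel QC) or "none".
#' @return a \code{\link{qc_thresholds}}.
#' @export
qc_profile <- function(profile = c("array", "wgs-panel", "none")) {
  profile <- match.arg(profile)
  switch(profile,
    "array" = qc_thresholds(),
    "wgs-panel" = qc_thresholds(site_maf_min = NA, site_call_rate_min = 0.75,
                                sample_missing_max = 0.25,
                                site_missing_max = 0.25,
                                qual_min = 100, gq_min = 25),
    "none" = qc_thresholds(site_maf_min = NA, site_call_rate_min = NA,
                           sample_missing_max = NA, site_missing_max = NA,
                           qual_min = NA, gq_min = NA))
}

#' Filter sites against QC thresholds
#'
#' Calls with GQ below \code{gq_min} are first set missing; sites are then
#' tested, in order, against the MAF, call-rate, per-group missingness and
#' QUAL rules. A site is removed when it fails any enabled rule; removal
#' counts are attributed to the first failing rule. Sites with no usable
#' calls fail the call-rate rule (MAF is undefined there).
#'
#' @param genotypes a \code{\link{genotype_matrix}} (QUAL is taken from its
#'   site table, GQ from its gq matrix).
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param by_group evaluate the site-missingness rule within each sample
#'   group (requires group labels); the rule fails if any group exceeds the
#'   cut-off.
#' @return list with \code{keep} (logical per site), \code{counts} (named
#'   removal counts per rule) and \code{first_fail} (per-site rule name or
#'   NA).
#' @export
filter_sites <- function(genotypes, thresholds = qc_thresholds(),
                         by_group = FALSE) {
  g <- genotypes$geno
  th <- thresholds
  if (!is.na(th$gq_min) && !is.null(genotypes$gq))
    g[genotypes$gq < th$gq_min] <- NA_integer_
  n <- nrow(g)
  n_obs <- colSums(!is.na(g))
  call_rate <- n_obs / n
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[n_obs == 0] <- NA_real_

  fail <- matrix(FALSE, ncol(g), 4,
                 dimnames = list(NULL, c("maf", "call_rate", "site_missing",
                                         "qual")))
  if (!is.na(th$site_maf_min))
    fail[, "maf"] <- !is.na(maf) & maf < th$site_maf_min
  if (!is.na(th$site_call_rate_min))
    fail[, "call_rate"] <- call_rate < th$site_call_rate_min
  if (!is.na(th$site_missing_max)) {
    if (by_group && !is.null(genotypes$groups)) {
      for (grp in unique(genotypes$groups)) {
        rows <- genotypes$groups == grp
        miss <- colMeans(is.na(g[rows, , drop = FALSE]))
        fail[, "site_missing"] <- fail[, "site_missing"] |
          miss > th$site_missing_max
      }
    } else {
      fail[, "site_missing"] <- colMeans(is.na(g)) > th$site_missing_max
    }
  }
  if (!is.na(th$qual_min)) {
    q <- genotypes$sites$qual
    fail[, "qual"] <- is.na(q) | q <= th$qual_min
  }
  # a site with zero usable calls has no MAF; attribute it to call rate
  no_data <- n_obs == 0
  fail[no_data, "maf"] <- FALSE
  if (is.na(th$site_call_rate_min) && !is.na(th$site_maf_min))
    fail[no_data, "call_rate"] <- TRUE

  keep <- rowSums(fail) == 0
  first <- apply(fail, 1, function(fr) {
    w <- which(fr)
    if (length(w)) colnames(fail)[w[1]] else NA_character_
  })
  counts <- table(factor(first, levels = colnames(fail)))
  list(keep = keep, counts = as.integer(counts) |>
         stats::setNames(colnames(fail)), first_fail = first)
}

#' Filter samples by missingness
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param thresholds a \code{\link{qc_thresholds}}; samples with a missing
#'   fraction above \code{sample_missing_max} are removed.
#' @return logical keep mask over samples.
#' @export
filter_samples <- function(genotypes, thresholds = qc_thresholds()) {
  if (nrow(genotypes$geno) == 0) return(logical(0))
  if (is.na(thresholds$sample_missing_max))
    return(rep(TRUE, nrow(genotypes$geno)))
  miss <- rowMeans(is.na(genotypes$geno))
  miss <= thresholds$sample_missing_max
}

#' KING-robust pairwise kinship matrix
#'
#' The between-family KING estimator:
#' phi = (N_het,het - 2 N_opp_hom) / (N_het(i) + N_het(j)),
#' with all counts over sites non-missing in both samples. Duplicates give
#' 0.5, unrelated pairs about 0; it is robust to population structure and
#' invariant to ref/alt allele swaps.
#'
#' @param genotypes a \code{\link{genotype_matrix}} with at least 2 samples
#'   and 1 polymorphic site.
#' @return symmetric numeric matrix (diagonal 0.5); pairs with no usable
#'   sites get NA.
#' @export
kinship_matrix <- function(genotypes) {
  g <- genotypes$geno
  if (nrow(g) < 2) stop("need at least 2 samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  if (!any(p > 0 & p < 1, na.rm = TRUE)) stop("need at least 1 polymorphic site")
  het <- (!is.na(g) & g == 1L) * 1
  hom0 <- (!is.na(g) & g == 0L) * 1
  hom2 <- (!is.na(g) & g == 2L) * 1
  obs <- (!is.na(g)) * 1
  n_hh <- tcrossprod(het)
  n_opp <- tcrossprod(hom0, hom2)
  n_opp <- n_opp + t(n_opp)
  het_in_shared <- tcrossprod(het, obs)  # [i, j] = het sites of i usable in j
  denom <- het_in_shared + t(het_in_shared)
  phi <- (n_hh - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  usable <- tcrossprod(obs)
  phi[usable == 0] <- NA_real_
  dimnames(phi) <- list(genotypes$sample_ids, genotypes$sample_ids)
  phi
}

#' Greedy pruning of related samples
#'
#' Iteratively drops the sample with the most over-threshold partners
#' (ties broken by higher mean kinship, then input order) until no pair
#' exceeds the threshold.
#'
#' @param kinship symmetric kinship matrix.
#' @param threshold kinship cut-off (e.g. 0.0625 for unrelated panels,
#'   0.40 for duplicate removal).
#' @return integer indices of the kept samples.
#' @export
prune_related <- function(kinship, threshold) {
  n <- nrow(kinship)
  adj <- !is.na(kinship) & kinship > threshold
  diag(adj) <- FALSE
  keep <- rep(TRUE, n)
  mean_kin <- rowMeans(kinship, na.rm = TRUE)
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    if (length(cand) > 1) {
      cand <- cand[order(-mean_kin[cand], cand)]
    }
    drop <- cand[1]
    keep[drop] <- FALSE
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  which(keep)
}
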