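#' Restrict a sequence panel to the sites of an array manifest
#'
#' Builds the masked-analysis target set: the panel restricted to the
#' (chrom, pos) overlap with the manifest, keeping all samples. The count
#' of manifest sites absent from the panel is the synthetic analogue of a
#' "retained from WGS" statistic.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param manifest an \code{\link{array_manifest}}.
#' @return list with \code{panel} (site subset), \code{site_idx} (indices
#'   into the source panel) and \code{n_absent} (manifest sites not in the
#'   panel).
#' @export
build_target_set <- function(panel, manifest) {
  ix <- intersect_sites(panel$sites, manifest)
  if (nrow(ix) == 0) stop("no overlap between panel and manifest")
  list(panel = subset_sites(panel, ix$idx_a), site_idx = ix$idx_a,
       n_absent = nrow(manifest) - nrow(ix))
}

#' Subset a panel by sample-group labels
#'
#' @param panel a \code{\link{haplotype_panel}} with group labels.
#' @param groups labels to keep (haplotype pairs stay together).
#' @return the panel subset.
#' @export
subset_panel <- function(panel, groups) {
  if (is.null(panel$groups)) stop("panel has no group labels")
  unknown <- setdiff(groups, unique(panel$groups))
  if (length(unknown)) stop("unknown group label(s): ",
                            paste(unknown, collapse = ", "))
  keep <- panel$groups %in% groups
  if (!any(keep)) stop("empty subset")
  subset_samples(panel, keep)
}

# Balanced reference-panel groupings for composition experiments: each pure
# population subset at the size of the smallest group, plus a combined
# panel of the SAME total size drawn half from each population.
panel_groupings <- function(ref_panel, seed = 1L) {
  groups <- unique(ref_panel$groups)
  n_min <- min(table(ref_panel$groups))
  out <- list()
  withr::with_seed(seed, {
    for (g in groups) {
      idx <- which(ref_panel$groups == g)
      out[[g]] <- subset_samples(ref_panel, sort(sample(idx, n_min)))
    }
    per <- n_min %/% length(groups)
    extra <- n_min - per * length(groups)
    comb <- integer(0)
    for (k in seq_along(groups)) {
      idx <- which(ref_panel$groups == groups[k])
      take <- per + (k <= extra)
      comb <- c(comb, sample(idx, take))
    }
    out[["combined"]] <- subset_samples(ref_panel, sort(comb))
  })
  out
}

#' Experiment configuration
#'
#' @param scenario list with \code{model}, \code{reference_spec},
#'   \code{target_spec} (see \code{\link{default_scenario}}).
#' @param arrays list of array design requests, each a list with
#'   \code{name}, \code{scheme}, \code{size} and optional \code{discovery},
#'   \code{maf_threshold} (see \code{\link{design_array}}).
#' @param arms analysis arms to run, subset of \code{c("tagging",
#'   "masked_imputation", "loo_cv", "one_step", "two_step")}.
#' @param qc a \code{\link{qc_thresholds}} applied to array target sites.
#' @param r2_threshold,window_bp tagging parameters.
#' @param min_post_qc_variants arrays retaining fewer post-QC variants are
#'   skipped and recorded (the exclusion floor for unusable arrays).
#' @param loo_n number of reference samples in the leave-one-out arm.
#' @param sparse_array,dense_array array names for the one-step/two-step
#'   comparison.
#' @param impact_spec impact-label mixture for the simulated cohorts.
#' @param params an \code{\link{ls_params}}.
#' @param n_pool_haps haplotypes per simulated population pool.
#' @param seed master seed; the run is deterministic given it.
#' @return an \code{experiment_config} list.
#' @export
experiment_config <- function(scenario = default_scenario(),
                              arrays,
                              arms = c("tagging", "masked_imputation"),
                              qc = qc_profile("none"),
                              r2_threshold = 0.8, window_bp = 500000,
                              min_post_qc_variants = 10000,
                              loo_n = 20L,
                              sparse_array = NULL, dense_array = NULL,
                              impact_spec = c(HIGH = 0.01, MODERATE = 0.04,
                                              LOW = 0.10),
                              params = ls_params(),
                              n_pool_haps = 120L,
                              seed = 1L) {
  known <- c("tagging", "masked_imputation", "loo_cv", "one_step", "two_step")
  if (length(arms) == 0 || !all(arms %in% known))
    stop("arms must be a non-empty subset of: ", paste(known, collapse = ", "))
  if (any(c("one_step", "two_step") %in% arms) &&
      (is.null(sparse_array) || is.null(dense_array)))
    stop("one_step/two_step arms need sparse_array and dense_array names")
  structure(list(scenario = scenario, arrays = arrays, arms = arms, qc = qc,
                 r2_threshold = r2_threshold, window_bp = window_bp,
                 min_post_qc_variants = min_post_qc_variants,
                 loo_n = as.integer(loo_n), sparse_array = sparse_array,
                 dense_array = dense_array, impact_spec = impact_spec,
                 params = params, n_pool_haps = as.integer(n_pool_haps),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

record_row <- function(arm, array, panel, target_group, stratum_type,
                       stratum, metric, value, n_sites, n_samples) {
  data.frame(arm = arm, array = array, panel = panel,
             target_group = target_group, stratum_type = stratum_type,
             stratum = stratum, metric = metric, value = value,
             n_sites = n_sites, n_samples = n_samples,
             stringsAsFactors = FALSE)
}

# Aggregate a per-site accuracy table into long-format records: overall
# means plus MAF-bin and impact-class strata (undefined sites excluded).
accuracy_records <- function(acc, arm, array, panel, target_group,
                             n_samples) {
  recs <- list()
  add <- function(...) recs[[length(recs) + 1L]] <<- record_row(...)
  for (metric in c("er2", "dosage_r2")) {
    v <- acc[[metric]]
    ok <- !is.na(v)
    if (any(ok))
      add(arm, array, panel, target_group, "all", "all",
          paste0("mean_", metric), mean(v[ok]), sum(ok), n_samples)
    for (b in levels(acc$maf_bin)) {
      sel <- ok & !is.na(acc$maf_bin) & acc$maf_bin == b
      if (any(sel))
        add(arm, array, panel, target_group, "maf_bin", b,
            paste0("mean_", metric), mean(v[sel]), sum(sel), n_samples)
    }
    for (cls in levels(acc$impact)) {
      sel <- ok & acc$impact == cls
      if (any(sel))
        add(arm, array, panel, target_group, "impact", cls,
            paste0("mean_", metric), mean(v[sel]), sum(sel), n_samples)
    }
  }
  do.call(rbind, recs)
}

#' Run a full array-evaluation experiment
#'
#' Simulates the scenario (population pools, a reference cohort and a
#' target cohort), designs the requested arrays, applies array-site QC with
#' the post-QC variant floor, and executes the requested arms:
#' \describe{
#'   \item{tagging}{windowed tagging proportion per array and target
#'     population;}
#'   \item{masked_imputation}{target cohort typed at array sites, imputed
#'     against the full reference panel; ER2 and dosage R2 stratified by
#'     MAF bin and impact class, per target group and overall;}
#'   \item{loo_cv}{leave-one-out cross-validation over reference samples;}
#'   \item{one_step/two_step}{sparse-array imputation direct to sequence
#'     vs through the dense grid, against balanced single-population and
#'     combined reference panels.}
#' }
#' The run is deterministic given the config seed.
#'
#' @param config an \code{\link{experiment_config}}.
#' @return an \code{experiment_report}: list with \code{records}
#'   (long-format data frame), \code{skipped_arrays}, \code{cohorts}
#'   (simulated data), \code{manifests} and \code{config}.
#' @export
run_experiment <- function(config) {
  seed <- config$seed
  model <- config$scenario$model
  sim <- simulate_pools(model, n_pool_haps = config$n_pool_haps,
                        seed = derive_seed(seed, 101L))
  ref_cohort <- simulate_cohort(model, sim$pools,
                                config$scenario$reference_spec,
                                impact_spec = config$impact_spec,
                                seed = derive_seed(seed, 102L))
  tgt_cohort <- simulate_cohort(model, sim$pools,
                                config$scenario$target_spec,
                                impact_spec = config$impact_spec,
                                seed = derive_seed(seed, 103L))
  ref_panel <- ref_cohort$truth
  tgt_panel <- tgt_cohort$truth
  tgt_truth <- collapse_haplotypes(tgt_panel)
  ref_maf <- site_maf(ref_panel)

  manifests <- list()
  for (a in config$arrays) {
    manifests[[a$name]] <- design_array(
      tgt_cohort, scheme = a$scheme, size = a$size,
      discovery = a$discovery,
      maf_threshold = if (is.null(a$maf_threshold)) 0.05 else a$maf_threshold,
      seed = derive_seed(seed, 200L + length(manifests)))
  }

  # array-site QC on the reference cohort genotypes; arrays under the
  # post-QC floor are excluded from every arm
  kept_sites <- list()
  skipped <- data.frame(array = character(0), n_post_qc = integer(0),
                        reason = character(0))
  for (nm in names(manifests)) {
    ts <- build_target_set(ref_panel, manifests[[nm]])
    gm <- subset_sites(ref_cohort$genotypes, ts$site_idx)
    fs <- filter_sites(gm, config$qc)
    kept <- ts$site_idx[fs$keep]
    if (length(kept) < config$min_post_qc_variants) {
      skipped <- rbind(skipped, data.frame(
        array = nm, n_post_qc = length(kept),
        reason = "below min_post_qc_variants"))
    } else {
      kept_sites[[nm]] <- kept
    }
  }

  records <- list()
  add <- function(df) records[[length(records) + 1L]] <<- df
  tgt_groups <- unique(tgt_panel$groups)

  run_arm <- function(arm, body) {
    tryCatch(body, error = function(e)
      stop("arm '", arm, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("tagging" %in% config$arms) run_arm("tagging", {
    for (nm in names(kept_sites)) {
      man_kept <- manifest_from_sites(
        ref_panel$sites[kept_sites[[nm]], , drop = FALSE])
      for (g in tgt_groups) {
        sub <- subset_panel(tgt_panel, g)
        ts <- tagging_summary(sub, man_kept, window_bp = config$window_bp,
                              r2_threshold = config$r2_threshold)
        add(record_row("tagging", nm, "none", g, "all", "all",
                       "tagging_proportion", ts$proportion,
                       sum(ts$per_site$polymorphic),
                       length(sub$sample_ids)))
        add(record_row("tagging", nm, "none", g, "all", "all",
                       "tagging_proportion_excluding_array",
                       ts$proportion_excluding_array,
                       sum(ts$per_site$polymorphic & !ts$per_site$array_site),
                       length(sub$sample_ids)))
      }
    }
  })

  if ("masked_imputation" %in% config$arms) run_arm("masked_imputation", {
    for (nm in names(kept_sites)) {
      targets <- subset_sites(tgt_panel, kept_sites[[nm]])
      res <- impute_cohort(targets, ref_panel, config$params)
      acc <- imputation_accuracy(res, tgt_truth, maf = ref_maf,
                                 impact = tgt_cohort$impact)
      add(accuracy_records(acc, "masked_imputation", nm, "global", "all",
                           length(targets$sample_ids)))
      for (g in tgt_groups) {
        keep <- tgt_panel$groups == g
        res_g <- list(sites = res$sites,
                      dosage = res$dosage[keep, , drop = FALSE],
                      loo_dosage = res$loo_dosage[keep, , drop = FALSE],
                      typed_idx = res$typed_idx,
                      sample_ids = res$sample_ids[keep])
        class(res_g) <- "imputation_result"
        truth_g <- subset_samples(tgt_truth, keep)
        acc_g <- imputation_accuracy(res_g, truth_g, maf = ref_maf,
                                     impact = tgt_cohort$impact)
        add(accuracy_records(acc_g, "masked_imputation", nm, "global", g,
                             sum(keep)))
      }
    }
  })

  if ("loo_cv" %in% config$arms) run_arm("loo_cv", {
    n_ref <- length(ref_panel$sample_ids)
    picks <- withr::with_seed(derive_seed(seed, 300L),
                              sample.int(n_ref, min(config$loo_n, n_ref)))
    for (nm in names(kept_sites)) {
      er2_rows <- matrix(NA_real_, length(picks), length(kept_sites[[nm]]))
      truth_rows <- matrix(NA_integer_, length(picks),
                           length(kept_sites[[nm]]))
      loo_rows <- er2_rows
      for (pi in seq_along(picks)) {
        i <- picks[pi]
        panel_i <- subset_samples(ref_panel,
                                  setdiff(seq_len(n_ref), i))
        target_i <- subset_sites(subset_samples(ref_panel, i),
                                 kept_sites[[nm]])
        res <- impute_cohort(target_i, panel_i, config$params)
        loo_rows[pi, ] <- res$loo_dosage[1, ]
        truth_rows[pi, ] <- collapse_haplotypes(
          subset_samples(ref_panel, i))$geno[1, kept_sites[[nm]]]
      }
      # ER2 across the held-out individuals at each typed site
      er2 <- vapply(seq_len(ncol(loo_rows)), function(s)
        squared_cor(truth_rows[, s], loo_rows[, s]), numeric(1))
      ok <- !is.na(er2)
      maf_t <- ref_maf[kept_sites[[nm]]]
      add(record_row("loo_cv", nm, "global", "reference", "all", "all",
                     "mean_er2", mean(er2[ok]), sum(ok), length(picks)))
      bins <- maf_bin(maf_t)
      for (b in levels(bins)) {
        sel <- ok & !is.na(bins) & bins == b
        if (any(sel))
          add(record_row("loo_cv", nm, "global", "reference", "maf_bin", b,
                         "mean_er2", mean(er2[sel]), sum(sel),
                         length(picks)))
      }
    }
  })

  if (any(c("one_step", "two_step") %in% config$arms)) {
    sparse_nm <- config$sparse_array
    dense_nm <- config$dense_array
    if (!sparse_nm %in% names(kept_sites) ||
        !dense_nm %in% names(kept_sites))
      stop("sparse/dense arrays unavailable after QC")
    sparse_idx <- intersect(kept_sites[[sparse_nm]], kept_sites[[dense_nm]])
    dense_idx <- kept_sites[[dense_nm]]
    sparse_targets <- subset_sites(tgt_panel, sparse_idx)
    groupings <- c(panel_groupings(ref_panel,
                                   seed = derive_seed(seed, 400L)),
                   list(global = ref_panel))
    for (pnm in names(groupings)) {
      panel <- groupings[[pnm]]
      if ("one_step" %in% config$arms) run_arm("one_step", {
        res <- impute_cohort(sparse_targets, panel, config$params)
        acc <- imputation_accuracy(res, tgt_truth, maf = ref_maf,
                                   impact = tgt_cohort$impact)
        add(accuracy_records(acc, "one_step", sparse_nm, pnm, "all",
                             length(sparse_targets$sample_ids)))
      })
      if ("two_step" %in% config$arms) run_arm("two_step", {
        intermediate <- subset_sites(panel, dense_idx)
        res2 <- two_step_impute(sparse_targets, intermediate, panel,
                                config$params)
        acc2 <- imputation_accuracy(res2, tgt_truth, maf = ref_maf,
                                    impact = tgt_cohort$impact)
        add(accuracy_records(acc2, "two_step", sparse_nm, pnm, "all",
                             length(sparse_targets$sample_ids)))
      })
    }
  }

  records <- do.call(rbind, records)
  rownames(records) <- NULL
  structure(list(records = records, skipped_arrays = skipped,
                 cohorts = list(pools = sim, reference = ref_cohort,
                                target = tgt_cohort),
                 manifests = manifests, kept_sites = kept_sites,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", nrow(x$records), "records;",
      nrow(x$skipped_arrays), "array(s) skipped\n")
  invisible(x)
}

#' Aggregate a long-format report
#'
#' Weighted means (by n_sites) of each metric within the requested
#' grouping columns; records with missing values are excluded and counted.
#'
#' @param report an \code{experiment_report} or its records data frame.
#' @param by character vector of grouping columns (e.g. \code{c("arm",
#'   "array", "metric")}).
#' @return data frame with grouped weighted means, total n_sites, and the
#'   number of excluded (undefined) records.
#' @export
summarize_report <- function(report, by = c("arm", "array", "panel",
                                            "metric")) {
  rec <- if (inherits(report, "experiment_report")) report$records else report
  if (nrow(rec) == 0) stop("empty report")
  keys <- interaction(rec[by], drop = TRUE, sep = "|")
  out <- lapply(levels(keys), function(k) {
    sub <- rec[keys == k, , drop = FALSE]
    ok <- !is.na(sub$value)
    w <- sub$n_sites[ok]
    data.frame(sub[which(ok)[1], by, drop = FALSE],
               value = sum(sub$value[ok] * w) / sum(w),
               n_sites = sum(w), n_excluded = sum(!ok))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
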