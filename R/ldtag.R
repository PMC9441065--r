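#' Pairwise linkage disequilibrium between two sites
#'
#' Exact haplotype-counting LD: with allele-1 frequencies pA, pB and
#' haplotype frequency pAB, D = pAB - pA pB and
#' r2 = D^2 / (pA (1 - pA) pB (1 - pB)). On phased haplotypes this equals
#' the squared Pearson correlation of the two allele indicator vectors.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param i,j site indices (columns).
#' @return list with pA, pB, pAB, D, r2, distance_bp and \code{defined}
#'   (FALSE, with r2 NA, when either site is monomorphic).
#' @export
pairwise_r2 <- function(panel, i, j) {
  x <- panel$haps[, i]
  y <- panel$haps[, j]
  pA <- mean(x); pB <- mean(y); pAB <- mean(x * y)
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  defined <- denom > 0
  list(pA = pA, pB = pB, pAB = pAB, D = D,
       r2 = if (defined) D^2 / denom else NA_real_,
       distance_bp = abs(panel$sites$pos[i] - panel$sites$pos[j]),
       defined = defined)
}

# Best squared correlation of each panel site against the array sites
# within +/- window_bp on the same chromosome. X is the 0/1 (or dosage)
# matrix with sites in columns; computed in column blocks so only local
# correlation slabs are materialized.
best_r2_in_window <- function(X, pos, chrom, array_idx, window_bp,
                              block = 1024L) {
  m <- ncol(X)
  best <- rep(NA_real_, m)
  sds <- apply(X, 2, stats::sd)
  poly <- sds > 0
  for (chr in unique(chrom)) {
    sites_c <- which(chrom == chr)
    arr_c <- array_idx[chrom[array_idx] == chr]
    arr_c <- arr_c[poly[arr_c]]
    if (!length(arr_c)) next
    arr_pos <- pos[arr_c]
    for (start in seq(1L, length(sites_c), by = block)) {
      blk <- sites_c[start:min(start + block - 1L, length(sites_c))]
      blk <- blk[poly[blk]]
      if (!length(blk)) next
      lo <- findInterval(pos[blk] - window_bp - 0.5, arr_pos) + 1L
      hi <- findInterval(pos[blk] + window_bp + 0.5, arr_pos)
      use <- lo <= hi
      if (!any(use)) next
      rng <- range(c(lo[use], hi[use]))
      cols <- arr_c[rng[1]:rng[2]]
      cc <- suppressWarnings(
        stats::cor(X[, blk, drop = FALSE], X[, cols, drop = FALSE]))^2
      for (b in seq_along(blk)) {
        if (!use[b]) next
        seg <- (lo[b]:hi[b]) - rng[1] + 1L
        v <- cc[b, seg]
        if (any(!is.na(v))) best[blk[b]] <- max(v, na.rm = TRUE)
      }
    }
  }
  best
}

#' Windowed tagging summary of an array against a sequence panel
#'
#' For every polymorphic panel variant, finds the best LD r2 against the
#' array variants lying within \code{window_bp} (a pair window, not
#' disjoint tiles) on the same chromosome; the variant is tagged when that
#' best r2 strictly exceeds the threshold. Array sites present in the
#' evaluation panel tag themselves (r2 = 1) and are counted as tagged;
#' the proportion excluding them is also reported since both conventions
#' are in use.
#'
#' @param panel a \code{\link{haplotype_panel}} (restrict to one
#'   population's haplotypes for per-population tagging).
#' @param manifest an \code{\link{array_manifest}} (or variant table).
#' @param window_bp window half-width in bp.
#' @param r2_threshold tagging threshold (strict inequality).
#' @param strata optional data frame of per-site stratifiers (e.g. MAF bin,
#'   impact class) aligned to panel sites.
#' @return list with \code{per_site} (best r2, tagged flag, array-site
#'   flag, plus strata), \code{proportion} (tagged fraction of polymorphic
#'   sites, array sites included), \code{proportion_excluding_array},
#'   \code{n_array_sites} (manifest sites found in the panel) and
#'   \code{by_stratum} when strata are given.
#' @export
tagging_summary <- function(panel, manifest, window_bp = 500000,
                            r2_threshold = 0.8, strata = NULL) {
  ix <- intersect_sites(panel$sites, manifest)
  array_idx <- ix$idx_a
  X <- panel$haps
  pos <- panel$sites$pos
  chrom <- panel$sites$chrom
  poly <- apply(X, 2, function(col) {
    p <- mean(col); p > 0 && p < 1
  })
  best <- best_r2_in_window(X, pos, chrom, array_idx, window_bp)
  is_array <- seq_len(ncol(X)) %in% array_idx
  best[is_array & poly] <- 1
  tagged <- !is.na(best) & best > r2_threshold
  tagged[is_array & poly] <- TRUE
  per_site <- data.frame(chrom = chrom, pos = pos, id = panel$sites$id,
                         polymorphic = poly, array_site = is_array,
                         best_r2 = best, tagged = tagged)
  if (!is.null(strata)) per_site <- cbind(per_site, strata)
  prop <- if (any(poly)) mean(tagged[poly]) else NA_real_
  non_array <- poly & !is_array
  prop_ex <- if (any(non_array)) mean(tagged[non_array]) else NA_real_
  out <- list(per_site = per_site, proportion = prop,
              proportion_excluding_array = prop_ex,
              n_array_sites = length(array_idx),
              window_bp = window_bp, r2_threshold = r2_threshold)
  if (!is.null(strata)) {
    keys <- interaction(as.data.frame(strata)[poly, , drop = FALSE],
                        drop = TRUE)
    agg <- tapply(tagged[poly], keys, mean)
    out$by_stratum <- data.frame(stratum = names(agg),
                                 proportion = as.numeric(agg),
                                 n_sites = as.integer(table(keys)[names(agg)]))
  }
  out
}

#' LD decay curve: mean r2 per distance bin
#'
#' Pairs of polymorphic sites are assigned to bins by bp distance; pairs
#' with undefined r2 are excluded. When the number of in-range pairs
#' exceeds \code{max_pairs}, a seeded uniform subsample of pairs is used.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param breaks distance-bin breakpoints in bp (left edge 0 is implied).
#' @param max_pairs pair budget before subsampling.
#' @param seed seed for the pair subsample.
#' @return data frame with bin label, mean r2 (NA for empty bins), and pair
#'   count per bin.
#' @export
ld_decay <- function(panel, breaks = c(1e4, 2.5e4, 5e4, 1e5, 2.5e5, 5e5),
                     max_pairs = 2e5, seed = 1L) {
  pos <- panel$sites$pos
  chrom <- panel$sites$chrom
  m <- length(pos)
  if (m < 2) stop("need at least 2 sites")
  max_d <- max(breaks)
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    hi <- findInterval(pos[idx] + max_d + 0.5, pos[idx])
    cnt <- hi - seq_along(idx)
    i_rep <- rep(seq_along(idx), cnt)
    j_off <- sequence(cnt)
    pairs_i <- c(pairs_i, idx[i_rep])
    pairs_j <- c(pairs_j, idx[i_rep + j_off])
  }
  if (length(pairs_i) > max_pairs) {
    pick <- withr::with_seed(seed,
                             sample.int(length(pairs_i), max_pairs))
    pairs_i <- pairs_i[pick]; pairs_j <- pairs_j[pick]
  }
  X <- panel$haps
  H <- nrow(X)
  p <- colMeans(X)
  r2 <- rep(NA_real_, length(pairs_i))
  chunk <- 20000L
  for (start in seq(1L, length(pairs_i), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(pairs_i))
    i <- pairs_i[sel]; j <- pairs_j[sel]
    pAB <- colMeans(X[, i, drop = FALSE] * X[, j, drop = FALSE])
    D <- pAB - p[i] * p[j]
    denom <- p[i] * (1 - p[i]) * p[j] * (1 - p[j])
    r2[sel] <- ifelse(denom > 0, D^2 / denom, NA_real_)
  }
  d <- abs(pos[pairs_j] - pos[pairs_i])
  bin <- cut(d, breaks = c(-0.5, breaks), right = TRUE)
  ok <- !is.na(r2)
  mean_r2 <- tapply(r2[ok], bin[ok], mean)
  n_pairs <- tapply(rep(1L, sum(ok)), bin[ok], sum)
  lev <- levels(bin)
  data.frame(bin = lev,
             upper_bp = breaks,
             mean_r2 = as.numeric(mean_r2[lev]),
             n_pairs = ifelse(is.na(n_pairs[lev]), 0L,
                              as.integer(n_pairs[lev])))
}
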