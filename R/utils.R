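#' herdimpute: array tagging and imputation accuracy for structured cattle
#' populations
#'
#' Simulates diverged/admixed cohorts, evaluates how well array designs tag
#' sequence variation (windowed LD r-squared), and measures imputation
#' accuracy (leave-one-out empirical R2 and masked-site dosage R2) under a
#' Li-Stephens haplotype-copying model.
#'
#' @keywords internal
"_PACKAGE"

# Complement map for SNV alleles; NA stays NA.
complement_allele <- function(a) {
  out <- c(A = "T", C = "G", G = "C", T = "A")[a]
  out[is.na(a)] <- NA_character_
  unname(out)
}

# Alleles that are their own strand-complement pair: A/T and C/G SNPs.
is_ambiguous_pair <- function(ref, alt) {
  !is.na(ref) & !is.na(alt) & complement_allele(ref) == alt
}

# Derive a stream-specific 32-bit seed from a master seed, so independent
# stochastic stages don't share RNG state.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stream) * 97) %%
               2147483647)
}

#' Default MAF bin breakpoints
#'
#' The conventional stratification for accuracy-by-frequency curves:
#' (0.01, 0.05], then bins of width 0.05 up to 0.5.
#'
#' @return numeric vector of bin breaks.
#' @export
default_maf_breaks <- function() c(0.01, seq(0.05, 0.5, by = 0.05))

#' Assign sites to MAF bins
#'
#' @param maf numeric vector of minor allele frequencies.
#' @param breaks bin breakpoints (left-open intervals).
#' @return factor of bin labels; MAF at or below the first break gives NA.
#' @export
maf_bin <- function(maf, breaks = default_maf_breaks()) {
  cut(maf, breaks = breaks, include.lowest = FALSE)
}

# Squared Pearson correlation with zero-variance guard; returns NA when
# either argument is constant (accuracy is undefined there, not zero).
squared_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# Draw random alleles A/C/G/T ref-alt pairs (distinct) for simulated sites.
draw_allele_pairs <- function(n) {
  ref <- sample(VALID_BASES, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- VALID_BASES[(match(ref, VALID_BASES) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}
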