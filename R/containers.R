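VALID_BASES <- c("A", "C", "G", "T")

#' Variant site table
#'
#' A data frame of biallelic SNV sites, sorted by chromosome and 1-based
#' position, with unique (chrom, pos, ref, alt) keys. This is the shared
#' site model used by haplotype panels, genotype matrices and manifests.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based base-pair positions.
#' @param id variant identifiers; defaults to \code{chrom:pos}.
#' @param ref,alt reference/alternate alleles (A/C/G/T); may be \code{NA}
#'   for records awaiting harmonization.
#' @param qual optional per-site quality scores.
#' @return a \code{variant_table} (data frame) sorted by (chrom, pos).
#' @export
variant_table <- function(chrom, pos, id = NULL, ref = NA_character_,
                          alt = NA_character_, qual = NA_real_) {
  n <- length(pos)
  chrom <- as.character(rep_len(chrom, n))
  pos <- as.integer(pos)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  tab <- data.frame(
    chrom = chrom, pos = pos, id = as.character(rep_len(id, n)),
    ref = as.character(rep_len(ref, n)), alt = as.character(rep_len(alt, n)),
    qual = as.numeric(rep_len(qual, n)),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(tab$ref) & !(tab$ref %in% VALID_BASES) |
    !is.na(tab$alt) & !(tab$alt %in% VALID_BASES)
  if (any(bad)) stop("non-SNV alleles in variant_table: rows ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  ord <- order(tab$chrom, tab$pos)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, ref, alt) keys")
  class(tab) <- c("variant_table", "data.frame")
  tab
}

#' Construct a phased haplotype panel
#'
#' Haplotypes are stored as a (2 * n_samples) x n_sites 0/1 matrix; rows
#' 2i - 1 and 2i hold the two phased haplotypes of sample i, columns align
#' with the rows of \code{sites}.
#'
#' @param sites a \code{\link{variant_table}}.
#' @param haps integer 0/1 matrix, haplotypes in rows, sites in columns.
#' @param sample_ids character vector, one per haplotype pair.
#' @param groups optional per-sample population/cohort labels.
#' @return a \code{haplotype_panel} object.
#' @export
haplotype_panel <- function(sites, haps, sample_ids = NULL, groups = NULL) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (ncol(haps) != nrow(sites))
    stop("haps has ", ncol(haps), " columns but sites has ", nrow(sites), " rows")
  if (nrow(haps) %% 2L != 0L) stop("haplotype count must be even (diploids)")
  n_sam <- nrow(haps) %/% 2L
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%d", seq_len(n_sam))
  if (length(sample_ids) != n_sam) stop("sample_ids length mismatch")
  if (!is.null(groups) && length(groups) != n_sam) stop("groups length mismatch")
  rng <- range(haps, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("haplotype alleles must be 0/1")
  structure(list(sites = sites, haps = haps,
                 sample_ids = as.character(sample_ids),
                 groups = if (is.null(groups)) NULL else as.character(groups)),
            class = "haplotype_panel")
}

#' Construct a diploid genotype matrix
#'
#' @param sites a \code{\link{variant_table}}.
#' @param geno n_samples x n_sites matrix of alternate-allele dosages in
#'   0/1/2, \code{NA} for missing calls.
#' @param sample_ids per-sample identifiers.
#' @param groups optional per-sample labels.
#' @param gq optional matrix of per-call genotype qualities (same shape).
#' @return a \code{genotype_matrix} object.
#' @export
genotype_matrix <- function(sites, geno, sample_ids = NULL, groups = NULL,
                            gq = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) != nrow(sites)) stop("geno/sites dimension mismatch")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%d", seq_len(nrow(geno)))
  if (length(sample_ids) != nrow(geno)) stop("sample_ids length mismatch")
  if (!is.null(groups) && length(groups) != nrow(geno)) stop("groups length mismatch")
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    if (!all(dim(gq) == dim(geno))) stop("gq/geno dimension mismatch")
  }
  rng <- suppressWarnings(range(geno, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("genotypes must be 0/1/2 or NA")
  structure(list(sites = sites, geno = geno,
                 sample_ids = as.character(sample_ids),
                 groups = if (is.null(groups)) NULL else as.character(groups),
                 gq = gq),
            class = "genotype_matrix")
}

#' Collapse a haplotype panel to diploid genotypes
#'
#' Sums each sample's two phased haplotypes site-wise.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @return a \code{\link{genotype_matrix}}.
#' @export
collapse_haplotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  odd <- seq(1L, nrow(panel$haps), by = 2L)
  geno <- panel$haps[odd, , drop = FALSE] + panel$haps[odd + 1L, , drop = FALSE]
  genotype_matrix(panel$sites, geno, panel$sample_ids, panel$groups)
}

#' Alternate-allele frequency of each site
#'
#' For a haplotype panel this is the mean allele over haplotypes; for a
#' genotype matrix the mean dosage / 2 over non-missing calls. Sites with
#' no usable calls get \code{NA}.
#'
#' @param x a \code{haplotype_panel} or \code{genotype_matrix}.
#' @return numeric vector of alt-allele frequencies, one per site.
#' @export
alt_freq <- function(x) {
  if (inherits(x, "haplotype_panel")) {
    colMeans(x$haps)
  } else if (inherits(x, "genotype_matrix")) {
    colMeans(x$geno, na.rm = TRUE) / 2
  } else stop("unsupported type")
}

#' Minor allele frequency of each site
#'
#' @inheritParams alt_freq
#' @return numeric vector; monomorphic sites give 0, sites with no data NA.
#' @export
site_maf <- function(x) {
  p <- alt_freq(x)
  pmin(p, 1 - p)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$haps), "haplotypes (",
      nrow(x$haps) %/% 2L, "samples ) x", ncol(x$haps), "sites\n")
  if (!is.null(x$groups)) {
    tb <- table(x$groups)
    cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "sites;",
      sum(is.na(x$geno)), "missing calls\n")
  invisible(x)
}

#' Subset sites of a panel or genotype matrix
#'
#' @param x panel or genotype matrix.
#' @param idx integer site indices (rows of \code{x$sites}) to keep, in
#'   genomic order.
#' @return object of the same class restricted to those sites.
#' @export
subset_sites <- function(x, idx) {
  idx <- as.integer(idx)
  if (inherits(x, "haplotype_panel")) {
    haplotype_panel(resubset_table(x$sites, idx), x$haps[, idx, drop = FALSE],
                    x$sample_ids, x$groups)
  } else if (inherits(x, "genotype_matrix")) {
    genotype_matrix(resubset_table(x$sites, idx), x$geno[, idx, drop = FALSE],
                    x$sample_ids, x$groups,
                    gq = if (is.null(x$gq)) NULL else x$gq[, idx, drop = FALSE])
  } else stop("unsupported type")
}

resubset_table <- function(sites, idx) {
  tab <- sites[idx, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("variant_table", "data.frame")
  tab
}

#' Subset samples of a panel or genotype matrix
#'
#' Haplotype pairs are kept together.
#'
#' @param x panel or genotype matrix.
#' @param keep integer or logical index over samples.
#' @return object of the same class.
#' @export
subset_samples <- function(x, keep) {
  if (is.logical(keep)) keep <- which(keep)
  keep <- as.integer(keep)
  if (inherits(x, "haplotype_panel")) {
    hap_rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
    haplotype_panel(x$sites, x$haps[hap_rows, , drop = FALSE],
                    x$sample_ids[keep],
                    if (is.null(x$groups)) NULL else x$groups[keep])
  } else if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$sites, x$geno[keep, , drop = FALSE], x$sample_ids[keep],
                    if (is.null(x$groups)) NULL else x$groups[keep],
                    gq = if (is.null(x$gq)) NULL else x$gq[keep, , drop = FALSE])
  } else stop("unsupported type")
}
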