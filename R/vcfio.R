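#' Read a VCF of biallelic SNVs
#'
#' Parses a VCF 4.x file (plain or gzipped) via \pkg{vcfR}. Multiallelic or
#' non-SNV records are skipped and counted. If every genotype call is phased
#' ("|" separator) and non-missing, the result is a phased
#' \code{\link{haplotype_panel}}; otherwise a \code{\link{genotype_matrix}}
#' with "./." mapped to missing. Per-call GQ is retained when present.
#'
#' @param path VCF file path.
#' @return list with \code{data} (panel or genotype matrix), \code{sites}
#'   (its \code{variant_table}) and \code{n_skipped} (records dropped as
#'   non-biallelic/non-SNV).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(ref) & !is.na(alt) & ref %in% VALID_BASES &
    alt %in% VALID_BASES
  n_skipped <- sum(!snv)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped, " non-biallelic/non-SNV records")
  if (!any(snv)) stop("no biallelic SNV records in ", path)
  keep <- which(snv)
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  sites <- variant_table(chrom = fix[keep, "CHROM"],
                         pos = as.integer(fix[keep, "POS"]),
                         id = fix[keep, "ID"],
                         ref = ref[keep], alt = alt[keep], qual = qual)
  # variant_table re-sorts; recover the permutation to align genotype rows
  ord <- order(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE][ord, , drop = FALSE]
  samples <- colnames(gt)
  phased <- all(grepl("|", gt, fixed = TRUE) & !grepl("\\.", gt))
  gq <- NULL
  if ("GQ" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
    gq <- t(gq[keep, , drop = FALSE][ord, , drop = FALSE])
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  if (phased) {
    m <- nrow(gt)
    H <- matrix(0L, 2L * length(samples), m)
    H[seq(1L, nrow(H), 2L), ] <- t(matrix(as.integer(a1), m))
    H[seq(2L, nrow(H), 2L), ] <- t(matrix(as.integer(a2), m))
    data <- haplotype_panel(sites, H, sample_ids = samples)
  } else {
    d1 <- suppressWarnings(as.integer(a1))
    d2 <- suppressWarnings(as.integer(a2))
    geno <- t(matrix(d1 + d2, nrow(gt)))
    data <- genotype_matrix(sites, geno, sample_ids = samples, gq = gq)
  }
  list(data = data, sites = sites, n_skipped = n_skipped)
}

#' Write a panel or genotype matrix as VCF 4.2
#'
#' Haplotype panels are written with phased GT ("|"); genotype matrices with
#' unphased GT ("/", "./." for missing) and a GQ FORMAT field when present.
#' A ".gz" path is written gzip-compressed.
#'
#' @param x a \code{\link{haplotype_panel}} or \code{\link{genotype_matrix}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_vcf <- function(x, path) {
  sites <- x$sites
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (inherits(x, "haplotype_panel")) {
    odd <- seq(1L, nrow(x$haps), by = 2L)
    body <- x$haps[odd, , drop = FALSE]
    body2 <- x$haps[odd + 1L, , drop = FALSE]
    calls <- matrix(paste0(body, "|", body2), nrow(body))
  } else if (inherits(x, "genotype_matrix")) {
    g <- x$geno
    call1 <- ifelse(is.na(g), ".", ifelse(g == 2L, "1", ifelse(g == 1L, "0", "0")))
    call2 <- ifelse(is.na(g), ".", ifelse(g >= 1L, "1", "0"))
    calls <- matrix(paste0(call1, "/", call2), nrow(g))
    if (!is.null(x$gq)) {
      header <- c(header,
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">")
      calls <- matrix(paste0(calls, ":", x$gq), nrow(g))
    }
  } else stop("unsupported type")
  fmt <- if (inherits(x, "genotype_matrix") && !is.null(x$gq)) "GT:GQ" else "GT"
  qual <- ifelse(is.na(sites$qual), ".", format(sites$qual, trim = TRUE))
  fixed <- paste(sites$chrom, sites$pos, sites$id, sites$ref, sites$alt,
                 qual, "PASS", ".", fmt, sep = "\t")
  gt_lines <- apply(calls, 2, paste, collapse = "\t")
  lines <- c(header,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$sample_ids), collapse = "\t"),
             paste(fixed, gt_lines, sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write imputed dosages as VCF
#'
#' Emits DS (posterior alternate-allele dosage) for every site and, at typed
#' sites, LDS (leave-one-out dosage).
#'
#' @param result an \code{imputation_result}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_imputed_vcf <- function(result, path) {
  sites <- result$sites
  m <- nrow(sites)
  ds <- formatC(t(result$dosage), digits = 4, format = "f")
  lds <- matrix(".", m, nrow(result$dosage))
  if (length(result$typed_idx))
    lds[result$typed_idx, ] <- formatC(t(result$loo_dosage), digits = 4,
                                       format = "f")
  calls <- matrix(paste0(ds, ":", lds), m)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed dosage\">",
    "##FORMAT=<ID=LDS,Number=1,Type=Float,Description=\"Leave-one-out dosage (typed sites)\">")
  fixed <- paste(sites$chrom, sites$pos, sites$id, sites$ref, sites$alt,
                 ".", "PASS",
                 ifelse(seq_len(m) %in% result$typed_idx, "TYPED", "IMPUTED"),
                 "DS:LDS", sep = "\t")
  lines <- c(header,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", result$sample_ids), collapse = "\t"),
             paste(fixed, apply(calls, 1, paste, collapse = "\t"), sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Match sites between two tables on (chrom, pos)
#'
#' Allele compatibility (swaps, strand flips) is resolved downstream by
#' \code{\link{reconcile_alleles}}; this is a pure positional join.
#'
#' @param a a \code{\link{variant_table}}.
#' @param b a \code{variant_table} or \code{array_manifest}.
#' @return data frame with aligned index vectors \code{idx_a}, \code{idx_b},
#'   in \code{a}'s order; zero rows when disjoint.
#' @export
intersect_sites <- function(a, b) {
  key_a <- paste(a$chrom, a$pos)
  key_b <- paste(b$chrom, b$pos)
  hit <- match(key_a, key_b)
  keep <- which(!is.na(hit))
  data.frame(idx_a = keep, idx_b = hit[keep])
}

#' Write a tabular report as CSV or JSON
#'
#' CSV output is RFC-4180 (quoted where needed) with a stable column order;
#' numeric columns are rounded to 6 significant digits.
#'
#' @param records a data frame.
#' @param path output path.
#' @param format "csv" or "json".
#' @return invisibly, the path.
#' @export
write_report <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], signif, digits = 6)
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite required for JSON reports")
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read an array manifest CSV
#'
#' Expected columns: id, chrom, pos, alleleA_top, alleleB_top, alleleA_fwd,
#' alleleB_fwd.
#'
#' @param path CSV path.
#' @return an \code{\link{array_manifest}}.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chrom = "character"))
  array_manifest(df)
}

#' Write an array manifest CSV
#'
#' @param manifest an \code{\link{array_manifest}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Read a coordinate remap table
#'
#' CSV with columns chrom_old, pos_old, chrom_new, pos_new and an optional
#' logical strand_flip column (default FALSE).
#'
#' @param path CSV path.
#' @return a \code{coordinate_map} data frame.
#' @export
read_coordinate_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chrom_old = "character",
                                       chrom_new = "character"))
  coordinate_map(df)
}

#' Coordinate map constructor / validator
#'
#' @param df data frame with chrom_old, pos_old, chrom_new, pos_new and
#'   optional strand_flip.
#' @return a \code{coordinate_map}; keys must be unique (injective map).
#' @export
coordinate_map <- function(df) {
  need <- c("chrom_old", "pos_old", "chrom_new", "pos_new")
  if (!all(need %in% names(df))) stop("coordinate map missing columns")
  if (is.null(df$strand_flip)) df$strand_flip <- FALSE
  if (anyDuplicated(paste(df$chrom_old, df$pos_old)))
    stop("coordinate map has duplicate source keys")
  class(df) <- c("coordinate_map", "data.frame")
  df
}
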