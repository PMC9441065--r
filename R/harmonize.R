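RECONCILE_CLASSES <- c("OK", "SWAPPED", "STRAND_FLIP", "SWAPPED_AND_FLIP",
                       "AMBIGUOUS_DISCARDED", "ABSENT_DISCARDED",
                       "NONBIALLELIC_DISCARDED")

#' Remap variant coordinates through a lookup table
#'
#' Table-driven analogue of an assembly liftover: mapped sites receive their
#' new (chrom, pos) and are re-sorted; rows flagged \code{strand_flip} get
#' both alleles complemented; unmapped sites are dropped and counted, and
#' when two inputs map to one output key the second (in input order) is
#' dropped as a collision.
#'
#' @param variants a \code{\link{variant_table}}.
#' @param map a \code{\link{coordinate_map}}.
#' @return list with \code{table} (remapped, sorted \code{variant_table}),
#'   \code{kept} (original row indices in the new order, for subsetting any
#'   aligned genotype matrix) and \code{dropped} (data frame of original
#'   index + reason).
#' @export
liftover <- function(variants, map) {
  key <- paste(variants$chrom, variants$pos)
  hit <- match(key, paste(map$chrom_old, map$pos_old))
  dropped <- data.frame(index = integer(0), reason = character(0))
  unmapped <- which(is.na(hit))
  if (length(unmapped))
    dropped <- rbind(dropped, data.frame(index = unmapped, reason = "unmapped"))
  mapped <- which(!is.na(hit))
  new_chrom <- map$chrom_new[hit[mapped]]
  new_pos <- map$pos_new[hit[mapped]]
  new_key <- paste(new_chrom, new_pos)
  dup <- duplicated(new_key)
  if (any(dup)) {
    dropped <- rbind(dropped,
                     data.frame(index = mapped[dup], reason = "collision"))
    message("liftover: ", sum(dup), " collision(s) dropped")
  }
  keep <- mapped[!dup]
  out <- variants[keep, , drop = FALSE]
  out$chrom <- new_chrom[!dup]
  out$pos <- as.integer(new_pos[!dup])
  flip <- map$strand_flip[hit[keep]]
  out$ref[flip] <- complement_allele(out$ref[flip])
  out$alt[flip] <- complement_allele(out$alt[flip])
  ord <- order(out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  list(table = out, kept = keep[ord], dropped = dropped)
}

#' Fill missing REF/ALT annotations from an array manifest
#'
#' Cross-references records (by id) against the manifest's allele coding
#' columns. A record with both alleles missing receives (alleleA, alleleB)
#' in the requested coding; a record with one allele present gets the other
#' member of the coded pair; complete records are untouched. Ids absent
#' from the manifest (or whose present allele contradicts the coded pair)
#' are left unfilled and flagged.
#'
#' @param records a \code{\link{variant_table}} possibly containing NA
#'   ref/alt.
#' @param manifest an \code{\link{array_manifest}}.
#' @param coding "forward" or "top" coding columns to consult.
#' @return list with \code{records} (filled table) and \code{flagged}
#'   (row indices left unresolved).
#' @export
fill_missing_alleles <- function(records, manifest,
                                 coding = c("forward", "top")) {
  coding <- match.arg(coding)
  a_col <- if (coding == "forward") "alleleA_fwd" else "alleleA_top"
  b_col <- if (coding == "forward") "alleleB_fwd" else "alleleB_top"
  hit <- match(records$id, manifest$id)
  flagged <- integer(0)
  for (i in which(is.na(records$ref) | is.na(records$alt))) {
    if (is.na(hit[i])) { flagged <- c(flagged, i); next }
    a <- manifest[[a_col]][hit[i]]
    b <- manifest[[b_col]][hit[i]]
    ref <- records$ref[i]; alt <- records$alt[i]
    if (is.na(ref) && is.na(alt)) {
      records$ref[i] <- a; records$alt[i] <- b
    } else if (is.na(alt)) {
      if (ref == a) records$alt[i] <- b
      else if (ref == b) records$alt[i] <- a
      else flagged <- c(flagged, i)
    } else {
      if (alt == a) records$ref[i] <- b
      else if (alt == b) records$ref[i] <- a
      else flagged <- c(flagged, i)
    }
  }
  list(records = records, flagged = flagged)
}

# Classify one query allele pair against a reference pair. Ambiguity (a
# pair equal to its own strand complement: A/T or C/G) is intrinsic to the
# query record and checked first; such sites are always discarded because a
# strand error there is undetectable from the alleles alone.
classify_pair <- function(q_ref, q_alt, r_ref, r_alt) {
  if (is.na(q_ref) || is.na(q_alt) ||
      !(q_ref %in% VALID_BASES) || !(q_alt %in% VALID_BASES) ||
      q_ref == q_alt)
    return("NONBIALLELIC_DISCARDED")
  if (is_ambiguous_pair(q_ref, q_alt)) return("AMBIGUOUS_DISCARDED")
  if (is.na(r_ref) || is.na(r_alt)) return("ABSENT_DISCARDED")
  qc_ref <- complement_allele(q_ref)
  qc_alt <- complement_allele(q_alt)
  if (q_ref == r_ref && q_alt == r_alt) "OK"
  else if (q_ref == r_alt && q_alt == r_ref) "SWAPPED"
  else if (qc_ref == r_ref && qc_alt == r_alt) "STRAND_FLIP"
  else if (qc_ref == r_alt && qc_alt == r_ref) "SWAPPED_AND_FLIP"
  else "NONBIALLELIC_DISCARDED"
}

#' Reconcile query alleles against a reference VCF's annotation
#'
#' Classifies every query record against the reference record at the same
#' (chrom, pos) key, corrects what can be fixed faithfully, and discards
#' what cannot:
#' \itemize{
#'   \item \code{OK}: alleles equal, nothing to do;
#'   \item \code{SWAPPED}: REF/ALT in reverse order; alleles reordered and
#'     genotypes recoded g to 2 - g (haplotype alleles a to 1 - a);
#'   \item \code{STRAND_FLIP}: alleles equal to the reference's complements;
#'     alleles complemented, genotypes unchanged;
#'   \item \code{SWAPPED_AND_FLIP}: both corrections applied;
#'   \item \code{AMBIGUOUS_DISCARDED}: A/T or C/G query pair, discarded
#'     regardless of match;
#'   \item \code{ABSENT_DISCARDED}: no reference record at the position;
#'   \item \code{NONBIALLELIC_DISCARDED}: anything else unresolvable.
#' }
#'
#' @param query a \code{\link{variant_table}}.
#' @param reference a \code{\link{variant_table}} with trusted annotation.
#' @param genotypes optional \code{\link{genotype_matrix}} or
#'   \code{\link{haplotype_panel}} aligned to \code{query} rows, recoded
#'   alongside.
#' @return list with \code{outcome} (per-record data frame: classification,
#'   corrected ref/alt, recode flag) and \code{corrected} (query table and
#'   genotypes restricted to non-discarded records, in reference allele
#'   order).
#' @export
reconcile_alleles <- function(query, reference, genotypes = NULL) {
  hit <- match(paste(query$chrom, query$pos),
               paste(reference$chrom, reference$pos))
  n <- nrow(query)
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- classify_pair(query$ref[i], query$alt[i],
                            if (is.na(hit[i])) NA_character_ else reference$ref[hit[i]],
                            if (is.na(hit[i])) NA_character_ else reference$alt[hit[i]])
  }
  corrected_ref <- rep(NA_character_, n)
  corrected_alt <- rep(NA_character_, n)
  keep <- cls %in% c("OK", "SWAPPED", "STRAND_FLIP", "SWAPPED_AND_FLIP")
  corrected_ref[keep] <- reference$ref[hit[keep]]
  corrected_alt[keep] <- reference$alt[hit[keep]]
  recode <- cls %in% c("SWAPPED", "SWAPPED_AND_FLIP")
  outcome <- data.frame(chrom = query$chrom, pos = query$pos, id = query$id,
                        classification = factor(cls, levels = RECONCILE_CLASSES),
                        corrected_ref = corrected_ref,
                        corrected_alt = corrected_alt,
                        genotype_recode = recode,
                        stringsAsFactors = FALSE)
  kept_idx <- which(keep)
  tab <- query[kept_idx, , drop = FALSE]
  tab$ref <- corrected_ref[kept_idx]
  tab$alt <- corrected_alt[kept_idx]
  rownames(tab) <- NULL
  class(tab) <- c("variant_table", "data.frame")
  gt_out <- NULL
  if (!is.null(genotypes)) {
    gt_out <- subset_sites(genotypes, kept_idx)
    flip_cols <- which(recode[kept_idx])
    if (length(flip_cols)) {
      if (inherits(gt_out, "haplotype_panel")) {
        gt_out$haps[, flip_cols] <- 1L - gt_out$haps[, flip_cols]
      } else {
        gt_out$geno[, flip_cols] <- 2L - gt_out$geno[, flip_cols]
      }
    }
    gt_out$sites <- tab
  }
  list(outcome = outcome, corrected = list(table = tab, genotypes = gt_out))
}
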