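test_that("identity coordinate maps leave variant tables unchanged", {
  tab <- variant_table("1", c(100L, 200L, 300L), ref = c("A", "C", "G"),
                       alt = c("G", "T", "A"))
  map <- coordinate_map(data.frame(chrom_old = "1", pos_old = tab$pos,
                                   chrom_new = "1", pos_new = tab$pos))
  out <- liftover(tab, map)
  expect_equal(as.data.frame(out$table), as.data.frame(tab))
  expect_equal(nrow(out$dropped), 0)
})

test_that("unmapped sites are dropped and counted; strand-flagged rows are complemented", {
  tab <- variant_table("1", c(100L, 200L, 300L, 400L, 500L),
                       ref = c("A", "C", "A", "G", "T"),
                       alt = c("G", "T", "G", "C", "C"))
  map <- coordinate_map(data.frame(
    chrom_old = "1", pos_old = c(100L, 300L, 500L),
    chrom_new = "2", pos_new = c(1100L, 1300L, 150L),
    strand_flip = c(FALSE, TRUE, FALSE)))
  out <- liftover(tab, map)
  expect_equal(nrow(out$table), 3)
  expect_equal(nrow(out$dropped), 2)
  expect_true(all(out$dropped$reason == "unmapped"))
  # remapped rows re-sorted by new position
  expect_equal(out$table$pos, c(150L, 1100L, 1300L))
  # the strand-flagged row (old pos 300, ref A alt G) becomes T/C
  row <- out$table[out$table$pos == 1300L, ]
  expect_equal(c(row$ref, row$alt), c("T", "C"))
  # kept indices let callers subset aligned matrices
  expect_equal(out$kept, c(5L, 1L, 3L))
})

test_that("colliding output coordinates keep the first input and log the second", {
  tab <- variant_table("1", c(100L, 200L), ref = "A", alt = c("G", "C"))
  map <- coordinate_map(data.frame(chrom_old = "1", pos_old = c(100L, 200L),
                                   chrom_new = "1", pos_new = c(900L, 900L)))
  expect_message(out <- liftover(tab, map), "collision")
  expect_equal(nrow(out$table), 1)
  expect_equal(out$dropped$reason, "collision")
})

test_that("missing allele annotations are filled from the manifest coding", {
  sites <- variant_table("1", c(100L, 200L, 300L),
                         id = c("v1", "v2", "v3"),
                         ref = c("A", "A", "C"),
                         alt = c("G", NA, NA))
  man <- herdimpute:::manifest_from_sites(
    variant_table("1", c(100L, 200L), id = c("v1", "v2"),
                  ref = c("A", "A"), alt = c("G", "G")))
  out <- fill_missing_alleles(sites, man, coding = "forward")
  expect_equal(out$records$alt[out$records$id == "v1"], "G")  # untouched
  expect_equal(out$records$alt[out$records$id == "v2"], "G")  # filled
  expect_true(3L %in% out$flagged)                            # absent id
  expect_true(is.na(out$records$alt[out$records$id == "v3"]))
})

test_that("reconcile_alleles reproduces the worked allele-inconsistency cases", {
  ref_tab <- variant_table("1", c(100L, 200L, 300L, 400L),
                           ref = c("A", "A", "A", "A"),
                           alt = c("G", "G", "T", "G"))
  q_tab <- variant_table("1", c(100L, 200L, 300L, 400L),
                         ref = c("A", "G", "A", "T"),
                         alt = c("G", "A", "T", "C"))
  g <- make_gm(matrix(c(1L, 2L, 0L, 1L), nrow = 1),
               pos = c(100L, 200L, 300L, 400L))
  out <- reconcile_alleles(q_tab, ref_tab, g)
  cls <- as.character(out$outcome$classification)
  expect_equal(cls, c("OK", "SWAPPED", "AMBIGUOUS_DISCARDED", "STRAND_FLIP"))
  corr <- out$corrected$genotypes$geno
  expect_equal(corr[1, ], c(1L, 0L, 1L))  # swapped site recoded 2 -> 0
  expect_equal(out$corrected$table$ref, c("A", "A", "A"))
  expect_equal(out$corrected$table$alt, c("G", "G", "G"))
})

test_that("classification matches a brute-force classifier over the exhaustive pair cross", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(q_ref = bases, q_alt = bases,
                       r_ref = bases, r_alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$q_ref != pairs$q_alt & pairs$r_ref != pairs$r_alt, ]
  for (i in seq_len(nrow(pairs))) {
    got <- herdimpute:::classify_pair(pairs$q_ref[i], pairs$q_alt[i],
                                      pairs$r_ref[i], pairs$r_alt[i])
    want <- oracle_classify(pairs$q_ref[i], pairs$q_alt[i],
                            pairs$r_ref[i], pairs$r_alt[i])
    expect_identical(got, want)
  }
  # absent-in-reference and malformed query records
  expect_identical(herdimpute:::classify_pair("A", "G", NA, NA),
                   oracle_classify("A", "G", NA, NA))
  expect_identical(herdimpute:::classify_pair("A", "A", "A", "G"),
                   "NONBIALLELIC_DISCARDED")
})

test_that("reconciling an already-corrected dataset is a no-op (all OK)", {
  ref_tab <- variant_table("1", c(100L, 200L, 400L),
                           ref = c("A", "A", "A"), alt = c("G", "G", "G"))
  q_tab <- variant_table("1", c(100L, 200L, 400L),
                         ref = c("G", "T", "A"), alt = c("A", "C", "G"))
  g <- make_gm(matrix(c(2L, 1L, 0L, 0L, 2L, 1L), nrow = 2),
               pos = c(100L, 200L, 400L))
  first <- reconcile_alleles(q_tab, ref_tab, g)
  second <- reconcile_alleles(first$corrected$table, ref_tab,
                              first$corrected$genotypes)
  expect_true(all(second$outcome$classification == "OK"))
  expect_identical(second$corrected$genotypes$geno,
                   first$corrected$genotypes$geno)
})

test_that("SWAPPED correction flips the alternate-allele frequency to its complement", {
  set.seed(30)
  g <- matrix(rbinom(40, 2, 0.3), ncol = 2)
  gm <- make_gm(g, pos = c(100L, 200L))
  q_tab <- variant_table("1", c(100L, 200L), ref = c("G", "C"),
                         alt = c("A", "A"))
  ref_tab <- variant_table("1", c(100L, 200L), ref = c("A", "A"),
                           alt = c("G", "C"))
  before <- colMeans(g) / 2
  out <- reconcile_alleles(q_tab, ref_tab, gm)
  expect_true(all(out$outcome$classification == "SWAPPED"))
  after <- colMeans(out$corrected$genotypes$geno) / 2
  expect_equal(after, 1 - before)
})

test_that("haplotype panels are recoded consistently on swapped sites", {
  H <- matrix(c(1L, 0L, 1L, 1L), nrow = 2)
  panel <- make_panel(H, pos = c(100L, 200L))
  q_tab <- variant_table("1", c(100L, 200L), ref = c("G", "A"),
                         alt = c("A", "G"))
  ref_tab <- variant_table("1", c(100L, 200L), ref = c("A", "A"),
                           alt = c("G", "G"))
  out <- reconcile_alleles(q_tab, ref_tab, panel)
  expect_equal(out$corrected$genotypes$haps[, 1], 1L - H[, 1])
  expect_equal(out$corrected$genotypes$haps[, 2], H[, 2])
})
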