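# A compact hand-built annotation: one coding gene with UTRs, one
# non-coding gene, on a 100 kb chromosome.
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gNC"),
    chrom = "chr1",
    start = c(10000, 60000), end = c(25000, 65000),
    strand = "+", stringsAsFactors = FALSE)
  features <- rbind(
    data.frame(gene_id = "gA", type = "exon",
               start = c(10000, 15000, 22000), end = c(12000, 17000, 25000)),
    data.frame(gene_id = "gA", type = "five_prime_UTR", start = 10000, end = 10500),
    data.frame(gene_id = "gA", type = "CDS",
               start = c(10500, 15000, 22000), end = c(12000, 17000, 23000)),
    data.frame(gene_id = "gA", type = "three_prime_UTR", start = 23000, end = 25000),
    data.frame(gene_id = "gNC", type = "exon", start = 60000, end = 65000))
  gene_annotation(genes, features)
}

toy_table <- function(pos, ref = "A", alt = "T",
                      dwarf = c(5L, 15L), other = c(15L, 5L)) {
  n <- length(pos)
  variant_table(
    data.frame(chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt),
    ref_counts = cbind(dw = rep(dwarf[1], n), nd = rep(other[1], n)),
    alt_counts = cbind(dw = rep(dwarf[2], n), nd = rep(other[2], n)))
}

toy_labels <- group_labels(c("dw", "nd"), c("dwarf", "non_dwarf"))

test_that("consequence classes follow the CDS > UTR > intron > intergenic priority", {
  ann <- toy_annotation()
  tbl <- toy_table(c(10250, 11000, 16000, 24000, 13000, 62000, 90000))
  cls <- classify_consequence(tbl, ann)
  expect_equal(cls$consequence,
               c("utr5", "cds_snv", "cds_snv", "utr3", "intron",
                 "noncoding_transcript", "intergenic"))
  expect_equal(cls$gene_id[1:6], c(rep("gA", 5), "gNC"))
  expect_true(is.na(cls$gene_id[7]))
})

test_that("CDS indels are frameshift iff their length is not a multiple of 3", {
  ann <- toy_annotation()
  ins1 <- variant_table(
    data.frame(chrom = "chr1", pos = c(11000L, 11010L, 11020L),
               ref = c("A", "A", "AT"),
               alt = c("AT", "ATTT", "A")),
    ref_counts = cbind(dw = rep(5L, 3)), alt_counts = cbind(dw = rep(5L, 3)))
  cls <- classify_consequence(ins1, ann)
  expect_equal(cls$consequence,
               c("cds_frameshift_indel", "cds_inframe_indel",
                 "cds_frameshift_indel"))
})

test_that("unknown chromosomes classify as intergenic with a warning", {
  tbl <- toy_table(5000)
  tbl$sites$chrom <- "chrZ"
  expect_warning(cls <- classify_consequence(tbl, toy_annotation()), "absent")
  expect_equal(cls$consequence, "intergenic")
})

test_that("the prioritisation filter is strict at the frequency boundary", {
  ann <- toy_annotation()
  regions <- data.frame(chrom = "chr1", core_start = 0, core_end = 50000,
                        ext_start = 0, ext_end = 50000, peak_value = 0.5,
                        n_windows = 1L)
  # dwarf AAF exactly 0.45 -> dropped; 0.46 -> retained
  at <- toy_table(11000, dwarf = c(55L, 45L))
  expect_equal(nrow(prioritize_variants(at, regions, toy_labels, ann)), 0)
  above <- toy_table(11000, dwarf = c(54L, 46L))
  pv <- prioritize_variants(above, regions, toy_labels, ann)
  expect_equal(nrow(pv), 1)
  expect_equal(pv$consequence, "cds_snv")
  expect_equal(pv$aaf_dwarf, 0.46)
  # intronic variant with high AAF is dropped
  intron <- toy_table(13000, dwarf = c(1L, 19L))
  expect_equal(nrow(prioritize_variants(intron, regions, toy_labels, ann)), 0)
  # exonic, high AAF, but outside the region -> dropped
  out_reg <- transform(regions, ext_end = 10500, core_end = 10500)
  expect_equal(nrow(prioritize_variants(above, out_reg, toy_labels, ann)), 0)
})

test_that("private and fixed flags use read-count frequencies exactly", {
  f <- private_fixed_flags(list(ref = 0, alt = 12),
                           list(list(ref = 10, alt = 0)))
  expect_true(f$private && f$fixed)
  f2 <- private_fixed_flags(list(ref = 4, alt = 8),
                            list(list(ref = 10, alt = 0)))
  expect_true(f2$private); expect_false(f2$fixed)
  f3 <- private_fixed_flags(list(ref = 0, alt = 12),
                            list(list(ref = 19, alt = 1)))
  expect_false(f3$private); expect_true(f3$fixed)
  # zero target depth -> flags undefined
  f4 <- private_fixed_flags(list(ref = 0, alt = 0),
                            list(list(ref = 1, alt = 1)))
  expect_true(is.na(f4$private) && is.na(f4$fixed))
  # tolerance flag admits one stray read when enabled
  f5 <- private_fixed_flags(list(ref = 1, alt = 99), list(), fixed_tol = 0.02)
  expect_true(f5$fixed)
})

test_that("prioritisation equals an independent brute-force filter on synthetic data", {
  sim <- tiny_sim()
  tbl <- subset_sites(sim$table, seq_len(1000))
  # the 1000-site subset spans roughly the first 0.8 Mb of chr1
  regions <- data.frame(chrom = "chr1",
                        core_start = 1e5, core_end = 4e5,
                        ext_start = 0, ext_end = 5.25e5,
                        peak_value = 0.5, n_windows = 2L)
  class(regions) <- c("sweep_regions", class(regions))
  pv <- prioritize_variants(tbl, regions, sim$labels, sim$annotation)
  got <- paste(pv$chrom, pv$pos, pv$alt)
  want <- oracle_prioritize_keys(tbl, regions, sim$labels, sim$annotation)
  expect_setequal(got, want)
  expect_gt(nrow(pv), 0)
  # every retained variant lies inside an extended region
  ok <- mapply(function(ch, p) any(regions$chrom == ch &
                                     p - 1 >= regions$ext_start &
                                     p - 1 < regions$ext_end),
               pv$chrom, pv$pos)
  expect_true(all(ok))
  # raising the threshold never enlarges the retained set
  stricter <- prioritize_variants(tbl, regions, sim$labels, sim$annotation,
                                  threshold = 0.8)
  expect_true(all(paste(stricter$chrom, stricter$pos, stricter$alt) %in% got))
})
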