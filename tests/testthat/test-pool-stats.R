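test_that("allele frequencies follow the read-count definition", {
  expect_equal(allele_frequency(10, 10), 0.5)
  expect_equal(allele_frequency(0, 7), 1)
  expect_equal(allele_frequency(30, 10), 0.25)
  expect_true(is.na(allele_frequency(0, 0)))
  expect_error(allele_frequency(-1, 5))
})

test_that("genotype-based allele frequency matches gene counting", {
  expect_equal(genotype_allele_frequency(2, 0, 14), 1 / 14)
  expect_equal(genotype_allele_frequency(0, 0, 14), 0)
  expect_equal(genotype_allele_frequency(0, 14, 14), 1)
  expect_error(genotype_allele_frequency(1, 0, 0))
  expect_error(genotype_allele_frequency(10, 8, 14), "exceed")
})

test_that("Karlsson FST matches hand-evaluated configurations", {
  # differentially fixed pools: within-heterozygosities 0, between 1
  expect_equal(fst_karlsson(0, 20, 15, 0), 1)
  # h1 = 72/380, h2 = 150/380, hb = 0.7
  expect_equal(fst_karlsson(2, 18, 15, 5), 1 - (222 / 380) / 1.4)
  # identical pools: unbiased estimator is slightly negative, -1/19
  expect_equal(fst_karlsson(10, 10, 10, 10), -1 / 19)
  # undefined cases: same-allele fixation, depth below 2
  expect_true(is.na(fst_karlsson(10, 0, 8, 0)))
  expect_true(is.na(fst_karlsson(1, 0, 5, 5)))
})

test_that("Karlsson FST is symmetric and monotone in frequency difference", {
  set.seed(4)
  for (i in 1:50) {
    c1 <- rmultinom(1, sample(2:40, 1), c(0.5, 0.5))
    c2 <- rmultinom(1, sample(2:40, 1), c(0.3, 0.7))
    expect_identical(fst_karlsson(c1[1], c1[2], c2[1], c2[2]),
                     fst_karlsson(c2[1], c2[2], c1[1], c1[2]))
  }
  # exact-count grid at depth 20: fixing pool 1 at its median configuration,
  # FST is non-decreasing as pool 2 moves away in allele frequency
  f <- fst_karlsson(10, 10, 20 - (10:20), 10:20)
  expect_true(all(diff(f) >= 0))
})

test_that("FST is centred at zero for identical population frequencies", {
  set.seed(42)
  p <- runif(1e4, 0.05, 0.95)
  a1 <- rbinom(1e4, 1000, p); a2 <- rbinom(1e4, 1000, p)
  f <- fst_karlsson(1000 - a1, a1, 1000 - a2, a2)
  expect_lt(abs(mean(f, na.rm = TRUE)), 0.01)
})

test_that("site inclusion follows the combined-segregation rule", {
  expect_false(site_is_informative(10, 0, 8, 0))
  expect_true(site_is_informative(10, 0, 0, 12))   # differentially fixed
  expect_true(site_is_informative(5, 5, 10, 0))
  expect_false(site_is_informative(0, 0, 5, 5))    # zero depth in one pool
  # the stricter within-population reading drops differentially fixed sites
  expect_false(site_is_informative(10, 0, 0, 12, rule = "within"))
  expect_true(site_is_informative(5, 5, 10, 0, rule = "within"))
})

test_that("group counts aggregate by summation and preserve frequencies", {
  tbl <- variant_table(
    data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T"),
    ref_counts = cbind(p1 = c(3L, 4L), p2 = c(5L, 4L), p3 = c(2L, 4L)),
    alt_counts = cbind(p1 = c(7L, 1L), p2 = c(5L, 1L), p3 = c(9L, 1L)))
  lab <- group_labels(c("p1", "p2", "p3"), c("dwarf", "dwarf", "non_dwarf"))
  cc <- combine_group_counts(tbl, lab, "dwarf")
  expect_equal(cc$ref, c(8L, 8L))
  expect_equal(cc$alt, c(12L, 2L))
  single <- combine_group_counts(tbl, lab, "non_dwarf")
  expect_equal(single$ref, tbl$ref_counts[, "p3"], ignore_attr = TRUE)
  # k identical pools leave the frequency unchanged
  expect_equal(allele_frequency(cc$ref, cc$alt)[2],
               allele_frequency(4, 1))
  expect_error(combine_group_counts(tbl, lab, "wilderness"), "unknown")
})

test_that("site_fst_table flags non-informative sites as NA", {
  tbl <- variant_table(
    data.frame(chrom = "chr1", pos = c(1L, 2L, 3L, 4L), ref = "A", alt = "T"),
    ref_counts = cbind(p1 = c(10L, 10L, 0L, 1L), p2 = c(10L, 8L, 15L, 10L)),
    alt_counts = cbind(p1 = c(10L, 0L, 20L, 0L), p2 = c(10L, 0L, 0L, 10L)))
  sf <- site_fst_table(tbl, "p1", "p2")
  expect_s3_class(sf, "site_fst")
  expect_equal(sf$informative, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(sf$fst[3], 1)
  expect_true(all(is.na(sf$fst[!sf$informative])))
})
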