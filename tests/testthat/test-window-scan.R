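test_that("window tiling partitions each chromosome, with a terminal stub", {
  w <- tile_windows(c(chrA = 625000))
  expect_equal(w$start, c(0, 250000, 500000))
  expect_equal(w$end, c(250000, 500000, 625000))
  w2 <- tile_windows(c(a = 300000, b = 500000))
  expect_equal(nrow(w2), 4)
  # partition property: disjoint, ordered, covering
  for (ch in c("a", "b")) {
    wc <- w2[w2$chrom == ch, ]
    expect_equal(wc$start[-1], wc$end[-nrow(wc)])
    expect_equal(min(wc$start), 0)
  }
  expect_error(tile_windows(c(100, 200)), "named")
})

test_that("window mean FST averages informative sites under the strict count rule", {
  w <- tile_windows(c(chr1 = 500000))
  mk_sf <- function(n, fst) {
    df <- data.frame(chrom = "chr1", pos = seq_len(n), fst = fst,
                     informative = TRUE)
    class(df) <- c("site_fst", class(df))
    df
  }
  # exactly 200 informative sites -> dropped; 201 -> kept
  expect_false(window_mean_fst(mk_sf(200, 0.5), w)$kept[1])
  expect_true(window_mean_fst(mk_sf(201, 0.5), w)$kept[1])
  # all-1 window averages to 1; simple mean check
  expect_equal(window_mean_fst(mk_sf(300, 1), w)$value[1], 1)
  ws <- window_mean_fst(mk_sf(3, c(0.2, 0.4, 0.9)), w, min_variants = 2)
  expect_equal(ws$value[1], 0.5)
  expect_true(ws$kept[1])
  # non-informative sites do not count
  sf <- mk_sf(300, 0.4); sf$informative[1:150] <- FALSE
  expect_equal(window_mean_fst(sf, w)$n_variants[1], 150)
})

test_that("pooled heterozygosity follows the major/minor count formula and its bounds", {
  w <- tile_windows(c(chr1 = 250000))
  tbl1 <- variant_table(
    data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "T"),
    ref_counts = cbind(p1 = 5L), alt_counts = cbind(p1 = 5L))
  expect_equal(window_hp(tbl1, "p1", w, min_variants = 0)$value[1], 0.5)
  tbl2 <- variant_table(
    data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T"),
    ref_counts = cbind(p1 = c(8L, 4L)), alt_counts = cbind(p1 = c(2L, 6L)))
  expect_equal(window_hp(tbl2, "p1", w, min_variants = 0)$value[1],
               2 * 14 * 6 / 400)
  # swapping ref/alt labels site-by-site leaves Hp unchanged
  tbl2s <- variant_table(tbl2$sites, tbl2$alt_counts, tbl2$ref_counts)
  expect_equal(window_hp(tbl2s, "p1", w, min_variants = 0)$value,
               window_hp(tbl2, "p1", w, min_variants = 0)$value)
  # monomorphic windows have Hp = 0; Hp never exceeds 0.5
  tbl3 <- variant_table(
    data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T"),
    ref_counts = cbind(p1 = c(9L, 7L)), alt_counts = cbind(p1 = c(0L, 0L)))
  expect_equal(window_hp(tbl3, "p1", w, min_variants = 0)$value[1], 0)
  sim <- tiny_sim()
  wt <- tile_windows(sim$truth$chrom_sizes)
  hp <- window_hp(sim$table, "dwarf", wt, labels = sim$labels)
  expect_true(all(hp$value >= 0 & hp$value <= 0.5, na.rm = TRUE))
})

test_that("percentile outlier selection returns round(N(1-q)) extreme windows", {
  mk_stats <- function(values) {
    n <- length(values)
    df <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 250000,
                     end = seq_len(n) * 250000, index = seq_len(n),
                     n_variants = 300L, value = values, kept = TRUE)
    class(df) <- c("window_stats", "data.frame")
    attr(df, "window_size") <- 250000
    df
  }
  set.seed(8)
  vals <- sample(seq(0, 1, length.out = 1000))
  out <- select_outliers(mk_stats(vals), 0.995)
  expect_equal(nrow(out), 5)
  expect_setequal(out$value, sort(vals, decreasing = TRUE)[1:5])
  low <- select_outliers(mk_stats(vals), 0.995, tail = "lower")
  expect_setequal(low$value, sort(vals)[1:5])
  # invariant to input ordering
  shuffled <- mk_stats(vals)[sample(1000), ]
  attr(shuffled, "window_size") <- 250000
  expect_equal(select_outliers(shuffled, 0.995)$index, out$index)
  # k = 0 warns and returns nothing
  expect_warning(none <- select_outliers(mk_stats(vals[1:50]), 0.995), "zero")
  expect_equal(nrow(none), 0)
  # ties at the cut resolve by genomic position
  tied <- mk_stats(c(rep(1, 10), rep(0, 990)))
  top <- select_outliers(tied, 0.995)
  expect_equal(top$start, (0:4) * 250000)
})

test_that("touching outlier windows merge; regions extend 125 kb with clamping", {
  mk <- function(chrom, starts) {
    df <- data.frame(chrom = chrom, start = starts, end = starts + 250000,
                     index = seq_along(starts), n_variants = 300L,
                     value = seq(0.5, by = 0.1, length.out = length(starts)),
                     kept = TRUE)
    class(df) <- c("window_stats", "data.frame")
    attr(df, "window_size") <- 250000
    df
  }
  sizes <- c(chr2 = 5e7)
  reg <- merge_and_extend(mk("chr2", c(500000, 750000, 1000000)), sizes)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$core_start, 500000)
  expect_equal(reg$core_end, 1250000)
  expect_equal(reg$n_windows, 3L)
  expect_equal(reg$peak_value, 0.7)
  expect_equal(reg$ext_start, 375000)
  single <- merge_and_extend(mk("chr2", 3250000), sizes)
  expect_equal(c(single$ext_start, single$ext_end), c(3125000, 3625000))
  clamped <- merge_and_extend(mk("chr2", 0), sizes)
  expect_equal(clamped$ext_start, 0)
  # a gap of one non-outlier window keeps regions separate
  gap <- merge_and_extend(mk("chr2", c(0, 500000)), sizes)
  expect_equal(nrow(gap), 2)
})

test_that("contrast comparison counts novel windows by exact identity", {
  mk <- function(starts) {
    df <- data.frame(chrom = "chr1", start = starts, end = starts + 250000,
                     index = seq_along(starts), n_variants = 300L,
                     value = 0.5, kept = TRUE)
    class(df) <- c("window_stats", "data.frame")
    attr(df, "window_size") <- 250000
    df
  }
  A <- mk((0:20) * 250000)
  B <- mk((13:40) * 250000)  # shares 8 of A's windows? no: shares 21-13 = 8
  cmp <- compare_contrasts(A, B)
  expect_equal(cmp$n_A, 21)
  expect_equal(cmp$n_novel, 13)
  expect_equal(compare_contrasts(A, A)$novel_percent, 0)
  expect_equal(compare_contrasts(A, mk(100:110 * 250000 + 1))$novel_percent, 100)
  wrong <- mk(0); attr(wrong, "window_size") <- 100000
  expect_error(compare_contrasts(A, wrong), "tilings")
})

test_that("planted sweeps depress dwarf-group Hp: lower-tail outliers are sweep-enriched", {
  rs <- recovery_scan()
  hp <- window_hp(rs$sim$table, "dwarf", rs$windows, labels = rs$sim$labels)
  hpo <- select_outliers(hp, 0.995, tail = "lower")
  sweep_keys <- window_key(hp[windows_in_sweeps(hp, rs$sim$truth$sweeps), ])
  n_hit <- sum(window_key(hpo) %in% sweep_keys)
  kept <- sum(hp$kept)
  tab <- matrix(c(n_hit, nrow(hpo) - n_hit,
                  length(sweep_keys) - n_hit,
                  kept - length(sweep_keys) - (nrow(hpo) - n_hit)), 2)
  expect_lt(stats::fisher.test(tab, alternative = "greater")$p.value, 0.01)
  expect_lt(mean(hp$value[windows_in_sweeps(hp, rs$sim$truth$sweeps)], na.rm = TRUE),
            mean(hp$value[!windows_in_sweeps(hp, rs$sim$truth$sweeps)], na.rm = TRUE))
})
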