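# Independent oracles and shared fixtures for the test suite.

# Brute-force Karlsson FST: build the explicit read-allele vectors and count
# allele-pair mismatches by enumeration, rather than using the closed form.
oracle_fst <- function(ref1, alt1, ref2, alt2) {
  x1 <- c(rep(0L, ref1), rep(1L, alt1))
  x2 <- c(rep(0L, ref2), rep(1L, alt2))
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  pairs_h <- function(x) {
    cmp <- outer(x, x, "!=")
    sum(cmp[upper.tri(cmp)]) / choose(length(x), 2)
  }
  hb <- mean(outer(x1, x2, "!="))
  if (hb == 0) return(NA_real_)
  1 - (pairs_h(x1) + pairs_h(x2)) / (2 * hb)
}

# Exhaustive hypergeometric upper tail by enumerating all draws of size m
# from a labelled universe of size M (feasible for M <= 15).
oracle_hyper_tail <- function(M, K, m, k) {
  draws <- utils::combn(M, m)
  hits <- colSums(draws <= K)  # first K elements are the term genes
  mean(hits >= k)
}

# Step-up BH by direct application of the definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  ranked <- p[ord]
  for (i in seq_len(n))
    adj[i] <- min(1, min(ranked[i:n] * n / (i:n)))
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Brute-force prioritisation filter: per-variant loop over regions, feature
# intervals and group frequencies, independent of the vectorised path.
oracle_prioritize_keys <- function(table, regions, labels, ann,
                                   target_groups = "dwarf",
                                   threshold = 0.45) {
  keep <- character()
  exonic_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  for (i in seq_len(n_sites(table))) {
    chrom <- table$sites$chrom[i]; pos <- table$sites$pos[i]
    in_reg <- FALSE
    for (r in seq_len(nrow(regions)))
      if (regions$chrom[r] == chrom && pos - 1 >= regions$ext_start[r] &&
          pos - 1 < regions$ext_end[r]) in_reg <- TRUE
    if (!in_reg) next
    exonic <- FALSE
    for (f in seq_len(nrow(ann$features))) {
      if (ann$features$type[f] == "exon") next  # exon of coding gene != CDS/UTR
      g <- ann$genes[ann$genes$gene_id == ann$features$gene_id[f], ]
      if (g$chrom == chrom && pos - 1 >= ann$features$start[f] &&
          pos - 1 < ann$features$end[f]) exonic <- TRUE
    }
    # exons of non-coding genes do not count as exon-including-UTR overlap
    if (!exonic) next
    pass <- FALSE
    for (g in target_groups) {
      pools <- labels$pool[labels$group == g]
      idx <- match(pools, pool_ids(table))
      ref <- sum(table$ref_counts[i, idx]); alt <- sum(table$alt_counts[i, idx])
      if (ref + alt > 0 && alt / (ref + alt) > threshold) pass <- TRUE
    }
    if (pass) keep <- c(keep, paste(chrom, pos, table$sites$alt[i]))
  }
  keep
}

# --- cached simulations (shared across test files) -----------------------
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

tiny_sim <- function() cached("tiny", simulate_pool_experiment(tiny_config()))

tiny_config <- function(seed = 3,
                        sweep_regions = data.frame(chrom = c("chr1", "chr2"),
                                                   start = c(1e6, 2.5e6),
                                                   end = c(1.5e6, 3e6),
                                                   divergence_shift = 0.8),
                        ...)
  sim_config(n_chromosomes = 2, chrom_length = 5e6,
             n_pools_per_group = c(dwarf = 2, non_dwarf = 2, wild = 1),
             sweep_regions = sweep_regions, seed = seed, ...)

# The "recovery" study: a genome large enough that the 99.5th-percentile cut
# selects more windows than are planted (1000 windows, 4 planted).
recovery_config <- function(seed = 11)
  sim_config(n_chromosomes = 2, chrom_length = 125e6,
             n_pools_per_group = c(dwarf = 2, non_dwarf = 3, wild = 0),
             pool_size = 14, mean_depth = 15,
             sweep_regions = data.frame(
               chrom = c("chr1", "chr2"), start = c(30e6, 80e6),
               end = c(30.5e6, 80.5e6), divergence_shift = 0.8),
             seed = seed)

recovery_sim <- function() cached("recovery",
                                  simulate_pool_experiment(recovery_config()))

recovery_scan <- function() cached("recovery_scan", {
  sim <- recovery_sim()
  w <- tile_windows(sim$truth$chrom_sizes)
  sf <- site_fst_table(sim$table, "dwarf", "non_dwarf", labels = sim$labels)
  ws <- window_mean_fst(sf, w)
  list(sim = sim, windows = w, site_fst = sf, window_fst = ws,
       outliers = select_outliers(ws, 0.995),
       sweep_mask = windows_in_sweeps(ws, sim$truth$sweeps))
})

window_key <- function(x) paste(x$chrom, x$start)
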