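#' Pool allele frequency from read depths
#'
#' The alternative-allele frequency of a pool is the number of reads
#' supporting the alternative allele divided by the total read depth at the
#' site. Zero-depth sites yield `NA` (the site is excluded downstream), not
#' an error.
#'
#' @param ref,alt non-negative read counts (vectors recycle).
#' @return numeric vector of alt-allele frequencies in `[0, 1]`, `NA` where
#'   `ref + alt == 0`.
#' @examples
#' allele_frequency(10, 10)  # 0.5
#' allele_frequency(30, 10)  # 0.25
#' @export
allele_frequency <- function(ref, alt) {
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  n <- ref + alt
  ifelse(n > 0, alt / n, NA_real_)
}

#' Allele frequency from individual genotype counts
#'
#' For individually genotyped animals (e.g. a PCR assay for a deletion
#' allele), the allele frequency is the usual gene-counting estimate:
#' heterozygotes carry one copy, homozygous alternative animals two.
#'
#' @param n_het number of heterozygous carriers.
#' @param n_hom_alt number of animals homozygous for the alternative allele.
#' @param n_individuals total animals genotyped.
#' @return allele frequency `(n_het + 2 n_hom_alt) / (2 n_individuals)`.
#' @examples
#' # two heterozygous carriers among 14 animals: ~7%
#' genotype_allele_frequency(2, 0, 14)
#' @export
genotype_allele_frequency <- function(n_het, n_hom_alt, n_individuals) {
  if (any(n_individuals <= 0)) stop("n_individuals must be positive")
  if (any(n_het < 0) || any(n_hom_alt < 0)) stop("genotype counts must be non-negative")
  if (any(n_het + n_hom_alt > n_individuals))
    stop("carrier counts exceed the number of individuals")
  (n_het + 2 * n_hom_alt) / (2 * n_individuals)
}

#' Karlsson per-SNP FST from two pools' read depths
#'
#' Unbiased allele-count estimator of the per-site fixation index between two
#' populations, with sequencing reads treated as sampled alleles. With alt
#' and ref counts \eqn{a_j, r_j} and depth \eqn{N_j = a_j + r_j} in pool
#' \eqn{j}, the unbiased within-pool heterozygosity is
#' \eqn{h_j = 2 a_j r_j / (N_j (N_j - 1))}, the between-pool heterozygosity
#' is \eqn{h_b = (a_1 r_2 + r_1 a_2)/(N_1 N_2)}, and
#' \deqn{F_{ST} = 1 - (h_1 + h_2) / (2 h_b).}
#'
#' The estimator is symmetric in pool order, equals 1 exactly when the pools
#' are fixed for different alleles, can be slightly negative when the pools
#' have near-identical frequencies, and is undefined (`NA`) when
#' \eqn{h_b = 0} (both pools fixed for the same allele) or when either depth
#' is below 2 (the unbiased divisor \eqn{N_j(N_j-1)} needs at least two
#' reads). Negative values are deliberately not clipped: clipping would bias
#' window means upward.
#'
#' @param ref1,alt1 read counts in the first pool (vectors recycle).
#' @param ref2,alt2 read counts in the second pool.
#' @return numeric vector of per-site FST values (`NA` where undefined).
#' @examples
#' fst_karlsson(0, 20, 15, 0)   # fixed difference: exactly 1
#' fst_karlsson(10, 10, 10, 10) # identical pools: slightly negative
#' @export
fst_karlsson <- function(ref1, alt1, ref2, alt2) {
  n1 <- ref1 + alt1
  n2 <- ref2 + alt2
  hb <- (alt1 * ref2 + ref1 * alt2) / (n1 * n2)
  h1 <- 2 * alt1 * ref1 / (n1 * (n1 - 1))
  h2 <- 2 * alt2 * ref2 / (n2 * (n2 - 1))
  fst <- 1 - (h1 + h2) / (2 * hb)
  fst[n1 < 2 | n2 < 2 | hb == 0] <- NA_real_
  fst
}

#' Site-inclusion rule for pairwise FST
#'
#' Only sites that are segregating and not fixed in the pair of populations
#' being compared enter the FST computation. Under the default
#' `"combined"` reading, both alleles must be observed in the union of the
#' two pools' reads (so differentially fixed sites, FST = 1, are retained).
#' The stricter `"within"` reading requires at least one pool to be
#' polymorphic on its own, which drops differentially fixed sites.
#'
#' Sites where either pool has zero depth are never informative; the FST
#' estimator additionally needs depth of at least 2 in each pool, which
#' [site_fst_table()] enforces.
#'
#' @param ref1,alt1,ref2,alt2 per-pool read counts (vectors recycle).
#' @param rule `"combined"` (default) or `"within"`; see Details.
#' @return logical vector.
#' @export
site_is_informative <- function(ref1, alt1, ref2, alt2,
                                rule = c("combined", "within")) {
  rule <- match.arg(rule)
  n1 <- ref1 + alt1
  n2 <- ref2 + alt2
  has_depth <- n1 > 0 & n2 > 0
  if (rule == "combined") {
    seg <- (alt1 + alt2) > 0 & (ref1 + ref2) > 0
  } else {
    seg <- (alt1 > 0 & ref1 > 0) | (alt2 > 0 & ref2 > 0)
  }
  has_depth & seg
}

#' Per-site FST between two pools or groups of a variant table
#'
#' Applies the segregation filter and the Karlsson estimator to every site,
#' returning one row per site with the informative flag. Non-informative
#' sites (fixed for the same allele in both pools, or depth < 2 in either)
#' carry `NA`.
#'
#' @param table a [variant_table()].
#' @param pool1,pool2 pool ids, or (with `labels`) group labels whose pools
#'   are aggregated by read-count summation.
#' @param labels optional [group_labels()], required when `pool1`/`pool2`
#'   name groups.
#' @param rule segregation rule passed to [site_is_informative()].
#' @return data.frame of class `site_fst` with columns `chrom`, `pos`,
#'   `fst`, `informative`.
#' @export
site_fst_table <- function(table, pool1, pool2, labels = NULL,
                           rule = c("combined", "within")) {
  rule <- match.arg(rule)
  c1 <- resolve_counts(table, pool1, labels)
  c2 <- resolve_counts(table, pool2, labels)
  inf <- site_is_informative(c1$ref, c1$alt, c2$ref, c2$alt, rule = rule) &
    (c1$ref + c1$alt) >= 2 & (c2$ref + c2$alt) >= 2
  fst <- fst_karlsson(c1$ref, c1$alt, c2$ref, c2$alt)
  fst[!inf] <- NA_real_
  inf <- inf & !is.na(fst)
  out <- data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
                    fst = fst, informative = inf, stringsAsFactors = FALSE)
  class(out) <- c("site_fst", class(out))
  out
}

# Resolve a pool id or group label into per-site summed counts.
resolve_counts <- function(table, who, labels = NULL) {
  if (length(who) == 1L && who %in% pool_ids(table)) {
    i <- match(who, pool_ids(table))
    return(list(ref = table$ref_counts[, i], alt = table$alt_counts[, i]))
  }
  if (is.null(labels))
    stop("'", who[1], "' is not a pool id; supply group labels to use groups")
  combine_group_counts(table, labels, who)
}
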