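#' Configuration for the synthetic pool-sequencing generator
#'
#' The generator emulates a multi-breed pool-seq study design: several DNA
#' pools of 10-20 diploid individuals per group (dwarf, non-dwarf
#' domesticated, wild), each sequenced at a modest mean depth (6-17x), with
#' sweep regions planted as allele-frequency shifts toward fixation in the
#' dwarf group. Breed structure follows a two-level Balding-Nichols model:
#' a shared ancestral allele frequency is perturbed first by a group-level
#' drift draw and then by a pool-level drift draw, so pools of the same
#' group are correlated (and cluster together) while the wild group, with
#' the largest drift parameter, is the most diverged — mirroring the
#' wild/domestic split such studies observe.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_pools_per_group named integer vector: pools per group label
#'   (`dwarf`, `non_dwarf`, `wild`; zero allowed).
#' @param pool_size diploid individuals per pool (10-20 in the emulated
#'   design).
#' @param mean_depth mean reads per site per pool (Poisson, minimum 1).
#' @param snp_density variant sites per bp.
#' @param sweep_regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `divergence_shift` in allele-frequency units
#'   (0-1): inside these intervals the dwarf group's frequencies are shifted
#'   by `divergence_shift` toward fixation of the alternative allele.
#' @param baseline_fst_drift pool-level Balding-Nichols drift parameter.
#' @param group_fst_drift named vector of group-level drift parameters.
#' @param mono_fraction fraction of emitted sites that are monomorphic
#'   (true frequency 0 or 1 in every pool), so segregation filters are
#'   exercised.
#' @param indel_fraction fraction of sites emitted as short indels.
#' @param height_fraction fraction of genes marked "height"-associated in
#'   the phenotype catalog; genes inside sweep regions are marked with
#'   probability `sweep_height_prob` instead.
#' @param dwarfism_fraction fraction of genes carrying the "dwarfism" term.
#' @param sweep_height_prob see `height_fraction`.
#' @param gene_spacing distance between tiled gene starts in bp.
#' @param seed integer seed; fully determines every output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 3,
                       chrom_length = 30e6,
                       n_pools_per_group = c(dwarf = 3, non_dwarf = 5, wild = 4),
                       pool_size = 14,
                       mean_depth = 12,
                       snp_density = 0.0012,
                       sweep_regions = NULL,
                       baseline_fst_drift = 0.03,
                       group_fst_drift = c(dwarf = 0.05, non_dwarf = 0.05,
                                           wild = 0.25),
                       mono_fraction = 0.1,
                       indel_fraction = 0.05,
                       height_fraction = 0.2,
                       dwarfism_fraction = 0.05,
                       sweep_height_prob = 0.8,
                       gene_spacing = 40000,
                       seed = 1L) {
  if (is.null(sweep_regions)) {
    sweep_regions <- data.frame(
      chrom = paste0("chr", seq_len(min(2, n_chromosomes))),
      start = c(5e6, 12.5e6)[seq_len(min(2, n_chromosomes))],
      end = c(5.75e6, 13.25e6)[seq_len(min(2, n_chromosomes))],
      divergence_shift = 0.8, stringsAsFactors = FALSE)
  }
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              n_pools_per_group = n_pools_per_group,
              pool_size = pool_size, mean_depth = mean_depth,
              snp_density = snp_density, sweep_regions = sweep_regions,
              baseline_fst_drift = baseline_fst_drift,
              group_fst_drift = group_fst_drift,
              mono_fraction = mono_fraction,
              indel_fraction = indel_fraction,
              height_fraction = height_fraction,
              dwarfism_fraction = dwarfism_fraction,
              sweep_height_prob = sweep_height_prob,
              gene_spacing = gene_spacing, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length > 0,
            cfg$pool_size >= 1, cfg$mean_depth > 0, cfg$snp_density > 0,
            cfg$baseline_fst_drift > 0, cfg$baseline_fst_drift < 1,
            all(cfg$group_fst_drift > 0), all(cfg$group_fst_drift < 1),
            cfg$mono_fraction >= 0, cfg$mono_fraction < 1)
  sw <- cfg$sweep_regions
  if (nrow(sw)) {
    if (any(sw$divergence_shift < 0 | sw$divergence_shift > 1))
      stop("divergence_shift must lie in [0, 1]")
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    if (any(!sw$chrom %in% chroms) || any(sw$start < 0) ||
        any(sw$end > cfg$chrom_length) || any(sw$end <= sw$start))
      stop("sweep region outside the simulated chromosomes")
  }
  invisible(cfg)
}

#' Binomial read counts for one pool at one site
#'
#' Sequencing a pooled library samples alleles with replacement from the
#' pool, so alternative-read counts are binomial in the pool's true allele
#' frequency: `alt ~ Binomial(depth, true_freq)`, `ref = depth - alt`.
#' Uses the current RNG state; vectorised over sites.
#'
#' @param true_freq true alt-allele frequency in `[0, 1]`.
#' @param depth read depth (non-negative integer).
#' @return list with integer vectors `ref` and `alt`.
#' @export
simulate_read_counts <- function(true_freq, depth) {
  stopifnot(all(true_freq >= 0), all(true_freq <= 1), all(depth >= 0))
  alt <- stats::rbinom(length(true_freq) * 1L, size = depth, prob = true_freq)
  list(ref = as.integer(depth - alt), alt = as.integer(alt))
}

# one Balding-Nichols draw around p with drift F
balding_nichols <- function(p, f) {
  shape <- (1 - f) / f
  stats::rbeta(length(p), p * shape, (1 - p) * shape)
}

#' Simulate a complete pool-sequencing experiment
#'
#' Generates a deterministic (seed-driven) synthetic dataset: a
#' [variant_table()] of biallelic sites with per-pool read depths, a tiled
#' [gene_annotation()], a phenotype catalog, [group_labels()], and a truth
#' track recording the planted sweep intervals and the true per-pool allele
#' frequencies.
#'
#' Per-site generation: an ancestral frequency is drawn from Beta(0.8, 0.8)
#' (monomorphic sites get exactly 0 or 1); each group perturbs it by a
#' Balding-Nichols draw with the group's drift parameter, and each pool
#' perturbs its group frequency with `baseline_fst_drift`. Inside planted
#' sweep intervals, dwarf-group frequencies of polymorphic sites are shifted
#' toward fixation of the alternative allele:
#' `p' = p + shift * (1 - p)`. Depth per pool per site is
#' `max(1, Poisson(mean_depth))` and alternative reads are binomial.
#'
#' @param config a [sim_config()].
#' @return list with elements `table`, `annotation`, `catalog`, `labels`,
#'   `truth` (list: `sweeps`, `true_freq` matrix, `chrom_sizes`).
#' @export
simulate_pool_experiment <- function(config) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(config$chrom_length,
                                     config$n_chromosomes), chroms)

  groups <- names(config$n_pools_per_group)
  n_pools <- config$n_pools_per_group
  pool_names <- unlist(lapply(groups[n_pools > 0], function(g)
    paste0(g, "_", seq_len(n_pools[[g]]))))
  pool_group <- sub("_[0-9]+$", "", pool_names)
  labels <- group_labels(pool_names, pool_group,
                         breed = paste0("breed_", pool_names))

  # --- sites --------------------------------------------------------------
  n_per_chrom <- round(config$chrom_length * config$snp_density)
  site_list <- lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chrom_length, n_per_chrom))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  ns <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, ns, replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(bases, r), 1), character(1))
  is_indel <- stats::runif(ns) < config$indel_fraction
  ins <- is_indel & stats::runif(ns) < 0.5
  indel_len <- 1L + stats::rgeom(ns, 0.5)  # short indels only
  indel_len <- pmin(indel_len, 10L)
  extra <- vapply(indel_len, function(k)
    paste(sample(bases, k, replace = TRUE), collapse = ""), character(1))
  sites$alt[ins] <- paste0(sites$ref[ins], extra[ins])
  del <- is_indel & !ins
  sites$ref[del] <- paste0(sites$ref[del], extra[del])
  sites$alt[del] <- substr(sites$ref[del], 1, 1)
  sites$kind <- ifelse(is_indel, "indel", "snp")

  # --- true frequencies ---------------------------------------------------
  mono <- stats::runif(ns) < config$mono_fraction
  p_anc <- stats::rbeta(ns, 0.8, 0.8)
  p_anc[mono] <- ifelse(stats::runif(sum(mono)) < 0.5, 0, 1)

  in_sweep <- rep(FALSE, ns)
  shift <- rep(0, ns)
  sw <- config$sweep_regions
  for (r in seq_len(nrow(sw))) {
    hit <- sites$chrom == sw$chrom[r] &
      sites$pos > sw$start[r] & sites$pos <= sw$end[r]
    in_sweep <- in_sweep | hit
    shift[hit] <- pmax(shift[hit], sw$divergence_shift[r])
  }

  true_freq <- matrix(0, ns, length(pool_names),
                      dimnames = list(NULL, pool_names))
  group_p <- list()
  for (g in unique(pool_group)) {
    pg <- balding_nichols(p_anc, config$group_fst_drift[[g]])
    pg[mono] <- p_anc[mono]
    if (g == "dwarf") {
      poly <- !mono
      pg[poly] <- pg[poly] + shift[poly] * (1 - pg[poly])
    }
    group_p[[g]] <- pg
  }
  for (i in seq_along(pool_names)) {
    pp <- balding_nichols(group_p[[pool_group[i]]], config$baseline_fst_drift)
    pp[mono] <- p_anc[mono]
    # pool frequencies are rationals over 2 * pool_size chromosomes
    pp <- stats::rbinom(ns, 2 * config$pool_size, pp) / (2 * config$pool_size)
    true_freq[, i] <- pp
  }

  # --- read counts --------------------------------------------------------
  ref_m <- alt_m <- matrix(0L, ns, length(pool_names),
                           dimnames = list(NULL, pool_names))
  for (i in seq_along(pool_names)) {
    depth <- pmax(1L, stats::rpois(ns, config$mean_depth))
    cc <- simulate_read_counts(true_freq[, i], depth)
    ref_m[, i] <- cc$ref
    alt_m[, i] <- cc$alt
  }
  table <- variant_table(sites, ref_m, alt_m)

  # --- gene models --------------------------------------------------------
  annotation <- tile_gene_models(chrom_sizes, config$gene_spacing)

  # --- phenotype catalog --------------------------------------------------
  sweep_gr <- if (nrow(sw)) {
    regions <- data.frame(chrom = sw$chrom, ext_start = sw$start,
                          ext_end = sw$end)
    genes_in_regions(regions, annotation)
  } else character()
  gid <- annotation$genes$gene_id
  p_height <- ifelse(gid %in% sweep_gr, config$sweep_height_prob,
                     config$height_fraction)
  height_genes <- gid[stats::runif(length(gid)) < p_height]
  dwarf_genes <- gid[stats::runif(length(gid)) < config$dwarfism_fraction]
  catalog <- list(height = height_genes, dwarfism = dwarf_genes)

  truth <- list(sweeps = sw, true_freq = true_freq,
                chrom_sizes = chrom_sizes)
  list(table = table, annotation = annotation, catalog = catalog,
       labels = labels, truth = truth)
}

# Deterministic fixed-template gene models tiled along each chromosome.
# Template (plus strand): 5'UTR [0,500) | CDS [500,2000) | intron |
# CDS [5000,7000) | intron | CDS [12000,13000) | 3'UTR [13000,15000).
# Every 7th gene is non-coding (exons only). Minus-strand genes mirror the
# UTR labels. Intervals are 0-based half-open.
tile_gene_models <- function(chrom_sizes, gene_spacing = 40000) {
  span <- 15000
  genes <- list(); feats <- list()
  for (ch in names(chrom_sizes)) {
    starts <- seq(0, chrom_sizes[[ch]] - span, by = gene_spacing)
    for (k in seq_along(starts)) {
      s <- starts[k]
      gid <- sprintf("%s_g%04d", ch, k)
      strand <- if (k %% 2 == 0) "-" else "+"
      noncoding <- k %% 7 == 0
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, chrom = ch, start = s, end = s + span,
        strand = strand, stringsAsFactors = FALSE)
      exon <- data.frame(type = "exon",
                         start = s + c(0, 5000, 12000),
                         end = s + c(2000, 7000, 15000))
      if (noncoding) {
        ff <- exon
      } else {
        utr5 <- data.frame(type = "five_prime_UTR", start = s, end = s + 500)
        utr3 <- data.frame(type = "three_prime_UTR", start = s + 13000,
                           end = s + 15000)
        if (strand == "-") {  # transcript orientation flips the UTR labels
          utr5$type <- "three_prime_UTR"; utr3$type <- "five_prime_UTR"
        }
        cds <- data.frame(type = "CDS",
                          start = s + c(500, 5000, 12000),
                          end = s + c(2000, 7000, 13000))
        ff <- rbind(exon, utr5, cds, utr3)
      }
      ff$gene_id <- gid
      feats[[length(feats) + 1L]] <- ff[, c("gene_id", "type", "start", "end")]
    }
  }
  gene_annotation(do.call(rbind, genes), do.call(rbind, feats))
}

#' Write all components of a simulated experiment to a directory
#'
#' Emits the variant table as VCF and sync TSV, the gene models as GFF3,
#' the phenotype catalog and group labels as TSV, and the truth track as a
#' BED of planted sweep intervals plus a TSV of true per-pool frequencies.
#'
#' @param sim result of [simulate_pool_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    sync = file.path(dir, "variants.sync.tsv"),
    gff3 = file.path(dir, "genes.gff3"),
    catalog = file.path(dir, "phenotype_catalog.tsv"),
    labels = file.path(dir, "pool_groups.tsv"),
    truth_bed = file.path(dir, "truth_sweeps.bed"),
    truth_freq = file.path(dir, "truth_frequencies.tsv"))
  write_variant_vcf(sim$table, paths["vcf"])
  write_variant_sync(sim$table, paths["sync"])
  write_gene_gff3(sim$annotation, paths["gff3"])
  write_term_sets(sim$catalog, paths["catalog"])
  write_group_labels(sim$labels, paths["labels"])
  sw <- sim$truth$sweeps
  writeLines(if (nrow(sw)) paste(sw$chrom,
                                 format(sw$start, scientific = FALSE, trim = TRUE),
                                 format(sw$end, scientific = FALSE, trim = TRUE),
                                 paste0("sweep_", seq_len(nrow(sw))),
                                 sw$divergence_shift, sep = "\t")
             else character(),
             paths["truth_bed"])
  tf <- data.frame(chrom = sim$table$sites$chrom, pos = sim$table$sites$pos,
                   sim$truth$true_freq, check.names = FALSE)
  utils::write.table(tf, paths["truth_freq"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Windows overlapping the planted sweep intervals
#'
#' Utility for benchmarking scans against the truth track: returns the rows
#' of a window tiling that overlap any planted sweep interval.
#'
#' @param windows a tiling from [tile_windows()] (or `window_stats`).
#' @param sweeps the `truth$sweeps` data.frame of a simulation.
#' @return logical vector, one entry per window.
#' @export
windows_in_sweeps <- function(windows, sweeps) {
  hit <- rep(FALSE, nrow(windows))
  for (r in seq_len(nrow(sweeps))) {
    hit <- hit | (windows$chrom == sweeps$chrom[r] &
                    windows$start < sweeps$end[r] &
                    windows$end > sweeps$start[r])
  }
  hit
}
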