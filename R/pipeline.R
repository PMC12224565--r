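#' Configuration for a full selection scan
#'
#' Bundles the inputs and tuning parameters of [run_scan()]. The defaults
#' are the scan's canonical parameters: 250 kb non-overlapping windows, a
#' strict >200-variant rule per kept window, outlier percentiles 99.5 and
#' 99.8, 125 kb region extension, and a strict 0.45 alternative-allele
#' frequency cutoff for variant prioritisation.
#'
#' @param table a [variant_table()].
#' @param labels a [group_labels()] covering the table's pools.
#' @param annotation a [gene_annotation()].
#' @param catalog named list of term gene sets (may be empty).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param contrasts named list; each element is `list(a = ..., b = ...)`
#'   where `a`/`b` are group labels or character vectors of pool ids. When
#'   `NULL`, one default contrast `dwarf_vs_non_dwarf` is used. Wild pools
#'   take part in the structure analyses but not in default sweep
#'   contrasts.
#' @param window_size,min_variants,quantiles,pad,aaf_threshold,hp_tail
#'   scan parameters (see Details).
#' @param target_groups groups whose frequencies drive prioritisation.
#' @param out_dir output directory.
#' @return a `scan_config` list.
#' @export
scan_config <- function(table, labels, annotation, catalog = list(),
                        chrom_sizes, contrasts = NULL,
                        window_size = 250000, min_variants = 200,
                        quantiles = c(0.995, 0.998), pad = 125000,
                        aaf_threshold = 0.45, hp_tail = "lower",
                        target_groups = "dwarf", out_dir = tempfile("scan")) {
  check_labels_cover(table, labels)
  if (is.null(contrasts))
    contrasts <- list(dwarf_vs_non_dwarf = list(a = "dwarf", b = "non_dwarf"))
  for (nm in names(contrasts)) {
    for (side in c("a", "b")) {
      who <- contrasts[[nm]][[side]]
      known <- all(who %in% c(labels$group, labels$pool))
      if (!known)
        stop("contrast '", nm, "' names unknown pool or group: ",
             paste(setdiff(who, c(labels$group, labels$pool)), collapse = ", "))
    }
  }
  structure(list(table = table, labels = labels, annotation = annotation,
                 catalog = catalog, chrom_sizes = chrom_sizes,
                 contrasts = contrasts, window_size = window_size,
                 min_variants = min_variants, quantiles = quantiles,
                 pad = pad, aaf_threshold = aaf_threshold,
                 hp_tail = hp_tail, target_groups = target_groups,
                 out_dir = out_dir),
            class = "scan_config")
}

#' Run the full selection-signature scan
#'
#' Executes, for each configured contrast: per-site FST, windowed mean FST,
#' percentile outlier selection at both configured quantiles, merging and
#' extension into sweep regions, region gene lists, variant prioritisation
#' and term enrichment; plus a windowed-Hp scan per target group, the
#' population-structure summaries (pairwise-FST matrix, UPGMA dendrogram in
#' Newick, principal coordinates), and a JSON run manifest with per-stage
#' record counts. All outputs are plain text (TSV/BED/Newick/JSON) and a
#' re-run on identical inputs reproduces them byte-identically.
#'
#' @param config a [scan_config()].
#' @return invisibly, the output directory; its `manifest.json` lists every
#'   file written and the per-stage counts.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  windows <- tile_windows(config$chrom_sizes, config$window_size)
  manifest <- list(
    tool = "poolsweep",
    version = as.character(utils::packageVersion("poolsweep")),
    parameters = config[c("window_size", "min_variants", "quantiles", "pad",
                          "aaf_threshold", "hp_tail", "target_groups")],
    n_sites = n_sites(config$table),
    n_pools = length(pool_ids(config$table)),
    n_windows = nrow(windows),
    stages = list())

  # population structure on all pools (wild included)
  d <- pairwise_fst_matrix(config$table)
  utils::write.table(round(d, 6), file.path(config$out_dir, "pairwise_fst.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  hc <- fst_hclust(d)
  writeLines(hc$newick, file.path(config$out_dir, "dendrogram.nwk"))
  pc <- principal_coordinates(d)
  pcdf <- data.frame(pool = rownames(pc$coordinates),
                     round(pc$coordinates, 6), check.names = FALSE)
  utils::write.table(pcdf, file.path(config$out_dir, "pcoa_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(axis = colnames(pc$coordinates),
               variance_fraction = round(pc$variance_fraction, 6)),
    file.path(config$out_dir, "pcoa_variance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$structure <- list(n_pools = nrow(d),
                                    pc1_variance = pc$variance_fraction[1])

  for (nm in names(config$contrasts)) {
    ct <- config$contrasts[[nm]]
    cdir <- file.path(config$out_dir, nm)
    dir.create(cdir, showWarnings = FALSE)
    sf <- site_fst_table(config$table, ct$a, ct$b, labels = config$labels)
    utils::write.table(
      data.frame(chrom = sf$chrom, pos = sf$pos, fst = round(sf$fst, 6)),
      file.path(cdir, "site_fst.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ws <- window_mean_fst(sf, windows, config$min_variants)
    write_window_stats(ws, file.path(cdir, "windows_fst.tsv"))
    stage <- list(n_informative_sites = sum(sf$informative),
                  n_kept_windows = sum(ws$kept))
    regions995 <- NULL
    for (q in config$quantiles) {
      out <- select_outliers(ws, q, tail = "upper")
      tag <- sub("^0\\.", "q", sprintf("%.4g", q))
      write_outlier_bed(out, file.path(cdir, paste0("outliers_", tag, ".bed")))
      reg <- merge_and_extend(out, config$chrom_sizes, config$pad)
      write_bed_regions(reg, file.path(cdir, paste0("regions_", tag, ".bed")))
      stage[[paste0("n_outliers_", tag)]] <- nrow(out)
      stage[[paste0("n_regions_", tag)]] <- nrow(reg)
      if (is.null(regions995)) regions995 <- reg
      export_manhattan(ws, out, file.path(cdir, paste0("manhattan_", tag, ".tsv")))
    }
    region_genes <- genes_in_regions(regions995, config$annotation)
    writeLines(region_genes, file.path(cdir, "region_genes.txt"))
    stage$n_region_genes <- length(region_genes)
    pv <- prioritize_variants(config$table, regions995, config$labels,
                              config$annotation,
                              target_groups = config$target_groups,
                              threshold = config$aaf_threshold)
    num <- vapply(pv, is.numeric, logical(1)) & names(pv) != "pos"
    pv[num] <- lapply(pv[num], round, 6)
    utils::write.table(pv, file.path(cdir, "prioritized_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage$n_prioritized_variants <- nrow(pv)
    if (length(config$catalog)) {
      enr <- fisher_enrichment(region_genes, config$catalog,
                               universe = config$annotation$genes$gene_id)
      enr$p_raw <- signif(enr$p_raw, 6); enr$p_bh <- signif(enr$p_bh, 6)
      utils::write.table(enr, file.path(cdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stage$n_enriched_terms <- sum(enr$p_bh < 0.05)
    }
    manifest$stages[[nm]] <- stage
  }

  for (g in config$target_groups) {
    hp <- window_hp(config$table, g, windows, config$min_variants,
                    labels = config$labels)
    write_window_stats(hp, file.path(config$out_dir,
                                     paste0("windows_hp_", g, ".tsv")))
    out <- select_outliers(hp, config$quantiles[1], tail = config$hp_tail)
    write_outlier_bed(out, file.path(config$out_dir,
                                     paste0("outliers_hp_", g, ".bed")))
    manifest$stages[[paste0("hp_", g)]] <-
      list(n_kept_windows = sum(hp$kept), n_outliers = nrow(out))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Write window statistics as TSV
#' @param stats a `window_stats` data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_window_stats <- function(stats, path) {
  df <- data.frame(chrom = stats$chrom, start = stats$start, end = stats$end,
                   n_variants = stats$n_variants,
                   value = round(stats$value, 6), kept = stats$kept)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_outlier_bed <- function(out, path) {
  lines <- if (nrow(out)) {
    paste(out$chrom,
          format(out$start, scientific = FALSE, trim = TRUE),
          format(out$end, scientific = FALSE, trim = TRUE),
          paste0("window_", out$index), round(out$value, 6), sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Export Manhattan-plot data for a windowed scan
#'
#' One row per kept window with a cumulative genome coordinate (strictly
#' increasing through the file), the window statistic, an outlier flag, and
#' the constant threshold value of the outlier cut — the data behind the
#' usual windowed-scan Manhattan plot.
#'
#' @param stats a `window_stats` data.frame for one contrast.
#' @param outliers the corresponding [select_outliers()] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_manhattan <- function(stats, outliers, path) {
  kept <- stats[stats$kept, , drop = FALSE]
  chroms <- unique(stats$chrom)
  span <- vapply(chroms, function(ch) max(stats$end[stats$chrom == ch]),
                 numeric(1))
  offset <- stats::setNames(cumsum(c(0, span[-length(span)])), chroms)
  key <- paste(outliers$chrom, outliers$start)
  thr <- attr(outliers, "threshold")
  df <- data.frame(chrom = kept$chrom, start = kept$start, end = kept$end,
                   cum_pos = offset[kept$chrom] + (kept$start + kept$end) / 2,
                   value = round(kept$value, 6),
                   outlier = paste(kept$chrom, kept$start) %in% key,
                   threshold = if (is.null(thr)) NA_real_ else round(thr, 6))
  df <- df[order(df$cum_pos), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
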