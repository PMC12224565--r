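#' Classify variant consequence against gene models
#'
#' Position-based consequence classification by interval overlap with the
#' representative gene model, with priority CDS > UTR > exon of a
#' non-coding transcript > intron > intergenic. Indels inside CDS are
#' frameshift when the length difference between alleles is not a multiple
#' of 3, in-frame otherwise. A variant on a chromosome absent from the
#' annotation is intergenic (with a warning). This is a deliberately
#' simplified region classifier, not a codon-level effect predictor.
#'
#' @param table a [variant_table()].
#' @param ann a [gene_annotation()].
#' @return data.frame with one row per site: `chrom`, `pos`, `gene_id`
#'   (`NA` when intergenic) and `consequence`, one of `cds_snv`,
#'   `cds_frameshift_indel`, `cds_inframe_indel`, `utr5`, `utr3`,
#'   `noncoding_transcript`, `intron`, `intergenic`.
#' @export
classify_consequence <- function(table, ann) {
  sites <- table$sites
  unknown <- !(sites$chrom %in% ann$genes$chrom)
  if (any(unknown))
    warning(sum(unknown), " variant(s) on chromosome(s) absent from the ",
            "annotation; classified as intergenic")
  vr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  fgr <- features_granges(ann)
  ggr <- genes_granges(ann)
  coding_genes <- unique(ann$features$gene_id[ann$features$type == "CDS"])

  consequence <- rep("intergenic", nrow(sites))
  gene <- rep(NA_character_, nrow(sites))
  indel_len <- abs(nchar(sites$ref) - nchar(sites$alt))

  # gene-span hits give intron as the floor classification
  hg <- suppressWarnings(GenomicRanges::findOverlaps(vr, ggr))
  if (length(hg)) {
    first <- !duplicated(S4Vectors::queryHits(hg))
    qi <- S4Vectors::queryHits(hg)[first]
    consequence[qi] <- "intron"
    gene[qi] <- ggr$gene_id[S4Vectors::subjectHits(hg)[first]]
  }

  hf <- suppressWarnings(GenomicRanges::findOverlaps(vr, fgr))
  if (length(hf)) {
    qh <- S4Vectors::queryHits(hf)
    sh <- S4Vectors::subjectHits(hf)
    ftype <- fgr$type[sh]
    fgene <- fgr$gene_id[sh]
    prio <- c(CDS = 1L, five_prime_UTR = 2L, three_prime_UTR = 2L, exon = 3L)
    ord <- order(qh, prio[ftype])
    keep <- !duplicated(qh[ord])
    qi <- qh[ord][keep]; ti <- ftype[ord][keep]; gi <- fgene[ord][keep]
    cls <- character(length(qi))
    is_indel <- sites$kind[qi] == "indel"
    cds <- ti == "CDS"
    cls[cds & !is_indel] <- "cds_snv"
    cls[cds & is_indel] <- ifelse(indel_len[qi][cds & is_indel] %% 3 != 0,
                                  "cds_frameshift_indel", "cds_inframe_indel")
    cls[ti == "five_prime_UTR"] <- "utr5"
    cls[ti == "three_prime_UTR"] <- "utr3"
    # exon of a transcript without CDS = non-coding transcript
    cls[ti == "exon"] <- ifelse(gi[ti == "exon"] %in% coding_genes,
                                "intron", "noncoding_transcript")
    # an exon hit in a coding gene without a CDS/UTR hit at that position can
    # only happen for malformed models; intron is the conservative fallback
    consequence[qi] <- cls
    gene[qi] <- gi
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, gene_id = gene,
             consequence = consequence, stringsAsFactors = FALSE)
}

#' Private / fixed flags for a variant relative to a group contrast
#'
#' A variant is private to the target group when the alternative allele is
#' absent (read-count frequency 0) from every other group, and fixed when
#' its read-count frequency in the target group is exactly 1 (an optional
#' tolerance is available for noisy depth, off by default).
#'
#' @param target_counts list with `ref` and `alt` counts for the target
#'   group (scalar or per-site vectors).
#' @param other_counts list of such lists, one per non-target group.
#' @param fixed_tol tolerance on the fixation frequency (default 0: exact).
#' @return data.frame with logical columns `private` and `fixed`; both `NA`
#'   where the target group has zero depth.
#' @export
private_fixed_flags <- function(target_counts, other_counts, fixed_tol = 0) {
  f_t <- allele_frequency(target_counts$ref, target_counts$alt)
  private <- rep(TRUE, length(f_t))
  for (oc in other_counts) {
    f_o <- allele_frequency(oc$ref, oc$alt)
    private <- private & (is.na(f_o) | f_o == 0)
  }
  fixed <- f_t >= 1 - fixed_tol
  private[is.na(f_t)] <- NA
  fixed[is.na(f_t)] <- NA
  data.frame(private = private, fixed = fixed)
}

#' Prioritise variants inside extended sweep regions
#'
#' Applies the prioritisation filter used for candidate-region follow-up:
#' retain a variant only if it (i) falls inside an extended sweep region,
#' (ii) overlaps an exon including UTRs (consequence among the CDS and UTR
#' classes), and (iii) has an alternative-allele frequency strictly greater
#' than `threshold` in at least one of the target groups (group frequencies
#' from summed read counts). Private/fixed flags are computed for the first
#' target group against all other groups.
#'
#' @param table a [variant_table()].
#' @param regions a `sweep_regions` data.frame (extended coordinates are
#'   used).
#' @param labels a [group_labels()].
#' @param ann a [gene_annotation()].
#' @param target_groups character vector of group labels; the frequency
#'   filter is an any-of disjunction over them (default `"dwarf"`).
#' @param threshold strict alt-allele frequency cutoff (default 0.45).
#' @return data.frame with one row per retained variant: site fields,
#'   `gene_id`, `consequence`, one `aaf_<group>` column per group in
#'   `labels`, and logical `private`, `fixed`.
#' @export
prioritize_variants <- function(table, regions, labels, ann,
                                target_groups = "dwarf", threshold = 0.45) {
  check_labels_cover(table, labels)
  groups <- unique(labels$group)
  if (!all(target_groups %in% groups))
    stop("target group(s) not present in labels: ",
         paste(setdiff(target_groups, groups), collapse = ", "))

  sites <- table$sites
  in_region <- rep(FALSE, nrow(sites))
  if (nrow(regions)) {
    vr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, sites$pos))
    rr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$ext_start + 1,
                                                  regions$ext_end))
    in_region <- IRanges::overlapsAny(vr, rr)
  }

  cls <- classify_consequence(table, ann)
  exonic <- cls$consequence %in% c("cds_snv", "cds_frameshift_indel",
                                   "cds_inframe_indel", "utr5", "utr3")

  gcounts <- lapply(groups, function(g) combine_group_counts(table, labels, g))
  names(gcounts) <- groups
  aaf <- vapply(gcounts, function(cc) allele_frequency(cc$ref, cc$alt),
                numeric(nrow(sites)))
  if (is.null(dim(aaf))) aaf <- matrix(aaf, nrow = 1, dimnames = list(NULL, groups))

  freq_pass <- rep(FALSE, nrow(sites))
  for (g in target_groups) {
    f <- aaf[, g]
    freq_pass <- freq_pass | (!is.na(f) & f > threshold)
  }

  keep <- in_region & exonic & freq_pass
  flags <- private_fixed_flags(
    gcounts[[target_groups[1]]],
    gcounts[setdiff(groups, target_groups[1])])

  out <- cbind(sites[keep, , drop = FALSE],
               gene_id = cls$gene_id[keep],
               consequence = cls$consequence[keep])
  colnames(aaf) <- paste0("aaf_", groups)
  out <- cbind(out, aaf[keep, , drop = FALSE],
               flags[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}
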