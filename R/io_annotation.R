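#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon/CDS/UTR features, converts GFF's 1-based inclusive
#' coordinates to the package's internal 0-based half-open convention, and
#' collapses each gene to a single representative transcript: the one with
#' the longest total CDS (total exon length for non-coding transcripts).
#' Child features whose parent transcript cannot be resolved are skipped
#' with a warning.
#'
#' @param path a GFF3 file (gzip transparent).
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- as.character(md$ID)
  parent <- vapply(as.list(md$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA")
  genes <- data.frame(
    gene_id = id[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    stringsAsFactors = FALSE)

  tx_gene <- parent[is_tx]
  tx_id <- id[is_tx]
  known_tx <- !is.na(tx_gene) & tx_gene %in% genes$gene_id
  if (any(!known_tx))
    warning("skipping ", sum(!known_tx), " transcript(s) without a known parent gene")
  tx_id <- tx_id[known_tx]; tx_gene <- tx_gene[known_tx]

  is_child <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  child <- data.frame(
    tx = parent[is_child],
    type = type[is_child],
    start = GenomicRanges::start(gr)[is_child] - 1L,
    end = GenomicRanges::end(gr)[is_child],
    stringsAsFactors = FALSE)
  known_child <- !is.na(child$tx) & child$tx %in% tx_id
  if (any(!known_child))
    warning("skipping ", sum(!known_child),
            " feature(s) without a known parent transcript")
  child <- child[known_child, , drop = FALSE]

  # representative transcript per gene: longest CDS, else longest exon sum
  tx_len <- vapply(tx_id, function(t) {
    cds <- child[child$tx == t & child$type == "CDS", ]
    if (nrow(cds)) return(sum(cds$end - cds$start))
    ex <- child[child$tx == t & child$type == "exon", ]
    sum(ex$end - ex$start) / 1e9  # exon-only length ranks below any CDS
  }, numeric(1))
  rep_tx <- vapply(genes$gene_id, function(g) {
    cand <- which(tx_gene == g)
    if (!length(cand)) return(NA_character_)
    tx_id[cand[which.max(tx_len[cand])]]
  }, character(1))

  feat <- child[child$tx %in% stats::na.omit(rep_tx), , drop = FALSE]
  feat$gene_id <- tx_gene[match(feat$tx, tx_id)]
  features <- feat[, c("gene_id", "type", "start", "end")]
  rownames(features) <- NULL
  gene_annotation(genes, features)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_annotation()]: each gene is written as a
#' gene/mRNA pair (one representative transcript) with exon, CDS and UTR
#' children, converting internal 0-based half-open intervals back to GFF's
#' 1-based inclusive coordinates.
#'
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gene_gff3 <- function(ann, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start0, end0, strand, attrs)
    paste(chrom, "poolsweep", type, start0 + 1, end0, ".", strand, ".",
          attrs, sep = "\t")
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               fmt(g$chrom, "gene", g$start, g$end, g$strand,
                   paste0("ID=", g$gene_id)),
               fmt(g$chrom, "mRNA", g$start, g$end, g$strand,
                   paste0("ID=", tid, ";Parent=", g$gene_id)))
    ff <- ann$features[ann$features$gene_id == g$gene_id, , drop = FALSE]
    ff <- ff[order(ff$start, ff$type), , drop = FALSE]
    for (j in seq_len(nrow(ff))) {
      lines <- c(lines, fmt(g$chrom, ff$type[j], ff$start[j], ff$end[j],
                            g$strand, paste0("Parent=", tid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write sweep regions as BED3+score
#'
#' One line per region in 0-based half-open BED coordinates using the core
#' (merged outlier windows) span, with the region name, the peak window
#' statistic as score, and the extended span as two extra columns. Input
#' must be sorted by chromosome then start, and regions must not overlap.
#'
#' @param regions a `sweep_regions` data.frame from [merge_and_extend()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bed_regions <- function(regions, path) {
  if (nrow(regions)) {
    ord <- order(regions$chrom, regions$core_start)
    if (!identical(ord, seq_len(nrow(regions))))
      stop("regions must be sorted by chromosome then start")
    same <- regions$chrom[-1] == regions$chrom[-nrow(regions)]
    if (any(same & regions$core_start[-1] < regions$core_end[-nrow(regions)]))
      stop("regions must not overlap")
  }
  lines <- if (nrow(regions)) {
    paste(regions$chrom,
          format(regions$core_start, scientific = FALSE, trim = TRUE),
          format(regions$core_end, scientific = FALSE, trim = TRUE),
          paste0("sweep_", seq_len(nrow(regions))),
          regions$peak_value,
          format(regions$ext_start, scientific = FALSE, trim = TRUE),
          format(regions$ext_end, scientific = FALSE, trim = TRUE),
          sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype catalog (term -> gene set)
#'
#' Accepts either a two-column TSV (`term`, `gene`; one row per pair,
#' header optional) or GMT (term, description, then gene ids, tab
#' separated).
#'
#' @param path input file.
#' @param format `"tsv"`, `"gmt"`, or `"auto"` (by extension).
#' @return named list mapping term to a character vector of gene ids.
#' @export
read_term_sets <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt(\\.gz)?$", path)) "gmt" else "tsv"
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (format == "gmt") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    out <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(out) <- vapply(fields, `[`, character(1), 1)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) stop("term TSV needs two columns: term, gene")
  fm <- do.call(rbind, lapply(fields, `[`, 1:2))
  if (identical(tolower(fm[1, ]), c("term", "gene"))) fm <- fm[-1, , drop = FALSE]
  split(fm[, 2], factor(fm[, 1], levels = unique(fm[, 1])))
}

#' Write a phenotype catalog as two-column TSV
#' @param term_sets named list of gene-id vectors.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_term_sets <- function(term_sets, path) {
  rows <- unlist(lapply(names(term_sets), function(t)
    paste(t, term_sets[[t]], sep = "\t")))
  writeLines(c("term\tgene", rows), path)
  invisible(path)
}

#' Read / write pool group labels as TSV
#'
#' Three columns: `pool`, `group`, `breed`.
#'
#' @param path input/output path.
#' @return [group_labels()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_group_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  group_labels(df$pool, df$group, df$breed)
}

#' @rdname read_group_labels
#' @param labels a [group_labels()] data.frame.
#' @export
write_group_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
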