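#' Gene annotation container
#'
#' Gene models with exon/CDS/UTR substructure, stored internally in 0-based
#' half-open coordinates (conversion from 1-based inclusive GFF happens only
#' at the format boundary). One model per gene id: when several transcripts
#' exist the longest-CDS transcript is representative.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open span), `strand` (`"+"`/`"-"`).
#' @param features data.frame with columns `gene_id`, `type` (one of
#'   `"exon"`, `"CDS"`, `"five_prime_UTR"`, `"three_prime_UTR"`), `start`,
#'   `end` (0-based half-open).
#' @return object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, features) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(c("gene_id", "type", "start", "end") %in% names(features)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  bad <- setdiff(unique(features$type),
                 c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"))
  if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  orphan <- setdiff(features$gene_id, genes$gene_id)
  if (length(orphan)) stop("features reference unknown gene: ", orphan[1])
  span <- genes[match(features$gene_id, genes$gene_id), ]
  if (any(features$start < span$start | features$end > span$end))
    stop("feature intervals must lie within their gene span")
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  rownames(genes) <- rownames(features) <- NULL
  structure(list(genes = genes, features = features),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,",
      nrow(x$features), "features on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

# GRanges view of gene spans / features for overlap queries.
genes_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$genes$chrom,
    ranges = IRanges::IRanges(start = ann$genes$start + 1L,
                              end = ann$genes$end),
    gene_id = ann$genes$gene_id)
}

features_granges <- function(ann) {
  chrom <- ann$genes$chrom[match(ann$features$gene_id, ann$genes$gene_id)]
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = ann$features$start + 1L,
                              end = ann$features$end),
    gene_id = ann$features$gene_id,
    type = ann$features$type)
}
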