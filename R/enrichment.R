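#' Genes overlapping extended sweep regions
#'
#' Returns the ids of genes whose span overlaps any extended sweep region by
#' at least 1 bp (half-open intervals: a gene ending exactly where a region
#' starts does not overlap).
#'
#' @param regions a `sweep_regions` data.frame (extended coordinates used).
#' @param ann a [gene_annotation()].
#' @return character vector of gene ids (sorted, unique).
#' @export
genes_in_regions <- function(regions, ann) {
  if (nrow(regions) == 0) return(character())
  rr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$ext_start + 1,
                                                regions$ext_end))
  gg <- genes_granges(ann)
  hits <- IRanges::overlapsAny(gg, rr)
  sort(unique(ann$genes$gene_id[hits]))
}

#' Fisher exact over-representation test for term sets
#'
#' One-sided Fisher's exact (hypergeometric upper-tail) test of each term's
#' gene set against a hit list, within a fixed gene universe. With universe
#' size \eqn{M}, term size \eqn{K}, hit-list size \eqn{m} and overlap
#' \eqn{k}, the p-value is \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(M, K, m)}. Raw p-values are adjusted with
#' [benjamini_hochberg()].
#'
#' @param hits character vector of input gene ids (intersected with the
#'   universe).
#' @param term_sets named list mapping term id to a character vector of gene
#'   ids (a phenotype catalog); sets are intersected with the universe.
#' @param universe character vector: the background gene universe.
#' @return data.frame sorted by raw p-value with columns `term`, `k`, `m`,
#'   `K`, `M`, `p_raw`, `p_bh`, `genes` (comma-separated overlap ids).
#' @export
fisher_enrichment <- function(hits, term_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  hits <- intersect(unique(hits), universe)
  M <- length(universe)
  m <- length(hits)
  rows <- lapply(names(term_sets), function(term) {
    tg <- intersect(unique(term_sets[[term]]), universe)
    K <- length(tg)
    ov <- intersect(hits, tg)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, M - K, m, lower.tail = FALSE)
    data.frame(term = term, k = k, m = m, K = K, M = M, p_raw = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), k = integer(), m = integer(),
                      K = integer(), M = integer(), p_raw = numeric(),
                      p_bh = numeric(), genes = character()))
  out$p_bh <- benjamini_hochberg(out$p_raw)
  out <- out[order(out$p_raw, out$term), c("term", "k", "m", "K", "M",
                                           "p_raw", "p_bh", "genes")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment: with ordered p-values \eqn{p_{(1)} \le \dots \le
#' p_{(n)}}, the adjusted value of \eqn{p_{(i)}} is
#' \eqn{\min_{j \ge i} (n/j)\, p_{(j)}}, capped at 1; the output preserves
#' the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
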