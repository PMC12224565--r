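#' Pool-sequencing variant table
#'
#' The central container of the package: a set of biallelic variant sites
#' together with per-pool reference and alternative read depths. Pool-seq
#' libraries have no meaningful genotypes, so allele depths (not genotype
#' calls) are the atomic observation throughout.
#'
#' @param sites data.frame with columns `chrom` (character), `pos` (1-based
#'   integer position), `ref`, `alt` (allele strings) and optionally `kind`
#'   (`"snp"` or `"indel"`; inferred from allele lengths when absent).
#' @param ref_counts,alt_counts integer matrices of per-pool read depths,
#'   one row per site, one column per pool; column names are pool ids.
#' @return An object of class `variant_table`: a list with elements
#'   `sites`, `ref_counts`, `alt_counts`.
#' @details Indels longer than 50 bp are rejected: the pipeline retains only
#'   short indels, mirroring common hard-filter practice for pooled data.
#' @export
variant_table <- function(sites, ref_counts, alt_counts) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  ref_counts <- as.matrix(ref_counts)
  alt_counts <- as.matrix(alt_counts)
  storage.mode(ref_counts) <- "integer"
  storage.mode(alt_counts) <- "integer"
  if (nrow(ref_counts) != nrow(sites) || nrow(alt_counts) != nrow(sites))
    stop("count matrices must have one row per site")
  if (!identical(dim(ref_counts), dim(alt_counts)))
    stop("ref_counts and alt_counts must have identical dimensions")
  if (is.null(colnames(ref_counts)))
    colnames(ref_counts) <- paste0("pool", seq_len(ncol(ref_counts)))
  colnames(alt_counts) <- colnames(ref_counts)
  if (any(ref_counts < 0, na.rm = TRUE) || any(alt_counts < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  if (any(sites$pos < 1)) stop("positions are 1-based; pos must be >= 1")
  if (is.null(sites$kind)) {
    sites$kind <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                         "snp", "indel")
  }
  too_long <- abs(nchar(sites$ref) - nchar(sites$alt)) >= 50L
  if (any(too_long))
    stop("indels of 50 bp or longer are not supported (site ",
         sites$chrom[which(too_long)[1]], ":", sites$pos[which(too_long)[1]], ")")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  structure(list(sites = sites, ref_counts = ref_counts,
                 alt_counts = alt_counts),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x", ncol(x$ref_counts),
      "pools\n")
  cat("pools:", paste(colnames(x$ref_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites in a variant table
#' @param table a [variant_table()]
#' @return integer count of sites
#' @export
n_sites <- function(table) nrow(table$sites)

#' Pool identifiers of a variant table
#' @param table a [variant_table()]
#' @return character vector of pool ids
#' @export
pool_ids <- function(table) colnames(table$ref_counts)

#' Pool group labels
#'
#' Maps each pool id to a group (`dwarf`, `non_dwarf` or `wild`) and a breed
#' name. Every pool in a variant table must be labelled exactly once before
#' group-level contrasts can be formed.
#'
#' @param pool character vector of pool ids.
#' @param group character vector of group labels, one per pool.
#' @param breed optional character vector of breed names (defaults to the
#'   pool id).
#' @return data.frame of class `group_labels` with columns `pool`, `group`,
#'   `breed`.
#' @export
group_labels <- function(pool, group, breed = pool) {
  stopifnot(length(pool) == length(group), length(breed) == length(pool))
  if (anyDuplicated(pool))
    stop("duplicated pool id: ", pool[duplicated(pool)][1])
  bad <- setdiff(unique(group), c("dwarf", "non_dwarf", "wild"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(pool = as.character(pool), group = as.character(group),
                    breed = as.character(breed), stringsAsFactors = FALSE)
  class(out) <- c("group_labels", class(out))
  out
}

check_labels_cover <- function(table, labels) {
  missing <- setdiff(pool_ids(table), labels$pool)
  if (length(missing))
    stop("pools without a group label: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Aggregate read counts over the pools of one group
#'
#' Group-level contrasts (e.g. all non-dwarf breeds pooled together) are
#' formed by summing reference and alternative read depths across the group's
#' pools at every site, consistent with the read-count definition of pool
#' allele frequency.
#'
#' @param table a [variant_table()].
#' @param labels a [group_labels()] data.frame covering the table's pools.
#' @param group a group label present in `labels`, or a character vector of
#'   pool ids to aggregate directly.
#' @return list with integer vectors `ref` and `alt`, one entry per site.
#' @export
combine_group_counts <- function(table, labels, group) {
  if (length(group) == 1L && group %in% labels$group) {
    pools <- labels$pool[labels$group == group]
  } else if (all(group %in% pool_ids(table))) {
    pools <- group
  } else {
    stop("unknown group label or pool id: ",
         paste(setdiff(group, c(labels$group, pool_ids(table))), collapse = ", "))
  }
  pools <- intersect(pools, pool_ids(table))
  if (!length(pools)) stop("group '", group[1], "' matches no pool in the table")
  idx <- match(pools, pool_ids(table))
  list(ref = as.integer(rowSums(table$ref_counts[, idx, drop = FALSE])),
       alt = as.integer(rowSums(table$alt_counts[, idx, drop = FALSE])))
}

#' Subset a variant table by site index
#' @param table a [variant_table()]
#' @param i integer or logical site index
#' @return a [variant_table()] with the selected sites
#' @export
subset_sites <- function(table, i) {
  variant_table(table$sites[i, , drop = FALSE],
                table$ref_counts[i, , drop = FALSE],
                table$alt_counts[i, , drop = FALSE])
}
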