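#' Read a pool-seq variant table from VCF or sync TSV
#'
#' Pools are VCF "samples" and allele counts are taken from the per-sample
#' `AD` field (reference,alternative read depths), never from genotype
#' calls: pooled libraries have no meaningful genotypes. Multi-allelic
#' records are split into one biallelic record per alternative allele
#' against the same reference. Gzipped input is read transparently.
#'
#' The sync dialect is a minimal tab-separated format: a `#`-prefixed header
#' naming the pools, then per site `chrom`, `pos` (1-based), `ref`, `alt`
#' and one `ref:alt` count pair per pool.
#'
#' @param path input file.
#' @param format `"vcf"` or `"sync"`; guessed from the extension when
#'   omitted.
#' @return a [variant_table()], sites in file order.
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "sync")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "sync"
  }
  if (format == "vcf") read_vcf_pools(path) else read_sync(path)
}

read_vcf_pools <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, "FORMAT", drop = TRUE]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    i <- which(!grepl("(^|:)AD(:|$)", fmt))[1]
    stop("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
         " has no AD field in FORMAT")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  pools <- colnames(ad)
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt_full <- fix[, "ALT"]

  sites <- list(); refs <- list(); alts <- list()
  for (r in seq_along(pos)) {
    alt_alleles <- strsplit(alt_full[r], ",", fixed = TRUE)[[1]]
    parts <- strsplit(ad[r, ], ",", fixed = TRUE)
    lens <- lengths(parts)
    if (any(is.na(ad[r, ])) || any(lens != length(alt_alleles) + 1))
      stop("record ", chrom[r], ":", pos[r],
           " has a malformed AD field (expected ",
           length(alt_alleles) + 1, " comma-separated counts)")
    counts <- suppressWarnings(
      matrix(as.numeric(unlist(parts)), ncol = length(pools)))
    if (any(is.na(counts)))
      stop("record ", chrom[r], ":", pos[r], " has non-numeric AD counts")
    for (a in seq_along(alt_alleles)) {
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = chrom[r], pos = pos[r], ref = ref[r],
        alt = alt_alleles[a], stringsAsFactors = FALSE)
      refs[[length(refs) + 1L]] <- counts[1, ]
      alts[[length(alts) + 1L]] <- counts[a + 1, ]
    }
  }
  ref_m <- do.call(rbind, refs); alt_m <- do.call(rbind, alts)
  colnames(ref_m) <- colnames(alt_m) <- pools
  variant_table(do.call(rbind, sites), ref_m, alt_m)
}

read_sync <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("sync file must start with a #-prefixed header naming the pools")
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  pools <- header[-(1:4)]
  if (!length(pools)) stop("sync header names no pools")
  body <- lines[-1]
  if (!length(body)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
    m <- matrix(integer(), 0, length(pools), dimnames = list(NULL, pools))
    return(variant_table(empty, m, m))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4 + length(pools)))
    stop("sync line with wrong field count: line ",
         which(lengths(fields) != 4 + length(pools))[1] + 1)
  fm <- do.call(rbind, fields)
  pairs <- fm[, -(1:4), drop = FALSE]
  split_counts <- function(col, what) {
    cc <- strsplit(col, ":", fixed = TRUE)
    if (any(lengths(cc) != 2))
      stop("malformed ", what, " count pair (expected ref:alt)")
    v <- suppressWarnings(as.numeric(unlist(cc)))
    if (any(is.na(v))) stop("non-numeric counts in sync file")
    matrix(v, ncol = 2, byrow = TRUE)
  }
  ref_m <- alt_m <- matrix(0L, nrow(fm), length(pools),
                           dimnames = list(NULL, pools))
  for (j in seq_along(pools)) {
    cm <- split_counts(pairs[, j], pools[j])
    ref_m[, j] <- as.integer(cm[, 1]); alt_m[, j] <- as.integer(cm[, 2])
  }
  sites <- data.frame(chrom = fm[, 1], pos = as.integer(fm[, 2]),
                      ref = fm[, 3], alt = fm[, 4], stringsAsFactors = FALSE)
  variant_table(sites, ref_m, alt_m)
}

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Write a variant table as VCF 4.2 with per-sample AD
#'
#' @param table a [variant_table()].
#' @param path output path (`.gz` writes gzip).
#' @return invisibly, the path.
#' @export
write_variant_vcf <- function(table, path) {
  s <- table$sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolsweep",
    paste0("##contig=<ID=", unique(s$chrom), ">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Read depths for ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pool_ids(table)), collapse = "\t"))
  ad <- matrix(paste(table$ref_counts, table$alt_counts, sep = ","),
               nrow = nrow(s))
  body <- apply(cbind(s$chrom, s$pos, ".", s$ref, s$alt, ".", ".", ".",
                      "AD", ad), 1, paste, collapse = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write a variant table in the sync TSV dialect
#'
#' @inheritParams write_variant_vcf
#' @return invisibly, the path.
#' @export
write_variant_sync <- function(table, path) {
  s <- table$sites
  pairs <- matrix(paste(table$ref_counts, table$alt_counts, sep = ":"),
                  nrow = nrow(s))
  lines <- c(paste0("#", paste(c("chrom", "pos", "ref", "alt",
                                 pool_ids(table)), collapse = "\t")),
             apply(cbind(s$chrom, s$pos, s$ref, s$alt, pairs), 1,
                   paste, collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
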