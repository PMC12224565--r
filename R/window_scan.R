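#' Tile chromosomes into non-overlapping windows
#'
#' Chromosomes are partitioned into consecutive fixed-size windows
#' `[k*w, (k+1)*w)` in 0-based half-open coordinates; a terminal partial
#' window is emitted when the chromosome length is not a multiple of the
#' window size. Terminal stubs are almost always removed later by the
#' minimum-variant rule.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param window_size window width in bp (default 250 kb).
#' @return data.frame of class `windows` with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `index`; carries `window_size` as an
#'   attribute.
#' @examples
#' tile_windows(c(chr1 = 625000))
#' @export
tile_windows <- function(chrom_sizes, window_size = 250000) {
  stopifnot(length(chrom_sizes) > 0, all(chrom_sizes > 0), window_size > 0)
  if (is.null(names(chrom_sizes)))
    stop("chrom_sizes must be a named vector")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$index <- seq_len(nrow(out))
  class(out) <- c("windows", class(out))
  attr(out, "window_size") <- window_size
  out
}

# Map 1-based site positions onto a fixed-size tiling; returns the row index
# in `windows` or NA for positions beyond the tiling.
assign_windows <- function(chrom, pos, windows) {
  w <- attr(windows, "window_size")
  key <- paste(windows$chrom, windows$start, sep = ":")
  site_key <- paste(chrom, ((pos - 1) %/% w) * w, sep = ":")
  match(site_key, key)
}

#' Mean per-site FST in each window
#'
#' Per-window arithmetic mean of the informative sites' FST values. A window
#' is kept only when it holds strictly more than `min_variants` informative
#' sites; sparse and empty windows are retained in the output with
#' `kept = FALSE` so that tilings stay comparable across contrasts.
#'
#' @param site_fst a `site_fst` data.frame from [site_fst_table()].
#' @param windows a tiling from [tile_windows()].
#' @param min_variants minimum informative-site count; the filter is strict
#'   (`n_variants > min_variants`). Default 200.
#' @return data.frame of class `window_stats`: `chrom`, `start`, `end`,
#'   `index`, `n_variants`, `value`, `kept`, with attributes `window_size`
#'   and `statistic = "fst"`.
#' @export
window_mean_fst <- function(site_fst, windows, min_variants = 200) {
  use <- site_fst$informative & !is.na(site_fst$fst)
  widx <- assign_windows(site_fst$chrom[use], site_fst$pos[use], windows)
  n <- tabulate(widx, nbins = nrow(windows))
  sums <- rep(0, nrow(windows))
  ok <- !is.na(widx)
  agg <- rowsum(site_fst$fst[use][ok], widx[ok])
  sums[as.integer(rownames(agg))] <- agg[, 1]
  out <- windows
  out$n_variants <- n
  out$value <- ifelse(n > 0, sums / n, NA_real_)
  out$kept <- n > min_variants
  class(out) <- c("window_stats", "data.frame")
  attr(out, "window_size") <- attr(windows, "window_size")
  attr(out, "statistic") <- "fst"
  out
}

#' Pooled heterozygosity (Hp) in each window
#'
#' Rubin-style windowed pooled heterozygosity. At every site the major
#' allele is the more frequent allele in the chosen pool or group; with
#' \eqn{\Sigma n_{MAJ}} and \eqn{\Sigma n_{MIN}} the window sums of major-
#' and minor-allele read counts,
#' \deqn{H_P = 2\,\Sigma n_{MAJ}\,\Sigma n_{MIN} / (\Sigma n_{MAJ} + \Sigma n_{MIN})^2.}
#' Hp lies in `[0, 0.5]`, attains 0.5 exactly when the two sums are equal,
#' and is depressed in swept regions where diversity is lost.
#'
#' @param table a [variant_table()].
#' @param pool a pool id or (with `labels`) a group label.
#' @param windows a tiling from [tile_windows()].
#' @param min_variants strict minimum number of covered sites per kept
#'   window (default 200).
#' @param labels optional [group_labels()] when `pool` names a group.
#' @return a `window_stats` data.frame as in [window_mean_fst()] with
#'   `statistic = "hp"`.
#' @export
window_hp <- function(table, pool, windows, min_variants = 200,
                      labels = NULL) {
  cc <- resolve_counts(table, pool, labels)
  covered <- (cc$ref + cc$alt) > 0
  maj <- pmax(cc$ref, cc$alt)[covered]
  min_ <- pmin(cc$ref, cc$alt)[covered]
  widx <- assign_windows(table$sites$chrom[covered],
                         table$sites$pos[covered], windows)
  ok <- !is.na(widx)
  n <- tabulate(widx[ok], nbins = nrow(windows))
  smaj <- smin <- rep(0, nrow(windows))
  if (any(ok)) {
    a1 <- rowsum(maj[ok], widx[ok]); smaj[as.integer(rownames(a1))] <- a1[, 1]
    a2 <- rowsum(min_[ok], widx[ok]); smin[as.integer(rownames(a2))] <- a2[, 1]
  }
  tot <- smaj + smin
  out <- windows
  out$n_variants <- n
  out$value <- ifelse(tot > 0, 2 * smaj * smin / tot^2, NA_real_)
  out$kept <- n > min_variants & tot > 0
  class(out) <- c("window_stats", "data.frame")
  attr(out, "window_size") <- attr(windows, "window_size")
  attr(out, "statistic") <- "hp"
  out
}

#' Select empirical-percentile outlier windows
#'
#' From the kept windows' statistic distribution, returns the
#' `k = round(N * (1 - q))` most extreme windows: the largest values for the
#' upper tail (high differentiation) or the smallest for the lower tail
#' (depleted heterozygosity). The count rule reproduces percentile cuts of
#' the form "top 52 of 10 441 windows at the 99.5th percentile"
#' (`round(10441 * 0.005) = 52`). Ties at the cut are broken by genomic
#' position (`chrom`, then `start`).
#'
#' @param stats a `window_stats` data.frame.
#' @param q percentile as a probability (e.g. `0.995`).
#' @param tail `"upper"` or `"lower"`.
#' @return the outlier rows of `stats`, ordered by genomic position, with
#'   attribute `threshold` (the least extreme selected value).
#' @export
select_outliers <- function(stats, q = 0.995, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(q > 0, q < 1)
  kept <- stats[stats$kept & !is.na(stats$value), , drop = FALSE]
  k <- round(nrow(kept) * (1 - q))
  if (k == 0) {
    warning("percentile cut selects zero windows (N = ", nrow(kept), ")")
    out <- kept[0, , drop = FALSE]
    attr(out, "window_size") <- attr(stats, "window_size")
    return(out)
  }
  sgn <- if (tail == "upper") -1 else 1
  ord <- order(sgn * kept$value, kept$chrom, kept$start)
  sel <- kept[ord[seq_len(k)], , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("window_stats", "data.frame")
  attr(sel, "window_size") <- attr(stats, "window_size")
  attr(sel, "statistic") <- attr(stats, "statistic")
  attr(sel, "threshold") <- if (tail == "upper") min(sel$value) else max(sel$value)
  sel
}

#' Merge adjacent outlier windows and extend candidate regions
#'
#' Outlier windows that share a boundary on the same chromosome are merged
#' into one candidate sweep region (windows separated by a non-outlier
#' window are not merged). Each region's core is then symmetrically extended
#' by `pad` bp on both sides, clamped to the chromosome, for gene annotation
#' and variant prioritisation.
#'
#' @param outliers outlier windows from [select_outliers()].
#' @param chrom_sizes named vector of chromosome lengths (for clamping).
#' @param pad extension in bp on each side (default 125 kb).
#' @return data.frame of class `sweep_regions`: `chrom`, `core_start`,
#'   `core_end`, `ext_start`, `ext_end`, `peak_value`, `n_windows`.
#' @export
merge_and_extend <- function(outliers, chrom_sizes, pad = 125000) {
  if (nrow(outliers) == 0) {
    out <- data.frame(chrom = character(), core_start = numeric(),
                      core_end = numeric(), ext_start = numeric(),
                      ext_end = numeric(), peak_value = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
    class(out) <- c("sweep_regions", class(out))
    return(out)
  }
  o <- outliers[order(outliers$chrom, outliers$start), , drop = FALSE]
  new_region <- c(TRUE, o$chrom[-1] != o$chrom[-nrow(o)] |
                    o$start[-1] != o$end[-nrow(o)])
  grp <- cumsum(new_region)
  out <- data.frame(
    chrom = tapply(o$chrom, grp, `[`, 1),
    core_start = as.numeric(tapply(o$start, grp, min)),
    core_end = as.numeric(tapply(o$end, grp, max)),
    peak_value = as.numeric(tapply(o$value, grp, max)),
    n_windows = as.integer(tapply(o$value, grp, length)),
    stringsAsFactors = FALSE)
  len <- chrom_sizes[out$chrom]
  if (any(is.na(len)))
    stop("chromosome missing from chrom_sizes: ",
         out$chrom[which(is.na(len))[1]])
  out$ext_start <- pmax(0, out$core_start - pad)
  out$ext_end <- pmin(as.numeric(len), out$core_end + pad)
  out <- out[, c("chrom", "core_start", "core_end", "ext_start", "ext_end",
                 "peak_value", "n_windows")]
  rownames(out) <- NULL
  class(out) <- c("sweep_regions", class(out))
  out
}

#' Compare outlier-window sets between two contrasts
#'
#' Reports how many windows of contrast A are absent from contrast B
#' ("novel") and how many are shared, by exact window identity on a common
#' tiling. The novel fraction is also given as an integer percentage, the
#' form in which such comparisons are usually quoted (e.g. 8 of 21 novel
#' windows = 38%).
#'
#' @param setA,setB `window_stats` data.frames (typically outlier sets) on
#'   the same window tiling.
#' @return list with `n_A`, `n_B`, `n_novel`, `n_shared`, `novel_fraction`,
#'   `novel_percent`, and the novel windows themselves.
#' @export
compare_contrasts <- function(setA, setB) {
  wA <- attr(setA, "window_size"); wB <- attr(setB, "window_size")
  if (!is.null(wA) && !is.null(wB) && wA != wB)
    stop("window tilings differ between the two sets (", wA, " vs ", wB, " bp)")
  keyA <- paste(setA$chrom, setA$start, setA$end)
  keyB <- paste(setB$chrom, setB$start, setB$end)
  novel <- !(keyA %in% keyB)
  list(n_A = nrow(setA), n_B = nrow(setB),
       n_novel = sum(novel), n_shared = sum(!novel),
       novel_fraction = if (nrow(setA)) sum(novel) / nrow(setA) else NA_real_,
       novel_percent = if (nrow(setA)) round(100 * sum(novel) / nrow(setA)) else NA_real_,
       novel_windows = setA[novel, , drop = FALSE])
}
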