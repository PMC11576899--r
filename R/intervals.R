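#' Genomic interval sets
#'
#' An `interval_set` is a data frame of genomic intervals with columns
#' `chrom`, `start`, `end` in 0-based half-open coordinates (BED
#' convention), sorted by chromosome and start, non-overlapping after
#' merging, and carrying an optional `label` attribute (e.g. a trait name).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `end > start`.
#' @param label optional label for the set (trait name).
#' @param merge merge overlapping/adjacent intervals (default `TRUE`).
#' @return An object of class `interval_set`.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), label = NULL, merge = TRUE) {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end <= start))
    stop("interval end must be greater than start (0-based half-open)")
  if (any(start < 0)) stop("negative interval start")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (merge && nrow(df) > 0) df <- merge_intervals(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("interval_set", "data.frame"))
}

## Union of possibly overlapping intervals, per chromosome.  The interval
## algebra is delegated to IRanges::reduce after shifting to 1-based closed.
merge_intervals <- function(df) {
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build trait-associated genomic regions (TAGRs) from GWAS hits
#'
#' Each hit position receives a fixed-width window centred on it;
#' overlapping or adjacent windows are merged into a single region.
#' Input positions are 1-based (VCF convention); output intervals are
#' 0-based half-open and clipped at zero.
#'
#' @param hits data frame with columns `chrom` and `pos` (1-based), or a
#'   two-column matrix-like object coercible to one.
#' @param window_bp total window width in bp (even; default 20000).
#' @param label optional trait label attached to the result.
#' @return An `interval_set` of merged windows (empty if `hits` is empty).
#' @export
define_tagrs <- function(hits, window_bp = 20000, label = NULL) {
  if (window_bp <= 0 || window_bp %% 2 != 0)
    stop("window_bp must be a positive even number")
  hits <- as.data.frame(hits)
  if (nrow(hits) == 0)
    return(interval_set(label = label))
  if (!all(c("chrom", "pos") %in% names(hits)))
    names(hits)[1:2] <- c("chrom", "pos")
  half <- window_bp / 2
  start <- pmax(0, hits$pos - 1 - half)
  end <- hits$pos - 1 + half
  interval_set(hits$chrom, start, end, label = label)
}

#' Indices of variants falling in an interval set
#'
#' @param x a `genotype_matrix` (or a data frame of variants with `chrom`
#'   and 1-based `pos` columns).
#' @param regions an `interval_set` (0-based half-open).
#' @return Integer vector of variant indices, in original (stable) order;
#'   may be empty.
#' @export
restrict_variants <- function(x, regions) {
  v <- if (inherits(x, "genotype_matrix")) x$variants else as.data.frame(x)
  if (nrow(v) == 0 || nrow(regions) == 0) return(integer())
  pos0 <- v$pos - 1  # 0-based position of the variant
  keep <- logical(nrow(v))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    iv <- which(v$chrom == ch)
    if (!length(iv)) next
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = pos0[iv] + 1, width = 1),
      IRanges::IRanges(start = r$start + 1, end = r$end))
    keep[iv] <- hit
  }
  which(keep)
}
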