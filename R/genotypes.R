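#' Diploid genotype matrix with variant and sample metadata
#'
#' The central container: an individuals x variants dosage matrix with
#' entries in {0, 1, 2, NA}, variant coordinates (1-based positions, as in
#' VCF) and alleles, and per-sample metadata (id, group/ancestry label,
#' optional sibship id).
#'
#' @param dosage numeric/integer matrix, individuals in rows, variants in
#'   columns; values 0, 1, 2 or NA.
#' @param variants data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` (alleles may be NA for simulated data).
#' @param samples data frame with at least a column `id`; optional
#'   `group` (ancestry/population label) and `sibship` columns.
#' @param validate check dosage values and variant uniqueness (default
#'   `TRUE`; the simulator skips it for matrices it builds itself).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples = NULL,
                            validate = TRUE) {
  dosage <- as.matrix(dosage)
  variants <- as.data.frame(variants)
  if (is.null(samples)) {
    samples <- data.frame(id = if (!is.null(rownames(dosage)))
      rownames(dosage) else sprintf("ind%d", seq_len(nrow(dosage))),
      stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples)
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but variants has ",
         nrow(variants), " rows")
  if (nrow(dosage) != nrow(samples))
    stop("dosage has ", nrow(dosage), " rows but samples has ",
         nrow(samples), " rows")
  if (!all(c("chrom", "pos") %in% names(variants)))
    stop("variants must have chrom and pos columns")
  if (validate) {
    bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
    if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
    dup <- duplicated(variants[c("chrom", "pos")])
    if (any(dup)) stop("duplicated variant positions per chromosome")
  }
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " variants\n", sep = "")
  if ("group" %in% names(x$samples))
    print(table(x$samples$group))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or variants
#'
#' @param x a `genotype_matrix`.
#' @param individuals,variants index vectors (integer/logical); `NULL`
#'   keeps all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(individuals)) individuals <- seq_len(nrow(x$dosage))
  if (is.null(variants)) variants <- seq_len(ncol(x$dosage))
  genotype_matrix(x$dosage[individuals, variants, drop = FALSE],
                  x$variants[variants, , drop = FALSE],
                  x$samples[individuals, , drop = FALSE])
}

#' Per-ancestry reference allele frequencies
#'
#' Computes the effect(alt)-allele frequency of each variant in each
#' ancestry group of a labelled reference panel, together with the number
#' of non-missing diploid calls.  Loci where any ancestry has fewer than
#' `min_calls` non-missing calls are masked (frequency set to NA) for all
#' ancestries, so that covA always contrasts the same locus set across
#' ancestries.
#'
#' @param panel a `genotype_matrix` whose `samples$group` labels every
#'   sample with one ancestry.
#' @param min_calls minimum non-missing diploid calls per ancestry per
#'   locus (default 10).
#' @return An object of class `ref_freqs`: list with `freq` and `calls`
#'   (variants x ancestries matrices), `ancestries`, and the `variants`
#'   table aligned to the panel.
#' @export
panel_frequencies <- function(panel, min_calls = 10) {
  stopifnot(inherits(panel, "genotype_matrix"))
  if (!"group" %in% names(panel$samples))
    stop("panel samples must carry a group (ancestry) label")
  grp <- as.character(panel$samples$group)
  if (anyNA(grp)) stop("all panel samples must be labelled")
  ancs <- sort(unique(grp))
  cnt <- table(grp)
  if (any(cnt == 0)) stop("empty ancestry group")
  m <- ncol(panel$dosage)
  freq <- matrix(NA_real_, m, length(ancs), dimnames = list(NULL, ancs))
  calls <- matrix(0L, m, length(ancs), dimnames = list(NULL, ancs))
  for (a in ancs) {
    d <- panel$dosage[grp == a, , drop = FALSE]
    n_ok <- colSums(!is.na(d))
    alt <- colSums(d, na.rm = TRUE)
    calls[, a] <- n_ok
    freq[, a] <- ifelse(n_ok > 0, alt / (2 * n_ok), NA_real_)
  }
  mask <- rowSums(calls < min_calls) > 0
  freq[mask, ] <- NA_real_
  structure(list(freq = freq, calls = calls, ancestries = ancs,
                 variants = panel$variants, min_calls = min_calls),
            class = "ref_freqs")
}

#' @export
print.ref_freqs <- function(x, ...) {
  cat("ref_freqs: ", nrow(x$freq), " variants x ",
      length(x$ancestries), " ancestries (",
      paste(x$ancestries, collapse = ", "), "); ",
      sum(!is.na(x$freq[, 1])), " unmasked loci\n", sep = "")
  invisible(x)
}
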