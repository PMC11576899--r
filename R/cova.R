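#' Compute the covA ancestry-similarity statistic
#'
#' For each individual i and ancestry p, covA is the covariance-like
#' cross-product between the individual's (haploid-scale) allele dosages
#' and the ancestry's reference allele frequencies, both centred:
#'
#' \deqn{covA(i,p) = \frac{1}{|S|}\sum_{l \in S}
#'   (x_{il} - \bar f_l)(f_{pl} - \bar g_l)}
#'
#' where \eqn{x_{il}} is dosage/2, \eqn{\bar f_l} the contemporary cohort
#' mean of \eqn{x_{\cdot l}}, \eqn{f_{pl}} the ancestry-p reference
#' frequency and \eqn{\bar g_l} the unweighted mean of \eqn{f_{\cdot l}}
#' across ancestries.  Centring by \eqn{\bar g_l} makes the statistic a
#' relative distance: values sum to zero across ancestries for every
#' individual, so with three ancestries there are two degrees of freedom.
#' Restricting the locus set S to trait-associated genomic regions yields
#' "TAGR-covA"; using all loci yields the genome-wide "GW-covA".
#'
#' Loci masked in `freqs` are dropped.  Missing dosages are handled by
#' skip-and-rescale: locus l is skipped for individual i and the sum
#' renormalized by that individual's non-missing locus count.
#'
#' @param cohort a `genotype_matrix` of contemporary individuals.
#' @param freqs a `ref_freqs` object with the same variant index.
#' @param regions optional `interval_set`; if supplied, covA is restricted
#'   to variants inside the regions (TAGR-covA).
#' @param standardize scale each ancestry's covA across individuals to
#'   mean 0, SD 1 (default `FALSE`; regression helpers standardize).
#' @return A `cova_matrix`: individuals x ancestries matrix with
#'   attributes `scope` ("genome-wide" or the region label), `n_loci`
#'   (size of the locus set) and `standardized`.
#' @export
compute_cova <- function(cohort, freqs, regions = NULL, standardize = FALSE) {
  stopifnot(inherits(cohort, "genotype_matrix"), inherits(freqs, "ref_freqs"))
  if (ncol(cohort$dosage) != nrow(freqs$freq))
    stop("cohort and reference frequencies have different variant counts")
  keep <- !is.na(freqs$freq[, 1])
  scope <- "genome-wide"
  if (!is.null(regions)) {
    idx <- restrict_variants(cohort, regions)
    if (length(idx) == 0)
      stop("no cohort variants fall inside the supplied regions")
    sel <- logical(ncol(cohort$dosage)); sel[idx] <- TRUE
    keep <- keep & sel
    scope <- if (!is.null(attr(regions, "label")))
      paste0("TAGR:", attr(regions, "label")) else "TAGR"
  }
  if (!any(keep))
    stop("all loci are masked in the reference frequencies")
  x <- cohort$dosage[, keep, drop = FALSE] / 2
  f <- freqs$freq[keep, , drop = FALSE]
  gbar <- rowMeans(f)
  D <- f - gbar                       # loci x ancestries, rows sum to 0
  fbar <- colMeans(x, na.rm = TRUE)
  xc <- sweep(x, 2, fbar)
  miss <- is.na(xc)
  n_i <- ncol(xc) - rowSums(miss)     # per-individual usable locus count
  if (any(n_i == 0)) stop("some individuals have no non-missing loci")
  xc[miss] <- 0
  cova <- (xc %*% D) / n_i
  rownames(cova) <- cohort$samples$id
  if (standardize) cova <- scale(cova)[, , drop = FALSE]
  structure(cova, scope = scope, n_loci = sum(keep),
            standardized = standardize, class = c("cova_matrix", "matrix"))
}

#' Standardize a covA matrix per ancestry
#'
#' Centres and scales each ancestry's covA values across individuals.
#' Any constant factor in the covA normalisation is immaterial after this.
#'
#' @param cova a `cova_matrix`.
#' @return The standardized `cova_matrix`.
#' @export
standardize_cova <- function(cova) {
  out <- scale(unclass(cova))[, , drop = FALSE]
  rownames(out) <- rownames(cova)
  structure(out, scope = attr(cova, "scope"), n_loci = attr(cova, "n_loci"),
            standardized = TRUE, class = c("cova_matrix", "matrix"))
}

#' @export
print.cova_matrix <- function(x, ...) {
  cat("cova_matrix: ", nrow(x), " individuals x ", ncol(x),
      " ancestries; scope ", attr(x, "scope"), ", ",
      attr(x, "n_loci"), " loci",
      if (isTRUE(attr(x, "standardized"))) ", standardized", "\n", sep = "")
  invisible(x)
}

#' GWAS-like ascertainment of causal variants
#'
#' Mimics GWAS discovery bias by keeping causal SNPs according to the
#' fraction of trait variance they explain in the contemporary cohort:
#' \eqn{varexp_l = 2 f_l (1 - f_l) \beta_l^2 / Var(t)}, with \eqn{f_l}
#' the cohort effect-allele frequency.  A SNP is ascertained iff
#' `varexp >= tau`.
#'
#' @param freq cohort effect-allele frequencies of the causal SNPs.
#' @param beta per-SNP effect sizes, aligned to `freq`.
#' @param trait_var phenotypic variance of the trait in the cohort.
#' @param tau variance-explained threshold (default
#'   `ancestra_defaults()$tau`).
#' @return Logical vector: `TRUE` for ascertained SNPs.
#' @export
ascertain_causal <- function(freq, beta, trait_var,
                             tau = ancestra_defaults()$tau) {
  if (tau < 0) stop("tau must be non-negative")
  if (length(freq) != length(beta)) stop("freq and beta lengths differ")
  if (!is.finite(trait_var) || trait_var <= 0)
    stop("trait variance must be positive")
  varexp <- 2 * freq * (1 - freq) * beta^2 / trait_var
  varexp >= tau
}

#' Package-wide default thresholds
#'
#' Single home for tunables shared across the analysis stages.
#'
#' @return Named list: `tau` (ascertainment variance-explained threshold),
#'   `min_calls` (per-ancestry per-locus call minimum), `fdr_q`
#'   (Benjamini-Hochberg level), `kinship_bounds` (full-sibling kinship
#'   window), `window_bp` (TAGR window width), `gw_cova_pair` (the two
#'   ancestries whose genome-wide covA enters models as controls).
#' @export
ancestra_defaults <- function() {
  list(tau = 1.5e-4,
       min_calls = 10,
       fdr_q = 0.05,
       kinship_bounds = c(0.177, 0.354),
       window_bp = 20000,
       gw_cova_pair = c("WHG", "EEF"))
}
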