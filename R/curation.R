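#' Project ancient samples onto modern principal components
#'
#' PCA is computed on the modern cohort's dosages, centred at twice the
#' allele frequency and scaled by the binomial SD sqrt(2 f (1 - f))
#' (monomorphic loci dropped).  Ancient samples, which typically have
#' substantial missingness, are projected by least squares on their
#' non-missing loci: the projection solves
#' \eqn{\hat b = (V_O' V_O)^{-1} V_O' z_O} over the observed locus set O,
#' which reduces to the ordinary PCA score when no loci are missing.
#'
#' @param moderns a `genotype_matrix` of modern reference individuals
#'   (complete enough for PCA; loci with missing modern calls are
#'   dropped).
#' @param ancients a `genotype_matrix` of candidate ancient samples on
#'   the same variant index.
#' @param k number of components (default 3).
#' @return List with `modern_scores` and `ancient_scores` (samples x k),
#'   `sdev`, and the locus `center`/`scale` used.
#' @export
pca_project <- function(moderns, ancients, k = 3) {
  stopifnot(inherits(moderns, "genotype_matrix"),
            inherits(ancients, "genotype_matrix"))
  if (ncol(moderns$dosage) != ncol(ancients$dosage))
    stop("moderns and ancients must share the variant index")
  X <- moderns$dosage
  use <- colSums(is.na(X)) == 0
  f <- colMeans(X[, use, drop = FALSE]) / 2
  poly <- f > 0 & f < 1
  use[use] <- poly
  f <- f[poly]
  if (sum(use) < k)
    stop("k exceeds the available components (",
         sum(use), " usable loci)")
  ctr <- 2 * f
  scl <- sqrt(2 * f * (1 - f))
  Z <- sweep(sweep(X[, use, drop = FALSE], 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  if (k > ncol(pc$rotation)) stop("k exceeds the available components")
  V <- pc$rotation[, seq_len(k), drop = FALSE]
  modern_scores <- pc$x[, seq_len(k), drop = FALSE]
  A <- ancients$dosage[, use, drop = FALSE]
  ancient_scores <- matrix(NA_real_, nrow(A), k,
                           dimnames = list(ancients$samples$id,
                                           colnames(V)))
  for (i in seq_len(nrow(A))) {
    obs <- which(!is.na(A[i, ]))
    if (length(obs) < k)
      stop("ancient sample ", ancients$samples$id[i],
           " has fewer non-missing loci than components")
    z <- (A[i, obs] - ctr[obs]) / scl[obs]
    Vo <- V[obs, , drop = FALSE]
    ancient_scores[i, ] <- drop(solve(crossprod(Vo), crossprod(Vo, z)))
  }
  rownames(modern_scores) <- moderns$samples$id
  list(modern_scores = modern_scores, ancient_scores = ancient_scores,
       sdev = pc$sdev[seq_len(k)], center = ctr, scale = scl)
}

#' Expand a curated core set by an ellipse rule
#'
#' Candidates are included when they fall inside the multi-dimensional
#' ellipse centred on the core set's per-dimension means, with semi-axes
#' of `semi_axis_sd` core-set standard deviations (the default 1.5 reads
#' "diameters equal to 3 core set SDs" as semi-axes of 1.5 SD):
#' \deqn{\sum_d \left(\frac{x_d - \mu_d}{s \cdot \sigma_d}\right)^2 \le 1.}
#' The usual dimensions are (date, PC1, PC2, PC3).
#'
#' @param core data frame of core-set coordinates (numeric columns =
#'   dimensions; >= 2 rows).
#' @param candidates data frame of candidate coordinates with the same
#'   columns.
#' @param semi_axis_sd ellipse semi-axis in core-SD units (default 1.5).
#' @return Logical inclusion flag per candidate, with the ellipse
#'   distance in attribute `distance`.
#' @export
expand_core_set <- function(core, candidates, semi_axis_sd = 1.5) {
  core <- as.data.frame(core)
  candidates <- as.data.frame(candidates)
  dims <- names(core)[vapply(core, is.numeric, logical(1))]
  if (!all(dims %in% names(candidates)))
    stop("candidates lack dimension(s): ",
         paste(setdiff(dims, names(candidates)), collapse = ", "))
  if (nrow(core) < 2) stop("core set needs at least 2 samples")
  mu <- vapply(core[dims], mean, numeric(1))
  sig <- vapply(core[dims], stats::sd, numeric(1))
  if (any(sig == 0))
    stop("zero core-set SD in dimension(s): ",
         paste(dims[sig == 0], collapse = ", "))
  d2 <- rowSums(sweep(sweep(as.matrix(candidates[dims]), 2, mu), 2,
                      semi_axis_sd * sig, "/")^2)
  structure(d2 <= 1, distance = sqrt(d2))
}
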