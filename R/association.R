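#' Preprocess a trait vector
#'
#' Applies the standard trait pipeline: optional log transform, optional
#' residualization on an adjustment covariate (e.g. BMI), removal of
#' outliers more distant than `iqr_mult` IQRs from the upper or lower
#' quartile, and standardization to mean 0, SD 1.  Removed individuals
#' are set to NA so they drop out of that trait's regressions only.
#' Categorical traits must already be coded {0, 1}; ordinal traits are
#' converted to an ordered factor with the stated category order.
#'
#' @param raw numeric vector (or factor/character for ordinal).
#' @param type `"continuous"`, `"categorical"` or `"ordinal"`.
#' @param transform `"none"` or `"log"` (continuous only).
#' @param adjust_on optional covariate to residualize on (continuous
#'   only), same length as `raw`.
#' @param levels category order for ordinal traits (low to high).
#' @param iqr_mult outlier distance in IQR units (default 4).
#' @return An object of class `trait_vector`: list with `values`
#'   (standardized, NA for removed individuals), `type`, `levels` and a
#'   `log` of the steps applied.
#' @export
preprocess_trait <- function(raw, type = c("continuous", "categorical",
                                           "ordinal"),
                             transform = c("none", "log"),
                             adjust_on = NULL, levels = NULL,
                             iqr_mult = 4) {
  type <- match.arg(type)
  transform <- match.arg(transform)
  steps <- character(0)
  if (type == "categorical") {
    v <- as.numeric(raw)
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop("categorical traits must be coded {0, 1}")
    return(structure(list(values = v, type = type, levels = NULL,
                          log = "coded {0,1}"), class = "trait_vector"))
  }
  if (type == "ordinal") {
    f <- factor(raw, levels = if (is.null(levels)) sort(unique(raw))
                else levels, ordered = TRUE)
    return(structure(list(values = f, type = type,
                          levels = base::levels(f),
                          log = "ordered factor"), class = "trait_vector"))
  }
  v <- as.numeric(raw)
  if (transform == "log") {
    if (any(v <= 0, na.rm = TRUE))
      stop("log transform of nonpositive trait values")
    v <- log(v)
    steps <- c(steps, "log")
  }
  if (!is.null(adjust_on)) {
    if (length(adjust_on) != length(v))
      stop("adjustment covariate length mismatch")
    fit <- stats::lm(v ~ adjust_on, na.action = stats::na.exclude)
    v <- stats::residuals(fit)
    steps <- c(steps, "residualized")
  }
  q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  out_lo <- q[1] - iqr_mult * iqr
  out_hi <- q[2] + iqr_mult * iqr
  drop <- !is.na(v) & (v < out_lo | v > out_hi)
  v[drop] <- NA
  steps <- c(steps, sprintf("%d outliers removed (%g-IQR rule)",
                            sum(drop), iqr_mult))
  s <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("zero trait variance after filtering")
  v <- (v - mean(v, na.rm = TRUE)) / s
  steps <- c(steps, "standardized")
  structure(list(values = v, type = type, levels = NULL, log = steps),
            class = "trait_vector")
}

trait_values <- function(trait) {
  if (inherits(trait, "trait_vector")) trait$values else trait
}

trait_type <- function(trait, default = "continuous") {
  if (inherits(trait, "trait_vector")) trait$type else default
}

## Model matrix for the covariate table: factor/character columns are
## expanded to treatment contrasts; constant columns are an error.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop("covariate table has wrong length")
  const <- vapply(covariates, function(x)
    length(unique(x[!is.na(x)])) < 2, logical(1))
  if (any(const))
    stop("constant covariate column(s): ",
         paste(names(covariates)[const], collapse = ", "))
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE]  # drop intercept; models add their own
}

## Rank check naming the aliased columns.
check_collinearity <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("perfectly collinear regressors: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

assoc_row <- function(trait_name, ancestry, model, coef, se, p, n,
                      estimate = coef) {
  structure(data.frame(trait = trait_name, ancestry = ancestry,
                       model = model, estimate = estimate, coef = coef,
                       se = se, z = coef / se, p = p, n = n,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Regress a trait on covA for one ancestry
#'
#' Fits \eqn{t_i = \beta_0 + \beta_{covA(p)} covA(i,p) + \beta_c c + \epsilon_i}
#' with the standardized covA of ancestry p and an optional covariate
#' table.  Continuous traits use least squares (estimate = slope),
#' categorical {0,1} traits a logistic regression (estimate = odds
#' ratio), ordinal traits a proportional-odds logistic regression
#' (estimate = odds ratio).  Two-sided Wald p-values in all cases.  When
#' covA is TAGR-restricted, the genome-wide covA pair of two ancestries
#' should be part of the covariates to control for genome-wide structure.
#'
#' @param trait a `trait_vector` or numeric vector (categorical traits
#'   as 0/1, ordinal as ordered factor).
#' @param cova a `cova_matrix` (standardized internally if not already)
#'   or a numeric vector of covA values for ancestry p.
#' @param ancestry which ancestry's covA column to test (required when
#'   `cova` is a matrix).
#' @param covariates optional data frame of covariates; factors are
#'   expanded to indicator contrasts.
#' @param trait_name label carried into the result row.
#' @return An `association_result` data frame row: trait, ancestry,
#'   model, estimate (slope or OR), coef (link scale), se, z, p, n.
#' @export
fit_cova_model <- function(trait, cova, ancestry = NULL, covariates = NULL,
                           trait_name = "trait") {
  if (inherits(cova, "cova_matrix") || is.matrix(cova)) {
    if (is.null(ancestry)) stop("ancestry is required with a covA matrix")
    if (!isTRUE(attr(cova, "standardized")) &&
        inherits(cova, "cova_matrix"))
      cova <- standardize_cova(cova)
    x <- unclass(cova)[, ancestry]
  } else {
    x <- as.numeric(cova)
    if (is.null(ancestry)) ancestry <- "covA"
  }
  y <- trait_values(trait)
  type <- trait_type(trait,
                     default = if (is.ordered(y)) "ordinal"
                     else "continuous")
  n_all <- length(y)
  if (length(x) != n_all) stop("trait and covA lengths differ")
  cm <- covariate_matrix(covariates, n_all)
  X <- cbind(covA = x, cm)
  keep <- stats::complete.cases(X) & !is.na(y)
  y <- if (type == "ordinal") y[keep] else as.numeric(y)[keep]
  X <- X[keep, , drop = FALSE]
  n <- sum(keep)
  if (n <= ncol(X) + 1) stop("more parameters than observations")
  check_collinearity(cbind(1, X))
  df <- data.frame(X, check.names = FALSE)
  if (type == "continuous") {
    fit <- stats::lm(y ~ ., data = df)
    cf <- summary(fit)$coefficients["covA", ]
    return(assoc_row(trait_name, ancestry, "linear",
                     coef = cf[1], se = cf[2], p = cf[4], n = n))
  }
  if (type == "categorical") {
    if (!all(y %in% c(0, 1))) stop("categorical trait must be coded {0,1}")
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    if (!fit$converged)
      stop("logistic regression did not converge after ", fit$iter,
           " iterations")
    cf <- summary(fit)$coefficients["covA", ]
    return(assoc_row(trait_name, ancestry, "logistic",
                     coef = cf[1], se = cf[2], p = cf[4], n = n,
                     estimate = exp(cf[1])))
  }
  ## ordinal: proportional-odds logistic regression
  df$.y <- y
  fit <- tryCatch(MASS::polr(.y ~ ., data = df, Hess = TRUE),
                  error = function(e)
                    stop("proportional-odds fit failed: ",
                         conditionMessage(e)))
  if (fit$convergence != 0)
    stop("proportional-odds fit did not converge (code ",
         fit$convergence, ")")
  cf <- summary(fit)$coefficients["covA", ]
  p <- 2 * stats::pnorm(-abs(cf[3]))
  assoc_row(trait_name, ancestry, "ordinal",
            coef = cf[1], se = cf[2], p = p, n = n,
            estimate = exp(cf[1]))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up FDR adjustment at level `q`.
#'
#' @param pvalues vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (monotone BH-adjusted values) and
#'   `significant` (logical flags at level `q`); empty input gives empty
#'   output.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0)
    return(list(adjusted = numeric(0), significant = logical(0)))
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, significant = !is.na(adj) & adj <= q)
}

#' Build sibships from a pairwise kinship table
#'
#' Retains pairs whose kinship coefficient lies within `bounds` and that
#' are flagged full siblings, forms connected components over the
#' retained pairs, and removes entirely any component whose members are
#' not all pairwise full siblings.
#'
#' @param kinship data frame with columns `id1`, `id2`, `kinship` and
#'   `full_sib` (logical).
#' @param bounds kinship window for full siblings (default
#'   `c(0.177, 0.354)`).
#' @return An object of class `sibship_assignment`: data frame with
#'   columns `id` and `sibship`, plus a `sizes` attribute.
#' @export
build_sibships <- function(kinship,
                           bounds = ancestra_defaults()$kinship_bounds) {
  kinship <- as.data.frame(kinship)
  need <- c("id1", "id2", "kinship", "full_sib")
  if (!all(need %in% names(kinship)))
    stop("kinship table needs columns: ", paste(need, collapse = ", "))
  if (any(kinship$id1 == kinship$id2))
    stop("self-pairs in the kinship table")
  ok <- kinship$kinship >= bounds[1] & kinship$kinship <= bounds[2] &
    as.logical(kinship$full_sib)
  pairs <- kinship[ok, , drop = FALSE]
  if (nrow(pairs) == 0)
    return(structure(data.frame(id = character(0), sibship = integer(0),
                                stringsAsFactors = FALSE),
                     sizes = integer(0), class = c("sibship_assignment",
                                                   "data.frame")))
  ## dedupe unordered pairs
  key <- paste(pmin(pairs$id1, pairs$id2), pmax(pairs$id1, pairs$id2))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(pairs[c("id1", "id2")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  ## a complete sibship of size s has choose(s, 2) retained pairs
  n_pairs <- table(memb[pairs$id1])
  sizes <- comp$csize
  complete <- sizes[as.integer(names(n_pairs))] *
    (sizes[as.integer(names(n_pairs))] - 1) / 2 == as.vector(n_pairs)
  keep_comp <- as.integer(names(n_pairs))[complete]
  keep <- memb %in% keep_comp
  out <- data.frame(id = names(memb)[keep],
                    sibship = match(memb[keep], sort(keep_comp)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sibship, out$id), ]
  rownames(out) <- NULL
  structure(out, sizes = as.integer(table(out$sibship)),
            class = c("sibship_assignment", "data.frame"))
}

#' Within-sibship covA association
#'
#' Decomposes each individual's covA into the sibship mean
#' \eqn{covA_{sib}} and the within-sibship residual
#' \eqn{covA' = covA - covA_{sib}} (so \eqn{covA' + covA_{sib} = covA}
#' exactly) and fits
#' \eqn{t_i = \beta_0 + \beta' covA'(i,p) + \beta_{sib} covA_{sib}(i,p)
#' + \beta_c c + \epsilon_i}.  The reported estimate is the coefficient
#' on \eqn{covA'}, which is robust to environmental confounders that are
#' constant within sibships and correlated with between-family ancestry.
#'
#' @param trait a `trait_vector` or numeric vector.
#' @param cova a `cova_matrix` (rownames = individual ids) or numeric
#'   vector aligned to the individuals.
#' @param ancestry covA column to test (matrix input).
#' @param sibships a `sibship_assignment` (matched to individuals by
#'   `ids`) or a vector of sibship ids aligned to the individuals (NA =
#'   not in a sibship).
#' @param covariates optional covariate data frame (aligned to
#'   individuals); for TAGR-covA this should include the genome-wide
#'   covA pair.
#' @param ids individual ids, needed to match a `sibship_assignment`;
#'   defaults to the covA matrix rownames.
#' @param trait_name label carried into the result row.
#' @return An `association_result` row for the within-sibship
#'   coefficient (`model = "sibling"`), with the between coefficient in
#'   attributes `coef_sib`, `se_sib`.
#' @export
fit_sibling_model <- function(trait, cova, ancestry = NULL, sibships,
                              covariates = NULL, ids = NULL,
                              trait_name = "trait") {
  if (inherits(cova, "cova_matrix") || is.matrix(cova)) {
    if (is.null(ancestry)) stop("ancestry is required with a covA matrix")
    if (!isTRUE(attr(cova, "standardized")) &&
        inherits(cova, "cova_matrix"))
      cova <- standardize_cova(cova)
    if (is.null(ids)) ids <- rownames(cova)
    x <- unclass(cova)[, ancestry]
  } else {
    x <- as.numeric(cova)
    if (is.null(ancestry)) ancestry <- "covA"
  }
  y <- as.numeric(trait_values(trait))
  n_all <- length(y)
  if (length(x) != n_all) stop("trait and covA lengths differ")
  sib <- if (inherits(sibships, "sibship_assignment")) {
    if (is.null(ids)) stop("ids are required to match a sibship assignment")
    sibships$sibship[match(ids, sibships$id)]
  } else as.vector(sibships)
  if (length(sib) != n_all) stop("sibship vector length mismatch")
  cm <- covariate_matrix(covariates, n_all)
  keep <- !is.na(sib) & !is.na(y) & !is.na(x)
  if (!is.null(cm)) keep <- keep & stats::complete.cases(cm)
  ## sibships need >= 2 analyzable members
  tab <- table(sib[keep])
  keep <- keep & sib %in% names(tab)[tab >= 2]
  if (!any(keep)) stop("no sibship has two or more analyzable members")
  y <- y[keep]; x <- x[keep]; sibk <- sib[keep]
  cova_sib <- stats::ave(x, sibk)
  cova_prime <- x - cova_sib
  if (stats::sd(cova_prime) == 0)
    stop("covA' is identically zero: no within-sibship covA variation")
  X <- cbind(covA_prime = cova_prime, covA_sib = cova_sib,
             if (!is.null(cm)) cm[keep, , drop = FALSE])
  check_collinearity(cbind(1, X))
  df <- data.frame(X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  out <- assoc_row(trait_name, ancestry, "sibling",
                   coef = cf["covA_prime", 1], se = cf["covA_prime", 2],
                   p = cf["covA_prime", 4], n = sum(keep))
  attr(out, "coef_sib") <- cf["covA_sib", 1]
  attr(out, "se_sib") <- cf["covA_sib", 2]
  out
}
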