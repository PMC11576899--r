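#' Three-ancestry admixture demography
#'
#' Builds and validates the demographic model used by the simulator: a
#' single ancestral population whose WHG-like branch splits first, a later
#' split of the remaining branch into EEF-like and SBA-like branches, and
#' a present-day lineage formed by the WHG substratum receiving admixture
#' pulses from the other branches.  All times are in generations before
#' present.  The expected final ancestry fractions follow in closed form
#' from the pulse proportions: processing pulses from oldest to youngest,
#' a pulse of proportion m from source s rescales all current fractions by
#' (1 - m) and adds m to source s.
#'
#' Defaults give a model relevant for a Northwest-European cohort: WHG
#' split 800 generations ago (about 23 ky at 29 y/generation), EEF/SBA
#' split 400 generations ago, an EEF pulse of 0.782 at 250 generations and
#' an SBA pulse of 0.45 at 150 generations, so the expected WHG-like
#' fraction is (1 - 0.782) x (1 - 0.45) = 0.1199, matching the ~12%
#' WHG-like contribution estimated for present-day Britain.
#'
#' @param ancestries character vector of ancestry labels; the first is the
#'   substratum of the present-day lineage.
#' @param ne named diploid population sizes: one per ancestry branch, plus
#'   `ancestral` (pre-split) and `present` (post-first-pulse lineage).
#' @param split_whg,split_ees generations before present of the WHG split
#'   and of the EEF/SBA split (`split_whg > split_ees`).
#' @param pulses data frame with columns `time` (generations before
#'   present, strictly decreasing), `source` (ancestry label) and
#'   `prop` (in `[0,1]`).
#' @param generation_time years per generation (bookkeeping only).
#' @return A validated object of class `demography_model` with an
#'   `expected_fractions` component (named, sums to 1).
#' @export
build_demography <- function(ancestries = c("WHG", "EEF", "SBA"),
                             ne = c(ancestral = 10000, WHG = 10000,
                                    EEF = 10000, SBA = 10000,
                                    present = 100000),
                             split_whg = 800, split_ees = 400,
                             pulses = data.frame(
                               time = c(250, 150),
                               source = c("EEF", "SBA"),
                               prop = c(0.782, 0.45)),
                             generation_time = 29) {
  if (length(ancestries) != 3) stop("exactly three ancestries are required")
  pulses <- as.data.frame(pulses)
  if (nrow(pulses) > 0) {
    if (any(pulses$prop < 0 | pulses$prop > 1))
      stop("pulse proportions must lie in [0, 1]")
    if (!all(pulses$source %in% ancestries))
      stop("pulse sources must be named ancestries")
    if (is.unsorted(rev(pulses$time), strictly = TRUE))
      stop("pulse times must be strictly decreasing (oldest first)")
  }
  if (!(split_whg > split_ees))
    stop("event times not ordered: WHG split must predate EEF/SBA split")
  if (nrow(pulses) > 0 && split_ees <= max(pulses$time))
    stop("event times not ordered: admixture pulses must postdate the splits")
  need <- c("ancestral", ancestries, "present")
  if (!all(need %in% names(ne)))
    stop("ne must name: ", paste(need, collapse = ", "))
  if (any(ne <= 0)) stop("population sizes must be positive")
  frac <- stats::setNames(c(1, 0, 0), ancestries)  # substratum lineage
  if (nrow(pulses) > 0) {
    for (k in seq_len(nrow(pulses))) {
      frac <- frac * (1 - pulses$prop[k])
      frac[pulses$source[k]] <- frac[pulses$source[k]] + pulses$prop[k]
    }
  }
  stopifnot(abs(sum(frac) - 1) < 1e-12)
  structure(list(ancestries = ancestries, ne = ne, split_whg = split_whg,
                 split_ees = split_ees, pulses = pulses,
                 generation_time = generation_time,
                 expected_fractions = frac),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat("demography_model:", paste(x$ancestries, collapse = "/"), "\n")
  cat("  splits (gen BP):", x$split_whg, "(WHG),", x$split_ees, "(EEF/SBA)\n")
  if (nrow(x$pulses)) {
    cat("  pulses:\n")
    for (k in seq_len(nrow(x$pulses)))
      cat(sprintf("    t=%d  %s  m=%.3f\n", x$pulses$time[k],
                  x$pulses$source[k], x$pulses$prop[k]))
  }
  cat("  expected fractions:",
      paste(sprintf("%s=%.4f", names(x$expected_fractions),
                    x$expected_fractions), collapse = "  "), "\n")
  invisible(x)
}

## Rescale a demography by 1/scale: Ne and times divided by scale.
## Used by the desk-scale simulation profile.
scale_demography <- function(dem, scale) {
  build_demography(ancestries = dem$ancestries,
                   ne = round(dem$ne / scale),
                   split_whg = round(dem$split_whg / scale),
                   split_ees = round(dem$split_ees / scale),
                   pulses = data.frame(time = round(dem$pulses$time / scale),
                                       source = dem$pulses$source,
                                       prop = dem$pulses$prop),
                   generation_time = dem$generation_time)
}
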