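#' Define a simulation scenario
#'
#' A scenario bundles the genetic architecture, stabilizing-selection
#' parameters and demography for one run of the hybrid coalescent /
#' forward Wright-Fisher simulator: three ancestral populations evolving
#' a polygenic trait under Gaussian stabilizing selection (optionally with
#' a shifted optimum in one ancestry), admixing into a present-day cohort.
#'
#' @param n_loci number of unlinked genomic intervals.
#' @param interval_len interval length in bp.
#' @param mu per-bp per-generation mutation rate (founder diversity).
#' @param r per-bp per-generation recombination rate (within-interval,
#'   forward phase).
#' @param h2 narrow-sense heritability, in (0, 1].
#' @param n_causal number of intervals harbouring one causal SNP each
#'   (polygenicity); at most `n_loci`.
#' @param omega fitness-function SD in units of the initial trait SD;
#'   `Inf` flags neutrality.
#' @param optima named per-ancestry trait optima (trait-SD units).
#' @param selection_mode when selection acts: `"pre_admixture"` (in the
#'   ancestral branches, neutral after admixture), `"post_admixture"`, or
#'   `"none"`.
#' @param demography a `demography_model`.
#' @param n_cohort present-day cohort sample size.
#' @param n_panel reference-panel sample size per ancestry.
#' @param causal_maf_min minimum founder MAF for a site to be eligible as
#'   the causal SNP of its interval.
#' @return An object of class `sim_scenario`.
#' @seealso [run_scenario()], [scenario_profile()]
#' @export
sim_scenario <- function(n_loci = 100, interval_len = 5000, mu = 5e-7,
                         r = 4e-7, h2 = 0.5, n_causal = n_loci,
                         omega = Inf, optima = c(WHG = 0, EEF = 0, SBA = 0),
                         selection_mode = c("pre_admixture",
                                            "post_admixture", "none"),
                         demography = scale_demography(build_demography(), 10),
                         n_cohort = 2000, n_panel = 100,
                         causal_maf_min = 0.01) {
  selection_mode <- match.arg(selection_mode)
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  if (n_causal > n_loci) stop("n_causal cannot exceed n_loci")
  if (n_causal < 1) stop("n_causal must be at least 1")
  if (!(omega > 0)) stop("omega must be positive (Inf for neutral)")
  if (is.infinite(omega)) selection_mode <- "none"
  if (selection_mode == "none") omega <- Inf
  stopifnot(inherits(demography, "demography_model"))
  if (nrow(demography$pulses) < 1)
    stop("the simulator requires at least one admixture pulse")
  if (!all(demography$ancestries %in% names(optima)))
    stop("optima must be named for every ancestry")
  if (n_cohort <= 0 || n_panel <= 0) stop("nonpositive sample size")
  if (n_cohort > demography$ne[["present"]])
    stop("cohort larger than the present-day population")
  structure(list(n_loci = as.integer(n_loci),
                 interval_len = as.integer(interval_len),
                 mu = mu, r = r, h2 = h2, n_causal = as.integer(n_causal),
                 omega = omega, optima = optima[demography$ancestries],
                 selection_mode = selection_mode, demography = demography,
                 n_cohort = as.integer(n_cohort),
                 n_panel = as.integer(n_panel),
                 causal_maf_min = causal_maf_min),
            class = "sim_scenario")
}

#' Preset scenario profiles
#'
#' `"full"` is the full-scale parameterization (1000 x 20 kb intervals,
#' mu = 1.25e-8, r = 1e-8, branch Ne 10,000, 10,000-strong cohort).
#' `"test"` is the desk-scale profile used throughout the test suite:
#' populations, split/pulse times and cohort scaled down 10-fold and
#' intervals shortened to 5 kb, with mu and r raised 40-fold so that
#' per-interval theta = 4*Ne*mu*L, rho = 4*Ne*r*L and drift time t/2Ne
#' all match their full-scale values.
#'
#' @param profile `"test"` or `"full"`.
#' @param ... overrides passed on to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
scenario_profile <- function(profile = c("test", "full"), ...) {
  profile <- match.arg(profile)
  args <- list(...)
  base <- if (profile == "full")
    list(n_loci = 1000, interval_len = 20000, mu = 1.25e-8, r = 1e-8,
         demography = build_demography(), n_cohort = 10000)
  else
    list(n_loci = 100, interval_len = 5000, mu = 5e-7, r = 4e-7,
         demography = scale_demography(build_demography(), 10),
         n_cohort = 2000)
  base[names(args)] <- args
  do.call(sim_scenario, base)
}

#' Additive genetic values from causal dosages
#'
#' \eqn{GV_i = \sum_l \beta_l \, d_{il}} with diploid dosages
#' \eqn{d_{il} \in \{0,1,2\}}.
#'
#' @param dosage individuals x causal-loci dosage matrix.
#' @param effects per-locus effect sizes, aligned to the columns.
#' @return Numeric vector of genetic values.
#' @export
compute_gv <- function(dosage, effects) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != length(effects))
    stop("effects length does not match the number of causal loci")
  if (any(!(dosage %in% c(0, 1, 2) | is.na(dosage))))
    stop("dosages must be 0, 1 or 2")
  drop(dosage %*% effects)
}

#' Phenotypes from genetic values at a target heritability
#'
#' Adds environmental noise \eqn{\epsilon \sim N(0, Var(GV)(1-h^2)/h^2)}
#' so that the realized narrow-sense heritability is `h2`.
#'
#' @param gv genetic values.
#' @param h2 heritability in (0, 1]; `h2 = 1` returns `gv` unchanged.
#' @param seed optional RNG seed for the noise draw.
#' @return Numeric trait vector.
#' @export
phenotype_from_gv <- function(gv, h2, seed = NULL) {
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  if (h2 == 1) return(gv)
  v <- stats::var(gv)
  if (!is.finite(v) || v <= 0)
    stop("zero genetic variance: environmental variance undefined for h2 < 1")
  if (!is.null(seed)) set.seed(seed)
  gv + stats::rnorm(length(gv), 0, sqrt(v * (1 - h2) / h2))
}

#' Gaussian stabilizing-selection fitness
#'
#' \eqn{w_i = \exp(-(t_i - optimum)^2 / (2\omega^2))}; `omega = Inf`
#' (neutrality) gives unit weights.
#'
#' @param trait trait values.
#' @param optimum trait optimum.
#' @param omega fitness-function SD; positive (`Inf` allowed).
#' @return Numeric vector of relative fitness weights in (0, 1].
#' @export
fitness_weights <- function(trait, optimum, omega) {
  if (!(omega > 0)) stop("omega must be positive")
  if (is.infinite(omega)) return(rep(1, length(trait)))
  exp(-(trait - optimum)^2 / (2 * omega^2))
}

## ---------------------------------------------------------------------
## Internal forward-simulation machinery.
##
## Haplotypes are integer ids into per-interval pools: ids 1..n_base are
## founder haplotypes (coalescent sample); larger ids are recombinants
## recorded in a global log as (interval, parentA, parentB, breakpoint),
## the gamete carrying parentA up to the breakpoint and parentB above it.
## Sequence content is resolved lazily, one interval at a time, after the
## forward phase; only the causal-allele state (one site per causal
## interval) is maintained generation by generation, in a preallocated
## matrix indexed by (hap id, interval).

new_engine <- function(scenario, founders, causal_iv, causal_site, cap) {
  eng <- new.env(parent = emptyenv())
  eng$n_loci <- scenario$n_loci
  eng$L <- scenario$interval_len
  eng$p_rec <- scenario$r * scenario$interval_len
  eng$founders <- founders            # list: $mat (raw 0/1), $pos
  eng$n_base <- nrow(founders[[1]]$mat)
  eng$cap <- as.integer(cap)          # recombinant slots per interval
  eng$cnt <- integer(scenario$n_loci)
  ## recombination log, appended one chunk per gamete batch; per-interval
  ## id order equals log order by construction
  eng$ev_chunks <- list()
  eng$causal_iv <- causal_iv
  eng$is_causal <- logical(scenario$n_loci)
  eng$is_causal[causal_iv] <- TRUE
  eng$causal_pos <- integer(scenario$n_loci)
  eng$ref_pos <- rep(as.integer(round(scenario$interval_len / 2)),
                     scenario$n_loci)
  eng$st_rows <- eng$n_base + eng$cap
  ## causal allele (0/1) of every hap id, per interval; non-causal
  ## columns stay zero and are never read
  eng$st <- matrix(0L, eng$st_rows, scenario$n_loci)
  for (j in seq_along(causal_iv)) {
    l <- causal_iv[j]
    eng$causal_pos[l] <- founders[[l]]$pos[causal_site[j]]
    eng$ref_pos[l] <- eng$causal_pos[l]
    eng$st[seq_len(eng$n_base), l] <-
      as.integer(founders[[l]]$mat[, causal_site[j]] != as.raw(0L))
  }
  eng
}

## Record a batch of recombinant haplotypes (vectors over events, sorted
## by interval); returns their ids aligned to the input order.  One
## chunk append and one causal-state subassignment per batch keeps the
## cost per gamete generation O(batch), not O(pool size x batch).
bulk_recomb <- function(eng, l, ha, hb, bp) {
  o <- order(l)
  lo <- l[o]; hao <- ha[o]; hbo <- hb[o]; bpo <- bp[o]
  runs <- rle(lo)
  ids_o <- eng$n_base + eng$cnt[lo] + sequence(runs$lengths)
  if (max(ids_o) > eng$st_rows)
    stop("recombination log capacity exceeded; raise cap")
  eng$cnt[runs$values] <- eng$cnt[runs$values] + runs$lengths
  eng$ev_chunks[[length(eng$ev_chunks) + 1L]] <-
    list(l = lo, a = hao, b = hbo, bp = bpo)
  cz <- eng$is_causal[lo]
  if (any(cz)) {
    lc <- lo[cz]
    keep_a <- eng$causal_pos[lc] <= bpo[cz]
    src <- ifelse(keep_a, hao[cz], hbo[cz])
    colo <- (lc - 1L) * eng$st_rows
    eng$st[ids_o[cz] + colo] <- eng$st[src + colo]
  }
  ids <- integer(length(l))
  ids[o] <- ids_o
  ids
}

## Diploid causal dosage matrix (individuals x causal loci).
pop_causal_dosage <- function(eng, pop, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(pop$N)
  d <- matrix(0L, length(rows), length(eng$causal_iv))
  off <- (eng$causal_iv - 1L) * eng$st_rows
  for (j in seq_along(eng$causal_iv)) {
    l <- eng$causal_iv[j]
    d[, j] <- eng$st[pop$H1[rows, l] + off[j]] +
      eng$st[pop$H2[rows, l] + off[j]]
  }
  d
}

## One gamete per requested parent: per interval pick one of the parent's
## two haplotypes (independent assortment across unlinked intervals), with
## probability r*L replaced by a within-interval recombinant.
make_gametes <- function(eng, pop, parent_rows) {
  n <- length(parent_rows); nL <- eng$n_loci; N <- pop$N
  idx <- rep.int(parent_rows, nL) +
    rep(seq.int(0L, by = N, length.out = nL), each = n)
  side1 <- stats::runif(n * nL) < 0.5
  h <- pop$H2[idx]
  w1 <- which(side1)
  h[w1] <- pop$H1[idx[w1]]
  labelled <- !is.null(pop$A1)
  a <- NULL
  if (labelled) {
    a <- pop$A2[idx]
    a[w1] <- pop$A1[idx[w1]]
  }
  rec <- which(stats::runif(n * nL) < eng$p_rec)
  if (length(rec)) {
    l <- (rec - 1L) %/% n + 1L
    pidx <- idx[rec]                  # parent flat index for these events
    ha <- pop$H1[pidx]; hb <- pop$H2[pidx]
    ok <- ha != hb                    # recombining identical haps: no-op
    if (any(ok)) {
      rec <- rec[ok]; l <- l[ok]; pidx <- pidx[ok]
      ha <- ha[ok]; hb <- hb[ok]
      swap <- stats::runif(length(rec)) < 0.5
      first <- ifelse(swap, hb, ha)
      second <- ifelse(swap, ha, hb)
      bp <- sample.int(eng$L - 1L, length(rec), replace = TRUE)
      h[rec] <- bulk_recomb(eng, l, first, second, bp)
      if (labelled) {
        la <- ifelse(swap, pop$A2[pidx], pop$A1[pidx])
        lb <- ifelse(swap, pop$A1[pidx], pop$A2[pidx])
        a[rec] <- ifelse(eng$ref_pos[l] <= bp, la, lb)
      }
    }
  }
  dim(h) <- c(n, nL)
  if (labelled) dim(a) <- c(n, nL)
  list(h = h, a = a)
}

## Fitness of a population under stabilizing selection on the trait.
pop_fitness <- function(eng, pop, beta, optimum, omega, var_e) {
  gv <- drop(pop_causal_dosage(eng, pop) %*% beta)
  trait <- gv + stats::rnorm(pop$N, 0, sqrt(var_e))
  w <- fitness_weights(trait, optimum, omega)
  if (sum(w) <= 0) w[] <- 1  # fully maladapted: uniform rescue
  w
}

## Produce the next generation (optionally receiving an admixture pulse
## from `src` with per-parent-slot probability m).  `lin_label` labels
## gametes from an unlabelled recipient population (NA = keep unlabelled);
## `src_label` labels gametes from the pulse source.
next_generation <- function(eng, pop, n_next, w = NULL,
                            src = NULL, m = 0, w_src = NULL,
                            lin_label = NA_integer_,
                            src_label = NA_integer_) {
  draw <- function(p, n, wt) sample.int(p$N, n, replace = TRUE, prob = wt)
  want_labels <- !is.null(pop$A1) || !is.na(lin_label)
  one_side <- function() {
    if (is.null(src)) {
      par <- draw(pop, n_next, w)
      g <- make_gametes(eng, pop, par)
      if (is.null(g$a) && want_labels)
        g$a <- matrix(lin_label, n_next, eng$n_loci)
      list(h = g$h, a = g$a, par = par)
    } else {
      from_src <- stats::runif(n_next) < m
      n_s <- sum(from_src)
      h <- matrix(0L, n_next, eng$n_loci)
      a <- matrix(NA_integer_, n_next, eng$n_loci)
      par <- integer(n_next)
      if (n_s < n_next) {
        pl <- draw(pop, n_next - n_s, w)
        gl <- make_gametes(eng, pop, pl)
        h[!from_src, ] <- gl$h
        a[!from_src, ] <- if (is.null(gl$a)) lin_label else gl$a
        par[!from_src] <- pl
      }
      if (n_s > 0) {
        ps <- draw(src, n_s, w_src)
        gs <- make_gametes(eng, src, ps)
        h[from_src, ] <- gs$h
        a[from_src, ] <- src_label
        par[from_src] <- -ps   # negative: row in the source branch
      }
      list(h = h, a = a, par = par)
    }
  }
  mat <- one_side()
  pat <- one_side()
  if (pop$N > 1) {  # avoid selfing among recipient-pool pairs
    repeat {
      same <- which(mat$par == pat$par & mat$par > 0)
      if (!length(same)) break
      newpar <- draw(pop, length(same), w)
      g <- make_gametes(eng, pop, newpar)
      pat$h[same, ] <- g$h
      if (!is.null(pat$a))
        pat$a[same, ] <- if (is.null(g$a)) lin_label else g$a
      pat$par[same] <- newpar
    }
  }
  has_labels <- !is.null(mat$a) && !anyNA(mat$a[1L, 1L])
  list(N = as.integer(n_next), H1 = mat$h, H2 = pat$h,
       A1 = if (has_labels) mat$a else NULL,
       A2 = if (has_labels) pat$a else NULL,
       mothers = mat$par, fathers = pat$par)
}

#' Run a simulation scenario
#'
#' Executes the hybrid simulation: (1) founder haplotypes for each
#' unlinked interval are drawn from a neutral coalescent at mutation-drift
#' equilibrium in the ancestral population; (2) from the deepest split a
#' diploid forward Wright-Fisher phase takes over, with
#' fitness-proportional parent sampling on the trait value (Gaussian
#' fitness around each branch's optimum), independent assortment across
#' intervals and within-interval recombination at rate r per bp; (3) the
#' present-day lineage (the first ancestry's substratum) receives the
#' configured admixture pulses, every allele copy being labelled by
#' source ancestry from admixture onwards; (4) reference panels are
#' sampled from each branch one generation before the first pulse
#' affecting it.  Effect sizes are drawn N(0, 1) at the causal SNPs and
#' rescaled once at the start of the forward phase so that the initial
#' Var(GV) equals h2 (initial trait SD = 1, the unit in which `omega`
#' and the optima are expressed).
#'
#' @param scenario a `sim_scenario`.
#' @param seed integer RNG seed; identical seed and scenario give
#'   bit-identical output.
#' @param resolve_genotypes build the cohort and panel genotype matrices
#'   (default `TRUE`).  With `FALSE` only the causal architecture,
#'   trait, ancestry labels and pedigree are returned, which is much
#'   faster and lighter when genome-wide variants are not needed (e.g.
#'   ascertainment studies).
#' @return An object of class `sim_output`: list with components
#'   `cohort` and `panels` (`genotype_matrix`; panels carry ancestry
#'   group labels), `gv`, `trait`, `effects` (causal chrom/pos/beta/
#'   interval table), `causal_dosage`, per-copy causal alleles
#'   (`causal_hap1/2`), per-copy ancestry labels (`anc1`, `anc2`, coded
#'   along `ancestries`), `panel_gv` (mean genetic value per reference
#'   panel), `pedigree` (parents and grandparents of the cohort),
#'   `scenario` and `seed`.
#' @export
run_scenario <- function(scenario, seed = 1L, resolve_genotypes = TRUE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  dem <- scenario$demography
  ancs <- dem$ancestries
  nL <- scenario$n_loci
  L <- scenario$interval_len
  ne <- dem$ne
  n_whg <- as.integer(ne[[ancs[1]]])
  n_anc <- as.integer(ne[["ancestral"]])

  ## --- founder coalescent per interval -------------------------------
  n_base <- 2L * (n_whg + n_anc)
  founders <- vector("list", nL)
  for (l in seq_len(nL))
    founders[[l]] <- sim_founder_interval(n_base, n_anc, scenario$mu, L)

  ## --- causal sites --------------------------------------------------
  eligible <- lapply(founders, function(fo) {
    if (ncol(fo$mat) == 0) return(integer(0))
    f <- colMeans(fo$mat != as.raw(0L))
    which(pmin(f, 1 - f) >= scenario$causal_maf_min)
  })
  ok <- which(lengths(eligible) > 0)
  if (length(ok) < scenario$n_causal)
    stop("only ", length(ok), " intervals have a site with MAF >= ",
         scenario$causal_maf_min, "; cannot place ", scenario$n_causal,
         " causal SNPs")
  causal_iv <- sort(ok[sample.int(length(ok), scenario$n_causal)])
  causal_site <- vapply(causal_iv, function(l) {
    e <- eligible[[l]]
    if (length(e) == 1L) e else e[sample.int(length(e), 1L)]
  }, integer(1))

  ## expected recombinants per interval bounds the log capacity
  t0 <- dem$split_whg
  pop_gens <- t0 * n_whg + (t0 - dem$split_ees) * n_anc +
    sum(vapply(ancs[2:3], function(a) {
      tp <- min(dem$pulses$time[dem$pulses$source == a], dem$split_ees)
      (dem$split_ees - tp) * ne[[a]]
    }, numeric(1))) +
    max(dem$pulses$time) * ne[["present"]]
  ## expected recombinants per interval: 2 gametes per child-generation,
  ## each recombining with probability r*L; 3x head-room
  cap <- ceiling(3 * 2 * pop_gens * scenario$r * L) + 200
  eng <- new_engine(scenario, founders, causal_iv, causal_site, cap)
  beta <- stats::rnorm(scenario$n_causal)

  ## --- initial populations at the deepest split ----------------------
  pop_from_haps <- function(first_ind, n_ind) {
    rows <- first_ind + seq_len(n_ind) - 1L
    list(N = n_ind,
         H1 = matrix(rep(2L * rows - 1L, nL), n_ind, nL),
         H2 = matrix(rep(2L * rows, nL), n_ind, nL),
         A1 = NULL, A2 = NULL)
  }
  pops <- list()
  pops[[ancs[1]]] <- pop_from_haps(1L, n_whg)
  pops[["EES"]] <- pop_from_haps(n_whg + 1L, n_anc)

  ## rescale effects once so initial Var(GV) = h2 (initial trait SD = 1)
  gv0 <- c(drop(pop_causal_dosage(eng, pops[[ancs[1]]]) %*% beta),
           drop(pop_causal_dosage(eng, pops[["EES"]]) %*% beta))
  v0 <- stats::var(gv0)
  if (v0 <= 0) stop("no initial genetic variance at the causal SNPs")
  beta <- beta * sqrt(scenario$h2 / v0)
  var_e <- 1 - scenario$h2

  ## --- event schedule (forward index g; time before present = t0 - g) -
  g_split <- t0 - dem$split_ees
  pulses <- dem$pulses
  g_pulse <- t0 - pulses$time
  g_panel <- stats::setNames(rep(NA_integer_, length(ancs)), ancs)
  g_panel[ancs[1]] <- min(g_pulse) - 1L
  for (a in unique(pulses$source))
    g_panel[a] <- min(g_pulse[pulses$source == a]) - 1L
  sel_branch <- scenario$selection_mode == "pre_admixture"
  sel_present <- scenario$selection_mode == "post_admixture"
  omega <- scenario$omega
  branch_opt <- c(stats::setNames(as.numeric(scenario$optima), ancs), EES = 0)
  alive <- c(ancs[1], "EES")   # ancs[1] doubles as the present-day lineage
  admixed <- FALSE
  panels <- list()
  ped_prev <- NULL; ped_last <- NULL

  for (g in seq_len(t0)) {
    born_now <- character(0)
    if (g == g_split) {
      w_ees <- if (sel_branch && !is.infinite(omega))
        pop_fitness(eng, pops[["EES"]], beta, branch_opt[["EES"]],
                    omega, var_e) else NULL
      for (a in ancs[2:3]) {
        pops[[a]] <- next_generation(eng, pops[["EES"]],
                                     as.integer(ne[[a]]), w_ees)
        alive <- c(alive, a)
      }
      born_now <- ancs[2:3]
      alive <- setdiff(alive, "EES")
      pops[["EES"]] <- NULL
    }
    pulse_now <- which(g_pulse == g)
    for (a in alive) {
      is_lineage <- a == ancs[1]
      if (!(a %in% born_now)) {
        selected <- if (is_lineage && admixed) sel_present else sel_branch
        opt <- if (is_lineage && admixed) 0 else branch_opt[[a]]
        w <- if (selected && !is.infinite(omega))
          pop_fitness(eng, pops[[a]], beta, opt, omega, var_e) else NULL
        if (is_lineage && length(pulse_now)) {
          k <- pulse_now[1]
          src_a <- pulses$source[k]
          w_src <- if (sel_branch && !is.infinite(omega))
            pop_fitness(eng, pops[[src_a]], beta, branch_opt[[src_a]],
                        omega, var_e) else NULL
          n_next <- if (!admixed) as.integer(ne[["present"]]) else pops[[a]]$N
          pops[[a]] <- next_generation(
            eng, pops[[a]], n_next, w,
            src = pops[[src_a]], m = pulses$prop[k], w_src = w_src,
            lin_label = 1L, src_label = match(src_a, ancs))
          admixed <- TRUE
        } else {
          pops[[a]] <- next_generation(
            eng, pops[[a]], pops[[a]]$N, w,
            lin_label = if (is_lineage && admixed) 1L else NA_integer_)
        }
      }
      if (!is.na(g_panel[a]) && g == g_panel[[a]]) {
        rows <- sample.int(pops[[a]]$N, scenario$n_panel)
        panels[[a]] <- list(H1 = pops[[a]]$H1[rows, , drop = FALSE],
                            H2 = pops[[a]]$H2[rows, , drop = FALSE],
                            gv = drop(pop_causal_dosage(eng, pops[[a]],
                                                        rows) %*% beta))
      }
    }
    ## retire source branches that have delivered their last pulse
    for (k in pulse_now) {
      src_a <- pulses$source[k]
      if (!any(pulses$source == src_a & g_pulse > g))
        alive <- setdiff(alive, src_a)
    }
    if (g == t0 - 1L)
      ped_prev <- list(mo = pops[[ancs[1]]]$mothers,
                       fa = pops[[ancs[1]]]$fathers)
    if (g == t0)
      ped_last <- list(mo = pops[[ancs[1]]]$mothers,
                       fa = pops[[ancs[1]]]$fathers)
  }

  ## --- present-day cohort --------------------------------------------
  lineage <- pops[[ancs[1]]]
  cohort_rows <- sort(sample.int(lineage$N, scenario$n_cohort))
  causal_dosage <- pop_causal_dosage(eng, lineage, cohort_rows)
  gv <- drop(causal_dosage %*% beta)
  trait <- phenotype_from_gv(gv, scenario$h2)

  off <- (causal_iv - 1L) * eng$st_rows
  st1 <- matrix(0L, scenario$n_cohort, scenario$n_causal)
  st2 <- matrix(0L, scenario$n_cohort, scenario$n_causal)
  for (j in seq_along(causal_iv)) {
    st1[, j] <- eng$st[lineage$H1[cohort_rows, causal_iv[j]] + off[j]]
    st2[, j] <- eng$st[lineage$H2[cohort_rows, causal_iv[j]] + off[j]]
  }
  anc1 <- lineage$A1[cohort_rows, , drop = FALSE]
  anc2 <- lineage$A2[cohort_rows, , drop = FALSE]

  ped <- data.frame(
    id = sprintf("ind%d", seq_len(scenario$n_cohort)),
    mother = sprintf("p%d", abs(ped_last$mo[cohort_rows])),
    father = sprintf("p%d", abs(ped_last$fa[cohort_rows])),
    stringsAsFactors = FALSE)
  gp <- function(pvec) {
    i <- abs(pvec)
    cbind(sprintf("g%d", abs(ped_prev$mo[i])),
          sprintf("g%d", abs(ped_prev$fa[i])))
  }
  gm <- gp(ped_last$mo[cohort_rows]); gf <- gp(ped_last$fa[cohort_rows])
  ped$mat_gm <- gm[, 1]; ped$mat_gf <- gm[, 2]
  ped$pat_gm <- gf[, 1]; ped$pat_gf <- gf[, 2]

  ## --- resolve sequence content, one interval at a time --------------
  panel_order0 <- ancs[ancs %in% names(panels)]
  if (!resolve_genotypes) {
    effects <- data.frame(chrom = sprintf("iv%d", causal_iv),
                          pos = eng$causal_pos[causal_iv],
                          beta = beta, interval = causal_iv,
                          stringsAsFactors = FALSE)
    return(structure(list(
      cohort = NULL, panels = NULL,
      gv = gv, trait = trait, effects = effects,
      causal_dosage = causal_dosage,
      causal_hap1 = st1, causal_hap2 = st2,
      anc1 = anc1, anc2 = anc2, ancestries = ancs,
      panel_gv = vapply(panels[panel_order0], function(p) mean(p$gv),
                        numeric(1)),
      pedigree = ped, scenario = scenario, seed = seed),
      class = "sim_output"))
  }
  ev_l <- unlist(lapply(eng$ev_chunks, `[[`, "l"))
  ev_a <- unlist(lapply(eng$ev_chunks, `[[`, "a"))
  ev_b <- unlist(lapply(eng$ev_chunks, `[[`, "b"))
  ev_bp <- unlist(lapply(eng$ev_chunks, `[[`, "bp"))
  ev_by_l <- split(seq_along(ev_l), ev_l)
  panel_order <- ancs[ancs %in% names(panels)]
  blocks <- vector("list", nL)
  pblocks <- vector("list", nL)
  variants <- vector("list", nL)
  for (l in seq_len(nL)) {
    S <- ncol(founders[[l]]$mat)
    if (S == 0) next
    M <- matrix(0L, eng$n_base + eng$cnt[l], S)
    M[seq_len(eng$n_base), ] <-
      as.integer(founders[[l]]$mat != as.raw(0L))
    evs <- ev_by_l[[as.character(l)]]
    if (!is.null(evs)) {
      pos <- founders[[l]]$pos
      for (jj in seq_along(evs)) {   # ids were assigned in log order
        k <- evs[jj]
        id <- eng$n_base + jj
        M[id, ] <- M[ev_a[k], ]
        right <- pos > ev_bp[k]
        if (any(right)) M[id, right] <- M[ev_b[k], right]
      }
    }
    dc <- M[lineage$H1[cohort_rows, l], , drop = FALSE] +
      M[lineage$H2[cohort_rows, l], , drop = FALSE]
    dp <- do.call(rbind, lapply(panel_order, function(a)
      M[panels[[a]]$H1[, l], , drop = FALSE] +
        M[panels[[a]]$H2[, l], , drop = FALSE]))
    tot <- colSums(dc) + colSums(dp)
    keep <- tot > 0 & tot < 2 * (nrow(dc) + nrow(dp))
    if (!any(keep)) next
    blocks[[l]] <- dc[, keep, drop = FALSE]
    pblocks[[l]] <- dp[, keep, drop = FALSE]
    variants[[l]] <- data.frame(chrom = sprintf("iv%d", l),
                                pos = founders[[l]]$pos[keep],
                                ref = "A", alt = "T",
                                stringsAsFactors = FALSE)
  }
  used <- which(!vapply(blocks, is.null, logical(1)))
  var_df <- do.call(rbind, variants[used])
  cohort_gm <- genotype_matrix(
    do.call(cbind, blocks[used]), var_df,
    data.frame(id = ped$id, group = "cohort", stringsAsFactors = FALSE),
    validate = FALSE)
  panel_gm <- genotype_matrix(
    do.call(cbind, pblocks[used]), var_df,
    data.frame(id = sprintf("%s_%d", rep(panel_order,
                                         each = scenario$n_panel),
                            seq_len(scenario$n_panel)),
               group = rep(panel_order, each = scenario$n_panel),
               stringsAsFactors = FALSE),
    validate = FALSE)

  effects <- data.frame(chrom = sprintf("iv%d", causal_iv),
                        pos = eng$causal_pos[causal_iv],
                        beta = beta, interval = causal_iv,
                        stringsAsFactors = FALSE)
  structure(list(
    cohort = cohort_gm, panels = panel_gm,
    gv = gv, trait = trait, effects = effects,
    causal_dosage = causal_dosage,
    causal_hap1 = st1, causal_hap2 = st2,
    anc1 = anc1, anc2 = anc2, ancestries = ancs,
    panel_gv = vapply(panels[panel_order], function(p) mean(p$gv),
                      numeric(1)),
    pedigree = ped, scenario = scenario, seed = seed),
    class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output: cohort ",
      if (is.null(x$cohort)) length(x$gv) else nrow(x$cohort$dosage),
      " x ", if (is.null(x$cohort)) "(unresolved)"
      else ncol(x$cohort$dosage), " variants; ", nrow(x$effects),
      " causal loci; panel GV: ",
      paste(sprintf("%s=%.3f", names(x$panel_gv), x$panel_gv),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Greedy filtering of close relatives
#'
#' Retains a prefix-greedy subset of the cohort such that no two retained
#' individuals share a parent or a grandparent.  Deterministic given the
#' pedigree row order.
#'
#' @param x a `sim_output`, or a pedigree data frame with columns `id`,
#'   `mother`, `father` and the four grandparent columns `mat_gm`,
#'   `mat_gf`, `pat_gm`, `pat_gf`.
#' @return Integer indices of retained individuals.
#' @export
filter_relatives <- function(x) {
  ped <- if (inherits(x, "sim_output")) x$pedigree else as.data.frame(x)
  if (is.null(ped) || !all(c("mother", "father") %in% names(ped)))
    stop("pedigree with parent columns is required")
  gcols <- intersect(c("mat_gm", "mat_gf", "pat_gm", "pat_gf"), names(ped))
  seen_par <- new.env(parent = emptyenv())
  seen_gp <- new.env(parent = emptyenv())
  keep <- logical(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    pars <- unique(c(ped$mother[i], ped$father[i]))
    gps <- unique(unlist(ped[i, gcols], use.names = FALSE))
    clash <- any(vapply(pars, exists, logical(1), envir = seen_par,
                        inherits = FALSE)) ||
      any(vapply(gps, exists, logical(1), envir = seen_gp,
                 inherits = FALSE))
    if (!clash) {
      keep[i] <- TRUE
      for (p in pars) assign(p, TRUE, envir = seen_par)
      for (p in gps) assign(p, TRUE, envir = seen_gp)
    }
  }
  which(keep)
}

#' Realized ancestry fractions in the simulated cohort
#'
#' Fraction of present-day allele copies (one label per haplotype per
#' interval) carrying each ancestry label.
#'
#' @param output a `sim_output`.
#' @return Named numeric vector over the scenario's ancestries, summing
#'   to 1.
#' @export
ancestry_fractions <- function(output) {
  stopifnot(inherits(output, "sim_output"))
  labs <- c(output$anc1, output$anc2)
  k <- length(output$ancestries)
  stats::setNames(tabulate(labs, k) / length(labs), output$ancestries)
}

#' Expected genetic value under pure local ancestry
#'
#' The expected GV of a hypothetical present-day individual whose causal
#' alleles are all drawn from allele copies of one ancestral origin:
#' \eqn{GV_p = 2 \sum_l \beta_l f^{local}_{pl}}, the local frequency
#' being computed among cohort allele copies labelled with ancestry p at
#' causal locus l.  Loci where ancestry p has no copies are skipped and
#' reported in the `skipped` attribute.
#'
#' @param output a `sim_output`.
#' @param ancestry ancestry label (one of `output$ancestries`).
#' @return Numeric scalar with attribute `skipped` (causal-locus indices
#'   without copies of the ancestry).
#' @export
local_ancestry_gv <- function(output, ancestry) {
  stopifnot(inherits(output, "sim_output"))
  code <- match(ancestry, output$ancestries)
  if (is.na(code)) stop("unknown ancestry: ", ancestry)
  st <- rbind(output$causal_hap1, output$causal_hap2)
  iv <- output$effects$interval
  an <- rbind(output$anc1[, iv, drop = FALSE],
              output$anc2[, iv, drop = FALSE])
  hit <- an == code
  n_p <- colSums(hit)
  if (all(n_p == 0)) stop("ancestry ", ancestry, " absent at all causal loci")
  fl <- colSums(st * hit) / pmax(n_p, 1L)
  use <- n_p > 0
  out <- 2 * sum(output$effects$beta[use] * fl[use])
  attr(out, "skipped") <- which(!use)
  out
}
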