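## Small fixtures shared across test files; everything is generated in
## code, nothing is read from disk.

## A ref_freqs object with hand-set frequencies (bypasses panel counts).
make_ref_freqs <- function(freq, ancestries = colnames(freq),
                           variants = NULL) {
  freq <- as.matrix(freq)
  if (is.null(ancestries)) ancestries <- c("WHG", "EEF", "SBA")[seq_len(ncol(freq))]
  colnames(freq) <- ancestries
  if (is.null(variants))
    variants <- data.frame(chrom = "chr1", pos = seq_len(nrow(freq)),
                           ref = "A", alt = "T")
  structure(list(freq = freq,
                 calls = matrix(100L, nrow(freq), ncol(freq),
                                dimnames = list(NULL, ancestries)),
                 ancestries = ancestries, variants = variants,
                 min_calls = 10),
            class = "ref_freqs")
}

## Random cohort + frequencies toy for covA algebra tests.
make_cova_toy <- function(n = 20, m = 30, seed = 1, miss = 0) {
  set.seed(seed)
  f0 <- runif(m, 0.05, 0.95)
  dos <- matrix(rbinom(n * m, 2, rep(f0, each = n)), n, m)
  if (miss > 0) dos[sample(length(dos), miss)] <- NA
  cohort <- genotype_matrix(dos, data.frame(chrom = "chr1", pos = 1:m,
                                            ref = "A", alt = "T"))
  freq <- cbind(WHG = pmin(pmax(f0 + rnorm(m, 0, 0.1), 0), 1),
                EEF = pmin(pmax(f0 + rnorm(m, 0, 0.1), 0), 1),
                SBA = pmin(pmax(f0 + rnorm(m, 0, 0.1), 0), 1))
  list(cohort = cohort, freqs = make_ref_freqs(freq))
}

## Per-individual, per-locus loop oracle for covA (independent of the
## vectorized implementation).
cova_loop_oracle <- function(dosage, freq) {
  x <- dosage / 2
  fbar <- colMeans(x, na.rm = TRUE)
  gbar <- rowMeans(freq)
  n <- nrow(x); k <- ncol(freq)
  out <- matrix(0, n, k, dimnames = list(NULL, colnames(freq)))
  for (i in seq_len(n)) {
    for (p in seq_len(k)) {
      s <- 0; cnt <- 0
      for (l in seq_len(ncol(x))) {
        if (is.na(x[i, l])) next
        s <- s + (x[i, l] - fbar[l]) * (freq[l, p] - gbar[l])
        cnt <- cnt + 1
      }
      out[i, p] <- s / cnt
    }
  }
  out
}

## Literal BH step-up reference.
bh_stepup_reference <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * q)
  sig <- logical(m)
  if (length(k)) sig[o[seq_len(max(k))]] <- TRUE
  sig
}

## A tiny simulated scenario shared by engine tests (cached).
.mini_cache <- new.env()
mini_sim <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.mini_cache[[key]])) {
    sc <- scenario_profile("test", n_loci = 20, n_cohort = 500)
    .mini_cache[[key]] <- run_scenario(sc, seed = seed)
  }
  .mini_cache[[key]]
}

## Hand-built sim_output stub for local-ancestry arithmetic tests.
make_local_gv_stub <- function(states, labels, beta = 1) {
  n <- nrow(states) / 2
  structure(list(
    causal_hap1 = states[seq_len(n), , drop = FALSE],
    causal_hap2 = states[n + seq_len(n), , drop = FALSE],
    anc1 = labels[seq_len(n), , drop = FALSE],
    anc2 = labels[n + seq_len(n), , drop = FALSE],
    ancestries = c("WHG", "EEF", "SBA"),
    effects = data.frame(beta = beta,
                         interval = seq_len(ncol(states)))),
    class = "sim_output")
}
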