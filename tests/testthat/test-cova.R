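test_that("panel frequencies count alleles and mask sparse loci", {
  dos <- rbind(c(0, 0), c(NA, 0), c(2, 0),
               c(1, 0), c(1, 0), c(2, 0))
  panel <- genotype_matrix(dos,
                           data.frame(chrom = "chr1", pos = 1:2,
                                      ref = "A", alt = "T"),
                           data.frame(id = letters[1:6],
                                      group = rep(c("WHG", "EEF"), each = 3)))
  fr <- panel_frequencies(panel, min_calls = 2)
  ## WHG at locus 1: genotypes {0, NA, 2} -> f = 2/4, n = 2
  expect_equal(unname(fr$freq[1, "WHG"]), 0.5)
  expect_equal(unname(fr$calls[1, "WHG"]), 2L)
  ## all-hom-ref locus
  expect_equal(unname(fr$freq[2, "WHG"]), 0)
  ## min_calls: any under-called ancestry masks the locus everywhere
  fr2 <- panel_frequencies(panel, min_calls = 3)
  expect_true(all(is.na(fr2$freq[1, ])))
  expect_false(anyNA(fr2$freq[2, ]))
  expect_error(panel_frequencies(
    genotype_matrix(dos, panel$variants,
                    data.frame(id = letters[1:6]))), "group")
})

test_that("covA evaluates its closed form on a one-locus example", {
  ## x_i = 1.0 (dosage 2), cohort mean 0.5, f = (0.9, 0.5, 0.1)
  cohort <- genotype_matrix(matrix(c(2, 1, 0, 1), 4, 1),
                            data.frame(chrom = "chr1", pos = 5,
                                       ref = "A", alt = "T"))
  fr <- make_ref_freqs(matrix(c(0.9, 0.5, 0.1), 1, 3,
                              dimnames = list(NULL, c("WHG", "EEF", "SBA"))),
                       variants = data.frame(chrom = "chr1", pos = 5))
  cova <- compute_cova(cohort, fr)
  expect_equal(unname(unclass(cova)[1, ]), c(0.20, 0.00, -0.20))
  expect_equal(max(abs(rowSums(unclass(cova)))), 0, tolerance = 1e-12)
  ## identical frequencies across ancestries kill the signal entirely
  fr0 <- make_ref_freqs(matrix(0.3, 1, 3), variants = fr$variants)
  expect_equal(max(abs(unclass(compute_cova(cohort, fr0)))), 0)
})

test_that("covA equals the per-locus loop oracle and sums to zero", {
  toy <- make_cova_toy(n = 20, m = 30, seed = 2, miss = 25)
  cova <- compute_cova(toy$cohort, toy$freqs)
  oracle <- cova_loop_oracle(toy$cohort$dosage, toy$freqs$freq)
  expect_equal(unclass(cova), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(unclass(cova)))), 1e-10)
})

test_that("covA is invariant to allele polarization", {
  toy <- make_cova_toy(n = 15, m = 25, seed = 4)
  cova <- compute_cova(toy$cohort, toy$freqs)
  flip <- sample(25, 10)
  dos2 <- toy$cohort$dosage
  dos2[, flip] <- 2 - dos2[, flip]
  fr2 <- toy$freqs
  fr2$freq[flip, ] <- 1 - fr2$freq[flip, ]
  cova2 <- compute_cova(genotype_matrix(dos2, toy$cohort$variants), fr2)
  expect_equal(unclass(cova), unclass(cova2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("covA on a locus union is the size-weighted subset mean", {
  toy <- make_cova_toy(n = 10, m = 30, seed = 6)
  r1 <- interval_set("chr1", 0, 12)     # loci at pos 1..12
  r2 <- interval_set("chr1", 12, 30)    # loci at pos 13..30
  c1 <- unclass(compute_cova(toy$cohort, toy$freqs, regions = r1))
  c2 <- unclass(compute_cova(toy$cohort, toy$freqs, regions = r2))
  call <- unclass(compute_cova(toy$cohort, toy$freqs))
  expect_equal((12 * c1 + 18 * c2) / 30, call, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("standardized covA has unit scale per ancestry", {
  toy <- make_cova_toy(n = 50, m = 40, seed = 9)
  cv <- compute_cova(toy$cohort, toy$freqs, standardize = TRUE)
  expect_equal(unname(apply(unclass(cv), 2, mean)), rep(0, 3),
               tolerance = 1e-12)
  expect_equal(unname(apply(unclass(cv), 2, sd)), rep(1, 3),
               tolerance = 1e-12)
})

test_that("TAGR construction centres, clips and merges windows", {
  t1 <- define_tagrs(data.frame(chrom = "chr1", pos = 100000))
  expect_equal(t1$start, 89999)
  expect_equal(t1$end, 109999)
  expect_equal(t1$end - t1$start, 20000)
  ## two hits 5 kb apart merge into one 25 kb region
  t2 <- define_tagrs(data.frame(chrom = "chr1", pos = c(100000, 105000)))
  expect_equal(nrow(t2), 1)
  expect_equal(t2$end - t2$start, 25000)
  ## duplicate hits are idempotent
  t3 <- define_tagrs(data.frame(chrom = "chr1",
                                pos = c(100000, 100000, 105000)))
  expect_equal(as.data.frame(t3), as.data.frame(t2))
  ## clipping at the chromosome start
  t4 <- define_tagrs(data.frame(chrom = "chr1", pos = 1000))
  expect_equal(t4$start, 0)
  ## empty hit list is an empty set, not an error
  expect_equal(nrow(define_tagrs(data.frame(chrom = character(),
                                            pos = numeric()))), 0)
  expect_error(define_tagrs(data.frame(chrom = "chr1", pos = 1),
                            window_bp = 333), "even")
})

test_that("TAGR merge equals brute-force window union", {
  set.seed(12)
  for (rep in 1:10) {
    pos <- sample(10000:90000, 8)
    tagr <- define_tagrs(data.frame(chrom = "chr1", pos = pos),
                         window_bp = 6000)
    ## brute force: paint covered bp on a line (0-based half-open)
    line <- logical(100000)
    for (p in pos) line[(p - 1 - 3000):(p - 1 + 3000 - 1) + 1] <- TRUE
    runs <- rle(line)
    ends <- cumsum(runs$lengths)
    starts <- c(0, ends[-length(ends)])
    expect_equal(tagr$start, starts[runs$values])
    expect_equal(tagr$end, ends[runs$values])
  }
})

test_that("ascertainment thresholds variance explained", {
  expect_false(any(ascertain_causal(runif(5), rep(0, 5), 1, tau = 1e-6)))
  ## f = 0.5, beta = 1, Var(t) = 10 -> varexp = 0.05
  expect_true(ascertain_causal(0.5, 1, 10, tau = 0.04))
  expect_false(ascertain_causal(0.5, 1, 10, tau = 0.06))
  expect_error(ascertain_causal(0.5, 1, 10, tau = -1), "negative")
  expect_error(ascertain_causal(0.5, 1, 0), "positive")
})

test_that("variant restriction agrees with a linear-scan oracle", {
  set.seed(7)
  v <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                  pos = sample(1:5000, 200))
  gm <- genotype_matrix(matrix(0, 2, 200), cbind(v, ref = "A", alt = "T"))
  regions <- interval_set(c("chr1", "chr1", "chr2"),
                          c(100, 2000, 0), c(600, 3500, 1000))
  oracle <- which(vapply(seq_len(200), function(i) {
    any(regions$chrom == v$chrom[i] &
          regions$start <= v$pos[i] - 1 & v$pos[i] - 1 < regions$end)
  }, logical(1)))
  expect_identical(restrict_variants(gm, regions), oracle)
  ## degenerate cases
  expect_identical(restrict_variants(gm, interval_set()), integer(0))
  all_cover <- interval_set(c("chr1", "chr2"), c(0, 0), c(5000, 5000))
  expect_identical(restrict_variants(gm, all_cover), seq_len(200))
})
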