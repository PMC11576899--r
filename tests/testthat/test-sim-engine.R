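test_that("compute_gv is the additive dosage sum", {
  expect_equal(compute_gv(matrix(c(0, 1, 2), 3, 1), 0.5),
               c(0, 0.5, 1.0))
  expect_equal(compute_gv(matrix(sample(0:2, 12, TRUE), 4, 3),
                          rep(0, 3)), rep(0, 4))
  ## brute-force per-individual oracle on a random toy
  set.seed(3)
  d <- matrix(sample(0:2, 30, TRUE), 6, 5)
  b <- rnorm(5)
  oracle <- vapply(1:6, function(i) sum(b * d[i, ]), numeric(1))
  expect_equal(compute_gv(d, b), oracle)
  expect_error(compute_gv(d, b[1:3]), "length")
})

test_that("phenotype_from_gv hits the target heritability", {
  gv <- rnorm(10000)
  expect_identical(phenotype_from_gv(gv, 1), gv)
  tr <- phenotype_from_gv(gv, 0.5, seed = 9)
  expect_equal(var(tr), var(gv) * 2, tolerance = 0.08)
  ## regressing GV on trait recovers h2
  expect_equal(unname(coef(lm(gv ~ tr))[2]), 0.5, tolerance = 0.05)
  expect_error(phenotype_from_gv(gv, 0), "h2")
  expect_error(phenotype_from_gv(gv, 1.2), "h2")
  expect_error(phenotype_from_gv(rep(1, 10), 0.5), "variance")
})

test_that("fitness_weights is the Gaussian fitness function", {
  expect_equal(fitness_weights(2, 2, 1), 1)
  expect_equal(fitness_weights(c(1, 3), 2, 1), rep(exp(-0.5), 2))
  expect_equal(fitness_weights(c(-5, 0, 7), 1, Inf), rep(1, 3))
  expect_error(fitness_weights(1, 0, -1), "positive")
  expect_error(fitness_weights(1, 0, 0), "positive")
})

test_that("relative filtering removes parent- and grandparent-sharers", {
  ped <- data.frame(id = c("a", "b", "c"),
                    mother = c("m1", "m2", "m3"),
                    father = c("f1", "f2", "f3"),
                    mat_gm = c("w", "x", "y"), mat_gf = c("w2", "x2", "y2"),
                    pat_gm = c("v", "u", "t"), pat_gf = c("v2", "u2", "t2"))
  expect_equal(filter_relatives(ped), 1:3)
  ## full siblings: same parents
  ped$mother[2] <- "m1"; ped$father[2] <- "f1"
  expect_equal(filter_relatives(ped), c(1, 3))
  ## grandparent shared only
  ped$mother[2] <- "m2"; ped$father[2] <- "f2"; ped$pat_gm[3] <- "v"
  expect_equal(filter_relatives(ped), 1:2)
  expect_error(filter_relatives(data.frame(id = "a")), "pedigree")
})

test_that("identical seeds reproduce a run bit for bit", {
  sc <- scenario_profile("test", n_loci = 12, n_cohort = 300)
  a <- run_scenario(sc, seed = 5)
  b <- run_scenario(sc, seed = 5)
  expect_identical(a, b)
  c <- run_scenario(sc, seed = 6)
  expect_false(identical(a$trait, c$trait))
})

test_that("simulated cohorts are calibrated", {
  out <- mini_sim()
  ## realized heritability: slope of GV on trait
  fit <- lm(out$gv ~ out$trait)
  expect_equal(unname(coef(fit)[2]), out$scenario$h2,
               tolerance = 3 * summary(fit)$coefficients[2, 2] /
                 out$scenario$h2 + 0.05)
  ## environmental variance matches Var(GV) (1 - h2) / h2
  noise <- out$trait - out$gv
  expect_equal(var(noise), var(out$gv) * (1 - out$scenario$h2) /
                 out$scenario$h2, tolerance = 0.15)
  ## ancestry labels: every cohort allele copy carries exactly one label
  expect_true(all(out$anc1 %in% 1:3) && all(out$anc2 %in% 1:3))
  ## cohort genotype dosages are complete and in {0,1,2}
  expect_true(all(out$cohort$dosage %in% 0:2))
  ## panels: 100 samples per ancestry, labelled
  expect_equal(as.integer(table(out$panels$samples$group)), rep(100L, 3))
})

test_that("skipping genotype resolution preserves the architecture", {
  sc <- scenario_profile("test", n_loci = 12, n_cohort = 300)
  full <- run_scenario(sc, seed = 5)
  light <- run_scenario(sc, seed = 5, resolve_genotypes = FALSE)
  expect_null(light$cohort)
  expect_identical(light$trait, full$trait)
  expect_identical(light$effects, full$effects)
  expect_identical(light$panel_gv, full$panel_gv)
})

test_that("local-ancestry GV matches hand counts", {
  ## one causal locus, beta = 1; WHG-labelled copies {1,0,1,1} -> 1.5
  states <- matrix(c(1, 1, 0, 1), 4, 1)
  labels <- matrix(1L, 4, 1)
  stub <- make_local_gv_stub(states, labels)
  expect_equal(as.numeric(local_ancestry_gv(stub, "WHG")), 2 * 3 / 4)
  expect_error(local_ancestry_gv(stub, "EEF"), "absent")
  expect_error(local_ancestry_gv(stub, "XXX"), "unknown")
  ## label degeneracy: single-ancestry population equals 2 sum beta f
  set.seed(8)
  st <- matrix(rbinom(40, 1, 0.4), 20, 2)
  stub2 <- make_local_gv_stub(st, matrix(2L, 20, 2), beta = c(0.5, -1))
  expect_equal(as.numeric(local_ancestry_gv(stub2, "EEF")),
               2 * sum(c(0.5, -1) * colMeans(st)))
})

test_that("optimum shifts drive the shifted ancestry's genetic value up", {
  ## directional-selection sanity: +1.5 SD shift in EEF, small replicates
  wins <- 0L
  for (s in 1:3) {
    sc <- scenario_profile("test", n_loci = 15, n_cohort = 200,
                           omega = 1, h2 = 0.5,
                           optima = c(WHG = 0, EEF = 1.5, SBA = 0))
    out <- run_scenario(sc, seed = 100 + s, resolve_genotypes = FALSE)
    if (names(which.max(out$panel_gv)) == "EEF") wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
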