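test_that("VCF genotypes round-trip through write and read", {
  set.seed(14)
  dos <- matrix(sample(c(0:2, NA), 60, TRUE, prob = c(4, 3, 2, 1)), 5, 12)
  gm <- genotype_matrix(dos,
                        data.frame(chrom = rep(c("chr1", "chr2"), each = 6),
                                   pos = rep(seq(100, 600, 100), 2),
                                   ref = "A", alt = "G"),
                        data.frame(id = sprintf("smp%d", 1:5)))
  path <- tempfile(fileext = ".vcf")
  write_genotype_vcf(gm, path)
  back <- read_genotype_vcf(path)
  expect_equal(unname(back$dosage), unname(gm$dosage))
  expect_equal(back$variants$pos, gm$variants$pos)
  expect_equal(back$variants$chrom, gm$variants$chrom)
  expect_equal(back$samples$id, gm$samples$id)
})

test_that("GT parsing handles codes, missingness and multiallelics", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2",
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t20\t.\tC\tG\t.\tPASS\t.\tGT\t1|1\t./.",
    "chr1\t30\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2",   # multiallelic
    "chr1\t40\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0"),   # indel
    path)
  gm <- read_genotype_vcf(path)
  expect_equal(ncol(gm$dosage), 2)        # two records skipped
  expect_equal(attr(gm, "skipped"), 2)
  expect_equal(unname(gm$dosage[, 1]), c(0, 1))
  expect_equal(unname(gm$dosage["i1", 2]), 2)
  expect_true(is.na(gm$dosage["i2", 2]))
  ## metadata join by id; unknown samples are an error
  meta <- data.frame(id = c("i1", "i2"), group = c("WHG", "EEF"))
  gm2 <- read_genotype_vcf(path, sample_meta = meta)
  expect_equal(gm2$samples$group, c("WHG", "EEF"))
  expect_error(read_genotype_vcf(path,
                                 sample_meta = data.frame(id = "i1")),
               "i2")
})

test_that("BED reading validates, sorts and merges", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t500\t900", "chr1\t0\t100", "chr1\t50\t200"), path)
  iv <- read_intervals_bed(path)
  expect_equal(as.data.frame(iv),
               data.frame(chrom = c("chr1", "chr2"), start = c(0, 500),
                          end = c(200, 900)))
  ## permutation of lines yields the same set
  path2 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t50\t200", "chr2\t500\t900", "chr1\t0\t100"), path2)
  expect_equal(as.data.frame(read_intervals_bed(path2)),
               as.data.frame(iv))
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t300\t300"), bad)
  expect_error(read_intervals_bed(bad), "line 2")
  ## BED round trip
  out <- tempfile(fileext = ".bed")
  write_intervals_bed(iv, out)
  expect_equal(as.data.frame(read_intervals_bed(out)), as.data.frame(iv))
})

test_that("results tables round-trip exactly, with NA and NaN as NA", {
  df <- data.frame(trait = c("height", "bmi"),
                   ancestry = c("WHG", "EEF"),
                   estimate = c(0.0123456789, NaN),
                   p = c(1e-8, NA),
                   significant = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_results(df, path)
  back <- read_results(path)
  expect_equal(back$trait, df$trait)
  expect_equal(back$estimate[1], df$estimate[1], tolerance = 1e-9)
  expect_true(is.na(back$estimate[2]) && is.na(back$p[2]))
  expect_equal(back$significant, df$significant)
  ## empty table: header-only file
  write_results(df[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(names(read_results(path)), names(df))
  expect_error(write_results(data.frame(), path), "column")
})

test_that("configurations round-trip through YAML with defaults filled", {
  cfg <- list(out_dir = "results",
              scenario = list(n_loci = 100, h2 = 0.5, omega = 1),
              seeds = list(master = 7),
              thresholds = list(tau = 2e-4))
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$scenario, cfg$scenario)
  expect_equal(back$thresholds$tau, 2e-4)          # explicit wins
  expect_equal(back$thresholds$fdr_q, 0.05)        # default filled
  expect_equal(back$thresholds$kinship_bounds, c(0.177, 0.354))
})
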