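#' Read a genotype matrix from a VCF file
#'
#' Parses GT fields of a VCF into a diploid dosage matrix.  Only
#' biallelic SNPs are retained; skipped records (multiallelic or
#' non-SNP) are counted in the `skipped` attribute.  `"./."` (or
#' `".|."`) genotypes become NA.  Positions stay 1-based as in the VCF.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_meta optional data frame with column `id` (and e.g.
#'   `group`, `sibship`), joined to the VCF samples by id; an error
#'   lists VCF samples missing from the metadata.
#' @return A `genotype_matrix` with attribute `skipped` (records
#'   dropped).
#' @export
read_genotype_vcf <- function(path, sample_meta = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  ok <- fix$REF %in% bases & fix$ALT %in% bases
  n_skip <- sum(!ok)
  if (!any(ok)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[ok, , drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA
  dos <- t(dos)   # individuals x variants
  variants <- data.frame(chrom = fix$CHROM[ok],
                         pos = as.integer(fix$POS[ok]),
                         ref = fix$REF[ok], alt = fix$ALT[ok],
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = rownames(dos), stringsAsFactors = FALSE)
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (!"id" %in% names(sample_meta))
      stop("sample metadata must have an id column")
    miss <- setdiff(samples$id, sample_meta$id)
    if (length(miss))
      stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    samples <- merge(samples, sample_meta, by = "id", sort = FALSE)
    samples <- samples[match(rownames(dos), samples$id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  gm <- genotype_matrix(dos, variants, samples)
  attr(gm, "skipped") <- n_skip
  gm
}

#' Write a genotype matrix to a VCF file
#'
#' Minimal VCFv4.2 writer (GT field only), the counterpart of
#' [read_genotype_vcf()] used to export simulated cohorts and panels.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  ref <- if ("ref" %in% names(v) && !anyNA(v$ref)) v$ref
         else rep("A", nrow(v))
  alt <- if ("alt" %in% names(v) && !anyNA(v$alt)) v$alt
         else rep("T", nrow(v))
  gt_code <- c("0/0", "0/1", "1/1")
  g <- matrix("./.", nrow(v), nrow(gm$dosage))
  d <- t(gm$dosage)
  ok <- !is.na(d)
  g[ok] <- gt_code[d[ok] + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$samples$id),
                     collapse = "\t")), con)
  body <- paste(v$chrom, v$pos, ".", ref, alt, ".", "PASS", ".", "GT",
                sep = "\t")
  writeLines(paste(body, apply(g, 1, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' 3+ column BED (0-based half-open); intervals are sorted and merged.
#' Lines with `end <= start` or non-numeric coordinates raise an error
#' naming the offending line.
#'
#' @param path BED file.
#' @param label optional label attached to the interval set.
#' @return An `interval_set`.
#' @export
read_intervals_bed <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (!length(lines)) return(interval_set(label = label))
  parts <- strsplit(lines, "[ \t]+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3)
      stop("BED line ", i, ": fewer than 3 columns")
    s <- suppressWarnings(as.numeric(p[2]))
    e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e))
      stop("BED line ", i, ": non-numeric coordinates")
    if (e <= s)
      stop("BED line ", i, ": end (", p[3], ") must exceed start (",
           p[2], ")")
  }
  interval_set(chrom = vapply(parts, `[`, character(1), 1),
               start = as.numeric(vapply(parts, `[`, character(1), 2)),
               end = as.numeric(vapply(parts, `[`, character(1), 3)),
               label = label)
}

#' Write an interval set to BED
#'
#' @param x an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(x, path) {
  utils::write.table(as.data.frame(x)[c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Tab-separated, headered, deterministic column order (as given);
#' numeric columns at fixed precision; NA and NaN encoded as "NA".
#'
#' @param table data frame.
#' @param path output path.
#' @param digits significant digits for numeric columns (default 10).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, digits = 10) {
  table <- as.data.frame(table)
  if (ncol(table) == 0) stop("results table must have at least one column")
  for (j in seq_along(table)) {
    if (is.double(table[[j]])) {
      x <- table[[j]]
      x[is.nan(x)] <- NA
      table[[j]] <- ifelse(is.na(x), NA, format(x, digits = digits,
                                                trim = TRUE,
                                                scientific = FALSE))
    }
  }
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path TSV file.
#' @return Data frame; "NA" fields become missing values.
#' @export
read_results <- function(path) {
  utils::read.delim(path, na.strings = "NA", stringsAsFactors = FALSE)
}

#' Read or write a run configuration
#'
#' The run configuration gathers every tunable of the pipeline (scenario
#' and grid parameters, seeds, thresholds, the genome-wide covA pair and
#' paths) in one YAML file that round-trips losslessly.
#'
#' @param path YAML file.
#' @return `read_config`: named list, with defaults from
#'   [ancestra_defaults()] filled in under `thresholds`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defs <- ancestra_defaults()
  if (is.null(cfg$thresholds)) cfg$thresholds <- list()
  for (k in names(defs))
    if (is.null(cfg$thresholds[[k]])) cfg$thresholds[[k]] <- defs[[k]]
  cfg
}

#' @rdname read_config
#' @param config named list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
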