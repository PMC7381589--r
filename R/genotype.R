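# ---------------------------------------------------------------------------
# GenotypeMatrix: individuals x biallelic SNPs as allele dosages 0/1/2/NA,
# with deme / range / sampling-time labels per individual.
# ---------------------------------------------------------------------------

#' Construct a genotype matrix
#'
#' @param dosage numeric matrix, individuals x SNPs, entries 0/1/2 or `NA`
#' @param info data frame with one row per individual: columns `id`, `deme`,
#'   `range`, `sample_time`
#' @param meta optional named list of provenance (seed, scenario, ...)
#' @return object of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosage, info, meta = list()) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == nrow(info), nrow(dosage) >= 2)
  need <- c("id", "deme", "range", "sample_time")
  miss <- setdiff(need, names(info))
  if (length(miss)) stop("info lacks column(s): ", paste(miss, collapse = ", "))
  rng <- range(dosage, na.rm = TRUE)
  if (ncol(dosage) > 0 && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  if (ncol(dosage) > 0 && any(colSums(!is.na(dosage)) == 0))
    stop("every SNP needs at least one non-missing call")
  rownames(dosage) <- info$id
  structure(list(dosage = dosage, info = info, meta = meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  demes: %s\n",
              paste(sort(unique(x$info$deme)), collapse = " ")))
  tt <- sort(unique(x$info$sample_time))
  if (length(tt) > 1)
    cat(sprintf("  serial sampling times (gen BP): %s\n",
                paste(tt, collapse = " ")))
  nmiss <- sum(is.na(x$dosage))
  if (nmiss) cat(sprintf("  missing calls: %d\n", nmiss))
  invisible(x)
}

#' Subset a genotype matrix by individuals
#'
#' Drops SNPs that become entirely missing in the subset.
#'
#' @param G a [genotype_matrix()]
#' @param keep logical or integer index over individuals
#' @return a [genotype_matrix()]
#' @export
subset_individuals <- function(G, keep) {
  d <- G$dosage[keep, , drop = FALSE]
  ok <- colSums(!is.na(d)) > 0
  genotype_matrix(d[, ok, drop = FALSE], G$info[keep, , drop = FALSE], G$meta)
}

#' Write / read a genotype matrix as a dosage TSV
#'
#' Layout: one row per individual; columns `id`, `deme`, `range`,
#' `sample_time`, then one column per SNP (ids `locus_site`), dosages 0/1/2
#' with `NA` for missing.
#'
#' @param G a [genotype_matrix()]
#' @param path file path
#' @return `read_dosage_tsv()` returns a [genotype_matrix()]
#' @export
write_dosage_tsv <- function(G, path) {
  df <- cbind(G$info[c("id", "deme", "range", "sample_time")],
              as.data.frame(G$dosage, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  lab <- c("id", "deme", "range", "sample_time")
  genotype_matrix(as.matrix(df[setdiff(names(df), lab)]), df[lab])
}

#' Write a minimal diploid VCF
#'
#' One record per SNP with `CHROM` = locus id, `POS` = site within the
#' locus, unphased `GT` genotypes. The reference allele is the ancestral
#' state; dosage counts the alternate allele.
#'
#' @param G a [genotype_matrix()]
#' @param path file path
#' @export
write_vcf <- function(G, path) {
  ids <- colnames(G$dosage)
  parts <- strsplit(ids, "_", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  pos <- vapply(parts, function(p) if (length(p) > 1) p[2] else "1", "")
  gt <- apply(G$dosage, 2, function(x)
    c("0/0", "0/1", "1/1")[x + 1L])
  gt[is.na(gt)] <- "./."
  gt <- matrix(gt, ncol = ncol(G$dosage))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$info$id), collapse = "\t")), con)
  for (j in seq_along(ids))
    writeLines(paste(c(chrom[j], pos[j], ids[j], "A", "T", ".", "PASS", ".",
                       "GT", gt[, j]), collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes with a population map
#'
#' Parses a biallelic diploid VCF (via \pkg{vcfR}) or a dosage TSV into a
#' [genotype_matrix()]. Multi-allelic and non-SNP VCF records are skipped and
#' the count reported in the returned object's `meta$skipped_records`.
#' Missing genotypes are preserved as `NA`.
#'
#' @param path VCF (`.vcf`) or dosage TSV
#' @param popmap_path TSV with columns `sample`, `deme`, `range` and
#'   optionally `sample_time`; must cover every sample in `path`
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, popmap_path) {
  popmap <- read.table(popmap_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  if (!all(c("sample", "deme", "range") %in% names(popmap)))
    stop("popmap needs columns sample, deme, range")
  if (is.null(popmap$sample_time)) popmap$sample_time <- 0

  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    is_snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
      !grepl(",", fix[, "ALT"], fixed = TRUE)
    is_snp[is.na(is_snp)] <- FALSE
    skipped <- sum(!is_snp)
    if (skipped) message(skipped, " multi-allelic/non-SNP record(s) skipped")
    gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
    count_alt <- function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    }
    nsam <- ncol(gt)
    dos <- vapply(seq_len(nrow(gt)),
                  function(i) vapply(gt[i, ], count_alt, 0),
                  numeric(nsam))           # individuals x SNPs
    dos <- matrix(dos, nrow = nsam)
    ids <- fix[is_snp, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[is_snp, "CHROM"], "_", fix[is_snp, "POS"])[noid]
    colnames(dos) <- ids
    samples <- colnames(gt)
  } else {
    G <- read_dosage_tsv(path)
    dos <- G$dosage
    samples <- G$info$id
  }
  if (ncol(dos) == 0 || nrow(dos) == 0) stop("no usable SNPs/samples in ", path)

  missing_map <- setdiff(samples, popmap$sample)
  if (length(missing_map))
    stop("sample(s) absent from popmap: ", paste(missing_map, collapse = ", "))
  m <- match(samples, popmap$sample)
  info <- data.frame(id = samples, deme = popmap$deme[m],
                     range = popmap$range[m],
                     sample_time = popmap$sample_time[m],
                     stringsAsFactors = FALSE)
  keep <- colSums(!is.na(dos)) > 0
  genotype_matrix(dos[, keep, drop = FALSE], info,
                  meta = list(source = path,
                              skipped_records = if (exists("skipped")) skipped else 0L))
}
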