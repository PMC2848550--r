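#' Genotype container: allele dosages with per-SNP metadata
#'
#' Bundles a samples x SNPs allele-dosage matrix (0/1/2 copies of the
#' alternate allele, `NA` for missing) with per-SNP metadata and, when the
#' source was phased, the underlying binary haplotypes (2 rows per sample).
#' SNPs are stored sorted by chromosome and position.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA`. Row names are sample ids, column names SNP ids.
#' @param snps data frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per column of `dosages`, same order.
#' @param haplotypes optional binary matrix with `2 * nrow(dosages)` rows
#'   (haplotypes `2i - 1` and `2i` belong to sample `i`) whose per-sample sums
#'   reproduce the non-missing dosages.
#' @return An object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(
#'   dosages = matrix(c(0, 1, 2, 0, 0, 1), nrow = 3,
#'                    dimnames = list(paste0("s", 1:3), c("rs1", "rs2"))),
#'   snps = data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                     pos = c(100L, 200L), ref = "A", alt = "G")
#' )
#' n_snps(g)
#' @export
genotype_matrix <- function(dosages, snps, haplotypes = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  snps <- as_tibble(snps)
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    abort(paste0("snps metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(snps) != ncol(dosages)) {
    abort("snps metadata must have one row per dosage column")
  }
  bad <- which(!(dosages %in% c(0, 1, 2) | is.na(dosages)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(dosages))
    abort(sprintf(
      "dosage value %s at sample '%s', SNP '%s' is not in {0, 1, 2, NA}",
      format(dosages[bad[1]]), rownames(dosages)[rc[1]] %||% rc[1],
      snps$snp_id[rc[2]]))
  }
  if (anyDuplicated(snps$snp_id)) {
    abort("duplicated SNP ids in genotype input")
  }
  snps$pos <- as.integer(snps$pos)
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, ]
  dosages <- dosages[, ord, drop = FALSE]
  if (!is.null(haplotypes)) haplotypes <- haplotypes[, ord, drop = FALSE]
  dup_pos <- duplicated(snps[, c("chrom", "pos")])
  if (any(dup_pos)) {
    abort(sprintf("SNP positions must be unique per chromosome (first clash: %s:%d)",
                  snps$chrom[which(dup_pos)[1]], snps$pos[which(dup_pos)[1]]))
  }
  colnames(dosages) <- snps$snp_id
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  }
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "double"
    if (nrow(haplotypes) != 2L * nrow(dosages)) {
      abort("haplotypes must have exactly two rows per sample")
    }
    recon <- haplotypes[seq(1, nrow(haplotypes), by = 2), , drop = FALSE] +
      haplotypes[seq(2, nrow(haplotypes), by = 2), , drop = FALSE]
    ok <- is.na(dosages) | recon == dosages
    if (!all(ok)) abort("haplotypes do not sum to the stored dosages")
    colnames(haplotypes) <- snps$snp_id
  }
  structure(
    list(sample_ids = rownames(dosages), snps = snps,
         dosages = dosages, haplotypes = haplotypes),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs%s\n",
              length(x$sample_ids), nrow(x$snps),
              if (is.null(x$haplotypes)) "" else " (phased)"))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chrom), collapse = ", ")))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_snps <- function(x) nrow(x$snps)

#' @rdname genotype_matrix
#' @export
n_samples <- function(x) length(x$sample_ids)

#' Extract dosage vectors by SNP id
#'
#' @param x a [genotype_matrix()].
#' @param snp_ids character vector of SNP ids.
#' @return Numeric matrix (samples x requested SNPs), or a vector when a
#'   single id is requested with `drop = TRUE`.
#' @param drop drop the matrix dimension for a single SNP.
#' @export
dosage_of <- function(x, snp_ids, drop = TRUE) {
  missing_ids <- setdiff(snp_ids, x$snps$snp_id)
  if (length(missing_ids) > 0) {
    abort(paste0("unknown SNP id(s): ", paste(head(missing_ids, 5), collapse = ", ")))
  }
  x$dosages[, snp_ids, drop = drop && length(snp_ids) == 1L]
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param snp_ids keep only these SNPs (default all).
#' @param sample_ids keep only these samples (default all).
#' @return A new `genotype_matrix`.
#' @export
subset_genotypes <- function(x, snp_ids = NULL, sample_ids = NULL) {
  keep_snp <- if (is.null(snp_ids)) x$snps$snp_id else snp_ids
  missing_ids <- setdiff(keep_snp, x$snps$snp_id)
  if (length(missing_ids) > 0) {
    abort(paste0("unknown SNP id(s): ", paste(head(missing_ids, 5), collapse = ", ")))
  }
  keep_sam <- if (is.null(sample_ids)) x$sample_ids else sample_ids
  missing_sam <- setdiff(keep_sam, x$sample_ids)
  if (length(missing_sam) > 0) {
    abort(paste0("unknown sample id(s): ", paste(head(missing_sam, 5), collapse = ", ")))
  }
  sam_idx <- match(keep_sam, x$sample_ids)
  hap <- NULL
  if (!is.null(x$haplotypes)) {
    hap_rows <- as.vector(rbind(2L * sam_idx - 1L, 2L * sam_idx))
    hap <- x$haplotypes[hap_rows, keep_snp, drop = FALSE]
  }
  genotype_matrix(
    dosages = x$dosages[sam_idx, keep_snp, drop = FALSE],
    snps = x$snps[match(keep_snp, x$snps$snp_id), ],
    haplotypes = hap)
}

#' Drop SNPs below a minor-allele-frequency cutoff
#'
#' Frequencies are computed from non-missing dosages. The number of removed
#' SNPs is reported through the package log.
#'
#' @param x a [genotype_matrix()].
#' @param maf_min minimum minor-allele frequency, in `[0, 0.5)`.
#' @return A filtered `genotype_matrix`.
#' @export
filter_maf <- function(x, maf_min) {
  stopifnot(is.numeric(maf_min), maf_min >= 0, maf_min < 0.5)
  if (maf_min == 0) return(x)
  af <- colMeans(x$dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  drop_n <- sum(maf < maf_min | is.nan(maf))
  keep <- x$snps$snp_id[!(maf < maf_min | is.nan(maf))]
  if (length(keep) == 0) abort("all SNPs removed by the MAF filter")
  if (drop_n > 0) rtc_log(sprintf("MAF filter (< %.3g): removed %d of %d SNPs",
                                  maf_min, drop_n, n_snps(x)))
  subset_genotypes(x, snp_ids = keep)
}

#' Read genotypes from VCF or a dosage table
#'
#' Supports two on-disk formats: VCF with `GT` fields (phase is preserved
#' when every call is phased) and a tab-separated dosage table with header
#' `snp_id  chrom  pos  ref  alt  <sample...>` and one row per SNP holding
#' alternate-allele dosages 0/1/2 (missing as `NA` or `.`). Multiallelic VCF
#' records are skipped with a warning; SNPs with minor-allele frequency
#' below `maf_min` are removed.
#'
#' @param path file path.
#' @param format `"vcf"`, `"dosage_tsv"`, or `"auto"` (by file extension).
#' @param maf_min minor-allele-frequency cutoff, in `[0, 0.5)`; default 0.05,
#'   the common-variant convention for this analysis.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv"),
                           maf_min = 0.05) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  stopifnot(maf_min >= 0, maf_min < 0.5)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  g <- switch(format,
              vcf = read_genotypes_vcf(path),
              dosage_tsv = read_genotypes_tsv(path))
  filter_maf(g, maf_min)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi)) {
    warn(sprintf("skipping %d multiallelic/non-SNP site(s)", sum(multi)))
  }
  keep <- which(!multi)
  if (length(keep) == 0) abort("no biallelic SNPs left in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  phased <- all(grepl("^[01.]\\|[01.]$", gt) | is.na(gt))
  allele_mat <- function(which_allele) {
    a <- substr(gt, if (which_allele == 1) 1 else 3,
                if (which_allele == 1) 1 else 3)
    suppressWarnings(matrix(as.numeric(a), nrow = nrow(gt)))
  }
  ok <- grepl("^[01.][/|][01.]$", gt) | is.na(gt)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf("malformed GT '%s' at record %s, sample %s",
                  gt[!ok][1], ids[bad[1]], colnames(gt)[bad[2]]))
  }
  a1 <- allele_mat(1); a2 <- allele_mat(2)
  dos <- t(a1 + a2)  # samples x SNPs
  rownames(dos) <- colnames(gt)
  hap <- NULL
  if (phased) {
    hap <- matrix(NA_real_, nrow = 2L * ncol(gt), ncol = nrow(gt))
    hap[seq(1, nrow(hap), 2), ] <- t(a1)
    hap[seq(2, nrow(hap), 2), ] <- t(a2)
  }
  genotype_matrix(
    dosages = dos,
    snps = tibble(snp_id = ids, chrom = fix$CHROM,
                  pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT),
    haplotypes = hap)
}

read_genotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character(), .default = readr::col_character()))
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(tab))) {
    abort(paste0("dosage table must start with columns: ",
                 paste(meta_cols, collapse = ", ")))
  }
  sample_cols <- setdiff(names(tab), meta_cols)
  if (length(sample_cols) == 0) abort("dosage table has no sample columns")
  vals <- as.matrix(tab[sample_cols])
  vals[vals == "."] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!(num %in% c(0, 1, 2) | is.na(num)) |
                 (is.na(num) & !is.na(vals)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(num))
    abort(sprintf("invalid dosage '%s' at SNP '%s', sample '%s' (line %d)",
                  vals[bad[1]], tab$snp_id[rc[1]], sample_cols[rc[2]],
                  rc[1] + 1L))
  }
  dos <- t(num)
  rownames(dos) <- sample_cols
  genotype_matrix(dosages = dos, snps = tab[meta_cols])
}

#' Write a genotype matrix as a dosage table
#'
#' Inverse of the `dosage_tsv` branch of [read_genotypes()]: writing then
#' reading back (with `maf_min = 0`) round-trips all records.
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(x, path) {
  tab <- dplyr::bind_cols(x$snps,
                          as_tibble(t(x$dosages), .name_repair = "minimal"))
  readr::write_tsv(tab, path)
  invisible(path)
}
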