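#' Expression container: per-sample values with gene metadata
#'
#' Bundles a samples x genes expression matrix with gene metadata. The
#' `normalized` flag records whether values went through the package's
#' normalization pipeline (or were declared pre-normalized on input).
#'
#' @param values numeric matrix, samples in rows, genes in columns; row
#'   names are sample ids.
#' @param genes data frame with columns `gene_id`, `chrom`, `tss` (1-based
#'   bp of the transcription start site; for minus-strand genes the
#'   annotated end coordinate), `strand`.
#' @param normalized logical flag.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes, normalized = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  genes <- as_tibble(genes)
  required <- c("gene_id", "chrom", "tss", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicated gene ids")
  if (nrow(genes) != ncol(values)) {
    abort("gene metadata must have one row per expression column")
  }
  if (normalized && anyNA(values)) {
    abort("normalized expression values must not contain missing entries")
  }
  genes$tss <- as.integer(genes$tss)
  colnames(values) <- genes$gene_id
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  }
  structure(list(sample_ids = rownames(values), genes = genes,
                 values = values, normalized = normalized),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes (%snormalized)\n",
              length(x$sample_ids), nrow(x$genes),
              if (x$normalized) "" else "not "))
  invisible(x)
}

#' Read expression values from a tab-separated table
#'
#' Layout: columns `gene_id`, `chrom`, `tss`, `strand`, then one column per
#' sample. With `replicate_mode = TRUE` the table instead carries two
#' technical-replicate columns per sample, named `<sample>_1` and
#' `<sample>_2`, holding raw (unlogged) intensities to be passed to
#' [normalize_expression()].
#'
#' @param path file path.
#' @param replicate_mode whether the table holds paired raw replicates.
#' @return With `replicate_mode = FALSE`, an [expression_matrix()] flagged
#'   normalized; otherwise a raw replicate object of class
#'   `expression_replicates` (genes metadata + intensity matrix + sample map).
#' @export
read_expression <- function(path, replicate_mode = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_integer(), strand = readr::col_character(),
    .default = readr::col_character()))
  meta_cols <- c("gene_id", "chrom", "tss", "strand")
  if (!all(meta_cols %in% names(tab))) {
    abort(paste0("expression table must contain columns: ",
                 paste(meta_cols, collapse = ", ")))
  }
  if (anyDuplicated(tab$gene_id)) abort("duplicated gene ids in expression table")
  value_cols <- setdiff(names(tab), meta_cols)
  if (length(value_cols) == 0) abort("expression table has no sample columns")
  vals <- as.matrix(tab[value_cols])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(num))
    abort(sprintf("non-numeric expression value '%s' at gene '%s', column '%s'",
                  vals[bad[1]], tab$gene_id[rc[1]], value_cols[rc[2]]))
  }
  genes <- tab[meta_cols]
  if (!replicate_mode) {
    m <- t(num)
    rownames(m) <- value_cols
    return(expression_matrix(m, genes, normalized = TRUE))
  }
  if (!all(grepl("_[12]$", value_cols))) {
    abort("replicate_mode requires sample columns named <sample>_1 and <sample>_2")
  }
  samples <- unique(sub("_[12]$", "", value_cols))
  need <- c(paste0(samples, "_1"), paste0(samples, "_2"))
  if (!all(need %in% value_cols)) {
    abort("every sample needs both replicate columns <sample>_1 and <sample>_2")
  }
  colnames(num) <- value_cols
  structure(list(genes = genes, intensities = num, samples = samples,
                 normalized = FALSE),
            class = "expression_replicates")
}

#' Normalize raw replicate intensities into an expression matrix
#'
#' Pipeline used for two-replicate array intensities: log2 transform,
#' quantile normalization of the two replicate vectors within each sample
#' followed by averaging into one value per individual, then median
#' normalization across individuals (each individual's values shifted in
#' log2 space so all per-individual medians equal the median of the
#' per-individual medians).
#'
#' @param raw an `expression_replicates` object from
#'   [read_expression(replicate_mode = TRUE)][read_expression], or an
#'   [expression_matrix()] of unlogged single-replicate intensities.
#' @param already_log2 set when intensities are already log2-scale.
#' @return An [expression_matrix()] with `normalized = TRUE`.
#' @export
normalize_expression <- function(raw, already_log2 = FALSE) {
  if (inherits(raw, "expression_replicates")) {
    ints <- raw$intensities
    genes <- raw$genes
    samples <- raw$samples
    per_sample <- lapply(samples, function(s) {
      ints[, paste0(s, c("_1", "_2")), drop = FALSE]
    })
  } else if (inherits(raw, "expression_matrix")) {
    ints <- t(raw$values)
    genes <- raw$genes
    samples <- raw$sample_ids
    per_sample <- lapply(seq_along(samples), function(i) ints[, i, drop = FALSE])
  } else {
    abort("raw must be an expression_replicates or expression_matrix object")
  }
  if (!already_log2) {
    bad <- which(ints <= 0)
    if (length(bad) > 0) {
      rc <- arrayInd(bad[1], dim(ints))
      abort(sprintf("non-positive raw intensity at gene '%s', column '%s'; cannot log2 transform",
                    genes$gene_id[rc[1]], colnames(ints)[rc[2]]))
    }
  }
  collapsed <- vapply(per_sample, function(m) {
    if (!already_log2) m <- log2(m)
    if (ncol(m) > 1) m <- limma::normalizeQuantiles(m)
    rowMeans(m)
  }, numeric(nrow(genes)))
  # median normalization across individuals, in log2 space
  med <- apply(collapsed, 2, median)
  ref <- median(med)
  centered <- sweep(collapsed, 2, med - ref)
  m <- t(centered)
  rownames(m) <- samples
  expression_matrix(m, genes, normalized = TRUE)
}

#' Read a GWAS SNP catalog
#'
#' Tab-separated file with header `snp_id<TAB>trait<TAB>immunity_related`;
#' `immunity_related` parsed as logical. Duplicate (snp, trait) pairs are
#' an error.
#'
#' @param path file path.
#' @return Tibble with columns `snp_id`, `trait`, `immunity_related`.
#' @export
read_gwas_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), trait = readr::col_character(),
    immunity_related = readr::col_logical()))
  if (!all(c("snp_id", "trait", "immunity_related") %in% names(tab))) {
    abort("GWAS catalog needs columns snp_id, trait, immunity_related")
  }
  if (anyDuplicated(tab[, c("snp_id", "trait")])) {
    abort("duplicated (snp_id, trait) pair in GWAS catalog")
  }
  tab
}

#' Intersect genotype and expression samples
#'
#' Takes the common samples of a genotype and an expression container (in
#' genotype order) and reports dropped ids, mirroring how matched panels
#' are assembled from independently produced files.
#'
#' @param geno a [genotype_matrix()].
#' @param expr an [expression_matrix()].
#' @return List with elements `geno` and `expr` restricted to the shared
#'   samples.
#' @export
match_samples <- function(geno, expr) {
  shared <- intersect(geno$sample_ids, expr$sample_ids)
  if (length(shared) == 0) abort("no samples shared between genotypes and expression")
  dropped <- c(setdiff(geno$sample_ids, shared), setdiff(expr$sample_ids, shared))
  if (length(dropped) > 0) {
    rtc_log(sprintf("sample intersection dropped %d id(s): %s",
                    length(dropped), paste(head(dropped, 10), collapse = ", ")))
  }
  expr_idx <- match(shared, expr$sample_ids)
  list(
    geno = subset_genotypes(geno, sample_ids = shared),
    expr = expression_matrix(expr$values[expr_idx, , drop = FALSE],
                             expr$genes, normalized = expr$normalized))
}
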