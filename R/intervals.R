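#' Recombination-hotspot interval set
#'
#' Ordered, non-overlapping genomic blocks delimited by recombination
#' hotspots. Internally intervals use 1-based half-open coordinates
#' `[start, end)`; a SNP at 1-based position `p` belongs to an interval iff
#' `start <= p < end`, so every position belongs to at most one interval.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (1-based half-open) and optionally `interval_id` (generated when
#'   absent).
#' @return A tibble of class `hotspot_intervals` with columns
#'   `interval_id`, `chrom`, `start`, `end`.
#' @export
hotspot_intervals <- function(intervals) {
  intervals <- as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (!"interval_id" %in% names(intervals)) {
    intervals$interval_id <- sprintf("int_%04d", seq_len(nrow(intervals)))
  }
  intervals <- intervals |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$chrom, .data$start) |>
    select("interval_id", "chrom", "start", "end")
  if (any(intervals$end <= intervals$start)) abort("empty or inverted interval")
  if (nrow(intervals) > 1) {
    same_chrom <- intervals$chrom[-1] == intervals$chrom[-nrow(intervals)]
    overlap <- intervals$start[-1] < intervals$end[-nrow(intervals)]
    if (any(same_chrom & overlap)) {
      i <- which(same_chrom & overlap)[1]
      abort(sprintf("overlapping intervals on %s: [%d,%d) and [%d,%d)",
                    intervals$chrom[i], intervals$start[i], intervals$end[i],
                    intervals$start[i + 1], intervals$end[i + 1]))
    }
  }
  class(intervals) <- c("hotspot_intervals", class(intervals))
  intervals
}

#' Read hotspot intervals from a BED file
#'
#' BED coordinates (0-based, half-open) are converted to the internal
#' 1-based half-open convention, so BED `chr1 0 1000` becomes `[1, 1001)`
#' and contains 1-based positions 1..1000. Overlapping intervals on one
#' chromosome are a validation error; an empty file yields an empty set
#' with a warning.
#'
#' @param path BED3+ file.
#' @return A [hotspot_intervals()] tibble.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  n_lines <- length(readr::read_lines(path, progress = FALSE))
  if (n_lines == 0) {
    warn("empty BED file: no hotspot intervals loaded")
    return(hotspot_intervals(tibble(chrom = character(), start = integer(),
                                    end = integer())))
  }
  gr <- rtracklayer::import(path, format = "BED")
  # rtracklayer returns 1-based closed ranges; [start, end] -> [start, end+1)
  hotspot_intervals(tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr) + 1L))
}

#' Assign SNPs to hotspot intervals
#'
#' Each SNP maps to the unique interval whose half-open range contains its
#' position; SNPs falling between intervals map to no interval (`NA`) and
#' the count is logged, since the score is only defined within a block.
#'
#' @param snps data frame with columns `snp_id`, `chrom`, `pos`, e.g. the
#'   `$snps` slot of a [genotype_matrix()].
#' @param intervals a [hotspot_intervals()] set.
#' @return The `snps` tibble with an added `interval_id` column.
#' @export
assign_snps_to_intervals <- function(snps, intervals) {
  snps <- as_tibble(snps)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  if (nrow(intervals) == 0 || nrow(snps) == 0) {
    return(mutate(snps, interval_id = NA_character_))
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  int_gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start,
                              end = intervals$end - 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, int_gr)
  interval_id <- rep(NA_character_, nrow(snps))
  interval_id[S4Vectors::queryHits(hits)] <-
    intervals$interval_id[S4Vectors::subjectHits(hits)]
  n_out <- sum(is.na(interval_id))
  if (n_out > 0) {
    rtc_log(sprintf("%d of %d SNPs fall outside every hotspot interval and are excluded from interval analyses",
                    n_out, nrow(snps)))
  }
  mutate(snps, interval_id = interval_id)
}
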