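#' Probability that both alleles are sampled at least once
#'
#' At a heterozygous germline site sequenced to depth \code{n_reads}, each
#' read samples one of the two alleles with probability 1/2. The probability
#' that both alleles are seen at least once is
#' P(1 <= X <= n-1) for X ~ Binomial(n, 1/2), i.e. 1 - 2 (1/2)^n. This is the
#' power to recognize a site as heterozygous in the reference tissue, and the
#' basis of the minimum reference-depth threshold: at sixfold coverage the
#' probability is 0.96875.
#'
#' @param n_reads Integer depth(s), >= 1.
#' @return Probability vector.
#' @export
prob_both_alleles_sampled <- function(n_reads) {
  if (any(n_reads < 1)) stop("n_reads must be >= 1")
  1 - 2 * 0.5^n_reads
}

#' Effective tumor coverage
#'
#' Sequencing depth attributable to neoplastic cells: total depth discounted
#' by the fraction of reads from non-tumor cells, i.e.
#' \code{total_depth * cellularity}. A 100x sample at 8\% cellularity has 8x
#' effective coverage.
#'
#' @param total_depth Non-negative depth(s).
#' @param cellularity Tumor purity in (0, 1].
#' @return Effective depth(s).
#' @export
effective_coverage <- function(total_depth, cellularity) {
  if (any(total_depth < 0)) stop("total_depth must be >= 0")
  .check_cellularity(cellularity)
  total_depth * cellularity
}

.check_cellularity <- function(rho) {
  if (any(rho <= 0) || any(rho > 1)) stop("cellularity must be in (0, 1]")
  invisible(rho)
}

#' Probability of detecting a clonal heterozygous mutation
#'
#' A clonal heterozygous somatic mutation is carried by half the tumor-derived
#' reads, so the mutant read count at effective depth n is X ~ Binomial(n, 1/2).
#' Detection requires at least \code{min_alt_reads} mutant reads; the returned
#' value is P(X >= min_alt_reads). Non-integer effective depth is rounded
#' half-to-even. At eightfold effective coverage with a 4-read minimum the
#' probability is 163/256, comfortably above one half.
#'
#' @param effective_depth Non-negative effective tumor depth(s).
#' @param min_alt_reads Minimum mutant read count, >= 0 (vectorized).
#' @return Probability vector.
#' @export
prob_detect_het <- function(effective_depth, min_alt_reads) {
  if (any(effective_depth < 0)) stop("effective_depth must be >= 0")
  if (any(min_alt_reads < 0)) stop("min_alt_reads must be >= 0")
  n <- round(effective_depth)
  stats::pbinom(min_alt_reads - 1, n, 0.5, lower.tail = FALSE)
}

#' Construct a coverage profile
#'
#' A coverage profile is a per-interval depth track over a bait territory:
#' a data frame with columns \code{chrom}, \code{start}, \code{end} (0-based
#' half-open) and \code{depth}, carrying the sample id, role and total bait
#' territory as attributes. Intervals must be non-overlapping within a
#' chromosome.
#'
#' @param intervals Data frame with chrom/start/end/depth.
#' @param sample_id Sample label.
#' @param role "tumor" or "reference".
#' @param bait_territory_bp Total targeted basepairs.
#' @return A \code{coverage_profile} data frame.
#' @export
coverage_profile <- function(intervals, sample_id, role = c("tumor", "reference"),
                             bait_territory_bp) {
  role <- match.arg(role)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) stop("intervals need start < end")
  if (any(intervals$depth < 0)) stop("depth must be >= 0")
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1, intervals$end))
  if (sum(GenomicRanges::width(GenomicRanges::reduce(gr))) < sum(GenomicRanges::width(gr))) {
    stop("intervals overlap within a chromosome")
  }
  structure(as.data.frame(intervals),
            sample_id = sample_id, role = role,
            bait_territory_bp = as.numeric(bait_territory_bp),
            class = c("coverage_profile", "data.frame"))
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (chrom, start, end, depth; no header).
#' @inheritParams coverage_profile
#' @return A \code{coverage_profile}.
#' @export
read_bedgraph <- function(path, sample_id, role, bait_territory_bp) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "depth"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  coverage_profile(df, sample_id, role, bait_territory_bp)
}

.passing_ranges <- function(profile, pass, levels) {
  GenomicRanges::reduce(GenomicRanges::GRanges(
    factor(profile$chrom[pass], levels = levels),
    IRanges::IRanges(profile$start[pass] + 1, profile$end[pass])))
}

#' Callable footprint of a tumor/reference pair
#'
#' The reference footprint is the number of targeted bases with reference
#' depth >= \code{min_ref_depth} (power to see both germline alleles); the
#' tumor footprint is the number of bases whose effective tumor coverage
#' (depth x cellularity) is >= \code{min_effective_depth} (power to see the
#' mutant allele at least \code{min_alt_reads} times about half the time).
#' The sample's callable footprint is, by default, the scalar minimum of the
#' two; \code{method = "intersection"} instead counts bases passing both
#' thresholds. The callable fraction divides by the bait territory.
#'
#' @param reference,tumor \code{coverage_profile}s sharing a bait territory.
#' @param cellularity Tumor purity in (0, 1].
#' @param min_ref_depth Minimum reference depth (default 6).
#' @param min_effective_depth Minimum effective tumor depth (default 8).
#' @param method "minimum" (scalar minimum of the two footprints) or
#'   "intersection" (per-base intersection).
#' @return One-row data frame: reference_footprint_bp, tumor_footprint_bp,
#'   sample_footprint_bp, fraction_callable, thresholds.
#' @export
callable_footprint <- function(reference, tumor, cellularity,
                               min_ref_depth = 6, min_effective_depth = 8,
                               method = c("minimum", "intersection")) {
  method <- match.arg(method)
  .check_cellularity(cellularity)
  bt_r <- attr(reference, "bait_territory_bp")
  bt_t <- attr(tumor, "bait_territory_bp")
  if (!isTRUE(all.equal(bt_r, bt_t))) stop("mismatched bait territories")

  ref_pass <- reference$depth >= min_ref_depth
  tum_pass <- effective_coverage(tumor$depth, cellularity) >= min_effective_depth
  ref_bp <- sum((reference$end - reference$start)[ref_pass])
  tum_bp <- sum((tumor$end - tumor$start)[tum_pass])

  if (method == "minimum") {
    sample_bp <- min(ref_bp, tum_bp)
  } else {
    lv <- union(unique(reference$chrom), unique(tumor$chrom))
    ov <- GenomicRanges::intersect(.passing_ranges(reference, ref_pass, lv),
                                   .passing_ranges(tumor, tum_pass, lv))
    sample_bp <- sum(GenomicRanges::width(ov))
  }
  data.frame(
    sample_id = attr(tumor, "sample_id") %||% NA_character_,
    reference_footprint_bp = ref_bp,
    tumor_footprint_bp = tum_bp,
    sample_footprint_bp = sample_bp,
    fraction_callable = sample_bp / bt_r,
    min_ref_depth = min_ref_depth,
    min_effective_depth = min_effective_depth,
    method = method,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
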