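#' Tumor cellularity from allelic imbalance and somatic MAFs
#'
#' Four estimators of the neoplastic cell fraction rho of a tumor sample,
#' each inverting a two-population read mixture in which a fraction rho of
#' cells are tumor and the remainder are diploid, heterozygous normal cells.
#'
#' For germline heterozygous SNPs over a clonal hemizygous deletion (tumor
#' carries one copy, normal two), all reads from the lost allele come from
#' normal cells, so the pooled minor-allele read fraction is
#' f = (1 - rho) / (2 - rho) and rho = (1 - 2f) / (1 - f).
#'
#' Over copy-number-neutral LOH (tumor carries two copies of one allele),
#' total copy number stays 2, so f = (1 - rho) / 2 and rho = 1 - 2f.
#'
#' A fully clonal heterozygous somatic mutation has expected MAF rho / 2, so
#' the modal (kernel-density peak) or median somatic MAF, doubled, estimates
#' rho; on male sex chromosomes mutations are hemizygous with expected MAF
#' rho / (2 - rho) which is close to rho when rho is not small and is
#' incorporated without doubling.
#'
#' All estimates are clamped to [0, 1]; an analytic value below 0 (pooled
#' fraction above its theoretical maximum, i.e. noise) maps to 0 with a
#' warning.
#'
#' @name cellularity
NULL

.clamp01 <- function(x) {
  if (x < 0) {
    warning("analytic cellularity below 0; clamping (allele fractions noisier than model)")
    x <- 0
  }
  min(1, max(0, x))
}

.pooled_minor_fraction <- function(snps) {
  tot <- snps$a_reads + snps$b_reads
  if (nrow(snps) == 0 || sum(tot) == 0) stop("no informative SNPs")
  sum(pmin(snps$a_reads, snps$b_reads)) / sum(tot)
}

.estimate <- function(rho, method, n_support) {
  data.frame(rho = rho, method = method, n_support = n_support,
             stringsAsFactors = FALSE)
}

#' @rdname cellularity
#' @param snps Data frame of heterozygous SNP counts with columns
#'   \code{a_reads}, \code{b_reads} (and optionally \code{region_label}).
#' @return Each estimator returns a one-row data frame with \code{rho},
#'   \code{method}, \code{n_support}.
#' @export
cellularity_from_deletion_ai <- function(snps) {
  f <- .pooled_minor_fraction(snps)
  .estimate(.clamp01((1 - 2 * f) / (1 - f)), "deletion_AI", nrow(snps))
}

#' @rdname cellularity
#' @export
cellularity_from_cnloh_ai <- function(snps) {
  f <- .pooled_minor_fraction(snps)
  .estimate(.clamp01(1 - 2 * f), "cnLOH_AI", nrow(snps))
}

#' @rdname cellularity
#' @param mafs Somatic mutant-allele fractions (autosomal, clonal candidates).
#' @param bandwidth Kernel bandwidth; \code{NULL} uses Silverman's rule
#'   (\code{stats::bw.nrd0}). With fewer than 3 distinct values the exact
#'   modal value is used; with a degenerate bandwidth, a 0.01-width
#'   histogram peak.
#' @param min_mutations Minimum number of MAFs required (default 50); fewer
#'   is an error so callers fall back to the median method.
#' @export
cellularity_from_modal_maf <- function(mafs, bandwidth = NULL, min_mutations = 50) {
  mafs <- mafs[!is.na(mafs)]
  if (length(mafs) < min_mutations) {
    stop("too few mutations for a modal MAF (", length(mafs), " < ",
         min_mutations, "); use the median method")
  }
  bw <- bandwidth %||% tryCatch(stats::bw.nrd0(mafs), error = function(e) 0)
  if (length(unique(mafs)) < 3) {
    tab <- table(mafs)
    peak <- as.numeric(names(tab)[which.max(tab)])
  } else if (is.finite(bw) && bw > 0) {
    d <- stats::density(mafs, bw = bw, from = 1e-3, to = 0.6, n = 512)
    peak <- d$x[which.max(d$y)]
  } else {
    breaks <- seq(0, 0.6 + 0.01, by = 0.01)
    h <- graphics::hist(pmin(mafs, 0.6), breaks = breaks, plot = FALSE)
    peak <- h$mids[which.max(h$counts)]
  }
  .estimate(.clamp01(2 * peak), "modal_MAF", length(mafs))
}

#' @rdname cellularity
#' @param mafs_autosomal,mafs_sex Autosomal and sex-chromosome somatic MAFs.
#' @param sex "male" or "female". Female (or absent sex-chromosome data):
#'   rho = 2 x median autosomal MAF. Male with sex-chromosome mutations:
#'   mutation-count-weighted mean of 2 x median(autosomal) and
#'   1 x median(sex-chromosome).
#' @export
cellularity_from_median_maf <- function(mafs_autosomal, mafs_sex = numeric(0),
                                        sex = c("female", "male")) {
  sex <- match.arg(sex)
  mafs_autosomal <- mafs_autosomal[!is.na(mafs_autosomal)]
  mafs_sex <- mafs_sex[!is.na(mafs_sex)]
  n_a <- length(mafs_autosomal); n_s <- length(mafs_sex)
  if (n_a + n_s == 0) stop("no mutations")
  if (sex == "male" && n_s > 0) {
    parts <- c(if (n_a > 0) 2 * stats::median(mafs_autosomal),
               stats::median(mafs_sex))
    w <- c(if (n_a > 0) n_a, n_s)
    rho <- sum(parts * w) / sum(w)
  } else {
    if (n_a == 0) stop("no autosomal mutations")
    rho <- 2 * stats::median(mafs_autosomal)
  }
  .estimate(.clamp01(rho), "median_MAF", n_a + n_s)
}

#' Estimate cellularity for one sample
#'
#' Applies the estimators in priority order deletion_AI > cnLOH_AI >
#' modal_MAF > median_MAF and selects the first whose support threshold is
#' met; all applicable estimates are retained for QC. Allelic-imbalance
#' methods rank first because they do not assume somatic mutations are
#' heterozygous-diploid; the MAF-doubling methods do.
#'
#' @param snps Het-SNP data frame with \code{region_label} in
#'   \{"deletion", "cnLOH", "neutral"\}; may be \code{NULL}.
#' @param mafs_autosomal,mafs_sex Somatic MAF vectors.
#' @param sex "female" or "male".
#' @param min_snps Minimum SNPs for an AI method (default 10).
#' @param min_mutations_modal Minimum mutations for the modal method
#'   (default 50).
#' @return List with \code{selected} (one-row data frame) and \code{all}
#'   (data frame of every applicable estimate).
#' @export
estimate_cellularity <- function(snps = NULL, mafs_autosomal = numeric(0),
                                 mafs_sex = numeric(0),
                                 sex = c("female", "male"),
                                 min_snps = 10, min_mutations_modal = 50) {
  sex <- match.arg(sex)
  ests <- list()
  if (!is.null(snps) && nrow(snps)) {
    del <- snps[snps$region_label == "deletion", , drop = FALSE]
    loh <- snps[snps$region_label == "cnLOH", , drop = FALSE]
    if (nrow(del) >= min_snps) ests$deletion <- cellularity_from_deletion_ai(del)
    if (nrow(loh) >= min_snps) ests$cnloh <- cellularity_from_cnloh_ai(loh)
  }
  if (length(mafs_autosomal) >= min_mutations_modal) {
    ests$modal <- cellularity_from_modal_maf(mafs_autosomal,
                                             min_mutations = min_mutations_modal)
  }
  if (length(mafs_autosomal) + length(mafs_sex) > 0) {
    ests$median <- tryCatch(
      cellularity_from_median_maf(mafs_autosomal, mafs_sex, sex),
      error = function(e) NULL)
  }
  ests <- Filter(Negate(is.null), ests)
  if (!length(ests)) stop("no cellularity method applicable")
  all <- do.call(rbind, unname(ests))
  order_pref <- c("deletion_AI", "cnLOH_AI", "modal_MAF", "median_MAF")
  sel <- all[order(match(all$method, order_pref)), , drop = FALSE][1, , drop = FALSE]
  rownames(sel) <- rownames(all) <- NULL
  list(selected = sel, all = all)
}
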