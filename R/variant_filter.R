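#' Cancer cell fraction of a variant
#'
#' Estimated fraction of tumor cells carrying a variant, under a
#' copy-number-unaware model. On autosomes (and female sex chromosomes) a
#' heterozygous variant present in all tumor cells of a sample with purity
#' rho has expected MAF rho / 2, so CCF = min(1, 2 maf / rho). On male sex
#' chromosomes the locus is hemizygous (one tumor copy against two normal
#' copies), giving CCF = min(1, maf (2 - rho) / rho).
#'
#' @param maf Mutant-allele fraction(s) in [0, 1].
#' @param rho Tumor cellularity in (0, 1].
#' @param is_sex_chrom Logical; variant on a sex chromosome.
#' @param sex "female" or "male".
#' @return CCF vector in [0, 1].
#' @export
cancer_cell_fraction <- function(maf, rho, is_sex_chrom = FALSE,
                                 sex = c("female", "male")) {
  sex <- match.arg(sex)
  .check_cellularity(rho)
  n <- max(length(maf), length(is_sex_chrom))
  maf <- rep_len(maf, n)
  hemi <- rep_len(is_sex_chrom, n) & sex == "male"
  ccf <- 2 * maf / rho
  ccf[hemi] <- maf[hemi] * (rho + 2 * (1 - rho)) / rho
  pmin(1, ccf)
}

#' Filter somatic variant calls on coverage, support and clonality
#'
#' Reimplements the post-calling filter: a variant is kept iff
#' (i) total reads >= \code{min_total_reads}, (ii) mutant reads >=
#' \code{min_alt_reads}, and (iii) its cancer cell fraction >=
#' \code{min_ccf}. The clonality rule removes subclonal mutations and
#' mutations from unrelated clones of mutant keratinocytes that commingle
#' with skin tumors; it also makes burdens comparable across samples whose
#' coverage differs in its power to reveal subclones. Every removal records
#' all failed criteria.
#'
#' @param variants Data frame with \code{ref_reads}, \code{alt_reads} and,
#'   for the CCF, \code{is_sex_chrom} (optional, default FALSE).
#' @param rho Sample cellularity in (0, 1].
#' @param sex "female" or "male" (for hemizygous CCF).
#' @param min_total_reads Coverage floor (default 14).
#' @param min_alt_reads Mutant-read floor (default 4).
#' @param min_ccf Clonality floor (default 0.40).
#' @return The input with added columns \code{maf}, \code{ccf}, \code{kept},
#'   \code{reasons} (comma-joined subset of low_coverage, few_alt_reads,
#'   subclonal_or_field_clone; empty iff kept). Input order is preserved.
#' @export
filter_somatic_variants <- function(variants, rho, sex = c("female", "male"),
                                    min_total_reads = 14, min_alt_reads = 4,
                                    min_ccf = 0.40) {
  sex <- match.arg(sex)
  .check_cellularity(rho)
  tot <- variants$ref_reads + variants$alt_reads
  maf <- ifelse(tot > 0, variants$alt_reads / tot, NA_real_)
  is_sex <- if ("is_sex_chrom" %in% names(variants)) variants$is_sex_chrom else FALSE
  ccf <- cancer_cell_fraction(ifelse(is.na(maf), 0, maf), rho, is_sex, sex)

  fail <- cbind(low_coverage = tot < min_total_reads,
                few_alt_reads = variants$alt_reads < min_alt_reads,
                subclonal_or_field_clone = ccf < min_ccf)
  reasons <- apply(fail, 1, function(f) paste(colnames(fail)[f], collapse = ","))
  out <- variants
  out$maf <- maf
  out$ccf <- ccf
  out$kept <- reasons == ""
  out$reasons <- reasons
  out
}

#' Select high-confidence germline heterozygous SNPs
#'
#' From reference-tissue variant calls, keeps sites that overlap a catalog of
#' known polymorphic sites (e.g. 1000 Genomes) and whose variant allele
#' frequency lies inside a closed window, 40--60\% by default — the signature
#' of a germline heterozygous genotype in a diploid tissue.
#'
#' @param reference_variants Data frame with \code{chrom}, \code{pos},
#'   \code{ref_reads}, \code{alt_reads}.
#' @param known_sites Data frame with \code{chrom}, \code{pos}.
#' @param vaf_window Closed VAF interval, default \code{c(0.40, 0.60)}.
#' @return Data frame of het-SNP counts: chrom, pos, a_reads (reference
#'   allele), b_reads (alternate allele).
#' @export
call_het_germline_snps <- function(reference_variants, known_sites,
                                   vaf_window = c(0.40, 0.60)) {
  key <- function(d) paste(d$chrom, d$pos)
  tot <- reference_variants$ref_reads + reference_variants$alt_reads
  vaf <- ifelse(tot > 0, reference_variants$alt_reads / tot, NA_real_)
  keep <- key(reference_variants) %in% key(known_sites) &
    !is.na(vaf) & vaf >= vaf_window[1] & vaf <= vaf_window[2]
  kept <- reference_variants[keep, , drop = FALSE]
  data.frame(chrom = kept$chrom, pos = kept$pos,
             a_reads = kept$ref_reads, b_reads = kept$alt_reads,
             stringsAsFactors = FALSE)
}
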