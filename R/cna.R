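#' Exact allelic-imbalance test on pooled het-SNP counts
#'
#' Pools minor-allele and total read counts over the germline heterozygous
#' SNPs in a segment and performs an exact two-sided binomial test against
#' the balanced expectation of 1/2. A genuine copy-number event skews the
#' allele ratio; technical amplification artifacts do not, which is the
#' basis of the corroboration requirement for amplifications.
#'
#' @param snps Data frame with \code{a_reads}, \code{b_reads}.
#' @param min_snps Minimum SNP count to attempt the test (default 5).
#' @return P-value, or \code{NA_real_} when fewer than \code{min_snps} SNPs
#'   are available (the segment then fails corroboration by default).
#' @export
allelic_imbalance_test <- function(snps, min_snps = 5) {
  if (is.null(snps) || nrow(snps) < min_snps) return(NA_real_)
  minor <- sum(pmin(snps$a_reads, snps$b_reads))
  total <- sum(snps$a_reads + snps$b_reads)
  if (total == 0) return(NA_real_)
  stats::binom.test(minor, total, p = 0.5, alternative = "two.sided")$p.value
}

#' Select focal copy-number events from segmented data
#'
#' Filters segments by amplitude and probe support: an amplification has
#' log2(tumor/reference) strictly above \code{amp_log2} (default 0.9), a
#' deep deletion strictly below \code{del_log2} (default -1); both need at
#' least \code{min_probes} supporting probes. Amplifications must in
#' addition show allelic imbalance (pooled exact binomial p <
#' \code{ai_alpha} over the segment's het SNPs); deletions are exempt unless
#' \code{require_ai_for_deletions}. Segments matched by an explicit
#' \code{allowlist} (manual rescues, e.g. an extremely focal deletion with
#' sparse probe support) are included regardless of thresholds.
#'
#' @param segments Data frame: sample_id, chrom, start, end (0-based
#'   half-open), n_probes, log2_ratio.
#' @param het_snps Optional data frame of het SNPs (sample_id, chrom, pos,
#'   a_reads, b_reads) used for corroboration; SNPs are assigned to segments
#'   by position.
#' @param amp_log2,del_log2 Amplitude thresholds (strict inequalities).
#' @param min_probes Minimum supporting probes (default 20).
#' @param ai_alpha Allelic-imbalance significance level (default 0.01).
#' @param ai_min_snps Minimum SNPs for the imbalance test (default 5).
#' @param require_ai_for_deletions Extend corroboration to deletions.
#' @param allowlist Optional data frame (sample_id, chrom, start, end,
#'   event_type) of manually rescued events.
#' @return Data frame of events with evidence columns \code{event_type},
#'   \code{allelic_imbalance_p}, \code{rescued}.
#' @export
select_focal_events <- function(segments, het_snps = NULL,
                                amp_log2 = 0.9, del_log2 = -1.0,
                                min_probes = 20, ai_alpha = 0.01,
                                ai_min_snps = 5,
                                require_ai_for_deletions = FALSE,
                                allowlist = NULL) {
  if (nrow(segments) == 0) return(cbind(segments, event_type = character(0)))

  ai_p <- rep(NA_real_, nrow(segments))
  if (!is.null(het_snps) && nrow(het_snps)) {
    for (i in seq_len(nrow(segments))) {
      s <- segments[i, ]
      in_seg <- het_snps$sample_id == s$sample_id &
        het_snps$chrom == s$chrom &
        het_snps$pos - 1 >= s$start & het_snps$pos - 1 < s$end
      ai_p[i] <- allelic_imbalance_test(het_snps[in_seg, , drop = FALSE],
                                        min_snps = ai_min_snps)
    }
  }
  ai_ok <- !is.na(ai_p) & ai_p < ai_alpha

  amp <- segments$log2_ratio > amp_log2 & segments$n_probes >= min_probes & ai_ok
  del <- segments$log2_ratio < del_log2 & segments$n_probes >= min_probes &
    (if (require_ai_for_deletions) ai_ok else TRUE)

  rescued <- rep(FALSE, nrow(segments))
  type <- ifelse(amp, "amplification", ifelse(del, "deep_deletion", NA))
  if (!is.null(allowlist) && nrow(allowlist)) {
    for (j in seq_len(nrow(allowlist))) {
      a <- allowlist[j, ]
      hit <- segments$sample_id == a$sample_id & segments$chrom == a$chrom &
        segments$start < a$end & segments$end > a$start
      rescued <- rescued | (hit & is.na(type))
      type[hit & is.na(type)] <- a$event_type
    }
  }
  out <- segments[!is.na(type), , drop = FALSE]
  out$event_type <- type[!is.na(type)]
  out$allelic_imbalance_p <- ai_p[!is.na(type)]
  out$rescued <- rescued[!is.na(type)]
  rownames(out) <- NULL
  out
}

#' Annotate events with overlapping genes
#'
#' Reports every gene whose interval overlaps a segment by at least one
#' base, under 0-based half-open semantics: a segment [100, 200) does not
#' overlap a gene starting at 200.
#'
#' @param events Data frame with chrom, start, end.
#' @param gene_intervals Data frame (BED-like): chrom, start, end, gene.
#' @return \code{events} with a \code{genes} column (comma-joined,
#'   coordinate-sorted; "" when none overlap).
#' @export
annotate_genes <- function(events, gene_intervals) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(gene_intervals)))
  if (any(gene_intervals$start >= gene_intervals$end)) stop("malformed BED interval")
  if (nrow(events) == 0) {
    events$genes <- character(0)
    return(events)
  }
  lv <- union(unique(events$chrom), unique(gene_intervals$chrom))
  ev <- GenomicRanges::GRanges(factor(events$chrom, levels = lv),
                               IRanges::IRanges(events$start + 1, events$end))
  gn <- GenomicRanges::GRanges(factor(gene_intervals$chrom, levels = lv),
                               IRanges::IRanges(gene_intervals$start + 1,
                                                gene_intervals$end))
  hits <- GenomicRanges::findOverlaps(ev, gn)
  genes <- rep("", nrow(events))
  if (length(hits)) {
    by_ev <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (k in names(by_ev)) {
      g <- by_ev[[k]]
      g <- g[order(gene_intervals$start[g])]
      genes[as.integer(k)] <- paste(gene_intervals$gene[g], collapse = ",")
    }
  }
  events$genes <- genes
  events
}

#' Read a SEG-like segment table
#'
#' Tab-separated with header: sample_id, chrom, start, end, n_probes,
#' log2_ratio.
#'
#' @param path File path.
#' @return Data frame of segments.
#' @export
read_segments <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character", chrom = "character"))
}
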