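#!/usr/bin/env Rscript
# Stage 3: callable footprints.
#
# A base is callable when the reference has >= 6x coverage (both germline
# alleles sampled with probability 0.969) and the tumor has >= 8x effective
# coverage (>= 4 mutant reads from a clonal heterozygous mutation more than
# half the time). The sample footprint is the minimum of the two.

suppressPackageStartupMessages(library(somaticQC))

cohort <- read_cohort("results/cohort")
cell <- read.delim("results/cellularity.tsv")
cell <- cell[cell$selected, ]
territory <- cohort$bait_territory_bp

reports <- NULL
for (i in seq_len(nrow(cohort$manifest))) {
  sid <- cohort$manifest$sample_id[i]
  rho <- cell$rho[cell$sample_id == sid]
  if (!length(rho) || rho <= 0) next
  s <- cohort$samples[[sid]]
  fp <- callable_footprint(
    coverage_profile(s$reference_coverage, sid, "reference", territory),
    coverage_profile(s$tumor_coverage, sid, "tumor", territory), rho)
  reports <- rbind(reports, fp)
}
write.table(reports, "results/footprints.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Callable fraction: mean ",
        round(100 * mean(reports$fraction_callable), 1), "%, range ",
        paste(round(100 * range(reports$fraction_callable), 1),
              collapse = "% - "), "%")
message("Samples below 60% callable: ",
        sum(reports$fraction_callable < 0.6))
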