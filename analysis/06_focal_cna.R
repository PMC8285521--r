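#!/usr/bin/env Rscript
# Stage 6: focal copy-number events.
#
# Amplifications need log2 ratio > 0.9, >= 20 probes and allelic-imbalance
# corroboration; deep deletions need log2 < -1 and >= 20 probes. Events are
# annotated with every overlapping gene.

suppressPackageStartupMessages(library(somaticQC))

cohort <- read_cohort("results/cohort")
fps <- read.delim("results/footprints.tsv")

segs <- do.call(rbind, lapply(fps$sample_id,
                              function(sid) cohort$samples[[sid]]$segments))
het <- do.call(rbind, lapply(fps$sample_id, function(sid) {
  cbind(sample_id = sid, cohort$samples[[sid]]$het_snps)
}))
events <- select_focal_events(segs, het_snps = het)
events <- annotate_genes(events, cohort$genes)
write.table(events, "results/focal_events.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(nrow(events), " focal events in ",
        length(unique(events$sample_id)), " samples (",
        sum(events$event_type == "amplification"), " amplifications, ",
        sum(events$event_type == "deep_deletion"), " deep deletions)")
message("Genes hit: ",
        paste(unique(unlist(strsplit(events$genes, ","))), collapse = ", "))
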