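#!/usr/bin/env Rscript
# Stage 7: mutational-overlap statistics.
#
# Builds the gene/pathway/subtype alteration matrix from kept non-silent
# mutations and focal events, then tests every feature pair altered in at
# least 16 tumors with the exact Fisher test and Benjamini-Hochberg
# correction. With 40 tumors the floor mainly admits pathway and subtype
# rows plus the most recurrently hit genes.

suppressPackageStartupMessages(library(somaticQC))

cohort <- read_cohort("results/cohort")
kept <- read.delim("results/filtered_variants.tsv")
events <- read.delim("results/focal_events.tsv")
fps <- read.delim("results/footprints.tsv")
ids <- fps$sample_id

alts <- kept[kept$gene != "" & kept$effect != "silent",
             c("sample_id", "gene")]
names(alts) <- c("sample_id", "feature")
if (nrow(events)) {
  ev <- do.call(rbind, lapply(seq_len(nrow(events)), function(j) {
    g <- strsplit(events$genes[j], ",")[[1]]
    if (length(g) && any(nzchar(g)))
      data.frame(sample_id = events$sample_id[j], feature = g[nzchar(g)])
  }))
  alts <- rbind(alts, ev)
}
subtypes <- setNames(cohort$manifest$subtype, cohort$manifest$sample_id)[ids]
m <- alteration_matrix(alts, samples = ids, pathways = default_pathways(),
                       subtypes = subtypes)
res <- overlap_analysis(m, min_mutant = 16)
write.table(res, "results/overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

long <- data.frame(sample = rep(colnames(m), each = nrow(m)),
                   feature = rep(rownames(m), ncol(m)),
                   altered = as.integer(m))
write.table(long[long$altered == 1, ], "results/alterations_long.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Features at the >= 16-tumor floor: ",
        paste(rownames(m)[rowSums(m) >= 16], collapse = ", "))
message(nrow(res), " pairs tested")
if (nrow(res)) {
  top <- res[1, ]
  message("Smallest q: ", top$feature_a, " vs ", top$feature_b,
          " (p = ", signif(top$p, 3), ", q = ", signif(top$q, 3), ")")
  message(sum(res$q < 0.05), " pairs at q < 0.05")
}
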