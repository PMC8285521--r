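#!/usr/bin/env Rscript
# Stage 5: footprint-normalized mutation burden, 96-context spectra,
# signature refitting and the UV dipyrimidine fraction — the per-sample
# tracks of a subtype overview figure, as machine-readable tables.

suppressPackageStartupMessages(library(somaticQC))

cohort <- read_cohort("results/cohort")
fps <- read.delim("results/footprints.tsv")
kept <- read.delim("results/filtered_variants.tsv")
truth <- read.delim("results/ground_truth.tsv")
S <- cohort$signatures

rows <- NULL
weights <- NULL
spectra <- NULL
for (sid in fps$sample_id) {
  v <- kept[kept$sample_id == sid, ]
  fp_bp <- fps$sample_footprint_bp[fps$sample_id == sid]
  burden <- mutation_burden(nrow(v), fp_bp)
  spec <- build_spectrum(v)
  att <- if (sum(spec) > 0) fit_signature_weights(spec, S) else
    list(weights = setNames(rep(NA, ncol(S)), colnames(S)), unattributed = NA)
  uvf <- if (nrow(v)) uv_fraction(v) else NA
  rows <- rbind(rows, data.frame(
    sample_id = sid, n_clonal = nrow(v), burden_per_mb = burden,
    uv_fraction = uvf, t(att$weights), unattributed = att$unattributed,
    check.names = FALSE))
  weights <- cbind(weights, att$weights)
  spectra <- cbind(spectra, spec)
}
colnames(spectra) <- fps$sample_id
write.table(rows, "results/burden_signatures.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(context = context_labels_96(), spectra,
                       check.names = FALSE),
            "results/spectra.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cmp <- merge(rows, truth, by = "sample_id")
message("Burden (per Mb): median ", round(median(rows$burden_per_mb), 1),
        ", range ", paste(round(range(rows$burden_per_mb), 1), collapse = " - "))
message("Mean relative burden error vs truth: ",
        round(100 * mean(abs(cmp$burden_per_mb - cmp$true_burden) /
                           cmp$true_burden), 1), "%")
by_st <- tapply(cmp$uv_fraction, cmp$subtype, mean, na.rm = TRUE)
message("Mean UV fraction by subtype: ",
        paste(names(by_st), round(by_st, 2), sep = "=", collapse = ", "))
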