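#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates a 40-tumor exome cohort across five clinical subtypes with known
# per-sample cellularity, burden, signature mixture and copy-number events,
# and writes it in the file dialects the downstream stages consume.

suppressPackageStartupMessages(library(somaticQC))

out_dir <- "results"
cohort_dir <- file.path(out_dir, "cohort")
dir.create(out_dir, showWarnings = FALSE)

cfg <- sim_config(n_samples = 40, bait_territory_bp = 5e6, seed = 20260919)
sim <- simulate_cohort(cfg)
write_cohort(sim$bundle, cohort_dir)

truth <- sim$truth$samples
write.table(truth, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(signature = rownames(sim$truth$signature_weights),
                       sim$truth$signature_weights, check.names = FALSE),
            file.path(out_dir, "ground_truth_signatures.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Simulated ", nrow(truth), " tumors over ",
        round(cfg$bait_territory_bp / 1e6, 1), " Mb of bait territory")
message("Subtype mix: ",
        paste(names(table(truth$subtype)), table(truth$subtype),
              sep = "=", collapse = ", "))
message("Cellularity range: ",
        paste(round(range(truth$cellularity), 2), collapse = " - "),
        "; burden range (per Mb): ",
        paste(round(range(truth$true_burden), 1), collapse = " - "))
message("Cohort written to ", cohort_dir)
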