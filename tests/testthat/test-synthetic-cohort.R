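test_that("config validation enforces the documented domains", {
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(cellularity_range = c(0, 0.9)), "cellularity")
  expect_error(sim_config(cellularity_range = c(0.2, 1.2)), "cellularity")
  expect_error(sim_config(depth_dispersion = -1), "positive")
  expect_error(sim_config(subclonal_fraction = 1), "subclonal")
  bad <- default_subtype_specs()
  bad$sporadic$signature_alpha <- c(-1, 1, 1, 1, 1, 1)
  expect_error(sim_config(subtype_specs = bad), "nonnegative")
})

test_that("signature-dimension mismatch is rejected", {
  cfg <- sim_config(n_samples = 2, seed = 1)
  S4 <- synthetic_signature_matrix()[, 1:4]
  S4 <- sweep(S4, 2, colSums(S4), "/")
  expect_error(simulate_cohort(cfg, signatures = S4), "Dirichlet dimension")
})

test_that("identical config and seed give byte-identical cohort files", {
  cfg <- sim_config(n_samples = 3, bait_territory_bp = 6e5, seed = 99)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(simulate_cohort(cfg)$bundle, d1)
  write_cohort(simulate_cohort(cfg)$bundle, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a written cohort round-trips to the in-memory tables", {
  sim <- small_sim(n_samples = 3, seed = 13)
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(sim$bundle, d)
  # 5 data files per sample plus manifest and 4 cohort-level files
  expect_length(list.files(d), 3 * 5 + 5)
  back <- read_cohort(d)
  for (sid in names(sim$bundle$samples)) {
    expect_equal(back$samples[[sid]]$variants,
                 sim$bundle$samples[[sid]]$variants, tolerance = 1e-12)
    expect_equal(back$samples[[sid]]$het_snps,
                 sim$bundle$samples[[sid]]$het_snps)
    expect_equal(back$samples[[sid]]$tumor_coverage,
                 sim$bundle$samples[[sid]]$tumor_coverage)
    expect_equal(back$samples[[sid]]$segments,
                 sim$bundle$samples[[sid]]$segments, tolerance = 1e-12)
  }
  expect_equal(back$manifest, sim$bundle$manifest)
  expect_equal(unclass(back$signatures)[, ],
               unclass(sim$bundle$signatures)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(d, recursive = TRUE)
})

test_that("clonal autosomal MAFs concentrate at rho/2 and hemizygous X at rho/(2-rho)", {
  dense <- list(hot = list(prob = 1, burden_lognormal = c(log(300), 0.1),
                           signature_alpha = c(UV = 12, AZA = 1, APOBEC = 1,
                                               OX = 1, CLOCK = 3, TA = 1),
                           casp8_enrichment_prob = 0))
  sim <- small_sim(n_samples = 6, seed = 29, territory = 2e6,
                   subtype_specs = dense,
                   cellularity_range = c(0.4, 0.9), subclonal_fraction = 0)
  truth <- sim$truth$samples
  for (i in seq_len(nrow(truth))) {
    sid <- truth$sample_id[i]
    rho <- truth$cellularity[i]
    v <- sim$bundle$samples[[sid]]$variants
    v <- v[v$variant_class == "SNV" & v$true_clonal, ]
    auto <- v[!v$is_sex_chrom, ]
    if (nrow(auto) >= 500) {
      maf <- auto$alt_reads / (auto$ref_reads + auto$alt_reads)
      se <- sd(maf) / sqrt(nrow(auto))
      expect_lte(abs(mean(maf) - rho / 2), 3 * se + 0.01)
    }
    if (truth$sex[i] == "male") {
      x <- v[v$is_sex_chrom, ]
      if (nrow(x) >= 20) {
        mafx <- x$alt_reads / (x$ref_reads + x$alt_reads)
        expect_lte(abs(mean(mafx) - rho / (2 - rho)),
                   3 * sd(mafx) / sqrt(nrow(x)) + 0.02)
      }
    }
  }
})

test_that("het-SNP B fractions follow the region mixtures", {
  sim <- small_sim(n_samples = 6, seed = 31, territory = 5e6,
                   cellularity_range = c(0.3, 0.9))
  truth <- sim$truth$samples
  checked <- 0
  for (i in seq_len(nrow(truth))) {
    sid <- truth$sample_id[i]
    rho <- truth$cellularity[i]
    h <- sim$bundle$samples[[sid]]$het_snps
    pooled_minor <- function(d) sum(pmin(d$a_reads, d$b_reads)) /
      sum(d$a_reads + d$b_reads)
    del <- h[h$region_label == "deletion", ]
    if (nrow(del) > 200) {
      expect_lte(abs(pooled_minor(del) - (1 - rho) / (2 - rho)), 0.03)
      checked <- checked + 1
    }
    loh <- h[h$region_label == "cnLOH", ]
    if (nrow(loh) > 200) {
      expect_lte(abs(pooled_minor(loh) - (1 - rho) / 2), 0.03)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 2)
})

test_that("simulated context mix reflects the requested signature mixture's UV content", {
  specs <- list(dense = list(prob = 1, burden_lognormal = c(log(150), 0.3),
                             signature_alpha = c(UV = 24, AZA = 1, APOBEC = 2,
                                                 OX = 2, CLOCK = 4, TA = 1),
                             casp8_enrichment_prob = 0))
  sim <- small_sim(n_samples = 4, seed = 37, territory = 2e6,
                   subtype_specs = specs, cellularity_range = c(0.8, 0.95))
  S <- sim$bundle$signatures
  labs <- context_labels_96()
  uv_class <- sub(".*\\[(.*)\\].*", "\\1", labs) == "C>T" &
    substr(labs, 1, 1) %in% c("C", "T")
  for (i in seq_len(nrow(sim$truth$samples))) {
    sid <- sim$truth$samples$sample_id[i]
    w <- sim$truth$signature_weights[, sid]
    expected_uv <- sum((S %*% w)[uv_class])
    v <- sim$bundle$samples[[sid]]$variants
    v <- v[v$variant_class == "SNV", ]
    if (nrow(v) < 100) next
    f <- uv_fraction(v)
    n_sd <- 3 * sqrt(expected_uv * (1 - expected_uv) / nrow(v))
    # small upward allowance for the CC>TT events in the denominator being UV
    expect_lte(abs(f - expected_uv), n_sd + 0.05)
  }
})

test_that("write_cohort fails cleanly on an unwritable path", {
  sim <- small_sim(n_samples = 1, seed = 3, territory = 5e5)
  expect_error(write_cohort(sim$bundle, "/proc/definitely/not/writable"))
})
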