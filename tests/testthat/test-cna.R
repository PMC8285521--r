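test_that("allelic-imbalance test matches exact binomial enumeration", {
  balanced <- data.frame(a_reads = rep(10, 5), b_reads = rep(10, 5))
  expect_equal(allelic_imbalance_test(balanced), 1)
  # pooled (90, 10): exact two-sided Binomial(100, 1/2) tail sum
  skew <- data.frame(a_reads = rep(18, 5), b_reads = rep(2, 5))
  pmf <- dbinom(0:100, 100, 0.5)
  p_oracle <- sum(pmf[pmf <= dbinom(10, 100, 0.5) * (1 + 1e-7)])
  expect_equal(allelic_imbalance_test(skew), p_oracle, tolerance = 1e-12)
  # too few SNPs: no test
  expect_true(is.na(allelic_imbalance_test(skew[1:3, , drop = FALSE])))
  expect_true(is.na(allelic_imbalance_test(NULL)))
})

.toy_segments <- function() {
  data.frame(
    sample_id = "s1", chrom = paste0("chr", 1:8),
    start = 0, end = 1e6,
    n_probes = c(25, 10, 25, 25, 25, 25, 10, 25),
    log2_ratio = c(1.2, 0.95, 0.95, 0.9, -1.5, -0.99, -1.5, 0.01),
    stringsAsFactors = FALSE)
}

.toy_snps <- function(chroms) {
  # strongly imbalanced SNPs on the given chromosomes
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(sample_id = "s1", chrom = ch, pos = (1:6) * 1000,
               a_reads = 40, b_reads = 2, stringsAsFactors = FALSE)
  }))
}

test_that("focal event selection applies the amplitude, support and imbalance rules exactly", {
  segs <- .toy_segments()
  snps <- .toy_snps(c("chr1", "chr2", "chr3"))
  ev <- select_focal_events(segs, het_snps = snps)
  # rule enumeration: chr1 amp (log2 1.2 > 0.9, 25 probes, AI) passes;
  # chr2 fails support; chr3 passes (0.95 > 0.9, AI); chr4 fails the strict
  # inequality (0.9 is not > 0.9); chr5 deep deletion passes (no AI needed);
  # chr6 fails strict -1 bound; chr7 fails support; chr8 neutral
  expect_equal(ev$chrom, c("chr1", "chr3", "chr5"))
  expect_equal(ev$event_type, c("amplification", "amplification", "deep_deletion"))
  # amplification without SNP corroboration is rejected
  ev2 <- select_focal_events(segs, het_snps = .toy_snps("chr3"))
  expect_equal(ev2$chrom[ev2$event_type == "amplification"], "chr3")
})

test_that("tightening any threshold never enlarges the event set", {
  set.seed(60)
  segs <- data.frame(sample_id = "s1", chrom = paste0("chr", 1:40),
                     start = 0, end = 1e6,
                     n_probes = sample(5:60, 40, TRUE),
                     log2_ratio = runif(40, -2, 2), stringsAsFactors = FALSE)
  snps <- .toy_snps(paste0("chr", 1:40))
  key <- function(ev) paste(ev$chrom, ev$event_type)
  base <- key(select_focal_events(segs, snps))
  for (amp in c(1.0, 1.2)) {
    expect_true(all(key(select_focal_events(segs, snps, amp_log2 = amp)) %in% base))
  }
  for (mp in c(30, 50)) {
    expect_true(all(key(select_focal_events(segs, snps, min_probes = mp)) %in% base))
  }
  expect_true(all(key(select_focal_events(segs, snps, del_log2 = -1.5)) %in% base))
  expect_true(all(key(select_focal_events(segs, snps, ai_alpha = 1e-6)) %in% base))
})

test_that("allowlisted segments are rescued regardless of thresholds", {
  segs <- data.frame(sample_id = "s1", chrom = "chr9", start = 100000,
                     end = 140000, n_probes = 4, log2_ratio = -1.8,
                     stringsAsFactors = FALSE)
  none <- select_focal_events(segs)
  expect_equal(nrow(none), 0)
  allow <- data.frame(sample_id = "s1", chrom = "chr9", start = 90000,
                      end = 150000, event_type = "deep_deletion",
                      stringsAsFactors = FALSE)
  ev <- select_focal_events(segs, allowlist = allow)
  expect_equal(ev$event_type, "deep_deletion")
  expect_true(ev$rescued)
})

test_that("planted amplifications in simulated cohorts are recalled at high purity", {
  sim <- small_sim(n_samples = 10, seed = 23, territory = 5e6,
                   cellularity_range = c(0.5, 0.95))
  b <- sim$bundle
  het <- do.call(rbind, lapply(names(b$samples), function(sid) {
    cbind(sample_id = sid, b$samples[[sid]]$het_snps)
  }))
  segs <- do.call(rbind, lapply(b$samples, `[[`, "segments"))
  ev <- select_focal_events(segs, het_snps = het)
  truth <- sim$truth$cn_events
  amps <- truth[truth$type == "amplification", ]
  if (nrow(amps)) {
    found <- mapply(function(sid, ch) {
      any(ev$sample_id == sid & ev$chrom == ch & ev$event_type == "amplification")
    }, amps$sample_id, amps$chrom)
    expect_gte(mean(found), 0.9)
  }
  # no neutral segment sneaks through
  neutral_hit <- merge(ev, truth, by = c("sample_id", "chrom"), all.x = TRUE)
  expect_true(all(!is.na(neutral_hit$type)))
})

test_that("gene annotation agrees with the quadratic all-pairs oracle", {
  genes <- data.frame(chrom = "chr1",
                      start = c(150, 200, 0, 500),
                      end = c(300, 300, 120, 600),
                      gene = c("G1", "G2", "G3", "G4"), stringsAsFactors = FALSE)
  ev <- data.frame(chrom = "chr1", start = c(100, 100, 0),
                   end = c(200, 200, 700), stringsAsFactors = FALSE)
  ann <- annotate_genes(ev, genes)
  expect_equal(ann$genes, quadratic_overlap_oracle(ev, genes))
  # half-open: [100, 200) does not reach a gene starting at 200
  expect_equal(ann$genes[2], "G3,G1")
  # random instances
  set.seed(71)
  for (i in 1:10) {
    g <- data.frame(chrom = sample(c("chr1", "chr2"), 15, TRUE),
                    start = sample(0:900, 15), gene = paste0("g", 1:15),
                    stringsAsFactors = FALSE)
    g$end <- g$start + sample(10:200, 15, TRUE)
    e <- data.frame(chrom = sample(c("chr1", "chr2"), 6, TRUE),
                    start = sample(0:900, 6), stringsAsFactors = FALSE)
    e$end <- e$start + sample(10:300, 6, TRUE)
    expect_equal(annotate_genes(e, g)$genes, quadratic_overlap_oracle(e, g))
  }
})
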