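# Independent brute-force oracles used across the suite.

# Per-base footprint counting: expand small tracks to individual bases.
brute_force_footprint <- function(reference, tumor, rho, min_ref = 6,
                                  min_eff = 8, territory) {
  expand <- function(df) {
    do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      data.frame(chrom = df$chrom[i],
                 base = seq(df$start[i], df$end[i] - 1),
                 depth = df$depth[i])
    }))
  }
  r <- expand(reference); t <- expand(tumor)
  ref_bp <- sum(r$depth >= min_ref)
  tum_bp <- sum(t$depth * rho >= min_eff)
  key <- function(d) paste(d$chrom, d$base)
  both <- sum(key(r)[r$depth >= min_ref] %in% key(t)[t$depth * rho >= min_eff])
  list(ref_bp = ref_bp, tum_bp = tum_bp, minimum = min(ref_bp, tum_bp),
       intersection = both,
       fraction = min(ref_bp, tum_bp) / territory)
}

# Grid-search inversion of a mixture model f(rho) for the cellularity oracles.
grid_invert <- function(f_target, f_of_rho, grid = seq(0, 1, by = 1e-6)) {
  grid[which.min(abs(f_of_rho(grid) - f_target))]
}

# Two-sided Fisher p by direct combinatorial enumeration over all tables
# with the observed margins: P(table) = C(r1, a) C(r2, c) / C(n, k).
fisher_enumeration_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; r2 <- c + d; k <- a + c
  support <- max(0, k - r2):min(k, r1)
  logp <- lchoose(r1, support) + lchoose(r2, k - support) - lchoose(n, k)
  p_tab <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, k))
  min(1, sum(p_tab[p_tab <= p_obs * (1 + 1e-12)]))
}

# Hand-applied BH step-up: q_i = min over j with p_(j) >= p_(i) of m p_(j)/j.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[ord] >= p[i] - 1e-15)
    q[i] <- min(1, min(m * p[ord][js] / js))
  }
  q
}

# Direct application of the three variant-filter rules, row by row.
brute_force_filter <- function(variants, rho, min_total = 14, min_alt = 4,
                               min_ccf = 0.40, sex = "female") {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    tot <- variants$ref_reads[i] + variants$alt_reads[i]
    maf <- if (tot > 0) variants$alt_reads[i] / tot else 0
    hemi <- isTRUE(variants$is_sex_chrom[i]) && sex == "male"
    ccf <- if (hemi) min(1, maf * (2 - rho) / rho) else min(1, 2 * maf / rho)
    keep[i] <- tot >= min_total && variants$alt_reads[i] >= min_alt &&
      ccf >= min_ccf
  }
  keep
}

# Quadratic all-pairs interval overlap (0-based half-open).
quadratic_overlap_oracle <- function(events, genes) {
  vapply(seq_len(nrow(events)), function(i) {
    hit <- genes$chrom == events$chrom[i] &
      genes$start < events$end[i] & genes$end > events$start[i]
    paste(genes$gene[hit][order(genes$start[hit])], collapse = ",")
  }, character(1))
}

# Minimal variant-table constructor for spectrum / UV / filter tests.
make_variants <- function(ref, alt, context, class = "SNV", ...) {
  data.frame(ref = ref, alt = alt, trinucleotide_context = context,
             variant_class = rep_len(class, length(ref)), ...,
             stringsAsFactors = FALSE)
}

# Het-SNP counts at a given pooled minor fraction and depth (exact counts,
# no sampling) for the analytic-inversion tests.
exact_snps <- function(f, n_snps = 10, depth = 60, label = "deletion") {
  minor <- round(depth * f)
  stopifnot(abs(minor - depth * f) < 1e-9)  # fixture must be exact
  data.frame(chrom = "chr1", pos = seq_len(n_snps) * 1000,
             a_reads = rep(depth - minor, n_snps),
             b_reads = rep(minor, n_snps),
             region_label = label, stringsAsFactors = FALSE)
}

# Binomially sampled het SNPs from the two-population mixture.
sample_snps <- function(n, rho, region, depth_mean = 80) {
  f <- switch(region,
              deletion = (1 - rho) / (2 - rho),
              cnLOH = (1 - rho) / 2,
              neutral = 0.5)
  depth <- pmax(1, stats::rpois(n, depth_mean))
  b <- stats::rbinom(n, depth, f)
  a <- depth - b
  swap <- stats::runif(n) < 0.5
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(chrom = "chr1", pos = seq_len(n), a_reads = a, b_reads = b,
             region_label = region, stringsAsFactors = FALSE)
}

small_sim <- function(n_samples = 5, seed = 11, territory = 1.5e6, ...) {
  simulate_cohort(sim_config(n_samples = n_samples, seed = seed,
                             bait_territory_bp = territory, ...))
}
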