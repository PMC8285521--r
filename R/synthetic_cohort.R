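#' Simulation configuration for a synthetic tumor cohort
#'
#' Bundles the study conditions a generated cohort emulates: per-subtype
#' burden and signature mixtures, the cellularity and depth ranges, the
#' depth-overdispersion model, and the subclonal mutation load. Defaults
#' describe a skin-cancer-like exome cohort: four clinical subtypes plus a
#' rare UV-hypersensitive one, purities spanning 12--99\%, and mean depths
#' spanning typical exome studies.
#'
#' @param n_samples Number of tumors (>= 1).
#' @param subtype_specs Named list; each element a list with
#'   \code{prob} (sampling weight), \code{burden_lognormal} (meanlog, sdlog
#'   of the per-Mb clonal burden), \code{signature_alpha} (Dirichlet
#'   concentration over the signature-matrix columns) and
#'   \code{casp8_enrichment_prob} (probability of planting a truncating
#'   CASP8 mutation).
#' @param cellularity_range Purity bounds in (0, 1].
#' @param bait_territory_bp Total targeted basepairs.
#' @param mean_depth_range Mean sequencing depth bounds (both roles).
#' @param depth_dispersion Negative-binomial overdispersion phi: per-bin
#'   depth has variance mu (1 + phi mu).
#' @param subclonal_fraction Fraction of simulated mutations drawn at
#'   subclonal cancer-cell fractions (Uniform(0.05, 0.35)).
#' @param dinucleotide_fraction CC>TT events per clonal SNV, scaled by the
#'   UV-like weight of the sample's signature mixture.
#' @param bin_bp Coverage bin width.
#' @param seed Integer RNG seed; identical config + seed gives
#'   byte-identical cohort files.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_samples = 20,
                       subtype_specs = default_subtype_specs(),
                       cellularity_range = c(0.12, 0.99),
                       bait_territory_bp = 5e6,
                       mean_depth_range = c(30, 300),
                       depth_dispersion = 0.15,
                       subclonal_fraction = 0.2,
                       dinucleotide_fraction = 0.03,
                       bin_bp = 1000,
                       seed = 1) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (cellularity_range[1] <= 0 || cellularity_range[2] > 1 ||
      cellularity_range[1] > cellularity_range[2]) {
    stop("cellularity bounds must lie in (0, 1]")
  }
  if (any(mean_depth_range <= 0) || depth_dispersion <= 0) {
    stop("depths and dispersion must be positive")
  }
  if (subclonal_fraction < 0 || subclonal_fraction >= 1) {
    stop("subclonal_fraction must be in [0, 1)")
  }
  for (st in subtype_specs) {
    if (any(st$signature_alpha < 0)) stop("Dirichlet weights must be nonnegative")
  }
  structure(list(n_samples = n_samples, subtype_specs = subtype_specs,
                 cellularity_range = cellularity_range,
                 bait_territory_bp = bait_territory_bp,
                 mean_depth_range = mean_depth_range,
                 depth_dispersion = depth_dispersion,
                 subclonal_fraction = subclonal_fraction,
                 dinucleotide_fraction = dinucleotide_fraction,
                 bin_bp = bin_bp, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default subtype mixture
#'
#' Five subtypes shaped like the clinical strata of a cutaneous
#' squamous-cell-carcinoma cohort: sporadic UV-driven tumors with high
#' burden, azathioprine-exposed immunosuppressed tumors with very high
#' burden, other immunosuppressed tumors, low-burden APOBEC-driven RDEB
#' tumors (CASP8-enriched), and rare UV-hypersensitive (XP-like) tumors.
#' Alphas index the columns of \code{\link{synthetic_signature_matrix}}.
#'
#' @return Named list of subtype specs.
#' @export
default_subtype_specs <- function() {
  list(
    sporadic = list(prob = 0.45, burden_lognormal = c(log(30), 0.6),
                    signature_alpha = c(UV = 24, AZA = 1, APOBEC = 2,
                                        OX = 2, CLOCK = 4, TA = 1),
                    casp8_enrichment_prob = 0.10),
    immunosuppressed_aza = list(prob = 0.18, burden_lognormal = c(log(60), 0.5),
                                signature_alpha = c(UV = 8, AZA = 20, APOBEC = 1,
                                                    OX = 1, CLOCK = 3, TA = 1),
                                casp8_enrichment_prob = 0.10),
    immunosuppressed_other = list(prob = 0.20, burden_lognormal = c(log(15), 0.6),
                                  signature_alpha = c(UV = 18, AZA = 1, APOBEC = 2,
                                                      OX = 2, CLOCK = 5, TA = 1),
                                  casp8_enrichment_prob = 0.10),
    rdeb = list(prob = 0.12, burden_lognormal = c(log(5), 0.5),
                signature_alpha = c(UV = 2, AZA = 1, APOBEC = 18,
                                    OX = 2, CLOCK = 5, TA = 1),
                casp8_enrichment_prob = 0.70),
    xp = list(prob = 0.05, burden_lognormal = c(log(80), 0.4),
              signature_alpha = c(UV = 30, AZA = 1, APOBEC = 1,
                                  OX = 1, CLOCK = 2, TA = 1),
              casp8_enrichment_prob = 0.10)
  )
}

# Pseudo-genome: four autosomes and one X share the bait territory.
.sim_genome <- function(territory_bp, bin_bp) {
  share <- c(chr1 = 0.25, chr2 = 0.25, chr3 = 0.23, chr4 = 0.21, chrX = 0.06)
  bins <- NULL
  for (ch in names(share)) {
    n <- max(10, floor(territory_bp * share[[ch]] / bin_bp))
    start <- (seq_len(n) - 1) * bin_bp
    gc <- 0.45 + 0.10 * sin(2 * pi * seq_len(n) / 150)
    bins <- rbind(bins, data.frame(chrom = ch, start = start,
                                   end = start + bin_bp, gc = gc,
                                   stringsAsFactors = FALSE))
  }
  bins
}

#' Gene intervals of the synthetic genome
#'
#' A fixed BED-like universe of driver-pathway genes tiled across the
#' pseudo-genome. \code{CDKN2A}/\code{PTEN} sit inside the focal-deletion
#' candidate region and \code{CCND1}/\code{YAP1} inside the amplification
#' candidate region so planted events hit nameable targets.
#'
#' @param genome Bin table from the simulator (internal layout).
#' @return Data frame: chrom, start, end, gene.
#' @keywords internal
.sim_genes <- function(genome) {
  chrlen <- vapply(split(genome$end, genome$chrom), max, numeric(1))
  g1 <- c("TP53", "NOTCH1", "NOTCH2", "NOTCH3", "FAT1", "EP300", "CREBBP",
          "ARID2", "PBRM1", "SMARCA4", "USP28", "CHUK", "NFE2L2", "CASP8",
          "HRAS", "KRAS", "PIK3CA", "MTOR", "EZH2", "KMT2D", "AJUBA",
          "LATS1", "LATS2", "RB1", "CDK4", "TERT")
  L1 <- chrlen[["chr1"]]
  starts <- floor(seq(0.02, 0.9, length.out = length(g1)) * L1)
  bed <- data.frame(chrom = "chr1", start = starts,
                    end = pmin(starts + 20000, L1), gene = g1,
                    stringsAsFactors = FALSE)
  L4 <- chrlen[["chr4"]]
  del0 <- floor(0.10 * L4); del1 <- floor(0.14 * L4)
  amp0 <- floor(0.60 * L4); amp1 <- floor(0.64 * L4)
  bed <- rbind(bed, data.frame(
    chrom = "chr4",
    start = c(del0 + 1000, floor((del0 + del1) / 2), amp0 + 1000,
              floor((amp0 + amp1) / 2)),
    end = c(del0 + 9000, floor((del0 + del1) / 2) + 8000, amp0 + 9000,
            floor((amp0 + amp1) / 2) + 8000),
    gene = c("CDKN2A", "PTEN", "CCND1", "YAP1"), stringsAsFactors = FALSE))
  bed[order(bed$chrom, bed$start), ]
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

.mix_factor <- function(rho, c_t) (rho * c_t + 2 * (1 - rho)) / 2

# Expected mutant/B-allele read fraction for m copies mutant of c_t tumor
# copies, n_normal normal copies carrying it, at purity rho.
.mix_vaf <- function(rho, m_t, c_t, n_normal = 0, normal_copies = 2) {
  (rho * m_t + (1 - rho) * n_normal) /
    (rho * c_t + (1 - rho) * normal_copies)
}

#' Simulate a tumor cohort with known ground truth
#'
#' Generates, for each sample: tumor and reference coverage tracks with
#' GC-modulated negative-binomial depth; germline het-SNP allele counts
#' whose B-fractions follow the tumor/normal read mixture for their region
#' (hemizygous deletion, copy-neutral LOH, or neutral); a somatic variant
#' table with binomially sampled read counts at the purity- and
#' copy-number-implied expected MAF, trinucleotide contexts drawn from the
#' sample's signature mixture, and a subclonal admixture at cancer-cell
#' fractions Uniform(0.05, 0.35); and a SEG table of planted copy-number
#' events. Males carry hemizygous X-chromosome variants at expected MAF
#' rho / (2 - rho). Somatic point mutations are placed in copy-neutral
#' territory (and chrX).
#'
#' @param config A \code{\link{sim_config}}.
#' @param signatures Signature matrix (96 x K, columns sum to 1) whose
#'   column count matches each subtype's \code{signature_alpha} length.
#' @return List with \code{bundle} (per-sample tables, manifest, baits,
#'   genes, signatures, config) and \code{truth} (per-sample cellularity,
#'   burden, signature weights, copy-number events, per-variant clonality).
#' @export
simulate_cohort <- function(config, signatures = synthetic_signature_matrix()) {
  stopifnot(inherits(config, "sim_config"))
  for (st in config$subtype_specs) {
    if (length(st$signature_alpha) != ncol(signatures)) {
      stop("signature matrix column count does not match subtype Dirichlet dimension")
    }
  }
  set.seed(config$seed)
  genome <- .sim_genome(config$bait_territory_bp, config$bin_bp)
  genes <- .sim_genes(genome)
  territory_bp <- sum(genome$end - genome$start)
  phi <- config$depth_dispersion
  uv_like <- attr(signatures, "uv_like") %||%
    stats::setNames(rep(FALSE, ncol(signatures)), colnames(signatures))

  st_names <- names(config$subtype_specs)
  st_prob <- vapply(config$subtype_specs, `[[`, numeric(1), "prob")
  chrlen <- vapply(split(genome$end, genome$chrom), max, numeric(1))

  samples <- list()
  truth_rows <- NULL
  truth_w <- matrix(NA_real_, ncol(signatures), config$n_samples,
                    dimnames = list(colnames(signatures), NULL))
  cn_truth <- NULL

  for (i in seq_len(config$n_samples)) {
    sid <- sprintf("S%03d", i)
    subtype <- sample(st_names, 1, prob = st_prob)
    spec <- config$subtype_specs[[subtype]]
    sex <- sample(c("male", "female"), 1)
    rho <- stats::runif(1, config$cellularity_range[1], config$cellularity_range[2])
    mu_t <- stats::runif(1, config$mean_depth_range[1], config$mean_depth_range[2])
    mu_r <- stats::runif(1, config$mean_depth_range[1], config$mean_depth_range[2])
    beta_gc <- stats::runif(1, 0, 8)

    # planted copy-number events (0-based half-open, within the territory)
    ev <- list()
    if (stats::runif(1) < 0.85) {
      ev$del <- list(chrom = "chr2", start = floor(0.5 * chrlen[["chr2"]]),
                     end = chrlen[["chr2"]], c_t = 1, m_B = 0, type = "deletion")
    }
    if (stats::runif(1) < 0.6) {
      ev$loh <- list(chrom = "chr3", start = floor(0.55 * chrlen[["chr3"]]),
                     end = chrlen[["chr3"]], c_t = 2, m_B = 0, type = "cnLOH")
    }
    if (stats::runif(1) < 0.35) {
      ev$amp <- list(chrom = "chr4", start = floor(0.60 * chrlen[["chr4"]]),
                     end = floor(0.64 * chrlen[["chr4"]]), c_t = 6, m_B = 1,
                     type = "amplification")
    }
    if (stats::runif(1) < 0.30) {
      ev$homdel <- list(chrom = "chr4", start = floor(0.10 * chrlen[["chr4"]]),
                        end = floor(0.14 * chrlen[["chr4"]]), c_t = 0, m_B = 0,
                        type = "homozygous_deletion")
    }

    bin <- genome
    bin$c_t <- 2
    bin$m_B <- 1
    bin$region <- "neutral"
    for (e in ev) {
      hit <- bin$chrom == e$chrom & bin$start >= e$start & bin$end <= e$end
      bin$c_t[hit] <- e$c_t
      bin$m_B[hit] <- e$m_B
      bin$region[hit] <- e$type
    }

    gcf <- exp(beta_gc * (bin$gc - 0.45))
    gcf <- gcf / mean(gcf)
    cnf <- .mix_factor(rho, bin$c_t)
    mu_bin_t <- mu_t * gcf * cnf
    mu_bin_r <- mu_r * gcf
    tumor_cov <- data.frame(chrom = bin$chrom, start = bin$start, end = bin$end,
                            depth = stats::rnbinom(nrow(bin), mu = mu_bin_t,
                                                   size = 1 / phi),
                            stringsAsFactors = FALSE)
    ref_cov <- data.frame(chrom = bin$chrom, start = bin$start, end = bin$end,
                          depth = stats::rnbinom(nrow(bin), mu = mu_bin_r,
                                                 size = 1 / phi),
                          stringsAsFactors = FALSE)

    # germline het SNPs (autosomes), B fraction from the region's mixture
    auto <- bin[bin$chrom != "chrX", , drop = FALSE]
    snp_bins <- seq(1, nrow(auto), by = 2)  # ~1 het SNP per 2 kb
    snp <- auto[snp_bins, , drop = FALSE]
    snp$pos <- snp$start + 1 + floor(stats::runif(nrow(snp)) * (snp$end - snp$start))
    bfrac <- .mix_vaf(rho, snp$m_B, snp$c_t, n_normal = 1)
    depth <- stats::rnbinom(nrow(snp), mu = mu_t * cnf[bin$chrom != "chrX"][snp_bins] *
                              gcf[bin$chrom != "chrX"][snp_bins], size = 1 / phi)
    keep <- depth > 0
    snp <- snp[keep, ]; bfrac <- bfrac[keep]; depth <- depth[keep]
    b <- stats::rbinom(nrow(snp), depth, bfrac)
    a <- depth - b
    swap <- stats::runif(nrow(snp)) < 0.5
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    region_label <- ifelse(snp$region %in% c("deletion", "cnLOH"),
                           snp$region, "neutral")
    het_snps <- data.frame(chrom = snp$chrom, pos = snp$pos,
                           a_reads = a, b_reads = b,
                           region_label = region_label,
                           stringsAsFactors = FALSE)

    # SEG table: one row per (chrom, region) run
    seg <- NULL
    for (ch in unique(bin$chrom)) {
      cb <- bin[bin$chrom == ch, ]
      runs <- rle(cb$region)
      ends <- cumsum(runs$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      for (r in seq_along(runs$values)) {
        rows <- cb[starts[r]:ends[r], ]
        c_t <- rows$c_t[1]
        log2r <- log2(max(.mix_factor(rho, c_t), 2^-8)) + stats::rnorm(1, 0, 0.05)
        seg <- rbind(seg, data.frame(
          sample_id = sid, chrom = ch, start = min(rows$start),
          end = max(rows$end), n_probes = nrow(rows),
          log2_ratio = round(log2r, 4), stringsAsFactors = FALSE))
      }
    }

    # somatic mutations in copy-neutral territory (and chrX)
    neutral_bins <- which(bin$region == "neutral")
    burden <- stats::rlnorm(1, spec$burden_lognormal[1], spec$burden_lognormal[2])
    mb <- territory_bp / 1e6
    n_clonal <- stats::rpois(1, burden * mb)
    sf <- config$subclonal_fraction
    n_sub <- stats::rpois(1, burden * mb * sf / (1 - sf))
    n_tot <- n_clonal + n_sub
    w <- .rdirichlet1(spec$signature_alpha)
    truth_w[, i] <- w

    variants <- NULL
    if (n_tot > 0) {
      vb <- sample(neutral_bins, n_tot, replace = TRUE)
      pos <- bin$start[vb] + 1 +
        floor(stats::runif(n_tot) * (bin$end[vb] - bin$start[vb]))
      chrom <- bin$chrom[vb]
      is_x <- chrom == "chrX"
      ccf <- c(rep(1, n_clonal), stats::runif(n_sub, 0.05, 0.35))
      hemi <- is_x & sex == "male"
      exp_maf <- ifelse(hemi, ccf * rho / (rho + 2 * (1 - rho)), ccf * rho / 2)
      p_mix <- as.numeric(signatures %*% w)
      cls <- sample.int(96, n_tot, replace = TRUE, prob = p_mix)
      labs <- context_labels_96()[cls]
      p5 <- substr(labs, 1, 1); ref <- substr(labs, 3, 3)
      alt <- substr(labs, 5, 5); p3 <- substr(labs, 7, 7)
      ctx <- paste0(p5, ref, p3)
      flip <- stats::runif(n_tot) < 0.5
      ref[flip] <- unname(.comp[ref[flip]])
      alt[flip] <- unname(.comp[alt[flip]])
      ctx[flip] <- .revcomp(ctx[flip])
      depth_v <- stats::rnbinom(n_tot, mu = mu_t * gcf[vb], size = 1 / phi)
      alt_reads <- stats::rbinom(n_tot, depth_v, exp_maf)
      variants <- data.frame(
        sample_id = sid, chrom = chrom, pos = pos, ref = ref, alt = alt,
        ref_reads = depth_v - alt_reads, alt_reads = alt_reads,
        trinucleotide_context = ctx, variant_class = "SNV",
        gene = "", effect = "other", protein_change = "",
        is_sex_chrom = is_x, true_clonal = ccf == 1,
        true_ccf = round(ccf, 6), stringsAsFactors = FALSE)
      variants <- variants[variants$alt_reads >= 1, , drop = FALSE]
    }

    # CC>TT dinucleotides in proportion to the UV-like mixture weight
    n_dinuc <- stats::rpois(1, n_clonal * config$dinucleotide_fraction *
                              sum(w[uv_like]))
    if (n_dinuc > 0) {
      db <- sample(neutral_bins[bin$chrom[neutral_bins] != "chrX"], n_dinuc,
                   replace = TRUE)
      dpos <- bin$start[db] + 1 +
        floor(stats::runif(n_dinuc) * (bin$end[db] - bin$start[db]))
      ddepth <- stats::rnbinom(n_dinuc, mu = mu_t * gcf[db], size = 1 / phi)
      dalt <- stats::rbinom(n_dinuc, ddepth, rho / 2)
      dn <- data.frame(
        sample_id = sid, chrom = bin$chrom[db], pos = dpos, ref = "CC",
        alt = "TT", ref_reads = ddepth - dalt, alt_reads = dalt,
        trinucleotide_context = "TCC", variant_class = "dinucleotide",
        gene = "", effect = "other", protein_change = "",
        is_sex_chrom = FALSE, true_clonal = TRUE, true_ccf = 1,
        stringsAsFactors = FALSE)
      variants <- rbind(variants, dn[dn$alt_reads >= 1, , drop = FALSE])
    }

    # planted truncating CASP8 mutation (subtype-dependent enrichment)
    if (stats::runif(1) < spec$casp8_enrichment_prob) {
      cg <- genes[genes$gene == "CASP8", ]
      cpos <- cg$start + 1 + floor(stats::runif(1) * (cg$end - cg$start))
      cdepth <- max(1, stats::rnbinom(1, mu = mu_t, size = 1 / phi))
      calt <- stats::rbinom(1, cdepth, rho / 2)
      variants <- rbind(variants, data.frame(
        sample_id = sid, chrom = cg$chrom, pos = cpos, ref = "C", alt = "A",
        ref_reads = cdepth - calt, alt_reads = calt,
        trinucleotide_context = "TCA", variant_class = "SNV", gene = "",
        effect = "nonsense", protein_change = "", is_sex_chrom = FALSE,
        true_clonal = TRUE, true_ccf = 1, stringsAsFactors = FALSE))
    }

    if (is.null(variants)) {
      variants <- data.frame(sample_id = character(0), chrom = character(0),
                             pos = numeric(0), ref = character(0),
                             alt = character(0), ref_reads = integer(0),
                             alt_reads = integer(0),
                             trinucleotide_context = character(0),
                             variant_class = character(0), gene = character(0),
                             effect = character(0), protein_change = character(0),
                             is_sex_chrom = logical(0), true_clonal = logical(0),
                             true_ccf = numeric(0), stringsAsFactors = FALSE)
    }
    variants <- .annotate_sim_genes(variants, genes)
    rownames(variants) <- NULL

    samples[[sid]] <- list(variants = variants, tumor_coverage = tumor_cov,
                           reference_coverage = ref_cov, het_snps = het_snps,
                           segments = seg)
    truth_rows <- rbind(truth_rows, data.frame(
      sample_id = sid, subtype = subtype, sex = sex, cellularity = rho,
      true_burden = burden, n_clonal = n_clonal, n_subclonal = n_sub,
      mean_depth_tumor = mu_t, mean_depth_reference = mu_r,
      stringsAsFactors = FALSE))
    for (e in ev) {
      cn_truth <- rbind(cn_truth, data.frame(
        sample_id = sid, chrom = e$chrom, start = e$start, end = e$end,
        c_t = e$c_t, type = e$type, stringsAsFactors = FALSE))
    }
  }
  colnames(truth_w) <- truth_rows$sample_id

  baits <- data.frame(chrom = genome$chrom, start = genome$start,
                      end = genome$end, stringsAsFactors = FALSE)
  manifest <- truth_rows[, c("sample_id", "subtype", "sex")]
  list(bundle = list(samples = samples, manifest = manifest, baits = baits,
                     genes = genes, signatures = signatures, config = config),
       truth = list(samples = truth_rows, signature_weights = truth_w,
                    cn_events = cn_truth))
}

# assign gene labels, effects and protein changes to variants in gene bodies
.annotate_sim_genes <- function(variants, genes) {
  if (nrow(variants) == 0) return(variants)
  for (g in seq_len(nrow(genes))) {
    hit <- variants$chrom == genes$chrom[g] &
      variants$pos - 1 >= genes$start[g] & variants$pos - 1 < genes$end[g] &
      variants$variant_class == "SNV"
    if (!any(hit)) next
    variants$gene[hit] <- genes$gene[g]
    n <- sum(hit)
    needs_effect <- hit & variants$effect == "other"
    variants$effect[needs_effect] <- sample(
      c("missense", "silent", "nonsense", "splice", "other"),
      sum(needs_effect), replace = TRUE, prob = c(0.55, 0.2, 0.12, 0.05, 0.08))
    aa <- c("A", "R", "N", "D", "G", "E", "Q", "H", "L", "K", "S", "T", "V", "W", "Y")
    variants$protein_change[hit] <- paste0(
      "p.", sample(aa, n, TRUE),
      1 + ((variants$pos[hit] - genes$start[g]) %/% 3),
      ifelse(variants$effect[hit] == "nonsense", "*", sample(aa, n, TRUE)))
  }
  variants
}

#' Write a simulated cohort to disk
#'
#' Writes, per sample, the variant TSV, tumor and reference bedGraphs, the
#' het-SNP TSV and the SEG TSV, plus cohort-level files: \code{baits.bed},
#' \code{genes.bed}, \code{signatures.tsv}, \code{config.yaml} and a
#' \code{manifest.tsv} listing every file with its sample id, subtype and
#' sex. File contents are deterministic functions of the bundle.
#'
#' @param bundle The \code{bundle} element of \code{\link{simulate_cohort}}.
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_cohort <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  tsv <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  man <- bundle$manifest
  man$variants <- paste0(man$sample_id, "_variants.tsv")
  man$tumor_coverage <- paste0(man$sample_id, "_tumor.bedgraph")
  man$reference_coverage <- paste0(man$sample_id, "_reference.bedgraph")
  man$het_snps <- paste0(man$sample_id, "_hetsnps.tsv")
  man$segments <- paste0(man$sample_id, "_segments.seg")
  for (i in seq_len(nrow(man))) {
    s <- bundle$samples[[man$sample_id[i]]]
    tsv(s$variants, man$variants[i])
    utils::write.table(s$tumor_coverage, file.path(out_dir, man$tumor_coverage[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(s$reference_coverage,
                       file.path(out_dir, man$reference_coverage[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    tsv(s$het_snps, man$het_snps[i])
    tsv(s$segments, man$segments[i])
  }
  utils::write.table(bundle$baits, file.path(out_dir, "baits.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tsv(bundle$genes, "genes.bed")
  write_signature_matrix(bundle$signatures, file.path(out_dir, "signatures.tsv"))
  cfg <- unclass(bundle$config)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  tsv(man, "manifest.tsv")
  invisible(file.path(out_dir, "manifest.tsv"))
}

#' Read a cohort directory written by \code{write_cohort}
#'
#' @param dir Cohort directory containing \code{manifest.tsv}.
#' @return A bundle-shaped list (samples, manifest, baits, genes,
#'   signatures, config when present).
#' @export
read_cohort <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  samples <- list()
  territory <- NULL
  baits <- utils::read.table(file.path(dir, "baits.bed"), sep = "\t",
                             col.names = c("chrom", "start", "end"),
                             colClasses = c("character", "numeric", "numeric"))
  territory <- sum(baits$end - baits$start)
  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    rd <- function(f, ...) utils::read.delim(file.path(dir, f),
                                             stringsAsFactors = FALSE, ...)
    samples[[sid]] <- list(
      variants = rd(man$variants[i], colClasses = c(chrom = "character",
                                                    ref = "character",
                                                    alt = "character")),
      tumor_coverage = utils::read.table(
        file.path(dir, man$tumor_coverage[i]), sep = "\t",
        col.names = c("chrom", "start", "end", "depth"),
        colClasses = c("character", "numeric", "numeric", "numeric")),
      reference_coverage = utils::read.table(
        file.path(dir, man$reference_coverage[i]), sep = "\t",
        col.names = c("chrom", "start", "end", "depth"),
        colClasses = c("character", "numeric", "numeric", "numeric")),
      het_snps = rd(man$het_snps[i], colClasses = c(chrom = "character")),
      segments = rd(man$segments[i], colClasses = c(sample_id = "character",
                                                    chrom = "character")))
  }
  genes <- utils::read.delim(file.path(dir, "genes.bed"),
                             stringsAsFactors = FALSE)
  sigs <- read_signature_matrix(file.path(dir, "signatures.tsv"))
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  list(samples = samples,
       manifest = man[, c("sample_id", "subtype", "sex")],
       baits = baits, genes = genes, signatures = sigs, config = cfg,
       bait_territory_bp = territory)
}
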