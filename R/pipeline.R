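#' Default pathway groupings
#'
#' Seven driver-pathway labels over member gene sets (NOTCH, p53,
#' cell cycle, SWI/SNF, Hippo, stress response, MAPK/PI3K), matching the
#' gene universe of the synthetic cohort. These are configuration, not a
#' biological claim: replace them (or the shipped
#' \code{inst/extdata/default_pathways.yaml}) with the memberships of your
#' own study.
#'
#' @param path Optional YAML file (pathway -> gene list) to read instead.
#' @return Named list of character vectors.
#' @export
default_pathways <- function(path = NULL) {
  if (!is.null(path)) return(yaml::read_yaml(path))
  list(
    NOTCH = c("NOTCH1", "NOTCH2", "NOTCH3", "FAT1", "EP300", "CREBBP"),
    p53 = c("TP53", "MDM2"),
    cell_cycle = c("CDKN2A", "CCND1", "CDK4", "RB1"),
    SWI_SNF = c("ARID2", "PBRM1", "SMARCA4"),
    Hippo = c("FAT1", "AJUBA", "LATS1", "LATS2", "YAP1"),
    stress = c("CASP8", "CHUK", "NFE2L2"),
    MAPK_PI3K = c("HRAS", "KRAS", "PIK3CA", "PTEN", "MTOR")
  )
}

#' Advisory exclusion screen
#'
#' Flags samples whose data quality undermines somatic calling:
#' \code{poor_sampling} when the kept mutation count is below
#' \code{min_mutations} and the modal MAF sits near the detection limit
#' (both conditions must hold — a genuinely quiet genome with well-supported
#' MAFs is not flagged), and \code{low_reference_coverage} when mean
#' reference depth is below \code{min_ref_coverage} (germline SNPs cannot be
#' confidently removed). Flags are advisory; enforcement is the caller's
#' switch.
#'
#' @param profiles Data frame with per-sample \code{n_clonal_kept},
#'   \code{modal_maf} (NA allowed) and \code{mean_reference_depth}.
#' @param min_mutations Mutation-count floor (default 20).
#' @param modal_maf_floor Near-detection-limit MAF threshold (default 0.1).
#' @param min_ref_coverage Minimum mean reference depth (default 5).
#' @return \code{profiles} with \code{exclusion_flags} (comma-joined, ""
#'   when clean) and \code{excluded} (logical).
#' @export
exclusion_screen <- function(profiles, min_mutations = 20,
                             modal_maf_floor = 0.1, min_ref_coverage = 5) {
  poor <- profiles$n_clonal_kept < min_mutations &
    !is.na(profiles$modal_maf) & profiles$modal_maf < modal_maf_floor
  poor[is.na(poor)] <- FALSE
  lowref <- profiles$mean_reference_depth < min_ref_coverage
  flags <- mapply(function(p, l) {
    paste(c(if (p) "poor_sampling", if (l) "low_reference_coverage"),
          collapse = ",")
  }, poor, lowref)
  profiles$exclusion_flags <- unname(flags)
  profiles$excluded <- flags != ""
  profiles
}

.modal_maf_raw <- function(mafs) {
  mafs <- mafs[!is.na(mafs)]
  if (length(mafs) < 5) return(if (length(mafs)) stats::median(mafs) else NA_real_)
  bw <- tryCatch(stats::bw.nrd0(mafs), error = function(e) 0)
  if (length(unique(mafs)) >= 3 && is.finite(bw) && bw > 0) {
    d <- stats::density(mafs, bw = bw, from = 1e-3, to = 0.6, n = 512)
    d$x[which.max(d$y)]
  } else {
    stats::median(mafs)
  }
}

#' Run the full cohort pipeline on a simulated or on-disk cohort
#'
#' Executes the stages in dependency order for every sample: cellularity
#' inference (allelic imbalance first, somatic-MAF methods as fallback),
#' callable-footprint computation, clonality-aware variant filtering,
#' footprint-normalized burden, 96-context spectrum, signature refit and
#' UV fraction; then cohort-level focal copy-number selection with gene
#' annotation, the alteration matrix (genes with kept non-silent mutations,
#' pathway OR-rows, subtype indicators) and the Fisher/BH overlap analysis.
#' A sample whose stages fail (e.g. no applicable cellularity method, zero
#' callable footprint) is quarantined with the reason logged and recorded;
#' remaining samples are unaffected.
#'
#' @param cohort A bundle from \code{\link{simulate_cohort}} or a directory
#'   path written by \code{\link{write_cohort}}.
#' @param min_ref_depth,min_effective_depth Footprint thresholds.
#' @param min_total_reads,min_alt_reads,min_ccf Variant-filter thresholds.
#' @param min_mutant Overlap-analysis prevalence floor (default 16).
#' @param pathways Named list of pathway memberships
#'   (default \code{\link{default_pathways}}).
#' @param prune_below Signature-weight pruning threshold.
#' @param enforce_exclusion Drop flagged samples from cohort-level outputs.
#' @param out_dir Optional directory for TSV outputs.
#' @param verbose Log one line per stage per sample.
#' @return List: \code{samples} (SampleProfile data frame),
#'   \code{signature_weights} (K x n matrix), \code{spectra} (96 x n),
#'   \code{filtered_variants}, \code{focal_events}, \code{overlap},
#'   \code{alteration_matrix}, \code{quarantined} (data frame of
#'   sample/reason), \code{run_info} (thresholds and versions).
#' @export
run_pipeline <- function(cohort,
                         min_ref_depth = 6, min_effective_depth = 8,
                         min_total_reads = 14, min_alt_reads = 4,
                         min_ccf = 0.40, min_mutant = 16,
                         pathways = default_pathways(),
                         prune_below = 0,
                         enforce_exclusion = FALSE,
                         out_dir = NULL, verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  territory <- cohort$bait_territory_bp %||%
    sum(cohort$baits$end - cohort$baits$start)
  sigs <- cohort$signatures
  man <- cohort$manifest
  say <- function(...) if (verbose) message(...)

  profiles <- NULL
  quarantined <- NULL
  weights <- matrix(NA_real_, ncol(sigs), 0, dimnames = list(colnames(sigs), NULL))
  spectra <- matrix(0, 96, 0)
  kept_all <- NULL

  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    sex <- man$sex[i]
    s <- cohort$samples[[sid]]
    res <- tryCatch({
      v <- s$variants
      tot <- v$ref_reads + v$alt_reads
      maf <- ifelse(tot > 0, v$alt_reads / tot, NA)
      snv_auto <- v$variant_class == "SNV" & !v$is_sex_chrom
      snv_x <- v$variant_class == "SNV" & v$is_sex_chrom

      cell <- estimate_cellularity(
        snps = s$het_snps, mafs_autosomal = maf[snv_auto],
        mafs_sex = maf[snv_x], sex = sex)
      rho <- cell$selected$rho
      if (rho <= 0) stop("estimated cellularity is 0")
      say(sid, ": cellularity ", round(rho, 3), " (", cell$selected$method, ")")

      ref_prof <- coverage_profile(s$reference_coverage, sid, "reference", territory)
      tum_prof <- coverage_profile(s$tumor_coverage, sid, "tumor", territory)
      fp <- callable_footprint(ref_prof, tum_prof, rho,
                               min_ref_depth, min_effective_depth)
      if (fp$sample_footprint_bp <= 0) stop("zero callable footprint")
      say(sid, ": callable fraction ", round(fp$fraction_callable, 3))

      filt <- filter_somatic_variants(v, rho, sex, min_total_reads,
                                      min_alt_reads, min_ccf)
      kept <- filt[filt$kept, , drop = FALSE]
      say(sid, ": variants ", nrow(filt), " in, ", nrow(kept), " kept")

      n_clonal <- nrow(kept)
      burden <- mutation_burden(n_clonal, fp$sample_footprint_bp)
      spec <- build_spectrum(kept)
      att <- if (sum(spec) > 0) fit_signature_weights(spec, sigs, prune_below)
      else list(weights = stats::setNames(rep(NA_real_, ncol(sigs)),
                                          colnames(sigs)),
                unattributed = NA_real_, reconstruction_error = NA_real_)
      uvf <- if (nrow(kept)) uv_fraction(kept) else NA_real_

      cov_w <- s$reference_coverage$end - s$reference_coverage$start
      mean_ref <- sum(s$reference_coverage$depth * cov_w) / sum(cov_w)

      prof <- data.frame(
        sample_id = sid, subtype = man$subtype[i], sex = sex,
        cellularity = rho, cellularity_method = cell$selected$method,
        callable_footprint_bp = fp$sample_footprint_bp,
        fraction_callable = fp$fraction_callable,
        n_variants_in = nrow(filt), n_clonal_kept = n_clonal,
        burden_per_mb = burden, uv_fraction = uvf,
        unattributed = att$unattributed,
        modal_maf = .modal_maf_raw(maf[snv_auto]),
        mean_reference_depth = mean_ref,
        stringsAsFactors = FALSE)
      list(prof = prof, w = att$weights, spec = spec, kept = kept)
    }, error = function(e) e)

    if (inherits(res, "error")) {
      say(sid, ": QUARANTINED (", conditionMessage(res), ")")
      quarantined <- rbind(quarantined, data.frame(
        sample_id = sid, reason = conditionMessage(res),
        stringsAsFactors = FALSE))
      next
    }
    profiles <- rbind(profiles, res$prof)
    weights <- cbind(weights, res$w)
    colnames(weights)[ncol(weights)] <- sid
    spectra <- cbind(spectra, res$spec)
    colnames(spectra)[ncol(spectra)] <- sid
    kept_all <- rbind(kept_all, res$kept)
  }
  if (is.null(profiles)) stop("every sample was quarantined")
  rownames(spectra) <- context_labels_96()

  profiles <- exclusion_screen(profiles)
  use <- if (enforce_exclusion) !profiles$excluded else rep(TRUE, nrow(profiles))
  ids <- profiles$sample_id[use]

  het_all <- do.call(rbind, lapply(ids, function(sid) {
    h <- cohort$samples[[sid]]$het_snps
    if (nrow(h)) cbind(sample_id = sid, h) else NULL
  }))
  seg_all <- do.call(rbind, lapply(ids, function(sid) cohort$samples[[sid]]$segments))
  events <- select_focal_events(seg_all, het_snps = het_all)
  events <- annotate_genes(events, cohort$genes)

  alts <- kept_all[kept_all$sample_id %in% ids & kept_all$gene != "" &
                     kept_all$effect != "silent", c("sample_id", "gene")]
  names(alts) <- c("sample_id", "feature")
  if (nrow(events)) {
    ev_genes <- do.call(rbind, lapply(seq_len(nrow(events)), function(j) {
      g <- strsplit(events$genes[j], ",")[[1]]
      if (length(g) && any(nzchar(g))) {
        data.frame(sample_id = events$sample_id[j], feature = g[nzchar(g)],
                   stringsAsFactors = FALSE)
      }
    }))
    alts <- rbind(alts, ev_genes)
  }
  subtypes <- stats::setNames(profiles$subtype, profiles$sample_id)[ids]
  amat <- alteration_matrix(alts, samples = ids, pathways = pathways,
                            subtypes = subtypes)
  overlap <- overlap_analysis(amat, min_mutant = min_mutant)

  run_info <- list(
    package_version = as.character(utils::packageVersion("somaticQC")),
    thresholds = list(min_ref_depth = min_ref_depth,
                      min_effective_depth = min_effective_depth,
                      min_total_reads = min_total_reads,
                      min_alt_reads = min_alt_reads, min_ccf = min_ccf,
                      min_mutant = min_mutant, prune_below = prune_below),
    n_samples_in = nrow(man), n_samples_profiled = nrow(profiles),
    n_quarantined = if (is.null(quarantined)) 0L else nrow(quarantined))

  out <- list(samples = profiles, signature_weights = weights,
              spectra = spectra, filtered_variants = kept_all,
              focal_events = events, overlap = overlap,
              alteration_matrix = amat,
              quarantined = quarantined %||%
                data.frame(sample_id = character(0), reason = character(0)),
              run_info = run_info)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                             sep = "\t", quote = FALSE,
                                             row.names = FALSE)
    tsv(profiles, "sample_profiles.tsv")
    tsv(data.frame(context = rownames(spectra), spectra, check.names = FALSE),
        "spectra.tsv")
    tsv(data.frame(signature = rownames(weights), weights, check.names = FALSE),
        "signature_weights.tsv")
    tsv(events, "focal_events.tsv")
    tsv(overlap, "overlap.tsv")
    tsv(out$quarantined, "quarantined.tsv")
    yaml::write_yaml(run_info, file.path(out_dir, "run_info.yaml"))
  }
  out
}
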