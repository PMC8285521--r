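#' Footprint-normalized tumor mutation burden
#'
#' Mutations per megabase, dividing the clonal mutation count by the
#' callable footprint — the basepairs at which the sample had power to call
#' a mutation — rather than by the nominal target size. This keeps burdens
#' comparable across samples with very different coverage and purity.
#'
#' @param n_clonal_mutations Count of clonal mutations kept by the filter.
#' @param callable_footprint_bp Callable footprint in basepairs, > 0.
#' @return Mutations per Mb.
#' @export
mutation_burden <- function(n_clonal_mutations, callable_footprint_bp) {
  if (any(callable_footprint_bp <= 0)) stop("callable footprint must be > 0")
  n_clonal_mutations / (callable_footprint_bp / 1e6)
}

#' Build a 96-class mutation spectrum
#'
#' Counts kept SNVs into the 96 strand-collapsed trinucleotide substitution
#' classes (see \code{\link{context_labels_96}}). Variants annotated on the
#' purine strand are reverse-complemented; non-SNV rows are ignored.
#'
#' @param variants Data frame with \code{ref}, \code{alt},
#'   \code{trinucleotide_context} (plain 3-mer) and, if present,
#'   \code{variant_class} (only "SNV" rows are counted).
#' @return Named integer vector of length 96 summing to the SNV count.
#' @export
build_spectrum <- function(variants) {
  counts <- stats::setNames(integer(96), context_labels_96())
  if (!is.null(variants$variant_class)) {
    variants <- variants[variants$variant_class == "SNV", , drop = FALSE]
  }
  if (nrow(variants) == 0) return(counts)
  idx <- spectrum_bin(variants$ref, variants$alt, variants$trinucleotide_context)
  tab <- tabulate(idx, nbins = 96)
  counts[] <- tab
  counts
}

#' Refit signature weights to a spectrum
#'
#' Solves the nonnegative least-squares problem min || p - S w ||_2, w >= 0,
#' where p is the spectrum normalized to sum 1 and S the signature matrix
#' (96 x K, columns summing to 1). Weights below \code{prune_below} are
#' zeroed and the retained weights rescaled to preserve the total attributed
#' mass; the unattributed fraction is max(0, 1 - sum(w)). A deterministic
#' Lawson-Hanson solve replaces iterative per-signature refitting: the
#' objective is the same and the solution reproducible.
#'
#' @param spectrum 96-vector of counts (total > 0).
#' @param sigs 96 x K signature matrix.
#' @param prune_below Zero out weights below this value (default 0; 0.06
#'   mimics common refitting practice).
#' @return List: \code{weights} (named K-vector), \code{unattributed},
#'   \code{reconstruction_error} (L2 residual of the pruned fit).
#' @export
fit_signature_weights <- function(spectrum, sigs, prune_below = 0) {
  if (length(spectrum) != nrow(sigs)) stop("spectrum/signature dimension mismatch")
  total <- sum(spectrum)
  if (total <= 0) stop("empty spectrum")
  p <- spectrum / total
  fit <- pracma::lsqnonneg(as.matrix(sigs), as.numeric(p))
  w <- fit$x
  if (prune_below > 0 && any(w > 0)) {
    keep <- w >= prune_below
    attributed <- sum(w)
    w[!keep] <- 0
    if (sum(w) > 0) w <- w * attributed / sum(w)
  }
  w <- stats::setNames(pmin(w, 1), colnames(sigs))
  resid <- sqrt(sum((p - as.matrix(sigs) %*% w)^2))
  list(weights = w,
       unattributed = max(0, 1 - sum(w)),
       reconstruction_error = resid)
}

#' Fraction of mutations with the UV dipyrimidine context
#'
#' UV photoproducts form at adjacent pyrimidines, yielding C>T at the 3'
#' base of a dipyrimidine and CC>TT tandem changes. The numerator counts
#' SNVs that are C>T (pyrimidine-strand convention) whose 5' neighbor is C
#' or T, plus CC>TT dinucleotide events (one count each); the denominator
#' is all SNV and dinucleotide events. Returns 0 with a warning on an empty
#' denominator.
#'
#' @param variants Data frame with \code{ref}, \code{alt},
#'   \code{trinucleotide_context}, \code{variant_class} in
#'   \{"SNV", "dinucleotide", ...\} (rows of other classes are ignored).
#' @return Fraction in [0, 1].
#' @export
uv_fraction <- function(variants) {
  cls <- variants$variant_class %||% rep("SNV", nrow(variants))
  snv <- variants[cls == "SNV", , drop = FALSE]
  dinuc <- variants[cls == "dinucleotide", , drop = FALSE]
  n_dinuc_uv <- sum(dinuc$ref == "CC" & dinuc$alt == "TT")
  denom <- nrow(snv) + nrow(dinuc)
  if (denom == 0) {
    warning("no SNV or dinucleotide events; UV fraction undefined, returning 0")
    return(0)
  }
  n_snv_uv <- 0
  if (nrow(snv)) {
    idx <- spectrum_bin(snv$ref, snv$alt, snv$trinucleotide_context)
    labs <- context_labels_96()[idx]
    sub <- sub(".*\\[(.*)\\].*", "\\1", labs)
    p5 <- substr(labs, 1, 1)
    n_snv_uv <- sum(sub == "C>T" & p5 %in% c("C", "T"))
  }
  (n_snv_uv + n_dinuc_uv) / denom
}

#' Aggregate spectra across samples
#'
#' Sums per-sample 96-class spectra, e.g. to build a subtype-level barplot
#' table.
#'
#' @param spectra List of 96-vectors (or a matrix with 96 rows).
#' @return Named 96-vector.
#' @export
aggregate_spectra <- function(spectra) {
  m <- if (is.matrix(spectra)) spectra else do.call(cbind, spectra)
  stopifnot(nrow(m) == 96)
  stats::setNames(rowSums(m), context_labels_96())
}
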