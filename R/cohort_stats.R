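#' Exact two-sided Fisher test for a 2x2 table
#'
#' Two-sided p-value under the minimum-likelihood convention: with the
#' table's margins fixed, the hypergeometric probabilities of all tables
#' whose probability is at most that of the observed table (within a 1e-12
#' relative slack for floating-point ties) are summed. An all-zero table has
#' p = 1.
#'
#' @param a,b,c,d Non-negative cell counts, rows = feature A altered/not,
#'   columns = feature B altered/not.
#' @return P-value in [0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
  n <- a + b + c + d
  if (n == 0) return(1)
  m1 <- a + b          # white balls (row 1 margin)
  k <- a + c           # draws (column 1 margin)
  support <- max(0, k - (n - m1)):min(k, m1)
  probs <- stats::dhyper(support, m1, n - m1, k)
  p_obs <- stats::dhyper(a, m1, n - m1, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: q_i is the minimum over j with
#' p_(j) >= p_(i) of m p_(j) / j, capped at 1, returned in input order.
#' Delegates to \code{stats::p.adjust(method = "BH")}, which implements
#' exactly this formula.
#'
#' @param pvalues Vector of p-values in [0, 1].
#' @return Vector of q-values, elementwise >= the p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Match variants against a hotspot catalog
#'
#' A match requires identical gene and protein change. Primary matches need
#' catalog q < \code{q_primary} (default 0.01). With
#' \code{relax_secondary}, every hotspot in a gene that already has a
#' primary match among the variants is also reported (with its own q), so
#' weaker recurrent sites in an established gene are not discarded.
#'
#' @param variants Data frame with \code{gene}, \code{protein_change}.
#' @param hotspots Catalog data frame: \code{gene}, \code{protein_change},
#'   \code{q_value}.
#' @param q_primary Primary q-value threshold.
#' @param relax_secondary Report secondary hotspots in primary-match genes.
#' @return Data frame of matches: gene, protein_change, q_value,
#'   match_type ("primary" or "secondary"), plus the matched variant rows'
#'   sample_id when present.
#' @export
annotate_hotspots <- function(variants, hotspots, q_primary = 0.01,
                              relax_secondary = FALSE) {
  key <- function(d) paste(d$gene, d$protein_change)
  hit <- match(key(variants), key(hotspots))
  matched <- !is.na(hit)
  q <- hotspots$q_value[hit[matched]]
  out <- data.frame(
    variants[matched, intersect(c("sample_id", "gene", "protein_change"),
                                names(variants)), drop = FALSE],
    q_value = q, stringsAsFactors = FALSE)
  out$match_type <- ifelse(out$q_value < q_primary, "primary", "secondary")
  primary_genes <- unique(out$gene[out$match_type == "primary"])
  if (!relax_secondary) {
    out <- out[out$match_type == "primary", , drop = FALSE]
  } else {
    out <- out[out$match_type == "primary" | out$gene %in% primary_genes, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Build a binary alteration matrix
#'
#' Features x samples 0/1 matrix from long-format alterations, with optional
#' pathway rows (the OR of their member gene rows) and subtype indicator
#' rows, so gene-gene, pathway-gene and subtype-gene overlaps all share one
#' test.
#'
#' @param alterations Data frame with \code{sample_id}, \code{feature}.
#' @param samples Character vector fixing the sample universe (columns).
#' @param pathways Named list mapping pathway label -> member gene labels.
#' @param subtypes Optional named character vector (sample_id -> subtype);
#'   each subtype becomes an indicator feature \code{subtype:<label>}.
#' @return Binary matrix with a \code{"pathway_members"} attribute (the
#'   pathway list restricted to members present) for downstream exclusion of
#'   pathway-vs-member tests.
#' @export
alteration_matrix <- function(alterations, samples, pathways = NULL,
                              subtypes = NULL) {
  feats <- sort(unique(alterations$feature))
  m <- matrix(0L, length(feats), length(samples),
              dimnames = list(feats, samples))
  ok <- alterations$sample_id %in% samples
  m[cbind(match(alterations$feature[ok], feats),
          match(alterations$sample_id[ok], samples))] <- 1L
  members <- list()
  if (!is.null(pathways)) {
    for (pw in names(pathways)) {
      genes <- intersect(pathways[[pw]], feats)
      if (!length(genes)) next
      row <- as.integer(colSums(m[genes, , drop = FALSE]) > 0)
      m <- rbind(m, matrix(row, 1, dimnames = list(paste0("pathway:", pw), NULL)))
      members[[paste0("pathway:", pw)]] <- genes
    }
  }
  if (!is.null(subtypes)) {
    for (st in sort(unique(subtypes))) {
      row <- as.integer(subtypes[samples] == st)
      row[is.na(row)] <- 0L
      m <- rbind(m, matrix(row, 1,
                           dimnames = list(paste0("subtype:", st), NULL)))
    }
  }
  attr(m, "pathway_members") <- members
  m
}

#' Pairwise mutational-overlap analysis
#'
#' Tests every unordered pair of features altered in at least
#' \code{min_mutant} samples (default 16, the prevalence floor below which
#' no pair could reach significance at the cohort's size after multiple-test
#' correction) for co-occurrence or mutual exclusivity with the exact
#' Fisher test, then applies Benjamini-Hochberg correction across all
#' performed tests. Pathway-vs-member-gene pairs are excluded (their overlap
#' is structural). Output rows are ordered by q, then p, then feature
#' labels.
#'
#' @param matrix Binary features x samples matrix, e.g. from
#'   \code{\link{alteration_matrix}} (its \code{pathway_members} attribute,
#'   if any, supplies the exclusions).
#' @param min_mutant Minimum altered-sample count per feature.
#' @param pathway_members Optional named list overriding the attribute.
#' @return Data frame: feature_a, feature_b, n11, n10, n01, n00, p, q.
#' @export
overlap_analysis <- function(matrix, min_mutant = 16, pathway_members = NULL) {
  pathway_members <- pathway_members %||% attr(matrix, "pathway_members") %||% list()
  keep <- rowSums(matrix) >= min_mutant
  feats <- sort(rownames(matrix)[keep])
  if (length(feats) < 2) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      n11 = integer(0), n10 = integer(0), n01 = integer(0),
                      n00 = integer(0), p = numeric(0), q = numeric(0)))
  }
  pairs <- utils::combn(feats, 2)
  excluded <- apply(pairs, 2, function(fp) {
    any(vapply(names(pathway_members), function(pw) {
      pw %in% fp && any(setdiff(fp, pw) %in% pathway_members[[pw]])
    }, logical(1)))
  })
  pairs <- pairs[, !excluded, drop = FALSE]
  if (ncol(pairs) == 0) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      n11 = integer(0), n10 = integer(0), n01 = integer(0),
                      n00 = integer(0), p = numeric(0), q = numeric(0)))
  }
  res <- apply(pairs, 2, function(fp) {
    x <- matrix[fp[1], ]; y <- matrix[fp[2], ]
    n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
    n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
    c(n11, n10, n01, n00, fisher_exact_2x2(n11, n10, n01, n00))
  })
  out <- data.frame(feature_a = pairs[1, ], feature_b = pairs[2, ],
                    n11 = res[1, ], n10 = res[2, ], n01 = res[3, ],
                    n00 = res[4, ], p = res[5, ], stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p, out$feature_a, out$feature_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
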