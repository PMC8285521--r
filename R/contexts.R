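#' The 96 trinucleotide substitution classes
#'
#' Canonical ordering of the strand-collapsed single-base substitution
#' classes: six substitutions on the pyrimidine strand (C>A, C>G, C>T,
#' T>A, T>C, T>G), each crossed with the four 5' and four 3' flanking
#' bases (A, C, G, T; 5' varies slowest). Labels look like \code{"A[C>T]G"}.
#'
#' @return Character vector of length 96.
#' @export
context_labels_96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(p5) paste0(p5, "[", s, "]", bases)))
  }))
}

.comp <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(.comp[ch])), collapse = "")
  }, character(1))
}

#' Map variants to their 96-class spectrum bin
#'
#' Takes plain 3-mer contexts (the mutated base in the middle) together with
#' ref/alt alleles and returns the index of each variant's bin in the
#' \code{\link{context_labels_96}} ordering. Variants reported on the purine
#' strand (ref A or G) are reverse-complemented to the pyrimidine-strand
#' convention first.
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @param context 3-mer genomic context; \code{substr(context, 2, 2)} must
#'   equal \code{ref}.
#' @return Integer vector of bin indices in 1..96.
#' @keywords internal
spectrum_bin <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  ok <- nchar(context) == 3 & substr(context, 2, 2) == ref &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  if (any(!ok)) {
    stop("malformed context string or ref/alt at rows: ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  purine <- ref %in% c("A", "G")
  ref[purine] <- unname(.comp[ref[purine]])
  alt[purine] <- unname(.comp[alt[purine]])
  context[purine] <- .revcomp(context[purine])
  lab <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
                substr(context, 3, 3))
  idx <- match(lab, context_labels_96())
  if (anyNA(idx)) stop("context does not map to a substitution class")
  idx
}

#' Synthetic reference signature matrix (K = 6)
#'
#' A deterministic 96 x 6 signature matrix for simulation and testing. The
#' columns are synthetic processes loosely shaped like well-known mutational
#' processes, not published signatures:
#' \describe{
#'   \item{UV}{C>T concentrated at the 3' base of dipyrimidines (5' C or T),
#'     the classic UV photoproduct context; flagged \code{uv_like}.}
#'   \item{AZA}{broad T>C with a minor T>A shoulder (thiopurine-like).}
#'   \item{APOBEC}{C>T and C>G restricted to the TpC context.}
#'   \item{OX}{C>A (oxidative-damage-like).}
#'   \item{CLOCK}{flat across all 96 classes (clock-like background).}
#'   \item{TA}{T>A concentrated at 5' C/T contexts.}
#' }
#' Columns sum to 1. The \code{"uv_like"} attribute is a logical vector
#' marking columns whose process produces CC>TT dinucleotides as well.
#'
#' @return Numeric 96 x 6 matrix with context-label rownames.
#' @export
synthetic_signature_matrix <- function() {
  labs <- context_labels_96()
  sub <- sub(".*\\[(.*)\\].*", "\\1", labs)
  p5 <- substr(labs, 1, 1)
  p3 <- substr(labs, 7, 7)

  S <- matrix(0, 96, 6, dimnames = list(labs, c("UV", "AZA", "APOBEC", "OX", "CLOCK", "TA")))

  uv <- sub == "C>T" & p5 %in% c("C", "T")
  S[uv, "UV"] <- ifelse(p5[uv] == "T", 2, 1) * ifelse(p3[uv] %in% c("C", "T"), 1.5, 1)

  S[sub == "T>C", "AZA"] <- 4
  S[sub == "T>A" & p5 == "G", "AZA"] <- 1

  apo <- p5 == "T" & sub %in% c("C>T", "C>G")
  S[apo, "APOBEC"] <- ifelse(p3[apo] %in% c("A", "T"), 3, 1)

  S[sub == "C>A", "OX"] <- ifelse(p5[sub == "C>A"] == "C", 2, 1)

  S[, "CLOCK"] <- 1

  ta <- sub == "T>A" & p5 %in% c("C", "T")
  S[ta, "TA"] <- 2

  S <- sweep(S, 2, colSums(S), "/")
  attr(S, "uv_like") <- c(UV = TRUE, AZA = FALSE, APOBEC = FALSE,
                          OX = FALSE, CLOCK = FALSE, TA = FALSE)
  S
}

#' Read / write a signature matrix TSV
#'
#' The dialect is one row per trinucleotide class: first column the context
#' label (\code{"A[C>T]G"}), remaining columns one signature each. Rows may
#' appear in any order; they are matched to the canonical ordering. Columns
#' must each sum to 1 (tolerance 1e-6).
#'
#' @param path File path.
#' @return For the reader, a 96 x K numeric matrix with rownames.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- context_labels_96()
  idx <- match(labs, df[[1]])
  if (anyNA(idx)) stop("signature matrix is missing context rows")
  S <- as.matrix(df[idx, -1, drop = FALSE])
  rownames(S) <- labs
  if (any(S < 0)) stop("signature probabilities must be nonnegative")
  if (any(abs(colSums(S) - 1) > 1e-6)) stop("signature columns must sum to 1")
  S
}

#' @rdname read_signature_matrix
#' @param S Signature matrix with context-label rownames.
#' @export
write_signature_matrix <- function(S, path) {
  df <- data.frame(context = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
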