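test_that("burden divides clonal mutations by the callable footprint in Mb", {
  expect_equal(mutation_burden(300, 30e6), 10)
  expect_equal(mutation_burden(0, 5e6), 0)
  expect_error(mutation_burden(10, 0), "footprint")
  # linear in count, invariant to how the count was assembled
  expect_equal(mutation_burden(2 * 150, 30e6), 2 * mutation_burden(150, 30e6))
})

test_that("spectrum bins SNVs on the pyrimidine strand, reverse-complementing purine records", {
  v <- make_variants("C", "T", "TCA")
  s <- build_spectrum(v)
  expect_equal(sum(s), 1)
  expect_equal(unname(s["T[C>T]A"]), 1L)
  # A[G>A]T on the purine strand is A[C>T]T after reverse complement
  v2 <- make_variants("G", "A", "AGT")
  s2 <- build_spectrum(v2)
  expect_equal(unname(s2["A[C>T]T"]), 1L)
  # empty input and non-SNV rows
  expect_equal(sum(build_spectrum(make_variants(character(0), character(0),
                                                character(0)))), 0)
  v3 <- rbind(v, make_variants("CC", "TT", "TCC", class = "dinucleotide"))
  expect_equal(sum(build_spectrum(v3)), 1)
  expect_error(build_spectrum(make_variants("C", "T", "TAA")), "malformed")
})

test_that("strand-flipped representations of the same mutations give identical spectra", {
  set.seed(30)
  labs <- context_labels_96()
  idx <- sample(96, 500, replace = TRUE)
  p5 <- substr(labs[idx], 1, 1); ref <- substr(labs[idx], 3, 3)
  alt <- substr(labs[idx], 5, 5); p3 <- substr(labs[idx], 7, 7)
  v_pyr <- make_variants(ref, alt, paste0(p5, ref, p3))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_pur <- make_variants(unname(comp[ref]), unname(comp[alt]),
                         paste0(comp[p3], comp[ref], comp[p5]))
  expect_equal(build_spectrum(v_pyr), build_spectrum(v_pur))
})

test_that("NNLS refit recovers pure signatures and mixtures", {
  S <- synthetic_signature_matrix()
  # spectrum exactly proportional to one column
  for (k in c(1, 3, 5)) {
    fit <- fit_signature_weights(S[, k] * 1000, S)
    expect_equal(unname(fit$weights[k]), 1, tolerance = 1e-6)
    expect_equal(sum(fit$weights[-k]), 0, tolerance = 1e-6)
    expect_lte(fit$reconstruction_error, 1e-8)
  }
  # exact 50/50 mixture of two signatures
  fit <- fit_signature_weights((0.5 * S[, "UV"] + 0.5 * S[, "OX"]) * 1e4, S)
  expect_equal(unname(fit$weights[c("UV", "OX")]), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(sum(fit$weights) + fit$unattributed, 1, tolerance = 1e-6)
})

test_that("multinomial sampling noise keeps mixture recovery within its tolerance", {
  S <- synthetic_signature_matrix()
  w_true <- c(UV = 0.5, AZA = 0, APOBEC = 0.3, OX = 0, CLOCK = 0.2, TA = 0)
  set.seed(41)
  l1 <- replicate(20, {
    counts <- as.numeric(stats::rmultinom(1, 10000, S %*% w_true))
    fit <- fit_signature_weights(counts, S)
    sum(abs(fit$weights - w_true))
  })
  expect_lte(mean(l1), 0.05)
})

test_that("a spectrum outside the signature cone is unattributed", {
  S <- synthetic_signature_matrix()
  # restrict to two signatures with disjoint substitution support and feed a
  # spectrum on neither support
  S2 <- S[, c("OX", "TA")]
  spec <- setNames(numeric(96), context_labels_96())
  spec["A[T>C]A"] <- 500
  fit <- fit_signature_weights(spec, S2)
  expect_equal(sum(fit$weights), 0, tolerance = 1e-8)
  expect_equal(fit$unattributed, 1)
  expect_error(fit_signature_weights(numeric(96), S), "empty")
})

test_that("weight pruning zeroes small weights and preserves attributed mass", {
  S <- synthetic_signature_matrix()
  w_true <- c(UV = 0.95, AZA = 0, APOBEC = 0.05, OX = 0, CLOCK = 0, TA = 0)
  fit <- fit_signature_weights(as.numeric(S %*% w_true) * 1e4, S,
                               prune_below = 0.06)
  expect_equal(unname(fit$weights["APOBEC"]), 0)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
})

test_that("UV fraction counts dipyrimidine C>T and CC>TT events", {
  expect_equal(uv_fraction(make_variants("C", "T", "TCA")), 1)
  expect_equal(uv_fraction(make_variants("C", "T", "ACA")), 0)
  # the four-variant construction: 2 UV events of 4
  v <- rbind(make_variants("C", "T", "TCG"),
             make_variants("C", "T", "ACA"),
             make_variants("CC", "TT", "TCC", class = "dinucleotide"),
             make_variants("T", "A", "TTC"))
  expect_equal(uv_fraction(v), 0.5)
  expect_warning(f0 <- uv_fraction(make_variants(character(0), character(0),
                                                 character(0))), "undefined")
  expect_equal(f0, 0)
})

test_that("UV fraction approaches 1 under a pure UV-like process and stays in [0,1]", {
  S <- synthetic_signature_matrix()
  set.seed(55)
  counts <- as.numeric(stats::rmultinom(1, 2000, S[, "UV"]))
  labs <- context_labels_96()
  idx <- rep(seq_len(96), counts)
  v <- make_variants(substr(labs[idx], 3, 3), substr(labs[idx], 5, 5),
                     paste0(substr(labs[idx], 1, 1), substr(labs[idx], 3, 3),
                            substr(labs[idx], 7, 7)))
  f <- uv_fraction(v)
  # the UV-like column is entirely dipyrimidine C>T, so f = 1 exactly here;
  # allow 3 SE of multinomial noise for generality
  expect_gte(f, 1 - 3 * sqrt(0.05 * 0.95 / 2000))
  expect_lte(f, 1)
})

test_that("signature matrix round-trips through its TSV dialect", {
  S <- synthetic_signature_matrix()
  tf <- tempfile(fileext = ".tsv")
  write_signature_matrix(S, tf)
  S2 <- read_signature_matrix(tf)
  expect_equal(unclass(S2), unclass(S)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(S2), context_labels_96())
  # shipped fixture parses and is column-normalized
  S3 <- read_signature_matrix(system.file("extdata",
                                          "synthetic_signatures_6.tsv",
                                          package = "somaticQC"))
  expect_equal(unname(colSums(S3)), rep(1, 6), tolerance = 1e-6)
})
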