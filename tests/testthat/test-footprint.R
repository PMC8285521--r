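test_that("both-alleles sampling probability matches the closed form and enumeration", {
  expect_equal(prob_both_alleles_sampled(6), 0.96875)
  expect_equal(prob_both_alleles_sampled(1), 0)
  # enumerate the Binomial(10, 0.5) pmf and sum the interior terms
  pmf <- choose(10, 0:10) / 2^10
  expect_equal(prob_both_alleles_sampled(10), sum(pmf[2:10]))
  expect_error(prob_both_alleles_sampled(0), "n_reads")
})

test_that("both-alleles probability is strictly increasing and tends to 1", {
  # strict growth checked below the double-precision saturation point
  p <- prob_both_alleles_sampled(1:50)
  expect_true(all(diff(p) > 0))
  expect_equal(prob_both_alleles_sampled(60), 1, tolerance = 1e-15)
})

test_that("effective coverage is depth times cellularity", {
  expect_equal(effective_coverage(100, 0.08), 8)
  expect_equal(effective_coverage(37.5, 1), 37.5)
  expect_equal(effective_coverage(0, 0.5), 0)
  expect_error(effective_coverage(10, 0), "cellularity")
  expect_error(effective_coverage(10, 1.2), "cellularity")
})

test_that("heterozygous-detection probability matches binomial tail enumeration", {
  # sum the Binomial(8, 1/2) pmf over 4..8 by hand: (70+56+28+8+1)/256
  expect_equal(prob_detect_het(8, 4), 163 / 256)
  expect_gte(prob_detect_het(8, 4), 0.5)
  expect_equal(prob_detect_het(3, 4), 0)
  expect_equal(prob_detect_het(8, 0), 1)
})

test_that("detection probability is monotone in depth and in the read threshold", {
  depths <- seq(0, 60, by = 0.5)
  p <- prob_detect_het(depths, 4)
  expect_true(all(diff(p) >= 0))
  for (d in c(8, 15, 40)) {
    p_thr <- prob_detect_het(d, 0:10)
    expect_true(all(diff(p_thr) <= 0))
  }
})

test_that("non-integer effective depth rounds half-to-even", {
  expect_equal(prob_detect_het(8.5, 4), prob_detect_het(8, 4))
  expect_equal(prob_detect_het(9.5, 4), prob_detect_het(10, 4))
})

test_that("callable footprint matches brute-force base counting on a piecewise track", {
  territory <- 1000
  ref <- coverage_profile(
    data.frame(chrom = "chr1", start = c(0, 300, 700),
               end = c(300, 700, 1000), depth = c(10, 5, 30)),
    "s1", "reference", territory)
  tum <- coverage_profile(
    data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
               depth = c(40, 10)),
    "s1", "tumor", territory)
  rho <- 0.5
  oracle <- brute_force_footprint(ref, tum, rho, territory = territory)
  fp <- callable_footprint(ref, tum, rho)
  expect_equal(fp$reference_footprint_bp, oracle$ref_bp)
  expect_equal(fp$tumor_footprint_bp, oracle$tum_bp)
  expect_equal(fp$sample_footprint_bp, oracle$minimum)
  expect_equal(fp$fraction_callable, oracle$fraction)
  fi <- callable_footprint(ref, tum, rho, method = "intersection")
  expect_equal(fi$sample_footprint_bp, oracle$intersection)
})

test_that("uniform tracks give the trivial footprints", {
  mk <- function(depth, role) coverage_profile(
    data.frame(chrom = "chr1", start = 0, end = 1e6, depth = depth),
    "s", role, 1e6)
  fp <- callable_footprint(mk(30, "reference"), mk(100, "tumor"), 0.5)
  expect_equal(fp$fraction_callable, 1)
  fp0 <- callable_footprint(mk(30, "reference"), mk(100, "tumor"), 0.05)
  expect_equal(fp0$tumor_footprint_bp, 0)
  expect_equal(fp0$fraction_callable, 0)
})

test_that("scalar-minimum footprint dominates the per-base intersection on random tracks", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 20
    bounds <- sort(sample(0:1000, n + 1))
    ref <- coverage_profile(
      data.frame(chrom = "chr1", start = bounds[-(n + 1)], end = bounds[-1],
                 depth = rpois(n, 10)), "s", "reference", 1000)
    tum <- coverage_profile(
      data.frame(chrom = "chr1", start = bounds[-(n + 1)], end = bounds[-1],
                 depth = rpois(n, 30)), "s", "tumor", 1000)
    rho <- runif(1, 0.2, 1)
    fmin <- callable_footprint(ref, tum, rho)$sample_footprint_bp
    fint <- callable_footprint(ref, tum, rho,
                               method = "intersection")$sample_footprint_bp
    expect_gte(fmin, fint)
  }
})

test_that("callable fraction is invariant under re-partitioning of the depth track", {
  ref <- data.frame(chrom = "chr1", start = c(0, 400), end = c(400, 1000),
                    depth = c(10, 10))
  ref_split <- data.frame(chrom = "chr1", start = c(0, 100, 400, 800),
                          end = c(100, 400, 800, 1000), depth = 10)
  tum <- data.frame(chrom = "chr1", start = 0, end = 1000, depth = 50)
  f1 <- callable_footprint(coverage_profile(ref, "s", "reference", 1000),
                           coverage_profile(tum, "s", "tumor", 1000), 0.4)
  f2 <- callable_footprint(coverage_profile(ref_split, "s", "reference", 1000),
                           coverage_profile(tum, "s", "tumor", 1000), 0.4)
  expect_equal(f1$fraction_callable, f2$fraction_callable)
})

test_that("profile validation rejects overlapping intervals and mismatched territories", {
  bad <- data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150),
                    depth = 5)
  expect_error(coverage_profile(bad, "s", "tumor", 150), "overlap")
  ref <- coverage_profile(data.frame(chrom = "chr1", start = 0, end = 10,
                                     depth = 10), "s", "reference", 10)
  tum <- coverage_profile(data.frame(chrom = "chr1", start = 0, end = 10,
                                     depth = 10), "s", "tumor", 20)
  expect_error(callable_footprint(ref, tum, 0.5), "territor")
})
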