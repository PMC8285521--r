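---
title: "Cohort QC for somatic variant meta-analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort QC for somatic variant meta-analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticQC)
```

## The problem

Meta-analyses of tumor sequencing data pool samples from studies with very
different sequencing depths, tumor purities, and coverage uniformity. Three
quantities distort every downstream comparison if left uncorrected: the
neoplastic cell content (cellularity, $\rho$), the fraction of the target
territory at which a mutation could have been called at all (the callable
footprint), and the admixture of subclonal or field-clone mutations whose
detectability depends on depth. somaticQC implements the corrections: it
models detection power, infers $\rho$ per sample, filters variants on
clonality, normalizes mutation burden by the callable footprint, refits
mutational-signature weights, selects corroborated focal copy-number
events, and tests mutational overlap across a cohort. A synthetic-cohort
generator with known ground truth makes every stage testable without
access to controlled-access patient data.

## Detection-power model

All power statements reduce to binomial sampling of two alleles.

* In the *reference* tissue, a germline heterozygous site is recognized
  only if both alleles are seen. With $n$ reads,
  $P = 1 - 2 (1/2)^n$; at the default minimum of $n = 6$ this is
  $0.96875$. `prob_both_alleles_sampled()`.
* In the *tumor*, only reads from neoplastic cells carry the mutant
  allele, so depth is discounted to the **effective coverage**
  $d \cdot \rho$ (`effective_coverage()`; 100x at 8% purity gives 8x). A
  clonal heterozygous mutation then yields mutant reads
  $X \sim \mathrm{Binomial}(\mathrm{round}(d\rho), 1/2)$, and detection
  requires $X \ge 4$ supporting reads: at 8x effective coverage
  $P(X \ge 4) = 163/256 \approx 0.64$, above one half.
  `prob_detect_het()`. Non-integer effective depth is rounded half-to-even
  — the binomial needs an integer trial count and the convention must be
  deterministic; round-half-even avoids a systematic upward bias.

The **callable footprint** counts target bases passing both thresholds
(reference depth $\ge 6$, effective tumor depth $\ge 8$). The per-sample
footprint is the *scalar minimum* of the reference and tumor footprints,
not their per-base intersection: the minimum is the explicit, reproducible
aggregation rule this pipeline standardizes on, and it is an upper bound
on the intersection (a property the test suite checks on random tracks).
The per-base intersection is available via `method = "intersection"` for
users who want the stricter count. Effective coverage uses one
sample-level $\rho$ with no local copy-number adjustment — the footprint
is a QC summary, not a caller.

## Cellularity inference

Four estimators, all inverting a two-population read mixture in which a
fraction $\rho$ of cells is tumor and the rest is diploid heterozygous
normal tissue:

| method | model | estimator |
|---|---|---|
| deletion AI | tumor has 1 copy; reads from the lost allele are all normal | $f = \frac{1-\rho}{2-\rho} \Rightarrow \rho = \frac{1-2f}{1-f}$ |
| cnLOH AI | tumor has 2 copies of one allele; total stays 2 | $f = \frac{1-\rho}{2} \Rightarrow \rho = 1-2f$ |
| modal MAF | clonal het mutation has MAF $\rho/2$ | $\rho = 2 \times$ density peak |
| median MAF | as above, robust small-$n$ fallback | $\rho = 2 \times$ median (sex chromosomes of males: $1 \times$) |

$f$ is the pooled minor-allele read fraction: summing minor and total
counts across SNPs weights deeper SNPs more (inverse-variance-flavoured)
and is what "the ratio of reads mapping to the A and B alleles" most
naturally means. Because the minor allele is taken per SNP, $f \le 1/2$
by construction and both AI estimators land in $[0, 1]$ without ever going
negative; the clamp with a warning remains as a guard for callers feeding
pre-polarized counts.

Where several methods apply, a fixed priority is used: deletion AI >
cnLOH AI > modal MAF > median MAF. The AI methods rank first because they
do not assume somatic mutations are heterozygous in a diploid genome,
which the MAF-doubling methods do; a fixed order keeps reruns
reproducible where per-sample manual choices cannot. All applicable
estimates are retained in the output so disagreements are visible.

The modal method uses a Gaussian KDE with Silverman's bandwidth on
$(0, 0.6]$ ("plot a histogram and find the peak" needs a concrete,
smooth, deterministic realization); with fewer than three distinct MAFs
the exact modal value is used, and a 0.01-width histogram backs up a
degenerate bandwidth. It requires 50 mutations by default — below that
the histogram is too rough and the median method takes over. The male
combination rule (count-weighted mean of the doubled autosomal and raw
sex-chromosome medians) is our choice of combiner; the source rule says
only that sex-chromosome values enter without doubling.

## Clonality filter

`cancer_cell_fraction()` converts a MAF to the fraction of tumor cells
carrying the variant: $\mathrm{CCF} = \min(1, 2\,\mathrm{maf}/\rho)$ for
heterozygous-diploid loci and
$\min(1, \mathrm{maf}\,(2-\rho)/\rho)$ for hemizygous male sex-chromosome
loci. The model is deliberately copy-number-unaware; local CN adjustment
would require per-segment absolute copy number, which is out of scope.

`filter_somatic_variants()` keeps a variant iff total reads $\ge 14$,
mutant reads $\ge 4$, and CCF $\ge 0.40$. The CCF floor removes
subclones and unrelated keratinocyte field clones; 4 mutant reads is the
caller-quality floor tied to the 8x effective-depth power analysis. The
total-read floor of 14 is an artifact default (roughly reference 6 +
tumor-effective 8), configurable and documented as such — the upstream
description leaves "low overall coverage" unquantified. The VAF window
for germline het SNPs, 40–60%, is closed on both ends: boundary values
are kept, a convention fixed for bit-reproducibility. Indels pass through
the same read-count/CCF rules; no separate thresholds are defined.

## Burden and signatures

Burden is clonal mutation count divided by callable megabases — not by
nominal target size — which removes the depth/purity artifacts that
otherwise dominate cross-study comparisons.

Spectra live on the 96 strand-collapsed trinucleotide classes
(pyrimidine-strand convention; purine-strand records are
reverse-complemented). Signature refitting solves the nonnegative least
squares problem $\min_{w \ge 0} \lVert p - S w \rVert_2$ with the
normalized spectrum $p$ and signature matrix $S$ via Lawson–Hanson
(`pracma::lsqnonneg`). This replaces iterative per-signature refitting
with a deterministic solve of the same objective. `prune_below = 0.06`
mimics the common practice of zeroing trace weights (the default, 0,
prunes nothing); pruned mass is redistributed over the retained weights
so the attributed total is preserved. The unattributed fraction is
$\max(0, 1 - \sum w)$.

The UV fraction counts C>T at the 3' base of a dipyrimidine plus CC>TT
tandem events, over all SNV + dinucleotide events. Each CC>TT event
counts once in numerator and denominator — event weighting is otherwise
undefined. Whether indels belong in the denominator is unstated upstream;
SNV + dinucleotide is the declared convention here.

The shipped 96 x 6 signature matrix is **synthetic** (one UV-like column
concentrated on dipyrimidine C>T, plus thiopurine-, APOBEC-, oxidative-,
clock- and T>A-shaped columns). Published signature catalogs are
third-party data; any real catalog in the same TSV dialect can be
supplied instead.

## Focal copy-number events

Amplifications: log2 ratio strictly above 0.9 with at least 20 probes and
exact-binomial allelic imbalance (pooled het-SNP minor counts vs 1/2,
$p < 0.01$). Deep deletions: log2 strictly below $-1$ with at least 20
probes; imbalance corroboration is optional for deletions (a homozygous
deletion retains no het SNPs to test). Strict-vs-inclusive amplitude
bounds are not stated upstream; strict is declared and configurable.
Manual rescues (e.g. an extremely focal deletion with sparse probe
support) enter through an explicit allowlist, never automatically. Gene
annotation is 1-bp overlap under 0-based half-open semantics.

## Overlap statistics

Features (genes, pathway OR-rows, subtype indicators) altered in at least
16 tumors are tested pairwise with a two-sided Fisher exact test under
the minimum-likelihood convention (hypergeometric probabilities at most
the observed table's, within 1e-12 relative slack), then BH-corrected
across all performed tests. Pathway-vs-member pairs are excluded — their
overlap is structural. The floor of 16 is honored as a configurable
constant; its original derivation ("minimum that could reach
significance") is not reproducible from the text and is not re-derived.
Subtypes are encoded as indicator features so subtype-vs-gene tests reuse
the same machinery. Hotspot matching requires identical gene and protein
change with catalog $q < 0.01$; with `relax_secondary`, additional
hotspots in genes that already have a primary match are reported at their
own $q$.

## The synthetic cohort

`simulate_cohort()` generates what the pipeline needs to see, with truth
recorded:

* **Read mixture.** Expected mutant-allele fraction
  $\rho m_t / (\rho c_t + 2(1-\rho))$ with $m_t$ mutant copies of $c_t$
  tumor copies; germline B fractions use the same mixture with
  region-appropriate copy numbers (deletion $c_t=1, m_B=0$; cnLOH
  $c_t=2, m_B=0$; neutral $c_t=2, m_B=1$). Read counts are binomial at
  the per-site depth.
* **Depth.** Negative binomial per 1-kb bin, variance
  $\mu(1 + \phi\mu)$ with $\phi = 0.15$, mean modulated by a smooth
  sinusoidal GC-like covariate with a per-sample exposure coefficient —
  reproducing the high-mean/high-variability samples whose footprints
  collapse.
* **Contexts.** Drawn from $S w$ with per-sample Dirichlet weights $w$;
  half the records are emitted on the purine strand to exercise
  reverse-complementation. CC>TT dinucleotides appear in proportion to
  the UV-like mixture weight, so non-UV mixtures generate none.
* **Subclones.** A configurable fraction of mutations (default 20%) at
  CCF ~ Uniform(0.05, 0.35), giving the 40% clonality filter genuine
  positives and negatives below its threshold.
* **Sex.** Bernoulli(1/2); male chrX variants are hemizygous with
  expected MAF $\rho/(2-\rho)$, exercising the no-doubling rule.
* **Copy-number events.** An arm-level hemizygous deletion (85% of
  samples), arm-level cnLOH (60%), a focal 6-copy amplification (35%)
  and a focal homozygous deletion (30%), each spanning enough probes and
  SNPs to be selectable at realistic purity; SEG log2 ratios follow
  $\log_2(\rho c_t/2 + (1-\rho))$ plus N(0, 0.05) noise.

Default study conditions: cellularity 12–99% (the analyzed cohort's
observed range), five subtype strata with lognormal per-Mb burdens
(sporadic median 30/Mb, azathioprine-exposed 60/Mb, other
immunosuppressed 15/Mb, RDEB 5/Mb APOBEC-shaped with 70% CASP8
enrichment, XP-like 80/Mb) spanning the orders of magnitude seen across
such cohorts. Mean depth defaults to 30–300x: typical exome practice;
sub-15x samples — which real cohorts contain and exclude — are exercised
explicitly by the QC tests rather than by the defaults. No distributional
forms for burden or cellularity are claimed by the source material; all
are artifact choices made once, here.

What the generator does **not** emulate: alignment artifacts, mapping
bias, FFPE damage, germline contamination of the tumor, subclonal
copy-number change, mutations inside CN-altered regions (point mutations
are placed in copy-neutral territory, matching the CN-unaware CCF model),
and realistic indels. Passing tests therefore demonstrate correctness of
the statistical machinery under its own model, not robustness to every
real-data failure mode.

## Pipeline behaviour and degenerate inputs

`run_pipeline()` executes cellularity, then footprint, filter, burden,
spectrum/refit and UV fraction per sample, then cohort-level CNA
selection, the alteration matrix and overlap tests. A sample whose stages
fail — no applicable cellularity method, zero callable footprint — is
quarantined with its reason; other samples are bit-unaffected (tested by
deleting a sample and comparing). `exclusion_screen()` flags samples with
fewer than 20 kept mutations *and* a modal MAF below 0.1 (poor sampling
of the neoplastic cells: both must hold, since a genuinely quiet genome
with clean MAFs is fine), or mean reference coverage below 5x. The
mutation-count and MAF floors are artifact defaults; the 5x reference
rule mirrors its source. Two further real-world exclusions —
tumor/reference pair mismatch and tumor-in-normal contamination — need
germline-concordance machinery that is out of scope; this is a documented
gap.

## Problem sizes and determinism

The test suite and acceptance script run the cohort end-to-end at 20–40
samples over a 5 Mb bait territory with ~1 kb coverage bins — sizes
chosen so a full run takes seconds while every estimator still has the
support its tolerances assume (1000 SNPs per CN region, hundreds of
mutations per sample). All randomness flows from a single integer seed;
identical configuration and seed give byte-identical cohort files, which
the suite verifies by hashing.

## Known limitations

* CCF and burden are copy-number-unaware; heavily aneuploid genomes will
  bias both.
* The AI cellularity estimators assume fully clonal CN events; subclonal
  deletions bias $\rho$ downward.
* The modal-MAF peak is only as good as the KDE at the chosen bandwidth;
  heavily skewed MAF distributions at low purity push the peak, which is
  why AI methods rank first.
* The Fisher floor of 16 mutant tumors is calibrated to an ~88-sample
  cohort; smaller cohorts should lower it consciously (the analysis
  scripts do).
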