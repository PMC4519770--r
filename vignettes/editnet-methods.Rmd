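---
title: "Methods: from editing variants to causal gene classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from editing variants to causal gene classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editnet)
```

`editnet` implements an analysis chain for serotonin-2C-receptor (5-HT2CR)
mRNA editing and its regulation by ADAR2 (*Adarb1*): quantification of
combinatorial editing variants from amplicon reads, a restriction-assay
estimator for Kv1.1 editing, differential expression, editing/*Adarb1*
trait signatures, co-expression modules, and a per-gene three-node Bayesian
network classifier. This vignette records the models, the parameters that
matter, and the design decisions taken where the methodology was open.

## The editing region and its combinatorics

Five adenosines (A, B, E, C, D in transcript order) sit within a 15-nt
window of the 5-HT2CR transcript. A and B share the residue-156 codon
(positions 1 and 3), E and C share the residue-158 codon (positions 1 and
2), and D sits at position 1 of the residue-160 codon. With inosine read as
guanosine, the 32 subsets of edited sites collapse onto 24 amino-acid
triplets; the codon layout is the unique one consistent with the unedited
INI isoform, VNI arising from the AB variant, and VSV arising from both ACD
and ABCD. `htr2c_region()` carries this layout on a synthetic 63-nt
amplicon: the 15-nt core (ATA-CGT-AAT-CCT-ATT, Ile-Arg-Asn-Pro-Ile) is the
genuine codon structure; the 24-nt flanks are invented anchor sequence, not
genomic, and are documented as synthetic.

```{r}
length(enumerate_variants())
length(unique(enumerate_isoforms()$isoform))
```

## Variant calling

No published assignment rule exists for this assay, so the caller uses a
deterministic, conservative procedure: a read is anchored by exact match of
the two 8-nt flanks immediately outside the outer sites (forward strand
first, then reverse complement); at each site an A is unedited and a G
edited; any other base at a site rejects the read, as do more than 2
mismatches at non-site positions inside the aligned window, or failure to
anchor. Rejection reasons are tallied per sample. The 8-nt exact anchors
make the caller strict: at a 1% per-base error rate roughly 15% of reads
fail to anchor. That cost is deliberate — anchoring errors cannot silently
shift site coordinates — and rejection is unbiased with respect to variant
identity, so frequencies are unaffected. Frequencies are counts over
assigned reads; site efficiency is the summed frequency of all variants
containing the site.

PCA of the samples-by-32 frequency matrix is centered but not scaled (the
frequencies share a scale; scaling would inflate rare variants). Component
signs are fixed by making each component's largest-magnitude loading
positive. Group comparisons use the two-sided exact Mann–Whitney test with
Benjamini–Hochberg adjustment across the 32 variants (or 5 sites): with 8
animals per group the full C(16,8) null is enumerable, and the source assay
protocol names no test, so the exact nonparametric choice is the defensible
default.

## The Kv1.1 MfeI assay

The 390-nt *Kcna1* amplicon carries a constitutive MfeI site (CAATTG, cut
C^AATTG) whose cut falls 220 nt into the amplicon, and an editing-dependent
site 51 nt further: unedited molecules digest to 220 + 51 + 119 nt, edited
molecules (the site's first adenosine becomes G) to 220 + 170 nt. The
packaged amplicon is synthetic — an ACGT-repeat background with the two
sites placed to reproduce exactly this arithmetic. The editing fraction is
the molar ratio M170 / (M170 + M119). Diagnostic fragments are matched with
a ±2 nt tolerance because the assay's reported sizes vary by 1 nt
(170/171, 119/120); mass-unit profiles (Bioanalyzer ng) are converted to
molar by dividing by length when `units = "mass"` — whether the original
ratio was molar or mass-based is not recorded, so the units are an explicit
argument rather than an assumption. The 220-nt fragment co-migrates in both
forms and is never used.

## Expression analysis

Counts are filtered (rows with no reads dropped; for multi-transcript
genes, the transcript with the highest SD of normalized signal kept),
normalized with DESeq-style median-of-ratios size factors rescaled to
geometric mean 1, and transformed with `log2(count / sf + 1)`. The
transform is a deliberate, documented surrogate for a fitted
variance-stabilizing transformation: on negative-binomial data its SD–mean
slope is near zero (asserted by test), and the analysis contract downstream
— the fold-change gates of >1.2 / <0.8 and BH-adjusted p < 0.05 — does not
depend on the exact VST form. Per-gene testing uses Welch's t on the
transformed values rather than a negative-binomial test; this is a declared
substitution whose calibration (≈0 false DE calls on null simulations at
FDR 0.05) is part of the test suite. Fold change is computed on
size-factor-scaled linear counts, control group in the denominator. qPCR
targets are normalized to the geometric mean of three endogenous controls.

## Trait signatures and overlaps

Gene-wise Spearman correlation against a per-sample trait (ABCD frequency,
or log2 *Adarb1* qPCR), BH adjustment, and signed signatures at FDR ≤ 0.1.
P-values are exact (full permutation null) for n ≤ 9 without ties and
asymptotic otherwise; with ties, average ranks with the asymptotic
approximation. Overlap between signatures is tested on the shared
(case-normalized) symbol universe with the two-sided Fisher exact test —
summing all tables no more probable than the observed one — reporting the
conditional-MLE odds ratio and its exact 95% CI. These conventions are
stated because odds ratios from the sample (cross-product) formula and the
conditional MLE differ slightly; the package's tests pin the p-value to a
brute-force hypergeometric summation oracle.

## Co-expression modules

The network is unsigned: adjacency `|cor|^β`, with β the smallest candidate
whose binned log–log degree distribution fits a line with R² ≥ 0.8 (fallback:
best-fitting candidate). Topological overlap uses the standard unsigned
formula; `1 − TOM` feeds average-linkage clustering. Module extraction is a
deterministic stand-in for dynamic tree cut: a static cut at 0.99 of the
maximum merge height, with two filters sending genes to grey — branches
smaller than `min_module_size` (default 20 genes) and branches whose mean
within-branch TOM falls below `min_module_tom` (default 0.1). The second
filter is what makes "independent genes come out grey" true: a static cut
alone always yields branches, and the cohesion floor plays the role of
dynamic cut's cluster-strength criterion. Planted-block recovery (adjusted
Rand index > 0.9 on four planted blocks) is preserved, which is the
property the module stage exists to provide. Colors follow the WGCNA
size-ordered convention (turquoise, blue, brown, ...). Enrichment against
user-supplied gene sets is the one-sided hypergeometric upper tail with
Bonferroni correction over module × set pairs.

## The three-node Bayesian network classifier

For each gene, twelve DAGs over {treatment T, gene G, *Adarb1* A} are
admissible: T is parentless, T→G and T→A are each optional, and G–A is
absent, forward, or reverse (2 × 2 × 3 = 12). Each DAG is scored by a log
marginal likelihood that factorizes over nodes:

* T: Beta(1,1)–Bernoulli marginal of the group labels;
* each continuous node given its parents: a conjugate normal–inverse-
  Wishart family score, computed as the difference of subset marginals
  `log m(child ∪ parents) − log m(parents)`, stratified by treatment when T
  is a parent.

The prior is empirical-Bayes and subset-consistent: for a q-dimensional
subset, κ₀ = prior strength (default 1 pseudo-observation), ν₀ = q + 1 +
κ₀, Λ₀ = κ₀ · diag(empirical variances), mean centered on the data means.
Because all continuous scores are ratios of marginals of one consistent
joint family, Markov-equivalent DAGs tie *exactly* (asserted to 1e-8):
directionality between G and A is only ever inferred from
treatment-induced v-structure asymmetry, which is precisely the epistemic
claim the four-way classification can support. *Adarb1* qPCR values are
log2-transformed before scoring, matching the generator's log link and the
Gaussian node model. Near-constant nodes have their prior variance floored
(1e-10) with a warning. The published procedure named its software but not
its score or prior; this score is therefore the package's own transparent
construction, and recovery on planted data — not numerical parity with any
particular implementation — is the tested contract.

Classification ranks the 12 scores (ties broken by canonical DAG order):
**ambiguous** if the runner-up's relative score `exp(logscore₂ − logscore₁)`
exceeds 0.9 — interpreted on the likelihood scale, since a threshold of 0.9
on raw log scores would be scale-dependent — else **upstream** if the top
DAG contains G→A, **downstream** for A→G, otherwise **independent**.

### What "upstream" can and cannot mean

Two identifiability facts shaped the synthetic study design, and they apply
equally to real data:

1. A gene that both receives a direct treatment effect and connects to a
   treatment-affected *Adarb1* presents the fully connected DAG, whose two
   G–A orientations are Markov equivalent; such genes are *correctly*
   reported ambiguous (or, when partial mediation dominates, drift to
   downstream). Upstream calls are only identifiable for genes whose
   association with *Adarb1* is not fully shielded by the treatment — the
   collider pattern T→A←G with G marginally treatment-independent, or a
   clean chain T→G→A where the gene mediates essentially all of the
   treatment's effect on *Adarb1*.
2. If a hub is driven equally by K genes, each driver's partial correlation
   with the hub is bounded by 1/√K; upstream recovery therefore requires a
   handful of strong drivers, not a diffuse many-gene influence.

## The synthetic-data generators

The generators define the study conditions under which every claim is
tested; their defaults are fixed and chosen to be realistic for a severe
CNS injury model.

* **Amplicon reads**: multinomial draws over the 32 variants (default
  mixtures put ABD at 36%, ABCD at 18%, AB at 14%, unedited at 3% for
  controls — the observed spinal-cord spectrum — with the injury group
  shifted along the ABCD/AB axis), full-length single-end reads, uniform
  substitution errors (default 0.1%), no indels (an amplicon assay;
  quality values are constant). Drawn variants are kept as a truth sidecar.
* **Expression study**: 2,000 genes × 16 samples (8 per group) by default;
  gamma-Poisson counts with dispersion 0.05; log2 baselines uniform on
  [2, 9]; per-gene biological SD 0.6 on the log2 scale — large enough that
  biological variance dominates counting noise, as in real tissue;
  library-size factors uniform on the configured range. Planted structure:
  treatment effects (default ±1.5 log2 on 120 genes — effects sized to be
  detectable at n = 8/group under SD 0.6); two 50-gene co-expression blocks
  (within-block correlation 0.7); 4 upstream driver genes with coefficient
  0.8 feeding the hub; 40 downstream genes driven by the hub with
  alternating coefficients ±0.8; hub treatment effect −1.8 log2 (≈2.4
  within-group SDs, matching the magnitude of the observed *Adarb1* qPCR
  group separation) plus N(0, 0.3) noise. The hub is exported twice — as
  the "Adarb1" count row and, through a log link with N(0, 0.2) noise, as
  per-sample qPCR metadata — mirroring the dual measurement design.
  The sign-balance of the downstream coefficients is not cosmetic: with
  all hub targets shifted one way, median-of-ratios normalization acquires
  a group-dependent composition bias that leaks a spurious treatment effect
  into every gene and degrades the network classification; balanced signs
  (as observed in the real signatures, which contain both positively and
  negatively correlated genes) remove it.
* **Digest mixtures**: molar mixtures of the edited and unedited digest
  profiles in proportion to the edited fraction, with optional mean-1
  lognormal molarity noise. The estimator composed with the generator is
  the identity in the noise-free case.

Each generator draws from its own stream derived from the root seed, so
adding a generator does not perturb the others, and fixed seeds reproduce
outputs byte-identically.

What the generators do *not* emulate: position-dependent sequencing error
profiles, PCR duplicates, read trimming or alignment artifacts, batch
effects, dispersion trends across expression, or electrophoresis peak
shapes. Passing recovery tests therefore demonstrates the correctness of
the estimators under the stated statistical structure, not robustness to
every artifact of real instruments.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally, 1-based in reports. Variant
labels concatenate site letters in A, B, C, D, E display order ("NONE" for
the empty set). Probability vectors must sum to 1 within 1e-9. Frequencies
sum to 1 within 1e-9 per sample. Zero assignable reads in a sample is an
explicit error, as are constant traits, empty filtered matrices, groups
with fewer than 2 samples (DE) or 3 per stratum (network scoring), and
missing *Adarb1* metadata. Ties in module size are broken by first gene
index; ties at the top of the DAG ranking trigger the ambiguity rule by
construction.

## Problem sizes

The default pipeline run uses 2,000 genes × 16 samples with 5,000 amplicon
reads per sample and completes in well under ten minutes on a single CPU.
Recovery experiments in the test suite use 100–150 samples per group for
the network classifier (the regime where per-gene direction is decidable),
200,000 reads for closed-loop variant-frequency recovery, and 100 genes per
block-recovery run. These sizes were chosen so each statistical claim is
tested in a regime where it should hold with margin.

## Known limitations

* The variant caller requires exact flank anchors; heavily degraded reads
  are rejected rather than rescued. Quality scores are ignored.
* The VST surrogate and Welch test will not numerically reproduce the
  output of a negative-binomial pipeline on the same data; thresholds and
  calibration, not numeric parity, are the contract.
* The static-cut module detector does not implement dynamic tree cut's
  branch-shape heuristics; very unequal or nested modules may merge.
* The three-node classifier inherits the identifiability limits described
  above; "ambiguous" is an informative outcome, not a failure mode.
* Cross-species overlap works at the level of case-normalized gene
  symbols; no ortholog mapping is attempted.
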