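---
title: "Fragment-based RRBS differential methylation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based RRBS differential methylation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfscreen)
```

# The unit of analysis

Reduced representation bisulfite sequencing begins with an MspI digest
(CCGG, cut C^CGG), so read coverage is organised around restriction
fragments. `dmfscreen` therefore tests *fragments*, not single CpGs and not
tiled windows. The in-silico digest places a cut at offset + 1 of every
forward-strand CCGG occurrence (the site is palindromic, so one strand
suffices); fragments are the intervals between consecutive cuts, and
chromosome-terminal pieces — which have only one cut end and are never
ligated into a library — are excluded.

Two conventions are fixed once and used everywhere:

* **Coordinates** are 0-based, half-open internally. Readers and writers
  convert at the boundary (Bismark coverage files are 1-based).
* **Cut placement**: the cut coordinate is the CCGG offset + 1, which keeps
  the CpG of each recognition site attached to the downstream fragment. Any
  consistent convention would do; this one is deterministic and makes the
  digestion idempotent and exactly invertible (fragments plus terminal
  pieces reconstruct the chromosome, a property the test suite asserts).

The analysis window is **40–220 bp, inclusive at both ends**. CpGs are
indexed by the forward-strand C offset; counts reported on the
reverse-strand G are collapsed onto the C position at read time, the usual
RRBS practice, which doubles effective coverage per CpG. `N` breaks both
CCGG and CG matches; no ambiguity expansion is attempted.

# Fragment methylation and the evidence gate

A fragment is *analysable* in a sample when at least `min_cpgs = 2` of its
CpGs have coverage of at least `cov_min = 10` reads. Once that gate passes,
the fragment's level is the **pooled read fraction** over *all* of its CpGs
with any coverage. The gate guarantees minimum evidence; pooling all reads
then uses every observation rather than discarding sub-threshold CpGs. The
alternative (mean of per-CpG fractions) weights a 1-read CpG as much as a
50-read CpG; the pooled fraction is the maximum-likelihood level under a
shared-level binomial model and is used consistently, including for the
difference Δ in DMF calling.

# Differential calling

For each pair the tested set is the fragments analysable in **both**
samples. Each fragment yields a 2×2 table, (methylated, unmethylated) ×
(sample A, sample B), of pooled counts. The two-sided Fisher exact p sums
the hypergeometric probabilities of all tables with the observed margins
whose probability is at most that of the observed table; a relative
tolerance factor of 1 + 1e-7 absorbs floating-point ties (mid-p is *not*
used). Bonferroni uses `m = |tested set|` **per pair comparison**, not
globally: each pair is an independent analysis with its own family. A
fragment is a DMF iff the adjusted p is below `alpha = 0.05` and
`|Δ| ≥ delta_min = 0.25`, both thresholds inclusive on the Δ side. The
0.25 threshold reflects the common view that methylation differences below
~25 % are rarely biologically actionable at fragment resolution; alpha is
the conventional 0.05.

Degenerate inputs are refused loudly: a zero margin (a sample with no reads
on the fragment) cannot reach the test because the analysability gate
removes it; calling `fisher_exact_two_sided()` directly with a zero margin
is an error rather than a silent p = 1.

# The driver screen

A candidate epigenetic driver is a fragment that is a DMF in **every**
pair with the **same direction** in all of them. Mixed-direction fragments
are excluded from both the hyper-in-all and hypo-in-all sets rather than
being assigned by majority — a frequency-based screen has no business
averaging over sign. Pairwise overlap percentages use the smaller set as
denominator by default (`|A∩B| / min(|A|,|B|)`), configurable to the union;
the smaller-set denominator answers "how much of the tighter list recurs",
which is the screening question.

Progression patterns classify fragments significant in both the
normal→primary and primary→metastatic step of one pair into the four
direction pairs (hyper-hyper, hyper-hypo, hypo-hyper, hypo-hypo).

Annotation uses any-overlap (≥ 1 bp) throughout, with gene-context
precedence promoter > exon > intron > intergenic. The promoter window is
`c(-2000, 500)` around the TSS, strand-aware and half-open — wide enough to
include promoter DMFs sitting ~1 kb upstream of a TSS. Distance to TSS is
measured from the fragment midpoint, signed, negative upstream. CpG-island
shores are the 2 kb flanks (the conventional width); a fragment overlapping
an island is `island_core`, within the shore width `shore`, else
`open_sea`. Regulatory-feature tracks are user-supplied BED intervals, and
the overlap heat-map values are plain fractions of the DMF set touching
each track. Gene association caps intergenic assignment at 50 kb from the
TSS (configurable); distal DMFs are reported unassigned rather than being
forced onto a gene.

# Validation statistics

* **Platform concordance**: Pearson r over matched per-CpG fractions, and
  again after averaging per amplicon. Aggregation helps because platform
  noise is (approximately) independent per CpG while the underlying
  methylation is regional.
* **Bland–Altman**: bias = mean(platform2 − platform1), SD with the n−1
  denominator, limits of agreement at ±1.96 SD (the conventional
  multiplier).
* **Mann–Whitney U**: exact p (`2·min(P(U≤u), P(U≥u))`, capped at 1) when
  the combined n ≤ 20 and there are no ties; otherwise normal approximation
  with tie correction and continuity correction. The switch point is a
  cost/precision compromise; the result records which path was used.
* **Shapiro–Wilk gate**: only annotates whether a t test would have been
  admissible; the rank test is always computed, because cohort beta values
  are rarely normal.
* **Spearman**: exact permutation p for n ≤ 9 without ties (full
  enumeration of the n! rank pairings), t approximation otherwise.
* **Cohort validation**: array probes match a DMF when they overlap it or
  fall within 500 bp of either edge; a probe matching several DMFs resolves
  to the nearest midpoint. Each matched probe is tested primary vs
  metastatic; direction concordance compares the sign of the median
  difference with the discovery consensus. Raw p-values are reported (a
  Bonferroni column is emitted for transparency only), matching the
  validation-not-discovery role of the cohort step.

# What the simulator emulates — and what it does not

The synthetic-data module exists so that every downstream stage has ground
truth. Its defaults *are* the study conditions of the package's tests:

* **Study structure**: one normal sample, three primary/metastatic pairs,
  replicate libraries for the normal and the first primary — the shape of a
  paired cell-line panel.
* **Genome**: chromosomes assembled between explicitly placed CCGG sites;
  mean cut-to-cut distance 1/`ccgg_rate` (default 150 bp) with
  gamma-distributed spread, so roughly half the fragments land in the
  40–220 bp window, as in real RRBS; short CpG-dense fragment runs act as
  CpG islands with recorded coordinates.
* **Background methylation**: a Beta mixture concentrated near 0.05 and
  0.95 — the bimodal hypo/hyper pattern of somatic methylomes. Planted DMFs
  shift levels by ±Δ (shared: all pairs; private: one pair), clipped to
  [0, 1]; planted base levels are drawn so clipping is avoided whenever the
  requested path fits inside (0.02, 0.98), which keeps the planted Δ exact
  and recoverable.
* **Counts**: coverage is negative-binomial with mean 30 and dispersion
  0.1 (0 gives Poisson); methylated reads are beta-binomial around the true
  level with the same dispersion as intra-class correlation (0 gives
  binomial). The count model is not taken from any particular dataset; it
  exposes the Fisher test to realistic overdispersion with a dial back to
  the idealised binomial. CpGs drawing zero coverage are omitted, as in
  real coverage files.
* **Cohort**: 99 primary and 359 metastatic samples with one probe per
  selected DMF placed within ±500 bp, betas drawn around the group-level
  truth (noise SD 0.05), plus decoy probes > 10 kb from any DMF.
* **Expression**: a linear monotone function of the linked probe's beta
  times a planted sign, plus Gaussian noise — enough for Spearman sign
  recovery, no more.

Not emulated: read-level artefacts (bisulfite conversion failure, mapping
bias, strand asymmetries), SNP interference, copy-number effects,
cell-type heterogeneity, and spatial correlation of methylation beyond the
fragment. Passing tests therefore demonstrate that the *statistics and
bookkeeping* are correct under a controlled generative model, not that the
pipeline is robust to every artefact of real libraries.

# Numerical and testing choices

Determinism is end-to-end: a master seed fixes the genome, truth, counts,
cohort and expression, and pipeline reruns with one seed are byte-identical
(asserted in the tests). Stage seeds are small offsets of the master seed.

Problem sizes in the test suite were chosen to make the checks sharp but
cheap: the exhaustive Fisher cross-check enumerates all ~630,000 2×2 tables
with total ≤ 60 against direct binomial-coefficient enumeration; the
Mann–Whitney exact path is compared with full label-permutation enumeration
for 500 random tie-free inputs with combined n ≤ 10; digestion is compared
with a naive string-scan reference on 100 random 5 kb sequences; the null
family-wise error study uses 3 pairs × 2000 fragments × 20 seeds with
binomial counts at 30× (the FWER check deliberately uses the idealised
count model the Fisher test assumes — overdispersion inflates its error
rate, which is a property of the test, not a bug in the code); planted
recovery uses the default overdispersed model (10 seeds); the sub-threshold
boundary check plants Δ = 0.10 at 50×, binomial, where the estimator's
sampling noise cannot plausibly cross the 0.25 threshold; progression
patterns are checked at 500× where recovery must be exact.

# Known limitations

* Bonferroni is the only multiple-testing correction offered, by design;
  FDR-based callers answer a different question than the strict per-pair
  screen implemented here.
* The Fisher test treats reads as independent Bernoulli draws; with strong
  overdispersion its p-values are anti-conservative. The simulator's
  dispersion dial exists precisely to quantify this on synthetic data.
* Non-CpG methylation is passed through but never analysed.
* Hierarchical clustering uses 1 − Pearson distance with average linkage
  over CpGs covered in all samples; other choices are defensible, and the
  tree should be read qualitatively.
* With three pairs, "shared in all" is a strong but small-n criterion; the
  cohort validation stage is the guard against over-interpreting it.
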