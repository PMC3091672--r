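---
title: "SuperSAGE analysis with sagexpr: models, decision rules and design choices"
author: "sagexpr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SuperSAGE analysis with sagexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagexpr)
```

# The experiment this package models

SuperSAGE quantifies a transcriptome by counting 26-bp tags cut at the
3'-most NlaIII site (CATG) of each mRNA.  Tags are sequenced pairwise as
*ditags* flanked by library-identifying linkers, demultiplexed, split into
mono-tags and counted.  The package targets the common multi-library
challenge design: five gill libraries from a euryhaline pufferfish
transferred to control, low-calcium and high-calcium water, sampled at 2 h
and 12 h (roles `C2h`, `LowCa2h`, `C12h`, `HighCa12h`, `LowCa12h`).  Every
stage — extraction, differential-expression calling, annotation,
clustering, GO enrichment — is driven by data objects, so the same code
runs on real count tables or on the bundled synthetic generator.

# The synthetic-data generator

`simulationConfig()` fixes the study conditions; its defaults are chosen
once to emulate the library structure of such an experiment:

* **Library depths** default to five sequencing-scale totals
  (65,378 / 87,388 / 67,996 / 60,142 / 63,471 tags, a half-run of 454
  pyrosequencing split over five barcodes).
* **Abundance law.**  Transcript frequencies follow a discretized
  log-normal, normalized to a per-library frequency vector.  With 700,000
  transcripts and
  `sdlog = 2.7` the expected unitag share of a ~69,000-tag library is 38.7%
  and the expected singleton share of unitags is 0.68, matching the
  sequencing-scale regime in which roughly 70% of unitags are singletons.
  These two parameters were calibrated against those two expectations and
  then frozen.
* **Planted differential expression.**  A configurable fraction of
  transcripts (default 0.02%, roughly 140 tags) receives a multiplicative
  effect drawn from `deFoldRange`, assigned to one of the four
  decision-rule classes (`deClassMix`).  Class 1 alters both low-calcium
  libraries, class 2 exactly one time point, class 3 alters the two 12 h
  challenges in opposite directions, class 4 in the same direction.
  Planting is restricted to the base-frequency band
  [`deMinFreq`, `deMaxFreq`] (default 1e-4 to 1e-3, about 7-70 expected
  counts at these depths): below the floor an effect is unrecoverable
  sampling noise, above the cap it would displace a large share of the
  library's probability mass.  In each treatment library the planted
  transcripts keep their exact fold relative to the control frequency and
  the non-planted background absorbs the compositional shift, so planted
  folds are recoverable quantities while columns still sum to one; the
  generator refuses configurations whose planted mass exceeds 90% of a
  library.
* **Read corruption.**  The QC failure modes are duplicated ditags,
  truncated linkers, internal linker contamination and ambiguous bases.
  The corresponding rates are not quantities the underlying experiment
  reports, so the defaults (5% / 1% / 1% / 1%) are small plausible values;
  every read records its intended QC outcome so the demultiplexer can be
  verified read-by-read.
* **Ditag pairing.**  Tags are paired uniformly without replacement.
  Coincidentally identical pairings are re-paired (or, when a library is so
  skewed that this is impossible, dropped and accounted for in
  `emittedCounts`), so that a *duplicate ditag* is by construction a
  PCR/emulsion artifact injected via `duplicateDitagRate`.  This makes the
  deduplication filter exactly invertible: with all corruption rates zero,
  extraction reproduces the generating counts bit-for-bit, and with
  corruption, extraction reproduces the generator's `passCounts`.

What the generator does **not** model: 454 flowgrams and quality scores,
PCR amplification bias, indels, and tag-internal CATG sites (tags are drawn
without internal CATG so that the anchoring site of a transcript is
unambiguous).  Passing tests on these data therefore demonstrate the
correctness of the statistical machinery under multinomial sampling, not
robustness to platform-specific artifacts.

# Differential expression

## The two test families

For a tag with counts $c_\ell$ in libraries of totals $n_\ell$:

* the **pairwise Z-test** is the classical two-proportion normal test with
  pooled variance, two-sided (the sidedness is not dictated by the
  experiment; two-sided is the conservative choice);
* the **replicated G-test** treats the tag as a $2 \times L$ table (tag vs
  all other tags) and decomposes the likelihood-ratio statistic exactly as
  $G_{total} = G_{pooled} + G_{heterogeneity}$, where $G_{pooled}$ is
  computed after pooling libraries into the design's groups.  Following
  the classical replicated goodness-of-fit terminology, the *intrinsic*
  hypothesis is tested by the pooled component; the *homogeneity* rules
  concern the heterogeneity component.  No small-sample (Williams)
  correction is applied; zero tag counts are replaced by the
  zero-substitution constant 0.345 before expected frequencies are formed,
  the single zero-handling device used throughout the pipeline.

## Zero-substitution fold change

The expression ratio $R$ is the raw treatment/control count ratio at one
time point with 0.345 substituted for zeros — deliberately with no
library-size normalization, which reproduces the fold-change convention of
SAGE reports (e.g. $0 \to 38$ gives $38/0.345 = 110.1 \to 110$).
Reported folds are $\max(R, 1/R)$ rounded half away from zero.  The
constant is configurable; the ±0.03 standard error attached to its
estimation is metadata only.

## The four decision-rule classes

The exact decision-rule set of the original multi-library G-test software
is not publicly documented, so the rules here are this package's own
interpretation, chosen to satisfy every behaviour the class definitions
describe while keeping the *joint* false-call rate of the full classifier
low (about 0.7% of null tags at sequencing-scale depths, measured by
simulation).  The rules are deliberately conjunctive — each class requires
its G-test rules *and* individually confirming Z-tests:

* **class 1** (low-calcium effect independent of time): all rules of
  design 1 (control group vs low-calcium group) pass, and the pairwise
  control-vs-low Z-test is significant at *both* time points;
* **class 2** (time-dependent low-calcium effect): the intrinsic (pooled)
  components of design 1 and of design 2 (2 h pool vs 12 h pool) are both
  significant — two near-orthogonal contrasts — design 1 fails a
  homogeneity rule, design 2's heterogeneity is significant, and a
  per-time Z-test confirms;
* **class 3** (challenge-discordant 12 h response): both pairwise 12 h
  G-tests pass, the treatment-heterogeneity component of the pooled 12 h
  design is significant, and both 12 h Z-tests confirm;
* **class 4** (global 12 h response): the pooled 12 h design passes all
  rules (treatments concordant) and both pairwise G- and Z-tests confirm.
  Reading the confirming Z-tests conjunctively (rather than "either") is
  the one place where this rule set is stricter than the loosest reading
  of the class descriptions; the disjunctive reading admits 2–3% of null
  tags, which is incompatible with the stringency the multi-test design is
  meant to provide.

The 12 h classes additionally require the two control libraries to be
homogeneous (a non-significant C2h-vs-C12h G-test), which suppresses false
calls driven by a chance dip in the single 12 h control.  A tag is
*retained* when it has at least one class and its maximum zero-substituted
ratio is at least 2-fold.  No multiple-testing correction is applied across
tags — stringency comes from the conjunction of tests plus the fold filter;
FDR control appears only in GO enrichment.

# Annotation

Tag-to-DNA matching is exact substring search of the 26-nt query
(CATG + printed 22 nt) on both strands of three datasets (curated cDNAs,
predicted cDNAs, genome).  At the perfect-match stringency this is
equivalent to an alignment search accepting 26/26 identities, and it is
reproducible to the byte.  Reduced stringency (24/24) trims the two 3'
bases, where sequencing errors and polymorphisms concentrate.  Coordinates
are 1-based closed intervals, the container convention of this ecosystem;
human-readable reports need no conversion.

Protein assignment consumes a precomputed DNA-to-protein table (the
translated search itself is out of scope) under the preference order
curated cDNA > predicted cDNA > genomic 1000-bp upstream fragment, with
E < 1e-5 for identity and E < 1e-10 for GO retrieval; ties break by lowest
E-value then lexicographic protein id, making the assignment a pure
function of the hit set.  Genome-dataset table rows are keyed as
`<chrom>:<tagStart>:<strand>`, the coordinates of the upstream fragment's
anchor.  Antisense calls flag orientation discordance between the
tag-to-DNA match and the DNA-to-protein orientation.  Tags matching more
than one genomic location are annotated but flagged ambiguous and should
be excluded from gene-level aggregation.

# Clustering

Profiles are normalized to percentages across the analysis libraries.  The
distance between a profile and a centroid is the Pearson chi-square
divergence of the profile against the centroid's shape — the natural
distance family for count-derived profiles — with Euclidean distance on
normalized profiles as a documented fallback.  The reference describing
the original chi-square clustering algorithm gives no formulas in the
source experiment's report, so the divergence form is isolated behind the
`distance` argument.  Fitting uses Lloyd iterations from kmeans++-style
seeded starts (random seeding rarely covers all well-separated groups and
systematically inflates $W_K$), best of `nRestarts` by within-cluster
dispersion, ties to the lowest cluster index.

The number of clusters is selected by the Gap statistic with the simple
uniform reference (per-dimension range of the data, renormalized to valid
profiles) and the one-standard-error rule.  Degenerate inputs (all
profiles identical) select $K = 1$.  Reference fits use fewer restarts
than data fits because the structureless reference surface is easy to
optimize.  At the sizes used in the tests (about 1,200 profiles over 4–5
libraries, $K \le 8$, $B = 20$ references) a selection run takes a few
seconds.

# GO enrichment

Enrichment of a tag list against the control-library background (both
control libraries for the low-calcium analysis; the 12 h control only for
the 12 h analysis) uses the pooled one-tailed two-proportion z-test per GO
term, Benjamini–Hochberg adjustment across all terms tested within the
run, and an adjusted-p threshold of 0.01.  The counting unit is the tag,
not the gene; terms are tested as annotated, with no ontology-graph
ancestor propagation (annotation here is direct term retrieval from
protein hits).  An exact hypergeometric variant is available behind
`method = "hypergeometric"` for sensitivity analysis; the z form agrees
with the exact binomial tail to within 10% at moderate tail mass and
diverges in extreme tails, where both are far beyond any decision
threshold.

# Numerical and testing notes

* Percentages in report tables round half away from zero to one decimal;
  folds round half away from zero to integers (base R's round-half-even
  would disagree with several printed values).
* Abundance classes are 1, [2,4], [5,9], [10,100], (100, ∞) — a partition,
  with "10 to 100" inclusive.
* The G decomposition is exactly additive in exact arithmetic; tests
  assert additivity to 1e-9.
* The test-suite problem sizes (tens of thousands of tags for calibration,
  20,000 transcripts for parameter recovery, 1,200 profiles for
  clustering, 20 seeds for stochastic claims) were chosen as the smallest
  sizes at which the targeted statistical properties are sharp.
* Determinism: all generator functions and fits take explicit seeds and
  restore the caller's RNG state; reruns are identical.

# Known limitations

* The decision-rule set is an interpretation (see above); it is isolated
  behind the `GTestResult`-style flags of `gTest()` so alternative rule
  sets can be composed from the same components.
* The classifier requires exactly the five-role design; other layouts need
  their own rule composition from `gTest()`/`zTest()`.
* Cross-orientation ditag deduplication (a ditag vs its reverse
  complement) is not performed; deduplication is same-orientation exact
  identity, the conservative testable reading.
* The synthetic genome embeds each cDNA contiguously (no introns), so
  genomic hits are easier than in real genomes; mapping code paths are
  nevertheless identical.
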