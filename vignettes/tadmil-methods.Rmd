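---
title: "Classifying pathogenic non-coding structural variants from domain disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pathogenic non-coding structural variants from domain disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadmil)
```

## The problem

Somatic structural variants (SVs) that never touch an exon can still
drive tumours: by breaking the boundary of a topologically associating
domain (TAD) or of an intra-TAD CTCF loop, an SV can place a gene into
contact with regulatory elements it was previously insulated from —
the enhancer-hijacking mechanism — or remove elements it depended on.
`tadmil` models this in two stages: a geometric stage that turns each
boundary-disrupting SV into a set of SV–gene pairs annotated with the
regulatory elements each gene gains or loses, and a learning stage that
classifies those pairs as pathogenic with a multiple-instance learner
trained on expression-derived labels.

## Derivative-domain rewiring

All coordinates are 0-based half-open (BED convention; VCF input is
converted on read), and "overlap" always means at least one shared
basepair. Only SVs whose breakpoints both fall inside a domain and
which cross at least one boundary are considered; an SV confined to one
domain reshuffles nothing.

Rather than hand-writing a gain/loss rule per SV type, the package
builds, for every SV, the derivative chromosome around the breakpoints
as an ordered list of source segments:

* deletion `[s, e)`: `[w0, s) + [e, w1)`;
* tandem duplication: `[w0, e) + [s, e) + [e, w1)` (the copy sits
  immediately 3' of the original span — the insertion position is not
  observable from short-read calls, and tandem is the dominant somatic
  class);
* inversion: `[w0, s) + reverse([s, e)) + [e, w1)`, i.e. the point map
  `p -> (s + e - 1) - p` on the inverted span;
* translocation: the retained side of breakpoint 1's domain joined to
  the retained side of breakpoint 2's domain, where orientation `+`
  retains the segment ending at the breakpoint and `-` the segment
  starting at it (this matches VCF breakend bracket notation).

`w0` and `w1` bound the modeled window: the two domains containing the
SV endpoints (plus anything between them). Domain structure on the
derivative is then *reconstructed*, not copied: a boundary survives
only where the two flanking basepairs are still adjacent in the
derivative sequence, while a novel junction fuses its flanking domains.
A gene **gains** an element when the two share a derivative domain but
shared none before, and **loses** it in the converse case. Features
overlapped by a deleted span are discarded entirely (a deletion
therefore produces only gains), and genes absent from the modeled
derivative (the lost side of a translocation) emit no records.

This single construction reproduces the classical per-type rules —
deletion bridging, the new domain between a duplicated boundary and its
copy, elements inverted into or out of a TAD, translocation fusion
domains — and handles the corner cases (elements straddling an SV edge,
multi-boundary spans, boundary gaps) uniformly. The test-suite checks
it against an independent per-basepair enumerator that materializes the
derivative sequence explicitly on small random genomes.

Two modeling restrictions are deliberate. Gains and losses are
computed only for features overlapping the two endpoint domains:
the phrasing of the per-type rules is in terms of the flanking domains,
and interior domains of a multi-boundary SV are ignored. For
translocations only the one derivative junction described by the
orientations is modeled; the reciprocal product is not. Contacts
running through domains outside the modeled window are unaffected by
the SV and are treated as unchanged.

## Pair filtering

A pair is discarded when the gene carries a coding explanation for any
expression change in the same patient: a moderate- or high-impact
coding SNV overlapping the gene body, a gene-level copy number below
1.7 or above 2.3, or any SV span overlapping the gene body. The
disrupting SV itself is exempt when it is a duplication or inversion,
which can legitimately overlap the gene they dysregulate. The coding
filter uses the gene body only (not a promoter margin); the promoter
context instead enters through the feature vector.

## Instances, features, labels

Each gained or lost element (eQTL, enhancer or super enhancer) becomes
one instance with a fixed 29-dimensional vector: gain/loss indicators;
binary >= 1 bp overlap with four histone marks, eight chromHMM states,
DNase, RNA Pol II, CTCF, TF binding sites and CpG islands; peak
strengths (the maximum signal among overlapping peaks — robust to peak
fragmentation) for six of the signal tracks; a one-hot element kind;
and the total number of elements the SV disrupts. The chromHMM
enhancer and repeat states, H3K9me3/H3K36me3 and Hi-C-derived features
of the earlier model generation are excluded by default because their
log-variance across instances falls below -10; the legacy set remains
available via `feature_schema("legacy")`. eQTLs are pre-filtered at
p <= 0.05 (inclusive; the stringent 5e-8 setting is a parameter), and
eQTLs, histone marks and TF binding sites are binned into 1 kb windows
with max-aggregated signal; strength features read the binned signal.
All features are min–max normalized to [0, 1] using training-fold
statistics only, with out-of-range values in held-out data clipped —
the normalization is part of the model, so test folds cannot leak into
it.

Labels come from patient-matched expression: for each pair, a z-score
of the focal patient's expression against the reference panel of
patients with no disruption of that gene (no coding SNV, copy-number
change, SV overlap, or non-coding SV-gene pair). `|z| > 1.5` (strict)
labels the bag positive. The sample standard deviation (n - 1) is
used, and panels smaller than 5 patients are discarded as unstable —
below that size the z-score is dominated by the panel estimate.
Negative bags are then subsampled to the positive count within each SV
type (models are per SV type, so balance is enforced per type), and
types with more than 700 bags are uniformly capped at 700 with the
class ratio preserved.

## MILES embedding and classification

A bag is embedded as its vector of distances to every training
instance: entry (i, j) is the L1 distance between the mean instance of
bag i and instance j. "Absolute distance" is read literally as
summed per-feature absolute differences; no kernel transform is
applied (a Gaussian kernel variant exists in the MILES literature, but
raw distances keep the embedding parameter-free), and L2 is available
as an option. In this space a random forest (100 trees, sqrt-features
per split, impurity importance; forests are grown with a fixed seed on
one thread, so runs are reproducible) is trained per SV type.

Performance is estimated by leave-one-patient-out cross-validation:
all bags of one patient form the test fold, and the embedding
reference, normalization statistics and forest are rebuilt from the
remaining patients, so no test instance ever appears among the
reference columns. The operating point is chosen on the pooled CV
predictions: among all thresholds achieving precision >= 0.5, the one
with maximal recall is selected; equal-recall ties resolve to the
higher precision and then to the lower threshold, which on a cleanly
separated score set lands just below the lowest positive score.
Pooling across folds (rather than selecting per fold) uses every
prediction once and gives a single deployable threshold.

## Downstream statistics

*Instance enrichment.* The 100 reference instances with highest forest
importance are compared against 100 instances sampled without
replacement from bags predicted non-pathogenic; per feature a
two-sample t-test is run and a standardized mean difference
`z = (mean_top - mean_random) / pooled sd` is reported, capped at ±10
for display (fully separated binary features are otherwise unbounded),
with Bonferroni correction across features × cancer types.

*Driver potential.* Candidate genes are tested for an excess of
moderate/high-impact coding SNVs: the null distribution is the mean
count of 10,000 random gene sets of the same size drawn from the gene
universe, and each candidate's count is compared to it with a
one-sided, one-sample t-test (one-sided "greater-than-null" because
the question is an excess; the catalog filter zeroes counts of genes
outside the supplied driver catalog), Bonferroni-corrected across
candidates.

*Regulatory swaps.* Replacing a tissue's regulatory tracks with
another tissue's and re-running the pipeline gives per-SV-type AUCs;
the signed differences to the original run are summed over SV types
and standardized over all swaps of that tissue, so the swap z-scores
have mean 0 and sd 1 by construction. Signed rather than absolute
differences are used so that a positive z means better performance —
the quantized significance bands (|z| < 1, 1-2, >= 2) are symmetric
either way.

## The synthetic cohort

No controlled-access tumour data is required: `simulate_reference()`
and `simulate_cohort()` generate a complete input set with planted
pathogenic structure. The generator's defaults describe a small but
structurally faithful study:

* 4 chromosomes of 1 Mb, each tiled by 25 abutting 40 kb domains; one
  2 kb gene per domain in the left half of the domain.
* A sparse regulatory landscape: 60% of domains carry two 1 kb
  enhancers (each with an adjacent eQTL) in the right half of the
  domain; 30% of enhancers are *active* — covered by an h3k27ac and a
  DNase peak of high signal (5–10) against a weak background (0.5–3).
  Around 10% of element-bearing domains also carry a super enhancer.
  Background peaks for the remaining tracks and random chromHMM
  segments complete the annotation.
* 40 patients with 5 SVs per type (DEL, DUP, INV, TRA) each. 30% of
  boundary-disrupting SVs are *planted*: the SV geometry is chosen so
  a target gene gains an active enhancer across a boundary (for
  translocations, across chromosomes). Within a patient, every SV uses
  its own pair of domains: at real genome scale twenty somatic SVs
  essentially never hit the same TAD twice, and the miniature genome
  would otherwise inflate such collisions, leaving bags whose label is
  caused by a different SV of the same patient.
* Expression is simulated directly on a normalized continuous scale
  (the pipeline consumes normalized values, so no count model is
  needed): gene baselines are Uniform(6, 12) with Normal(0, 1) patient
  noise. The response model is causal: any gene that gains an element
  carrying the active-enhancer signature (an element overlapping a
  strong h3k27ac window, judged on the same filtered and binned element
  set the pipeline encodes) is shifted up by `effect_size` (default 4)
  standard deviations in that patient, and any gene that loses one is
  shifted down. Planted targets gain one by construction; background
  SVs that happen to hijack an active enhancer respond identically, so
  features and labels are consistent by mechanism, not by bookkeeping.
* Two coding SNVs and two copy-number outliers per patient land on
  random non-planted genes, exercising the coding filters. Planted
  target genes are protected from coding mutations and from other SVs
  of the same patient, so every truth-table pair survives pairing and
  filtering — a construction guarantee the tests assert.

The sizes were chosen to keep a full leave-one-patient-out run of all
four SV types in the minutes range on a single core while leaving
roughly a hundred bags per SV type, enough that a pooled AUC is stable
to a few points. The active-enhancer fraction (30%) keeps background
bags mostly inactive, so that the planted signature — a gained,
strongly marked enhancer in open chromatin — is learnable; the
label-noise floor is set by the z-threshold itself (about 13% of null
bags exceed |z| = 1.5, and an occasional truly dysregulated gene
misses it), which is faithful to how labels behave on real cohorts and
is what keeps the planted-cohort AUCs in the mid-0.9s rather than at
1.

What passing on this generator does **not** show: robustness to
imperfect TAD maps, to missing or mismatched tissue tracks, to complex
or nested SVs, to count-level expression noise, or to the much weaker
and rarer signal in real tumours — the original study's AUCs on real
pan-cancer data are far below what the planted cohort allows. The
synthetic results validate the machinery, not the biology.

## Numerical and degenerate-input choices

* Chromosome names are compared after stripping an optional `chr`
  prefix; `chr1` and `1` refer to the same chromosome everywhere.
* An empty interval (`start >= end`) in a BED file is an error, not a
  silent skip.
* Min–max normalization maps constant features to 0; binary features
  with both levels present are unchanged by it.
* A reference panel with zero standard deviation excludes the bag
  rather than producing an infinite z.
* A CV fold whose training set lacks a class is skipped with a
  warning; an SV type without positive bags is skipped by balancing.
* `compute_auc()` is the Mann–Whitney rank form with ties counted 0.5;
  it errors on single-class input rather than returning a default.
* All stochastic steps (balancing, capping, forest growth, enrichment
  draws, the generator) take explicit seeds; a master seed fans out to
  per-stage child seeds, and two runs with the same configuration are
  byte-identical through CV.

## Known limitations

* The instance-enrichment comparison (top-importance instances vs
  random instances from non-pathogenic predictions) is not fully
  calibrated under a label-permutation null: impurity importance
  concentrates on distinctive, high-signal instances whether or not
  the labels carry information, so the top group can differ from the
  random pool even for shuffled labels. Enrichment z-scores should be
  read as descriptive effect patterns (as in the heatmap view), not as
  exact null-calibrated tests.

* Duplications are assumed tandem; dispersed insertions would need the
  insertion locus, which short-read BND calls rarely resolve.
* Multi-boundary SVs are modeled only for their endpoint domains, and
  only one translocation derivative is constructed; reciprocal-product
  pairs are not emitted.
* The instance count feature counts gain/loss records of the parent SV
  across all of its pairs, which double-counts an element shared by
  two genes of the same SV.
* Missing tissue tracks are simply absent (their features encode 0);
  a fallback-track substitution mechanism as used with GM12878 data in
  real analyses is left to the caller, who can pass any track list.
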