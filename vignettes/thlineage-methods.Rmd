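---
title: "Methods: lineage-specific gene and lncRNA discovery with thlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-specific gene and lncRNA discovery with thlineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thlineage)
```

## The analytical problem

During the first days of CD4+ T-helper cell differentiation, naive precursor
cells (Thp) respond both to T-cell receptor activation itself (captured by
the Th0 activation control) and to polarizing cytokines that commit them to
the Th1 (IL-12-driven) or Th2 (IL-4-driven) lineage. A gene or lncRNA is
informative about lineage commitment only if its expression change is
*specific* to one polarized condition: differentially expressed in
Thp-vs-Th1 (or Thp-vs-Th2) but in neither the activation control comparison
Thp-vs-Th0 nor the opposite lineage comparison. `thlineage` implements this
definition over multi-platform expression data (two array-like intensity
platforms plus an RNA-seq count platform) and then characterizes the
resulting lineage-specific sets by their regulatory context: enhancer and
promoter histone-mark enrichment, lncRNA-gene vicinity and co-expression,
guilt-by-association GO annotation, and disease-SNP trait enrichment.

## Presence calling

Expression values on a platform are modelled chip-wide as a two-component
Gaussian mixture on the log2 scale: a low-mean "unexpressed" component
(background/cross-hybridization) and a high-mean "expressed" component.
`fit_two_component_em()` fits the mixture by EM on the pooled values of a
platform. A feature is called **present** in a sample subtype when *every*
replicate of that subtype favors the high-mean component
(`call_presence_mixture()`); requiring all replicates makes the call robust
to single-replicate artifacts at the cost of sensitivity for borderline
features. For Illumina-style arrays that ship detection p-values the rule is
instead detection p < 0.01, strictly, in all replicates
(`call_presence_detection()`).

Numerical choices in the EM, chosen once and fixed:

* initialization by a median split of the data (restarts use a random
  quantile in [0.25, 0.75]), `n_starts = 5`, best final log-likelihood wins;
* convergence at a relative log-likelihood change of `1e-8`, at most 500
  iterations; non-convergence returns a flagged fit with a warning;
* a variance floor `sd_floor = 1e-3` (log2 scale) prevents a component from
  collapsing onto a point mass;
* components are always reported ordered (`mean_low < mean_high`), so
  label switching cannot affect presence calls.

"Favoring the high component" is interpreted as posterior responsibility
above 0.5 — i.e. the mixing weights participate. The unweighted density
comparison is available via `rule = "density"`; with well-separated
components the two rules differ only in a narrow band between the means.
One fit is shared by all arrays of a platform (pooled values); the
chip-wide mixture is a platform property, not an array property.

Duplicate probes mapping to one gene are collapsed by retaining the probe
with the largest inter-quartile range across all samples
(`collapse_duplicates_by_iqr()`); exact ties go to the lexicographically
smallest probe identifier so the collapse is deterministic.

## Differential expression

The thresholds — BH-adjusted p < 0.05 **and** |log2FC| > 1, both strict —
and the presence refinement are the substance here; the two-group tests are
deliberately plain, reference implementations with a pluggable interface
(any external DE table in the same schema can be substituted).

*Intensity platforms.* `moderated_t_test()` computes per-feature log2FC and
the pooled two-sample variance \(s^2\) on \(df = n_1 + n_2 - 2\) degrees of
freedom, then shrinks variances with the standard hierarchical model
\(s^2/s_0^2 \sim F(df, d_0)\): the prior \((d_0, s_0^2)\) is estimated by
moment matching of mean and variance of \(\log s^2\) through
digamma/trigamma identities (trigamma inverted by Newton iteration), the
posterior variance \((d_0 s_0^2 + df\, s^2)/(d_0 + df)\) replaces \(s^2\),
and the t statistic gains \(d_0\) degrees of freedom. `d0 = 0` recovers the
ordinary equal-variance t-test; \(d_0\) is capped at \(10^6\), representing
complete shrinkage. The estimator is checked in the test suite against
simulated priors and against an independent reference implementation.

*Count platform.* Raw counts are normalized by median-of-ratios size
factors (`median_of_ratios_size_factors()`, rescaled to geometric mean
exactly 1) and variance-stabilized with the parameter-free reference
transform \(\log_2(\text{count}/\text{factor} + 1)\)
(`variance_stabilize()`). The moderated t is then applied to the stabilized
values, so the reported fold change is a "modified" log2FC shrunk toward
zero for low counts. This transform is monotone per sample and adequate for
mixture presence calling and the DE thresholds; it does not model
count-level dispersion trends (a non-goal).

*Refinement.* The DE filter additionally requires the feature to be present
in at least one of the two compared groups (`refine = "either"`). The
precise refinement rule is a genuinely open design point — present in the
test group, the reference group, either, or both are all defensible — so it
is switchable; "either" was chosen because a feature confidently expressed
in exactly one condition of a comparison is the canonical on/off signal.
lncRNA DE applies no presence refinement by default (their low expression
makes mixture presence calls conservative), also switchable.

## Consensus and lineage classification

`build_consensus()` accepts per-platform DE tables and marks a feature's
comparison as confidently DE when at least two platforms call it DE with
the same fold-change direction. A feature missing from a platform's
annotation contributes no vote (platform annotation coverage differs);
a sign conflict vetoes consensus regardless of how many platforms agree.
`classify_lineage()` then applies the specificity definition; "uniquely
differentially expressed" excludes both the activation control *and* the
opposite polarized comparison, which is what makes the Th1 and Th2 lists
disjoint by construction. Two evidence modes are kept side by side:
`consensus` (the confident cross-platform list) and `seqonly` (the count
platform alone, which also covers features absent from array annotations).

## Genomic context

Windows are computed on 1-based closed coordinates (GRanges conventions;
BED I/O converts at the boundary). Enhancer windows are ±125 kb and
promoter windows ±2.5 kb around the TSS; since these are symmetric they are
strand-independent. The lncRNA vicinity rule — within 5 kb upstream or
30 kb downstream of a gene — is asymmetric and therefore anchored on the
gene *body* and oriented by the gene's strand; both the anchor and the
strand handling are switchable because the rule could equally be read as
TSS-anchored.

`randomization_enrichment()` scores the number of *distinct* marks
overlapping the union of the target set's windows (a mark near two target
features counts once; per-feature counting is available), then draws
`n_iter = 10,000` same-size feature sets uniformly from the universe
excluding the target ("anywhere else in the genome") and reports the
empirical p-value \((r + 1)/(n + 1)\) with \(r\) the number of null draws
reaching the observed count. The +1 correction keeps the p-value positive
with a floor of \(1/(n+1)\) — at 10,000 draws, "p < 10^-4" is the strongest
statement the test can make. The null preserves only set size, not
chromosome or expression matching.

## lncRNA function

Lineage-specific lncRNAs are tallied by GENCODE-style biotype (antisense,
lincRNA, processed transcript, sense intronic, sense overlapping,
3' overlapping; anything else as "other"). The co-expression network joins
a lncRNA to a protein-coding gene when |Pearson r| > 0.9, strictly, across
all samples of the count platform's variance-stabilized values; constant
profiles are excluded with a warning rather than assigned r = 0. For each
lncRNA, its co-expressed gene group is tested for GO enrichment and terms
with raw p < 0.01 are attributed to the lncRNA. No multiple-testing
correction is applied at this step by design (the attribution is a
hypothesis-generating annotation, not an inference); BH is available behind
a flag.

The topology-aware test is the **elim** algorithm: terms are visited
children before parents (topological order), each term is scored by the
one-sided Fisher exact test (hypergeometric upper tail), and when a term
scores below `alpha_elim` (default 0.01, matching the attribution cutoff)
its annotated genes are removed from all ancestors before those are tested.
This prevents a significant specific term from dragging its general
ancestors along. The `classic` test (no elimination) is exposed alongside,
and `elim` with nothing significant reproduces `classic` exactly — a tested
identity. Terms annotating fewer than 3 universe genes are skipped
(degenerate tables). Annotations are propagated to ancestors (true-path
rule) before any testing. The enrichment universe is the expressed
(present) protein-coding genes rather than all annotated genes, because
attribution should be relative to the pool that could have been
co-expressed; this too is switchable.

## Disease-SNP trait enrichment

SNPs with association p strictly above 1e-5 are excluded (a SNP at exactly
1e-5 survives). A gene is associated with a SNP's trait when the SNP lies
within ±100 kb of the gene *body* (positional distance, strand-independent);
one gene-trait association counts once regardless of how many SNPs support
it. Per trait, enrichment of a lineage set is the hypergeometric upper tail
\(P(X \ge k)\) with the expressed-gene universe as background. Raw
p-values are reported across traits (matching the tabular-report style of
this analysis); the same machinery serves lncRNA sets by passing lncRNA
features as the "genes".

## The synthetic-data generator

`generate_synthetic_dataset()` produces every pipeline input with known
ground truth. Its defaults *are* the study conditions the pipeline is
demonstrated at, chosen once:

* 4 subtypes (Thp, Th0, Th1, Th2) × 3 replicates on 3 platforms
  (two intensity, one count); intensity platforms carry the 10,000 genes,
  the count platform additionally the 200 lncRNAs;
* bimodal log2 expression: unexpressed N(5, 1), expressed N(11, 1.5),
  expressed fraction 0.5 — a caricature of real array/VST value
  distributions with a clean valley;
* replicate noise sd 0.25 (log2) on arrays; counts drawn negative-binomial
  with mean \(2^{\text{signal}}\) and common dispersion 0.05 (per-gene
  dispersion is deliberately not modelled — a config extension);
* 300 Th1- and 300 Th2-specific genes and 30 + 30 lncRNAs planted with
  |log2FC| = 2, random sign, applied *only* in the matching polarized
  subtype and identically across platforms, so the specificity logic is
  exercised exactly as defined; planted features are drawn from the
  expressed component (an effect on an unexpressed feature would be
  invisible by construction);
* half of the planted lineage lncRNAs are placed inside the 5 kb-up /
  30 kb-down vicinity window of a same-lineage planted gene and inherit its
  effect sign (positive coupling); all other lncRNAs are placed in slots
  whose neighboring genes are not lineage-planted, far outside any planted
  vicinity window;
* one gene per ~50 kb genomic slot (slot order randomized) keeps gene
  bodies non-overlapping and vicinity semantics unambiguous;
* enhancer/promoter marks: uniform background (2,000/1,000 per lineage)
  with density multiplied by 5 inside the TSS windows of planted
  same-lineage genes;
* SNPs: 2,000 uniform background SNPs with association p-values spanning
  both sides of 1e-5, plus one planted trait whose significant SNPs sit
  within ±50 kb of planted Th1 genes;
* a 21-term, 3-level GO DAG in which one leaf term annotates exactly a
  15-gene co-expression module that shares a per-sample latent signal
  (sd 1.5, count platform) with one designated lncRNA — the
  guilt-by-association target.

Everything derives per-stage seeds deterministically from one root seed, so
identical configs reproduce byte-identical files.

What the generator does **not** emulate — and therefore what passing tests
do *not* establish about real data: probe-level array artifacts and
normalization residue, count-dispersion trends and library-composition
bias, overlapping genes and multi-isoform structure, LD among SNPs,
GC-/length-dependent mark placement, and realistic GO DAG shape. The
generator validates the *logic* of the pipeline (thresholds, consensus,
specificity, window arithmetic, null calibration), not its robustness to
platform pathology.

## Problem sizes and runtime

The demonstration (`run_demo()`) runs the full design above — 10,000 genes,
200 lncRNAs, 3 platforms, 10,000 randomization draws per enrichment test —
in well under a minute on one CPU. The test suite uses the same design for
end-to-end checks and smaller replicas (≈400 genes) for per-module
properties; calibration checks use 100–200 replicate datasets with 499-draw
randomizations, where the discrete empirical p-value grid is fine enough
for uniformity testing.

## Known limitations

* The DE engines are reference implementations; exact replication of any
  specific array/count package's internals is a non-goal, and users wanting
  a particular engine can feed its tables into the consensus stage.
* The variance-stabilizing transform is parameter-free and ignores the
  mean-dispersion relationship; for very low counts its "modified" fold
  changes are strongly shrunk.
* The mixture presence model assumes exactly two Gaussian components;
  platforms with trimodal value distributions would need a different model.
* Randomization nulls match set size only; matched nulls (chromosome,
  expression, GC) are out of scope.
* The elim implementation covers is_a edges and a single ontology root;
  part_of relations and cross-ontology links are not modelled.
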