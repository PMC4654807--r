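# thlineage

Identification and characterization of **Th1- and Th2-lineage-specific
protein-coding genes and lncRNAs** from multi-platform expression profiling
of early CD4+ T-helper cell differentiation.

During the first ~72 h of T-helper polarization, naive precursor cells
(Thp) change expression both because they are activated (the Th0 control)
and because cytokines commit them to the Th1 or Th2 lineage. `thlineage`
separates the two: a feature is *lineage-specific* when it is
differentially expressed in Thp-vs-Th1 (or Thp-vs-Th2) **only** — not in
Thp-vs-Th0 and not in the opposite polarized comparison. The package is
aimed at computational immunologists who have per-platform expression
matrices (array intensities and/or RNA-seq counts) and want a reproducible,
tested implementation of this workflow, plus a synthetic benchmark with
planted ground truth.

## The method

1. **Presence calls** — platform-wide log2 values are fitted with a
   two-component Gaussian mixture by EM,
   `w_lo N(mu_lo, sd_lo) + w_hi N(mu_hi, sd_hi)`; a feature is *present* in
   a subtype when every replicate favors the high-mean component (posterior
   > 0.5). Illumina-style arrays instead use detection p < 0.01 in all
   replicates. Duplicate probes collapse to the highest-IQR probe.
2. **Differential expression** — moderated t with empirical-Bayes variance
   shrinkage (posterior variance `(d0*s0^2 + df*s^2)/(d0 + df)`, prior by
   moment matching on log s^2) for intensities; for counts, the same test
   on `log2(count/size_factor + 1)` after median-of-ratios normalization.
   DE means BH-adjusted p < 0.05 **and** |log2FC| > 1 (strict), refined by
   presence in at least one compared group.
3. **Consensus & classification** — confident DE = same-direction DE on
   >= 2 platforms; lineage labels from the uniqueness definition above
   (`consensus` mode, plus a `seqonly` mode for sequencing-only discovery).
4. **Regulatory context** — randomization test (10,000 draws) for
   lineage-matched enhancer (±125 kb TSS) and active-promoter (±2.5 kb TSS)
   mark enrichment, with empirical p = (r+1)/(n+1); lncRNA-gene vicinity
   (5 kb up / 30 kb down, gene-strand-aware) and expression trend;
   guilt-by-association GO annotation of lncRNAs via |Pearson r| > 0.9
   co-expression and the topology-aware *elim* Fisher test (attribution at
   p < 0.01); disease-SNP trait enrichment (SNP filter p <= 1e-5, gene
   association within ±100 kb, hypergeometric upper tail).

## Worked example

The one-command demonstration generates the default synthetic design
(10,000 genes, 200 lncRNAs, 300 + 300 planted lineage genes, 30 + 30
planted lncRNAs, 3 platforms, |log2FC| = 2, 3 replicates per subtype) and
runs the full pipeline:

```r
library(thlineage)
report <- run_demo(seed = 1)   # ~15 s on one CPU
print(report)
```

```
PipelineReport
  lineage genes (consensus): Th1 300, Th2 299
  lineage lncRNAs: Th1 31, Th2 31
  enrichment Th1.enhancer.genes: observed 1410, p = 9.999e-05
  enrichment Th1.promoter.genes: observed 18, p = 9.999e-05
  enrichment Th2.enhancer.genes: observed 1377, p = 9.999e-05
  enrichment Th2.promoter.genes: observed 14, p = 9.999e-05
  ...
  evaluation vs ground truth:
    presence_sensitivity: 0.9835
    presence_specificity: 0.9949
    f1_th1_genes: 1
    f1_th2_genes: 0.9983
    vicinity_pipeline_recall: 1
    planted_trait_rank: 1
    module_term_attributed: 1
```

Reading: the consensus classifier recovered 300/299 of the 300 + 300
planted lineage genes (F1 ≈ 1); planted enhancer/promoter marks around
lineage genes are detected at the randomization floor p < 10⁻⁴ (10,000
draws); all 30 planted vicinity lncRNA-gene pairs are found, with a
positive expression trend (mean r = 0.90, all pairs positive); the planted
disease trait ranks first by hypergeometric p:

```
               trait  k   n   K    N       pvalue
       planted trait 65 299 163 5260 2.657111e-40
 background trait 04  5 299  51 5260 1.618072e-01
```

and the planted co-expression module's GO term is attributed to its lncRNA
by the elim test:

```
 lncrna_id    term_id       pvalue algorithm
   LNC0200 GO:0020001 2.043576e-44      elim
```

With `run_demo(out_dir = "demo_out", seed = 1)` every stage writes plain
TSV/JSON artifacts (presence calls, DE tables, consensus, lineage lists,
co-expression edges, GO attributions, trait tables, `report.json`), all
byte-identical across runs at a fixed seed. `inst/scripts/thlineage.R`
wraps `demo`/`simulate`/`run` for shell use, and `run_pipeline()` +
`read_pipeline_inputs()` run the same workflow on your own files
(expression TSV + sample sheet, GTF annotation, BED marks, SNP TSV, GO
edge-list/OBO + gene2term).

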