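# apaflow

Most human genes produce mRNA isoforms that differ only in the length of
their 3′UTR, generated by alternative cleavage and polyadenylation (APA).
In a two-condition bulk RNA-seq design — for example hematopoietic stem
cells differentiating into erythroblasts — a gene can respond by raising
its overall expression, by shifting usage toward its short-3′UTR (SU)
isoform, or both. `apaflow` implements the downstream analysis that asks
whether cell type-specific enhancers preferentially associate with genes
that upregulate their SU isoforms, together with the luciferase reporter
calculus used to dissect 3′ end processing (CPA) activity at single
polyadenylation sites.

The pipeline starts from isoform-level count/TPM tables (one SU and one LU
isoform per multi-UTR gene, QAPA-style) and runs:

1. **Quantification** — median-of-ratios size factors, rescaled TPM,
   poly(A) site usage `PAU = SU/(SU+LU)` per sample, condition means, and
   `dPAU = PAU_B − PAU_A`.
2. **Differential testing** — a negative-binomial Wald test for gene-level
   log₂ fold changes (method-of-moments dispersion, t small-sample
   reference) and a beta-binomial likelihood-ratio test for SU usage with
   an across-gene shared overdispersion; Benjamini–Hochberg FDR control.
3. **Classification** — every filtered multi-UTR gene is assigned to
   `gene_not_up`, `gene_up`, `su_up`, `gene_and_su_up` or `unclassified`
   using the printed thresholds: gene FC > 2 at 10% FDR; SU TPM FC > 2,
   dPAU > 0.1, usage p < 0.05 at 10% FDR; control genes need SU FC < 2,
   dPAU < 0.1 and usage p > 0.05.
4. **Enrichment** — per-category fractions of enhancer-associated (Ery+)
   genes with Pearson χ² tests against the `gene_not_up` reference, and a
   stratified expression-matched resampling control: 13 equal-width strata
   over the gene-expression log₂FC range (upper bound 1), per-stratum
   subsampling to the smaller group, repeated with derived sub-seeds.
5. **Reporter calculus** — renilla/firefly transcriptional activity, CPA
   activity (test PAS over SV40 PAS), read-through fractions, exponential
   mRNA decay fits (`y = e^{kt}`, half-life `ln(0.5)/k`), nascent and LU
   fractions, and the knock-down screen banding (Welch t-test; > 0.30
   CPA-activity change = strong hit).

A fully seeded synthetic-data generator (`simulate_apa_dataset()`) plants
known gene-level fold changes, SU-usage shifts and enhancer enrichment so
every stage is testable without external data.

## Worked example

```r
library(apaflow)

run <- run_pipeline(pipeline_config(
  simulate = sim_config(n_multi_utr_genes = 4000, n_single_utr_genes = 1000,
                        gene_log2fc = 1.5, pau_shift = 0.2, seed = 101),
  seed = 101))
run
#> apaflow pipeline run
#>   5000 genes; 4000 filtered multi-UTR genes
#>   categories: gene_not_up=2779 gene_up=361 su_up=475 gene_and_su_up=52 unclassified=333
#>   stratified resampling: 3 repeats, enhancer fraction 0.308 vs 0.098

run$enrichment
#> # A tibble: 4 x 7
#>   category           n n_enh fraction chisq   p_value odds_ratio
#> 1 gene_not_up     2779   270   0.0972  NA    NA            NA
#> 2 gene_up          361   114   0.316  142.    8.45e-33      4.29
#> 3 su_up            475   146   0.307  161.    7.68e-37      4.12
#> 4 gene_and_su_up    52    15   0.288   20.6   5.56e-06      3.77
```

The category tallies recover the planted structure (about 15% of genes
carry a usage shift of dPAU = 0.2 from a baseline SU usage of 0.10, about
15% a 2.8-fold expression increase). The enrichment table shows the Ery+
fraction per category: planted-effect genes were made enhancer-associated
at 3× the 10% background, and all three "up" categories are significantly
enriched over the `gene_not_up` reference. The stratified resampling line
is the expression-matched version of the same comparison — the SU-up
excess (0.308 vs 0.098) survives matching, so it is not explained by the
small expression increase that accompanies SU upregulation.

Reporter calculus:

```r
fit <- fit_decay(simulate_decay_series(k = -0.3466, timepoints = c(0, 2, 4, 8)))
glance(fit)
#> # A tibble: 1 x 6
#>        k half_life stable      sse converged     n
#> 1 -0.347      2.00 FALSE  6.93e-33 TRUE          4

classify_screen_hit(c(0.19, 0.20, 0.21), c(0.59, 0.60, 0.61))
#> # A tibble: 1 x 5
#>   band    delta    p_value mean_kd mean_ctrl
#> 1 strong  -0.4  0.00000104     0.2       0.6
```

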