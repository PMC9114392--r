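---
title: "Models and methods behind apaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind apaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaflow)
```

`apaflow` analyses short- versus long-3′UTR isoform usage in a replicated
two-condition RNA-seq design and asks whether genes that upregulate their
short (SU) isoform are preferentially associated with cell type-specific
enhancers. This vignette records the statistical models, the parameter
choices that matter, and the design decisions taken where the problem was
genuinely open — the things a maintainer or reviewer would want to know
before trusting a result.

## Quantities

For a multi-UTR gene with one SU and one LU isoform, poly(A) site usage is

$$\mathrm{PAU} = \frac{\mathrm{SU}}{\mathrm{SU} + \mathrm{LU}}$$

computed per sample on normalized TPM and averaged (unweighted) over
replicates within each condition; `dPAU` is the difference of condition
means (B − A). The same quantity is sometimes called the short-3′UTR
index (SUI); `compute_sui()` is an alias. PAU is kept on the fraction
scale throughout, so the printed decision threshold `dPAU > 0.1` means
ten percentage points of usage; percent-scale input tables are converted
at read time (`pau_scale = "percent"`).

Two conventions were open and are both implemented, with the defaults
chosen as follows:

* **Replicate-mean versus pooled PAU.** The default averages
  per-replicate PAUs, matching replicate-level quantification output;
  pooled counts are available via `pooled = TRUE`. With balanced depth
  the two differ negligibly.
* **Gene-level versus isoform-level expression filter.** Multi-UTR genes
  are retained when gene-level TPM reaches 3 in at least one sample
  (`min_tpm_level = "isoform"` switches the reading). "At least 3" is
  inclusive: a gene at exactly 3 TPM passes.

## Normalization

Counts are normalized by median-of-ratios size factors: the reference is
the per-gene geometric mean over samples (genes positive everywhere), and
a sample's factor is the median ratio to that reference. No
pseudo-reference fallback is attempted when no gene is positive in every
sample — that situation signals an input problem and raises an error.

TPM needs its own factors. TPM is already depth-normalized, so when many
genes rise in condition B the TPM of every *unchanged* gene is deflated
there (a compositional artifact), and factors computed from raw counts
cannot see it. The pipeline therefore computes one set of factors on
gene-level counts (used by the count-based test) and a second set on the
gene-level TPM matrix (used to rescale TPM before PAU and fold-change
computation). Expression fold changes use condition means of rescaled
TPM with a pseudocount of ε = 0.01 TPM in numerator and denominator; ε
only matters for genes near zero expression and leaves FC > 2 decisions
for expressed genes untouched.

## Differential tests

**Gene level.** A Wald test on the log2 fold change of normalized
counts. Per-gene NB dispersion (variance μ + αμ²) is estimated by the
method of moments within each condition, pooled with residual-df weights
and floored at 10⁻⁸. The Wald statistic is referred to a t distribution
with N − 2 degrees of freedom rather than the normal: with 3 replicates
per condition the normal reference rejected a true null at ≈ 0.12
instead of 0.05 in simulation, while the t reference is calibrated
(≈ 0.047). All-zero genes are flagged and returned with p = 1.

**Isoform usage.** SU counts given SU+LU totals are modeled as
beta-binomial with intraclass correlation ρ. The test is a likelihood
ratio between one shared usage proportion (null) and one per condition
(alternative), referred to χ²(1). The overdispersion is *shared across
genes*: a pooled within-condition method-of-moments ρ is computed per
gene and averaged over all genes — the moderation idea of the
established dispersion-sharing tools. Two facts motivated this:

* estimating ρ separately per gene from 2–3 replicates makes the χ²(1)
  reference about twice anti-conservative (≈ 0.10 at nominal 0.05), and
  trying to repair that with a small-sample F reference costs
  substantial power;
* with the across-gene estimate, the null rejection rate is ≈ 0.05 and
  power against a planted usage shift roughly matches the
  known-dispersion test.

The plain (untrimmed) mean is used to combine the per-gene estimates:
the per-gene values are right-skewed, so trimmed or median combinations
underestimate ρ (0.0086 and 0.0076 versus a true 0.01 in simulation;
the mean gave 0.0102). The cost of sharing is that genuine gene-to-gene
dispersion differences are ignored; `usage_test(rho = )` accepts a fixed
value for sensitivity analysis or single-gene input. Genes with zero
coverage in a whole condition are flagged and excluded from the FDR
correction.

**FDR.** Benjamini–Hochberg q-values are computed by an explicit
step-up implementation (`bh_fdr()`), cross-checked in the test suite
against both `p.adjust` and a brute-force evaluation of the defining
minimum.

## Classification

Using the printed thresholds (gene FC > 2 at 10% FDR; SU TPM FC > 2,
dPAU > 0.1, usage p < 0.05 at 10% FDR; control: SU FC < 2, dPAU < 0.1,
usage p > 0.05), every filtered multi-UTR gene receives exactly one of
five labels. Genes meeting the gene-up criterion split *binarily* into
`gene_and_su_up` or `gene_up` by the SU-up criterion. The control
criterion — and with it the `unclassified` exclusion zone for genes with
a slight, non-significant SU increase — applies within the gene-not-up
group only. The alternative reading (requiring the control criterion of
gene-up genes too) would empty the gene-up category, because a gene that
doubles its expression at constant usage necessarily doubles its SU
isoform. All inequalities are strict as printed, so boundary values
(SU FC = 2, dPAU = 0.1, p = 0.05) fall into `unclassified`.

## Enhancer enrichment and the stratified control

Per-category enrichment uses the closed-form Pearson χ² on the 2×2 table
of category membership × enhancer association, compared against the
`gene_not_up` reference. No continuity correction is applied by default
— the choice was not documented in the source analysis — and
`correct = TRUE` enables the Yates correction for sensitivity analysis.
Odds ratios are ad/bc with zero cells flagged.

Because SU upregulation usually brings a slight expression increase,
raw enrichment of the SU-up group could simply reflect expression. The
stratified control matches the SU-up and control groups on expression
change: the log2FC range from the SU-up minimum up to a fixed upper
bound of 1 is divided into 13 equal-width strata; within each stratum
both groups are subsampled without replacement to the size of the
smaller; the pooled matched sets are then compared. Strata are half-open
`[lo, hi)` with the last interval closed at 1, and genes outside the
bounds are excluded from matching (both conventions were unstated in the
source and are documented here as this package's choices). The default
of three repeats with deterministically derived sub-seeds is
configurable; per-repeat gene lists are retained for audit.

## Reporter calculus

All reporter quantities are ratios and inherit scale invariance:
transcriptional activity (renilla/firefly), CPA activity (test-PAS over
SV40-PAS activity in the same promoter context, with a delta-method
standard deviation), read-through (downstream over upstream signal),
nascent fraction and LU fraction. Decay series are normalized to t = 0
and fitted as y = e^(kt) by nonlinear least squares, initialized from
the log-linear regression through the origin; half-life is ln(0.5)/k,
with non-negative rates flagged "stable" (half-life ∞). Convergence uses
an SSE tolerance of 10⁻¹⁰ with at most 200 iterations; the zero-residual
case is handled explicitly. Screen hits are banded by a two-sided Welch
t-test at α = 0.05: significant changes with |Δ CPA activity| > 0.30
are "strong".

## The synthetic-data generator

`simulate_apa_dataset()` emulates a replicated two-condition bulk
RNA-seq design with planted ground truth:

* per-gene baseline totals are log-normal (`baseline_mean` = 300 counts
  median, `baseline_sdlog` = 0.8), drawn negative-binomially per sample
  with dispersion α = 0.05;
* a fraction `frac_gene_up` = 0.15 of genes carries a gene-level log2FC
  (default 1.5) in condition B; a fraction `frac_su_up` = 0.15 of
  multi-UTR genes carries a usage shift `pau_shift` = 0.2 from a
  baseline PAU of 0.10 (the two are drawn independently, so ≈ 2% carry
  both);
* the SU/LU split is beta-binomial with ρ = 0.01 (ρ = 0 degenerates to
  binomial);
* enhancer flags are independent Bernoulli: background rate 0.10,
  multiplied by a relative risk of 3 for genes with any planted effect;
* TPM treats all isoforms as 1 kb (lengths cancel; a per-isoform length
  is accepted).

The depth and dispersion of the emulated libraries are not documented in
the source analysis; these defaults were chosen once for test power —
deep enough that a planted dPAU of 0.2 is detectable with 3 replicates —
and for plausibility of a filtered bulk RNA-seq gene set. The baseline
PAU of 0.10 encodes a substantive premise: genes that shift toward SU
usage start distal-dominant, so a +0.2 usage shift is a genuine ≥2-fold
SU increase, the kind of event the classifier's SU FC > 2 gate is built
to call. With a higher baseline (say 0.3), a +0.2 shift raises SU only
1.7-fold and is invisible to the printed thresholds by construction —
a property of the thresholds, not a defect of the test.

Determinism: each simulation consumes a single seeded RNG stream in a
fixed documented order (baselines, planted indicators, totals, SU
splits, enhancer flags), so identical configurations give bitwise
identical datasets; multi-stage procedures (stratified repeats, the
pipeline) derive sub-seeds deterministically from the master seed.

What the generator does *not* emulate: isoform-level quantification
uncertainty (reads are never simulated), more than two 3′UTR isoforms
per gene, correlated enhancer assignment along the genome, batch
effects, and gene-to-gene dispersion variation. Passing recovery tests
on this benchmark therefore demonstrates the pipeline's correctness and
calibration under its stated model, not performance on any real
library.

## Problem sizes used in the tests

The test suite and the acceptance script run at deliberately moderate
sizes chosen to exercise the asymptotics that matter while staying
quick: null calibration uses 2000 genes × 3 replicates over 10 seeds;
planted-effect recovery uses the full default design (4000 multi-UTR +
1000 single-UTR genes) over 20 seeds; oracle sweeps are exhaustive (all
2×2 tables with margins ≤ 20; all BH inputs over a 4-point grid up to
length 6); decay recovery uses 100 noisy series. These sizes are the
package's own benchmark definition and are stated here so reruns are
comparable.

## Known limitations

* The usage test assumes one shared overdispersion across genes; highly
  heterogeneous dispersion would make it anti-conservative for the most
  overdispersed genes.
* No fold-change shrinkage is applied; thresholds act on raw estimates,
  as the classification rules require.
* The NB test has no covariates, outlier handling or dispersion trend —
  it is a calibrated stand-in for the full GLM machinery of the
  established tools, adequate for threshold-based classification.
* Exact reproduction of the source study's χ² values would require its
  external sequencing libraries and enhancer target list, which are out
  of scope; the acceptance script instead reports the quantities the
  pipeline computes on its own synthetic benchmark.
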