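---
title: "Methods: muscle-contrast differential expression with GO semantic-similarity clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semde)
```

This vignette is the package's own account of its statistics: the models,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

# The experimental design being modelled

The pipeline targets one-color microarray studies contrasting two tissues
sampled from the same animals — concretely, two glycolytic pig skeletal
muscles (*Longissimus*, LM, and *Semimembranosus*, SM) from 90 pigs drawn
from two paternal half-sib families of 41 and 49 animals. Each animal
contributes one LM and one SM hybridization, so the expression matrix has
paired columns. The nuisance structure is: sex (2 levels), slaughter
season (2 levels), hybridization batch nested within sire family (9 and 11
levels at full scale), and carcass weight as a covariate.

Although the sampling is paired, the fitted model contains no animal term:
the analysis this package re-implements treats muscle as a plain fixed
effect. The generator records animal identity but the model ignores it;
the within-animal residual correlation is exposed as a generator parameter
(`within_animal_cor`, default 0, since the source design states none), so
users can probe the consequence of that modelling choice.

# Quality control

Stages run in a fixed order, each with its published threshold:

1. **Flag filter** (`max_flag_fraction = 0.5`): a probe is dropped when
   *strictly more than* 50% of its spots are quality-flagged within either
   muscle. Exactly 50% survives; the inequality is strict on both sides of
   the pipeline ("more than 50%").
2. **ln + median centering**: natural-log transform, then each sample's
   median (over non-missing spots) is subtracted, making every column's
   median exactly 0.
3. **Outlier masking** (`k_sd = 3`): within a probe, spots deviating from
   the probe mean by more than 3 SD are masked. Mean and SD are computed
   in a single pass over all usable spots, *including* the candidate
   outlier — the simplest reading of "deviated from the mean"; an
   exclude-the-candidate variant would mask more aggressively. Probes with
   fewer than 3 usable spots are skipped with a warning.
4. **Sparsity drop**: probes flagged-or-masked in more than 50% of either
   muscle's samples are removed.
5. **Variability filter** (`kmeans_k = 3`): 1-D k-means on ln(per-probe
   variance) with 10 restarts and a fixed seed; the cluster with the
   smallest center is removed. Variance (not SD or CV) is the clustered
   quantity — the source method names only "expression variability", so
   this is a documented choice, and clustering on the log scale keeps the
   k-means objective from being dominated by the heavy right tail.
   `k = 1` is rejected (it would remove everything); all-equal variances
   degenerate to a warning and no removal.

A caveat worth knowing: median centering subtracts a per-sample constant.
When the planted (or real) differential expression is not symmetric
around zero, the LM and SM sample medians shift by slightly different
amounts, displacing *every* probe's muscle contrast by a small common
offset. This is inherent to the published normalization, not a defect of
the fitting; the forward-model consistency test therefore feeds
uncentered log intensities to the DE module (the model has an intercept,
so centering is not needed for identifiability).

# Per-probe linear model

For each probe, ordinary least squares fits

$$Y = \mathrm{Sex} + \mathrm{SlaughterBatch} +
      \mathrm{HybBatch(Sire)} + \beta\,\mathrm{CarcassWeight} +
      \mathrm{Muscle} + E.$$

Per-effect p-values are partial F tests (model comparison: the effect
dropped from the otherwise-full model), the type-III-like choice required
for a drop rule on unbalanced data. The retention sentence in the source
is self-contradictory as printed ("effects exceeding the significant
level of P<0.2 were kept"); this package reads it as *effects with
p < 0.2 are kept*, applied in a single backward pass followed by one
refit. Muscle is forced into every model regardless of its p-value.

Least-squares adjusted means for the two muscles average all retained
factor levels with equal weight and fix the covariate at its sample mean
— the conventional lsmeans definition; on balanced designs they reduce to
raw group means (tested). Fold change is `exp(|mean_LM − mean_SM|)` (so
FC ≥ 1 by construction) with direction given by the greater mean; exact
ties yield FC 1 and a flag. BH adjustment is applied once across all
analysed probes' muscle p-values — the probe level, matching the way the
source counts DE probes before collapsing to genes. Significance is
inclusive (adjusted p ≤ 0.05), the relevance filter strict (FC > 1.5).

Probe-to-gene collapse keeps one call per gene: the significant probe with
the largest FC is representative; genes whose significant probes disagree
in direction are flagged as conflicting and excluded from the functional
lists; unmapped probes are counted as unannotated.

Implementation note: with complete data every probe shares one design
matrix, so the whole matrix is analysed with a handful of QR projections
(residual sums of squares for the full and each drop-one model at once);
probes with masked spots fall back to a per-probe `lm` path. The two
routes are equivalence-tested against each other and against a
normal-equations oracle.

# Wang semantic similarity

S-values over a term's ancestor graph follow the weighted-contribution
recursion with edge weights 0.8 (is_a) and 0.6 (part_of) — the canonical
constants of the cited graph-based measure, which the source itself never
prints. Term similarity is the normalized shared-ancestor sum; gene
similarity defaults to the best-match average (BMA), the default of the
implementation the source cites, with `max` and `mean` available because
the source is silent on the combination rule. Only biological_process
terms are used; annotations enter as directly assigned terms (ancestors
contribute through S-values only). The engine is checked against an
exhaustive path-enumeration oracle on random mixed-edge DAGs to 1e-12.

# Clustering and enrichment

Genes with at least one BP term are clustered on `1 − similarity`; the
excluded unannotated set is reported, mirroring the source's annotated
subset bookkeeping. The Ward variant question matters: R's historical
`ward.D` (what a 2008-era analysis ran) feeds raw dissimilarities into
the Ward update, while `ward.D2` implements the classical criterion on
squared dissimilarities. The default here is `ward.D2` — the criterion
Ward actually defined — with `ward.D` available; partition-recovery tests
use the default only. `k` defaults to 5, the source's outcome; no
automatic selection is attempted because none was described.

Per cluster and per collection (GO BP with ancestor propagation, plus any
pathway sets), the hypergeometric upper tail is computed by direct
summation of the mass function, with ES = observed/expected, a minimum of
5 cluster genes per reported term, and BH within each cluster-by-
collection family — mirroring the per-analysis correction of web
enrichment tools. The ES = observed/expected reading follows the cited
tool's convention; the source does not define ES explicitly.

# qPCR validation arm

Efficiency comes from the calibration-curve slope (E = 10^(−1/slope));
relative quantities are E^(−ΔCt) against a calibrator; geNorm M is the
mean SD of pairwise log2 ratios with stepwise exclusion down to the final
pair; the normalization factor is the geometric mean of the selected
references; N_exp = E^(−ΔCt)/NF is compared between muscles with a
classical pooled-variance Student t-test (Welch available). The
calibrator in the synthetic arm is the per-assay mean Ct across samples —
the analogue of the source's pooled-sample calibrator. Replicate wells
collapse by arithmetic mean Ct. The stability ranking takes the provided
references through geNorm ranking rather than applying a pairwise-
variation cutoff to choose their number, which the source leaves
unstated.

# The synthetic world

The generator is the analysis model run forward, with defaults set to the
stated study conditions: 90 animals per muscle (scalable down, minimum
4), two sire families in a 41:49 ratio, 9/11 hybridization-batch levels
scaling down with cohort size, carcass weights around 108 kg, 37% of
genes with a planted muscle effect, and 30% probe redundancy implemented
as a second probe with its own affinity and independent noise.

Planted |log FC| values are drawn log-normally (meanlog `log(0.25)`,
sdlog 0.8) and truncated to ratio range [1.1, 15], reproducing the
reported fold-change span with median below 1.5; the source states the
range and the median but no distribution, so the log-normal shape is this
package's one-time choice. Residual SD defaults to 0.2 on the ln scale
(~20% CV, typical for one-color arrays); nuisance effect sizes (0.1 for
sex and season, 0.05 SD across hybridization batches, 0.005/kg) are
realistic small batch effects chosen once. Sex is randomized and batches
are consecutive blocks so that no nuisance factor is aliased with
another. Flags are independent Bernoulli spots (`flag_prob = 0.01`).

The ontology generator plants `n_modules` disjoint subtrees under one
root and annotates each gene predominantly (purity, default 0.9) to its
own module; 65% of genes carry any annotation, matching the roughly
two-thirds annotated fraction of the source's relevant set. The qPCR
generator writes Ct = 22 − log_E(quantity) plus technical noise, with
reference stability controlled per assay.

What a green test does **not** establish: the generator has no
intensity-dependent (heteroscedastic) noise, no spatial or dye artefacts,
no correlated flag structure, no realistic GO term names, and no
annotation incompleteness bias — so passing recovery tests validates the
statistical machinery, not robustness to those real-data pathologies.

# Numerical choices and degenerate inputs

* Strict inequalities at every published threshold boundary (50% flags,
  FC 1.5); inclusive at significance boundaries (adjusted p ≤ 0.05), each
  following the source's wording.
* k-means ties and restarts: 10 restarts, fixed seed, smallest-center
  cluster removed; RNG state is saved and restored around the call.
* Hypergeometric p is clamped to ≤ 1 against accumulated floating-point
  drift; partial-F statistics are clamped at 0 for the same reason.
* BH excludes NA p-values from the test count and propagates them.
* Zero-variance t-test inputs: identical groups give t = 0, p = 1;
  separated constants give p = 0.
* `s_values` memoizes per anchor; the similarity matrix caches S-value
  maps per term and computes each unordered pair once.

# Known limitations

* No mixed/random-effects or empirical-Bayes moderated variance — the
  source used none, and the per-probe OLS inherits its power profile.
* The paired design is not exploited (no animal term), matching the
  source; with strong within-animal correlation the muscle test is
  conservative.
* Hierarchical clustering is exclusive: a gene sits in exactly one
  functional cluster even when its annotations span several themes.
* Enrichment tests are upper-tail only; under-representation is out of
  scope.
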