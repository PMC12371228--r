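---
title: "Evaluating transcriptomic node-status predictors without fooling yourself"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating transcriptomic node-status predictors without fooling yourself}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigleak)
```

## The problem

Bulk tumour transcriptomes are repeatedly mined for signatures that predict
pathologic lymph-node status (`pN0` versus `pN+`) in muscle-invasive bladder
cancer. Published signatures rarely replicate across cohorts, and a large
part of the apparent performance of newly derived predictors can be an
artefact of *information leakage*: selecting features on the very data that
later evaluates the model. `sigleak` packages the complete evaluation
machinery needed to quantify both phenomena — signature scoring, chance
overlap baselines, differential expression, and nested cross-validation
with internal versus leaky feature selection — together with a synthetic
two-cohort generator that supplies ground truth, so every stage can be
audited without access to patient data.

## Mean signature scores and directionality inference

For a signature with up-genes $U$ and down-genes $D$ on per-gene
median-centered log2 data, each sample's score is

$$ s_j = \frac{1}{|U|}\sum_{g \in U} x_{gj} \;-\;
         \frac{1}{|D|}\sum_{g \in D} x_{gj}, $$

with the obvious one-sided conventions when $U$ or $D$ is empty. Scores are
only defined on centered data; `meanSignatureScore()` enforces the
`centered` flag that `medianCenter()` sets.

When a published signature does not state a gene's direction,
`inferDirectionality()` sets the gene "up in `pN+`" when its mean
expression in node-positive samples lies strictly above its median over all
samples, and "down" otherwise. Two deliberate choices:

* **Strict tie rule.** Equality goes to "down". Median-centered genes sit
  exactly at 0 in at least half of their values, so ties are not
  exotic; a deterministic rule keeps results reproducible.
* **Mean, not median, on the positive side.** The score itself averages
  expression, so the mean is the matching summary; a `statistic = "median"`
  switch is provided.

Directions inferred from the same dataset that is subsequently scored are
tuned to that dataset. On label-free noise this biases the score AUC above
0.5 — the package's test suite asserts the bias on null data rather than
pretending it away. Reported directions are never overridden.

## Chance-overlap baselines

Two constructions cover the package's overlap questions:

* **Two lists** (`listOverlapTest()`): the expected overlap of random
  lists of sizes $n_A$, $n_B$ from a universe of $N$ genes is the
  hypergeometric mean $n_A n_B / N$; significance comes from Fisher's
  exact test on the 2×2 membership table. With a 16,297-gene universe and
  two 10% lists this expectation is 163 genes; at 5%, 41; at 1%, 1.6 —
  values worth keeping in mind whenever two cohorts' top genes "overlap".
* **Many signatures** (`signatureOverlap()`): the statistic is the number
  of distinct genes present in at least two signatures. Each signature is
  redrawn uniformly without replacement from the universe, independently
  across signatures (10,000 replicates by default, fixed seed). The
  analytic first-order value $\sum_{i<j} n_i n_j / N$ is reported
  alongside; it slightly overstates the simulated mean because genes hit
  by three or more signatures are counted once, but at realistic sizes the
  two agree to about one part in a hundred.

## Moderated-t differential expression

`differentialExpression()` implements the standard two-group empirical
Bayes workflow: per-gene fold change $\bar{x}_{+} - \bar{x}_{0}$ and pooled
variance $s^2$ on $d = n - 2$ df; a scaled-F prior
$s^2 \sim s_0^2 F(d, d_0)$ whose parameters are estimated by moment
matching on $\log s^2$ (closed-form via Newton inversion of the trigamma
function); posterior variances
$\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$; and a t statistic on
$d_0 + d$ df with BH-adjusted q-values.

Degenerate branches are defined rather than left to chance: an
underdispersed $\log s^2$ (non-positive moment estimate) yields
$d_0 = \infty$ with the prior variance pooled to $\text{mean}(s^2)$, and
the total df is capped at the pooled residual df so the reference
distribution stays proper. `priorDf = 0` switches off moderation entirely
and reproduces the ordinary pooled t-test exactly — the package tests this
to 1e-10, and separately checks the full moderated statistics against
limma on a shared fixture. Zero-variance genes are permitted; moderation
absorbs them (and with `priorDf = 0` a zero-variance, zero-difference gene
is reported as $t = 0$).

Top up-/down-lists (`topGeneLists()`) rank by the moderated t (a
`metric = "log2fc"` switch exists, since either reading of "most
differentially expressed" is defensible), truncate to
$\lceil f \cdot m \rceil$ or $k$ genes, and partition the universe by sign
with $t = 0$ assigned to the down side; ties break by $|\text{log2fc}|$,
then gene symbol.

## Pre-ranked gene-set enrichment

`prerankedGsea()` computes the classic weighted KS running sum: hits
increment by $|t|^p / \sum_{\text{hits}} |t|^p$ (weight $p = 1$ by
default), misses decrement by $1/(N - n_h)$, and the enrichment score is
the signed maximum deviation. The null permutes gene labels — set
positions are redrawn uniformly — with one shared null per distinct set
size. NES divides ES by the mean absolute same-sign null; p-values are
same-sign tail probabilities; FDR follows the positive/negative
normalised-null ratio convention. Set-size bounds default to 15–500
matched genes; permutation count and seed are explicit arguments. These
bounds and the permutation count are conventional defaults, not values
reconstructed from any particular analysis.

## Nested cross-validation and the leakage contrast

The evaluation protocol is built around a *predefined* fold plan
(`makeFoldPlan()`): `repeats` × `kOuter` stratified outer folds, each
outer training set split into `kInner` stratified inner folds, all derived
from one seed. Every signature and selection method evaluated under the
same plan sees identical partitions, so comparisons are paired.
Stratification keeps per-fold class counts within one sample of
proportionality — necessary for stable AUCs at a 0.34 prevalence with
five folds.

`nestedCvEvaluate()` runs, per outer fold: feature selection
(`t_test`, `wilcoxon`, `rf_importance`, or `embedded_enet`) on the outer
training set only; standardisation to training-fold mean/SD; elastic-net
tuning over the α grid (0 to 1 in 0.05 steps) × a 100-point log-spaced λ
path (down to $10^{-4}\lambda_{\max}$, minimum rule, no 1-SE) by mean
inner-fold AUC; prediction of the untouched outer fold. The outer test
fold influences nothing — not centering, not scaling, not selection, not
tuning. `leakyEvaluate()` is byte-for-byte the same engine except that
selection runs once on the full labelled dataset first; its results carry
`leaky = TRUE`.

Numerical choices that matter:

* **Tuning criterion.** Mean inner-fold AUC matches the reporting metric;
  binomial deviance is available (`tuneMetric = "deviance"`). Under the
  AUC criterion exact ties along the λ path are common on separable data;
  ties resolve to the *least* penalised λ among the maxima so predicted
  probabilities remain usable at the 0.5 threshold that balanced accuracy
  uses.
* **Degenerate fits.** A tuned elastic net that keeps zero features is
  flagged, predicts the constant training prevalence, and is scored AUC
  0.5 — reported, not dropped, so aggregates stay defined (a `strict`
  mode drops such folds instead). With ridge (α = 0) in the grid a fully
  degenerate fit is an occasional event, mostly seen under lasso-leaning
  tuning on pure noise.
* **Random forests** use fixed hyperparameters (500 trees,
  $\sqrt{p}$ mtry, permutation importance for selection) and no inner
  tuning.

`trainFinalAndApply()` completes the audit: selection and tuning on an
entire cohort (the full-data protocol whose optimism is under study),
then application to a second, untouched cohort, with all standardisation
parameters taken from the training cohort. The gap between the apparent
training AUC and the external AUC — and the agreement between the external
AUC and the honest nested estimate — are the package's headline outputs,
tabulated by `summarizeLeakageGap()`.

## The synthetic cohort generator

`simulateCohortPair()` draws, for cohort $c$, sample $j$, gene $g$:

$$ x_{gjc} = \mu_g + B_{gc} + S_{g,\,k(j)} +
   y_j\, \delta\, d_g\, \mathbf{1}[g \in \text{signal}(c)] +
   \varepsilon_{gj} $$

with gene baselines $\mu_g \sim N(0,1)$ shared between cohorts,
cohort-specific location offsets $B_{gc} \sim N(0, \sigma_B)$, latent
subtype effects $S \sim N(0, \sigma_S)$ on a random 20% of genes per
subtype (the same effects act in both cohorts — subtype biology is shared,
sample composition is not), Bernoulli node-status labels, a planted effect
$\delta$ with direction $d_g = \pm 1$ (half up, half down), and Gaussian
noise. The two cohorts' signal-gene sets share exactly
$\text{round}(\rho \cdot n_{\text{signal}})$ genes, so $\rho$ dials
cross-cohort transferability from none to full. Optional zero-inflated
genes (a Uniform(0.5, 0.9) fraction of entries set to 0) exercise the
zero-fraction filter. One user seed governs everything through derived
substreams, so adding a stage never perturbs another stage's draws.

Defaults were fixed once to emulate the study conditions the package
targets: 5,000 genes (scalable to the full 22,383-gene universe), 300
samples per cohort at prevalence 0.34, 50 signal genes at $\delta = 1$,
five subtypes with $\sigma_S = 0.5$, $\sigma_B = 0.3$, unit noise, and
dropout off (enabled where the filter is under test). The between-cohort
platform shift has no quantitative anchor in public summaries, so
$\sigma_B$ is an explicit knob, not an estimate.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: count-level RNA-seq noise (no negative
binomial), library-size and probe-affinity artifacts, gene–gene
correlation beyond the block structure that subtypes induce, survival
endpoints, and any real biology of nodal spread. It is a calibration
instrument: it makes leakage, transferability and null behaviour
measurable against known truth.

For calibration checks of the moderated-t p-values the package uses a
pure-null configuration ($\delta = 0$, subtype and cohort shifts 0):
subtype mixtures make the marginal two-group null only approximately
Gaussian, and the calibration question is about the statistic, not about
mixture artifacts.

## Problem sizes used by the test suite

The shipped tests run the leakage demonstration at $n = 100$, $p = 5000$,
top-50 t-test selection, 5 × 5 folds over ten seeds, and the
transferability contrast at $n = 300$, $p = 5000$, $\delta = 1.5$, 50
signal genes with $\rho \in \{0, 1\}$ — sizes at which the selection-bias
effect is large and stable while a complete run stays in the minutes
range on one core. The multi-signature overlap null uses the published
matched sizes (68, 20, 12, 14, 27, 16, 46, 3, 17, 3, 17, 5) in a
22,383-gene universe with 10,000 replicates.

## Known limitations

* The elastic-net tuning criterion, λ-path length, and fold stratification
  are documented assumptions; published protocols often leave them
  unstated, and different choices shift absolute AUCs by a few points.
* Wilcoxon selection uses the normal approximation with tie correction —
  adequate for ranking at $n \ge 30$, not for exact small-sample p-values.
* `signatureOverlap()` reports the first-order analytic value as a
  cross-check only; the simulation is the estimator.
* The GSEA FDR follows the ratio convention of the original
  implementation; it is not a BH adjustment and can be non-monotone in
  small set collections.

## A worked miniature

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  synthetic = syntheticConfig(n_genes = 2000, n_samples_per_cohort = 200,
                              n_signal_genes = 50, effect_size_delta = 0.3,
                              shared_fraction_rho = 0.2, seed = 1),
  fsMethods = "t_test", families = "elastic_net_logistic",
  enetRepeats = 2, cvRepeats = 1, selectK = 100, seed = 1)
report <- runPipeline(cfg)
summarizeLeakageGap(report)
```

With a mostly cohort-private signal ($\rho = 0.2$) the summary shows the
characteristic pattern: leaky AUC well above the nested estimate within
each cohort, and external AUCs collapsing toward chance.
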