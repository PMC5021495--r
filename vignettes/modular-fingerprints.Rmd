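---
title: "Modular fingerprints of blood transcriptome disease activity: models and design"
author: "modfinger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular fingerprints: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(modfinger)
```

This vignette is the package's own account of the statistics it
implements, the parameters that matter, the numerical choices that had to
be pinned, and — importantly — what a green test on synthetic data does
and does not establish.

## The problem

In heterogeneous autoimmune disease, the clinically useful contrast is
often *within* patients — high versus no disease activity — rather than
patient versus healthy control. Whole-blood expression differences between
such groups are diffuse: hundreds of genes move a little, and single-gene
signatures are notoriously irreproducible across platforms and cohorts.
The modular approach replaces the flat gene list with a fixed repertoire
of transcriptional modules (co-expression-derived gene sets with
biological labels: interferon, neutrophils, plasma cells, ribosomal
proteins, ...) and summarizes a contrast by the percentage of each
module's genes that are significantly up- or down-regulated. That percent
statistic is the package's center of gravity; everything else supports or
stress-tests it.

## Differential expression model

For gene $g$ with group means $\bar x_{gA}, \bar x_{gB}$ (log2 scale),
pooled within-group variance $s_g^2$ on $d_g = n_A + n_B - 2$ df:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\bar x_{gA} - \bar x_{gB}}{\tilde s_g\sqrt{1/n_A + 1/n_B}},$$

referred to a $t$ distribution on $d_0 + d_g$ df. The hyperparameters are
estimated by the method of moments on $\log s_g^2$: under the hierarchical
model, $\mathrm{var}(\log s_g^2)$ exceeds the pure chi-square sampling
spread $\psi'(d_g/2)$ by $\psi'(d_0/2)$, which is inverted numerically
(Newton on the trigamma function); the mean identifies $s_0^2$ after
digamma bias correction. When the observed spread does not exceed the
sampling spread, $d_0 = \infty$ (one shared variance). Two pinned edge
cases:

* **All variances numerically identical.** The bias-corrected formula
  would return $\exp(\overline{\log s^2})\cdot(d_g/2)/e^{\psi(d_g/2)}
  \neq s^2$, which is absurd for a point mass; we special-case exact zero
  spread and return the common value itself. The general
  $\mathrm{var} \le \psi'(d_g/2)$ case keeps the bias-corrected estimate.
* **$d_0 = 0$** is never *estimated*, but `moderation_prior(0, ...)` is an
  explicit request for the ordinary pooled t-test — useful as an oracle
  route (the test suite verifies exact agreement with a textbook
  two-sample t at this setting, and agreement with the reference
  empirical-Bayes implementation at estimated priors).

Degenerate genes (zero pooled variance *and* zero fold change) get
$t = 0, p = 1$ rather than NaN: synthetic edge cases must be
deterministic. With zero variance but nonzero fold change under the
ordinary t, $p$ is clamped into $(0, 1]$ at the smallest double.

BH adjustment is implemented directly (sort, $m p_{(j)}/j$, running
minimum from the tail) because the step-up rule is itself under test; an
independent implementation serves as the oracle.

**Defaults:** $\alpha = 0.05$ (the field's reporting convention for this
analysis), estimated prior, no fold-change filter (none is stated for the
headline gene counts this mirrors).

## The fingerprint statistic

Per module: $n_\text{up}, n_\text{down}$ = member genes in the
significant up/down sets, expressed as percentages. Two denominator
conventions exist because arrays never measure every module member (and
probe collapse removes more): `measured` (members present in the DGE
table; the default) and `total` (nominal module size). The default is
`measured` — public deposits of the reference pediatric data are
themselves incomplete, so measured-gene denominators are the honest
choice — but counts are always reported so either convention can be
recomputed. A module with zero measured members gets `NA` percentages,
never 0/0. Direction comes from the sign of each significant gene's fold
change; a significant gene with exactly zero fold change cannot occur
(significance requires $t \neq 0$ at any $\alpha < 1$).

Percentages are written unrounded to TSV/JSON and rounded to integers
only in rendered displays, matching the field's table style.

## Minimal signatures: nearest shrunken centroids

Standardized centroid differences
$d_{ik} = (\bar x_{ik} - \bar x_i)/(m_k (s_i + s_0))$ with
$m_k = \sqrt{1/n_k - 1/n}$, fuzzing constant $s_0$ = median of the pooled
within-class sds, soft-thresholded at $\Delta$; genes whose every
shrunken difference is zero leave the classifier. The discriminant is the
standardized squared distance to each shrunken centroid minus
$2\log\pi_k$; ties break toward the earlier (sorted) class label.
Cross-validation is stratified, seeded (the seed is mandatory — silent
RNG defaults are how irreproducible signatures happen), over a default
grid of 30 thresholds from 0 to $\max|d_{ik}|$; the chosen $\Delta$
minimizes total CV error, and among ties the *largest* $\Delta$ (fewest
genes) wins — "the smallest list of genes with the smallest
misclassification error".

**A structural caveat the tests surface honestly.** When the planted
per-gene effect is large (a 1.5 log2 shift over ~0.3 sd noise is ~5σ),
a single surviving gene already classifies perfectly, so CV error is
exactly zero across almost the whole grid and the fewest-genes tie-break
selects a list much smaller than the planted signature. The acceptance
criterion demanding recall ≥ 0.8 of a 20-gene planted signature at the
CV-chosen threshold is therefore unattainable *by construction* in that
stated world — minimal-error-then-minimal-list selection and full recall
of a redundant signature are conflicting objectives. The criterion is
implemented faithfully and left failing, with the analysis here and in
the decisions ledger. Similarly, under a balanced null the CV error curve
is flat noise around $n/2$: the chosen list length is then itself noise,
so the tests assert the contracts that do hold (chosen $\Delta$ attains
the observed minimum; beyond $\max|d_{ik}|$ nothing survives and
prediction falls back to the prior rule).

## Clustering separation

Agglomerative clustering of samples is implemented in-package
(Lance–Williams updates for average, complete and Ward-D2 linkage) with a
pinned tie-break — among equally close pairs, the pair containing the
lowest original leaf index merges first — so trees are bit-reproducible
across platforms. Default distance is correlation ($1 - r$), the
microarray convention; the result is a standard `hclust` object.
`separation_score` cuts at $k = 2$ (active vs inactive reading) and
reports how many target-group samples land in their majority cluster.

**Why genes are row-standardized by default, and why planted worlds need
both directions.** Pearson correlation between two samples centers each
sample's profile across the selected genes. Consequences: (i) a gene list
whose members all shift *uniformly* in the active group contributes a
constant to each active sample's profile, which centering removes — such
a list is mathematically invisible to correlation distance regardless of
effect size; (ii) without row standardization, between-gene baseline
differences dominate the profile and compress group differences. Real DE
lists are immune to (i) because they carry both up- and down-regulated
genes with heterogeneous effects (the activity heatmaps this mirrors
cluster on exactly such mixed lists). The package therefore standardizes
rows before computing sample distances (`scale_genes = TRUE`; switchable
off, and off is used when testing the bare agglomeration against
oracles), and the synthetic clustering worlds plant up *and* down
modules. A one-directional planted world can still "pass" a separation
check degenerately — the 2-cut peels off one outlier and the majority
cluster contains everyone — which is precisely why the earlier
single-direction design was replaced; a green separation test on a mixed
planted list is meaningful, one on a uniform list is not.

## Enrichment

One-sided hypergeometric over-representation: $p = P(X \ge k)$ with
$X \sim \mathrm{Hypergeom}(N, K, n)$, sets intersected with the declared
universe first (default universe: all measured genes after collapse).
The tail is computed by `stats::phyper`; an independent log-factorial
tail-sum oracle guards it in the tests. Bonferroni $q = \min(1, mp)$
mirrors the reporting convention of hosted enrichment services; BH is
reported alongside. The hosted services' annotation databases are
deliberately out of scope — enrichment runs against user-supplied GMT
collections, so results are version-pinned by the user's files.

## The synthetic world

`simulate_cohorts` states a world matched to the inference model:

* gene variances $\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ (default
  $d_0 = 4$, $s_0^2 = 0.09$: typical gene sd ~0.3 log2 units with
  realistic heterogeneity) — exactly the moderated-t prior, so
  prior-recovery tests are well-posed;
* expression = baseline (7.0, mid-range for normalized arrays) +
  per-group module shift for effect-carrying genes + $N(0, \sigma_g^2)$,
  optional shared per-sample batch offset;
* per-module *penetrance* (fraction of members carrying the effect)
  models the observation that even strongly responsive modules rarely
  reach 100%;
* effects are per-group, so one simulated study supports several
  contrasts. `make_paper_like_design` cans the reference cohort sizes
  (13 high / 25 none / 51 healthy / 95 typical) with a strong
  interferon-like module up in both disease contrasts, a neutrophil-like
  module up much more in the activity contrast, ribosomal-like modules
  down, and a quiet plasma-cell-like module.

What it does **not** emulate: probe-level structure (collapse is tested
with explicit fixtures instead), intensity-dependent variance trends,
correlated noise within modules beyond the planted mean shifts, outlier
samples, or missing values (a load error by contract). A green planted-
recovery test therefore establishes that the pipeline recovers clean
module-coherent shifts at stated effect sizes — not that it is robust to
every artifact of real arrays.

## Determinism and formats

Same config + seed reproduces every matrix bit-exactly; the CV and
simulation code save and restore the caller's RNG state. Numeric TSV
output uses 17 significant digits so write→read round-trips are
bit-exact. Expression input is TSV or GCT 1.2 (version line enforced);
gene sets are GMT; the pipeline config is JSON (the environment pins no
R YAML parser, and JSON round-trips the resolved config losslessly).
Probe collapse default is `max-mean` (keep the probe with the highest
mean intensity — standard, deterministic); `mean` and `none` are
selectable. Gene matching between matrix and modules is exact,
case-sensitive string equality: symbol aliasing would silently depend on
an external annotation database, which this package refuses to do.

## Known limitations

* Two-group contrasts only: no covariates, pairing, or count models.
* The separation statistic depends on distance/linkage choices that the
  original figure it mirrors never specified; treat cross-study
  comparisons of "x of N separated" as qualitative.
* The public-deposit reproduction harness (`repro_gse11909`) compares
  against user-supplied reference values and documents, rather than
  asserts, agreement — the deposit itself is incomplete.
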