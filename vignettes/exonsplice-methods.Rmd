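---
title: "Exon-array alternative-splicing analysis with exonsplice: models and methods"
author: "exonsplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-array alternative-splicing analysis with exonsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonsplice)
```

## Scope and data model

Human exon arrays interrogate every exon of a gene with a small *probeset*
of probes; probesets are grouped into *transcript clusters* that roughly
correspond to genes. After probe-level preprocessing (background
correction, normalization, RMA-style summarization — performed upstream by
the vendor's tooling and **not** by this package), the data are a
probesets × samples matrix of log2 intensities, optionally accompanied by
per-cell DABG (detection above background) p-values. `exonsplice` starts
from exactly that point: its central container, `ExonArrayExperiment`,
extends `RangedSummarizedExperiment` with an `exprs` (and optional `dabg`)
assay, probeset annotation as genomic ranges (transcript cluster, gene,
exon ordinal in transcription order, isoform membership) and clinical
sample metadata (condition `normal`/`pathological`, patient pairing,
gender, age, stage, free covariates).

All expression values are required to be on the log2 scale on input; the
package never exponentiates except to render a ratio-scale fold change in
reports.

## Exon-level statistics

Let $x_{ps,s}$ be the log2 intensity of probeset $ps$ in sample $s$, and
$g_{c(ps),s}$ a per-sample summary of the transcript cluster containing
$ps$. The cluster-normalized value is the log-ratio

$$e_{ps,s} = x_{ps,s} - g_{c(ps),s},$$

which removes overall gene expression and isolates exon-specific signal.
On these values the package computes, per probeset:

* the **Splicing Index**,
  $SI = \overline{e}_{normal} - \overline{e}_{pathological}$, positive
  when the normal normalized signal is higher (the exon is relatively
  lost in disease);
* the two-sided **Student t-test** (equal-variance two-sample by default;
  a paired mode tests within-patient differences);
* a **MiDAS-style p-value**, realized as a one-way fixed-effects ANOVA of
  $e$ across the experimental groups. With exactly two groups $F = t^2$
  and the two p-values coincide — an identity the test suite checks to
  $10^{-10}$, and the internal contract of this realization. The original
  vendor algorithm includes an unpublished variance-stabilization
  constant; it is not reproduced here, which is the one acknowledged
  approximation of this module;
* the **fold change** on *raw* intensities,
  $FC = \overline{x}_{normal} - \overline{x}_{pathological}$ (log2
  units), deliberately not gene-normalized so that gene-level shifts
  remain visible at the exon level.

DABG p-values are reduced to per-group detection fractions (fraction of
samples with $p \le 0.05$, threshold tunable); probesets detected in
fewer than half the samples of at least one group (`"either"`, default)
or both groups (`"both"`) are marked `filtered` but never deleted —
downstream summaries simply skip them. Optional Benjamini–Hochberg
q-values are available; raw p-values are the default output.

### Choice of the cluster summary

The summarizer behind $g$ matters more than it first appears. Three
options are provided:

* `"medianpolish"` (default): Tukey median polish on the cluster's
  probesets × samples submatrix; $g$ = overall + column effects. This
  mirrors the RMA-style summarization used upstream. Because probeset
  affinities are absorbed by the row effects before the column sweep, a
  single aberrant exon leaves the cluster summary essentially untouched,
  and a planted splicing shift of $\delta$ on one probeset yields
  $SI \approx \delta$.
* `"median"`: per-sample median across probesets. Robust in the typical
  case, but when the aberrant probeset's affinity ranks near the middle
  of the cluster its shift drags the median, diluting the Splicing Index
  noticeably (about 10% at realistic noise levels).
* `"mean"`: fully transparent, but a shift of $\delta$ on one of $K$
  probesets contaminates the summary by $\delta/K$ and biases the SI of
  every sibling probeset.

A residual bias of a few percent remains even under median polish (an
order-statistic effect of the column-median sweep when one row carries an
extreme residual); it is small relative to the noise bands used in the
test suite.

Degenerate inputs never produce `NaN`: zero pooled variance with zero
mean difference gives $p = 1$ (no evidence), zero between-group sum of
squares gives $p = 1$, a zero-variance difference with a non-zero mean
gives $p = 0$.

## Gene-level statistics

Transcript-cluster values can mix genes that merely share probesets, so
gene expression is summarized from the probesets mapped to the gene's
known isoforms only (probesets with non-empty isoform membership); genes
with no isoform-mapped probesets fall back to all their probesets, with a
warning, rather than dropping out. The summarizer is again Tukey median
polish over the selected probesets (per-sample summary = overall + column
effect), with `"mean"` as a transparent alternative; convergence is fixed
at tolerance $10^{-6}$, at most 10 row-then-column sweeps, so results are
deterministic across platforms. The gene-level fold change and t-test
reuse the exon-level machinery and sign convention.

## Meta statistics and distance ranking

The gene-level fold change alone says little about splicing: an isolated
event leaves most of a gene's probesets untouched. The package therefore
summarizes each gene's exon-level results into a 16-component *meta
statistics* vector: minimum, maximum, mean and sample variance
($n-1$ denominator; defined as 0 for single-probeset genes) of each of
{t p-value, MiDAS p-value, Splicing Index, fold change}. An isolated
splicing event shows up as a minimum p-value near 0 while the mean stays
high; a whole-gene expression shift instead moves the fold-change mean.

For searching, the components are standardized across genes (z-score;
zero-variance components become all-zero and drop out of distances;
min–max scaling is available behind a flag), and genes are ranked by the
Euclidean distance between their scaled vectors and a scaled *query
point* over the query's **active components only** — mirroring a search
form where each slider has a checkbox. Ties are broken by gene id so
orderings are total and reproducible. The same distance, with all 16
components active, ranks the members of a pathway or GO set around a
focal gene, so genes that statistically behave like it come first.
`defaultASQuery()` (min t and MiDAS p at 0, mean t p at 1) is this
package's own reconstruction of a sensible splicing-discovery preset, not
a published set of values.

Note that the "mean p-value tending to 1" intuition for isolated events
should be read qualitatively: the non-affected probesets of a gene have
approximately uniform null p-values, so the mean of an 8-probeset gene
with one strong event concentrates near $7/16 \approx 0.44$, not near 1.
The minimum-p component carries the discriminating signal; the test suite
verifies the min-p side of the signature and treats the literal
mean-above-0.5 reading as what it is — unattainable for uniform nulls.

## Multivariate analysis: conditional-inference splice trees

To relate a probeset's normalized expression to clinical covariates
(condition, gender, age of onset, stage, ...), the package grows a
conditional-inference-style regression tree:

1. At each node, test the global null that the response is independent of
   every covariate. Each covariate gets a **permutation test**: the
   statistic is $|r_{Pearson}|$ for numeric covariates and the largest
   absolute standardized group-mean deviation
   $\max_g \sqrt{n_g}\,|\bar y_g - \bar y|/s_y$ for categorical ones;
   the response is permuted `nPermutations` times (default 9999) and
   $p = (1 + \#\{stat_{perm} \ge stat_{obs}\})/(B+1)$, so the smallest
   attainable p-value is $1/(B+1)$. Per-covariate p-values are
   Bonferroni-adjusted by the number of testable covariates; the global
   test is their minimum.
2. Stop if the adjusted minimum exceeds `alpha` (default 0.05) — a
   single-leaf tree is the expected outcome on null data, and the test
   suite checks that the root-level family-wise error stays at `alpha`.
3. Otherwise split the selected covariate at its **ANOVA-optimal** point:
   numeric covariates at the midpoint between consecutive sorted unique
   values maximizing the two-group F statistic (ties to the smallest
   threshold), binary categorical covariates by their two values, and
   categorical covariates with $3 \le k \le 8$ levels by exhaustive
   enumeration of the $2^{k-1}-1$ two-group level partitions. Both
   children must keep `minLeafSize` (default 5) samples; nodes below
   `minNodeSize` (default 10) or at `maxDepth` (default 4) become leaves.
4. Recurse.

Variable selection is kept separate from split search, which avoids the
selection bias of exhaustive-search trees. Permutation p-values are used
instead of the asymptotic conditional-inference distribution: at the
sample sizes of paired clinical designs (tens of samples) the exact
Monte-Carlo test is both simpler and more honest, and it makes the floor
$1/(B+1)$ explicit. Missing covariate values are excluded pairwise at
test time; samples missing the chosen split variable follow the larger
child (no surrogate splits). All randomness flows from a single seed in
`treeControl()`, so identical inputs give identical trees.

`condition` is included as a candidate covariate by default when trees
are grown per probeset (`probesetTrees()`): if a probeset's expression
tracks gender or an age threshold rather than disease status, the tree
says so explicitly — the main reason to run the multivariate analysis at
all. Fitting within condition strata is available by excluding
`condition` from the candidates.

## The synthetic-data generator

Real exon-array studies of paired normal/tumor designs (e.g. 14
colorectal or 13 renal cancer pairs) are emulated by a generative model:

$$x_{ps,s} = \mu_g + a_{ps} + c_g\,1(s\ path) + \delta_{ps}\,1(s\ path)
  + \textstyle\sum \text{covariate effects} + \varepsilon_{ps,s}$$

with gene baselines $\mu_g \sim N(7, 1)$ (log2 units), probeset
affinities $a_{ps} \sim N(0,1)$ fixed across samples (emulating the probe
affinity structure RMA leaves behind, without re-implementing RMA), noise
$\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.25$ by default, and
planted effects applied to pathological samples only. Defaults
$\delta = 1$ and $c_g = 1$ log2 units (two-fold) are this package's
choices of a realistic effect size; no published magnitudes exist for the
motivating datasets, so all are exposed in `simulationConfig()`.

* *Cassette events* subtract $\delta$ from one probeset (the exon is
  skipped in disease, so the normal signal is higher and the expected SI
  sign is positive).
* *Mutually exclusive events* add $\delta$ to one probeset and subtract
  it from the adjacent exon's probeset; the isoform annotation places the
  two exons in disjoint isoforms so the report's isoform matrix shows
  they never co-occur.
* Gender and age (Uniform(40, 80), making an age-of-onset threshold of 60
  interior) are drawn per patient, shared by both samples of a pair and
  therefore exactly independent of condition. Covariate *effects* are
  only planted when requested, on non-event probesets, for samples above
  a numeric threshold or at a categorical level.
* Unexpressed (*background*) probesets fall to a low constant intensity
  and draw DABG p-values from Uniform(0, 1); expressed probesets draw
  from Uniform(0, 0.01).

Truth tables record every planted event with its expected SI sign, so
recovery tests are sign-exact. Identical configuration and seed give
byte-identical datasets.

What the generator deliberately does **not** emulate: probe-level
structure (it starts where RMA ends), batch or scanner effects,
correlated noise between neighboring exons, patient-specific expression
offsets, and heavy-tailed intensity distributions. Passing tests
therefore demonstrate correctness of the statistics under the stated
model, not robustness to every artifact of real arrays.

## Problem sizes and reproducibility

The test suite and the acceptance script work at desk scale: null
calibration on 2000 probesets (250 genes × 8 probesets, 15 pairs),
recovery on 200 planted events at 1000 genes, tree properties over
100–500 seeded replicates with 999 permutations per test. These sizes
give Monte-Carlo error well inside the asserted bands while keeping a
full run in minutes. The `analyze` pipeline records a JSON manifest
(package version, parameters, row counts, seed), and re-running any stage
with the same inputs reproduces byte-identical tables.

## Known limitations

* The MiDAS realization is plain one-way ANOVA on cluster-normalized
  values; the vendor's unpublished stabilization constant is omitted.
* Whether the Splicing Index should average normalized log values (done
  here, standard for RMA outputs) or log the ratio of group-mean linear
  values is a genuine ambiguity; the difference is second-order at these
  noise levels.
* Stage is treated as plain categorical; no ordinal-aware splitting.
* The search defaults (`defaultASQuery()`) are reconstructions, and
  min–max scaling is provided but z-scoring is the default since no
  published scaling is specified.
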