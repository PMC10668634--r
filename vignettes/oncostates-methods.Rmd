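---
title: "Methods: cell-state decomposition and enrichment analysis for dual-identity lung cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-state decomposition and enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncostates)
```

# The analysis problem

When an oncogenic Ras allele is activated in alveolar type II (AT2)
cells of the mouse lung, a population appears that co-expresses AT2
markers (Sftpc) and alveolar type I (AT1) markers (Rage, Podoplanin).
Characterizing these *dual-positive* cells transcriptionally involves a
small, well-defined chain of computations on bulk RNA-seq of sorted
populations (type I, type II, dual-positive; three replicates each):

1. unsupervised sample clustering by non-negative matrix factorization
   (NMF);
2. derivation of cell-type gene signatures from reference expression
   panels (top-100 most differentially expressed genes per cell type);
3. per-sample signature scoring by single-sample gene-set enrichment
   (ssGSEA);
4. association of each score profile with the dual-positive phenotype
   by the information coefficient (IC) with an empirical permutation
   test;
5. projection of the study samples onto an Onco-GPS style state map
   built from an oncogene-responsive gene module in a cell-line
   compendium;
6. per-gene differential expression for the dual-positive vs type II
   contrast; and
7. two bespoke bench quantifications: qPCR fold changes by the
   delta-delta-CT rule, and marker-gated population percentages from
   flow-cytometry-like intensity data.

This package implements each stage as a tested, reusable function and
couples them to a synthetic-data module that generates inputs with the
statistical structure the analysis assumes, so every claim the pipeline
makes can be verified by parameter recovery on planted ground truth.

# Statistical methods

## Rank-normalized enrichment scoring (ssGSEA)

Within each sample, expression values are rank-normalized: ascending
ranks (average ties) mapped to $(0, 1]$ by $r/n$. For a gene set $S$
and the genes ordered by decreasing normalized rank $r_{(i)}$, the
enrichment score is the running-sum total of the difference between the
weighted in-set ECDF and the out-of-set ECDF:

$$ES = \sum_{i=1}^{n}\left[\frac{\sum_{j \le i,\, j \in S} r_j^{\,w}}
{\sum_{j \in S} r_j^{\,w}} -
\frac{|\{j \le i,\, j \notin S\}|}{n - |S|}\right].$$

Positive scores mean the set concentrates at the top of the sample's
ranking. The area (running-sum total) form is used rather than the
maximum deviation, matching the ECDF-difference description of the
scoring; with $w = 0$ the statistic reduces to the unweighted
running-sum total. The weight exponent defaults to $w = 0.75$, the
widely used ssGSEA default; it is configurable, and a brute-force
double-loop implementation of the same definition serves as the test
oracle (agreement to $10^{-12}$). Scores depend on the data only
through within-sample ranks, so any strictly monotone per-sample
transform of expression leaves them unchanged — this makes the stage
indifferent to whether inputs are TPM, FPKM or log counts. Sets
overlapping the gene space by fewer than 5 genes are dropped (degenerate
signatures). No cross-sample renormalization is applied by default;
an optional min-max rescaling is available behind a flag, since whether
the original heatmaps were renormalized is not stated anywhere.

## Information coefficient

The IC between a score profile $x$ and a phenotype $y$ is

$$IC = \operatorname{sign}(\rho)\sqrt{1 - e^{-2\,MI(x, y)}} \in [-1, 1],$$

with $\rho$ the Pearson correlation and $MI$ the mutual information
(nats) of the pair. $MI$ is estimated by a bivariate Gaussian kernel
density on a $25 \times 25$ grid over standardized values. The
bandwidth is Silverman's rule for unit-variance data, doubled for bias
control and shrunk as correlation grows:

$$h = 2 \cdot 1.06\, n^{-1/5} (1 - 0.85\,|\rho|).$$

The shrinkage keeps mass concentrated along the ridge of highly
correlated pairs (the same intent as scaling a minor-axis bandwidth),
while the doubling suppresses the upward MI bias of kernel estimates
under independence. No authoritative bandwidth constant exists for this
estimator in the literature chain it comes from, so the estimator's
*contract* is the bivariate-Gaussian closed form: for Gaussian pairs
$MI = -\frac12\ln(1-\rho^2)$, hence $IC = |\rho|$ with the sign of
$\rho$. The implementation is required (and tested) to recover
$\rho \in \{0.3, 0.6, 0.9\}$ within $\pm 0.05$ at $n = 5{,}000$, to keep
mean $|IC| < 0.1$ under independence at $n = 1{,}000$, and to exceed
$0.95$ for self-association at $n = 100$. These three constraints
pinned the two bandwidth constants before any other test was written;
they have not been revisited since.

Binary phenotype vectors are jittered by $10^{-6}$ Gaussian noise
(fixed internal stream, so the IC stays a pure function of its
arguments) to avoid degenerate densities.

Significance is an empirical permutation test: $y$ is shuffled with a
seeded generator and the two-sided add-one p-value is
$p = (1 + \#\{|IC^*| \ge |IC_{obs}|\})/(n_{perm} + 1)$, bounded below
by $1/(n_{perm}+1)$. With nine samples only $9!$ distinct label
permutations exist, and a binary three-vs-six phenotype admits just 84
distinct partitions; permutations are therefore sampled with
replacement and the attainable p-value floor is about $1/84$ plus the
add-one correction, which the tests account for. Across a collection,
Benjamini–Hochberg FDR is applied over sets and results are sorted by
IC descending.

## NMF and sample clustering

Factorization minimizes the Frobenius error $\|V - WH\|_F$ by
Lee–Seung multiplicative updates, whose monotone non-increase is
provable and is asserted at every iteration in the tests. Defaults: 20
random restarts (best final objective wins), convergence at relative
objective change $< 10^{-6}$ or 2,000 iterations, all driven by one
seed via fixed per-restart child seeds. Log-scale input containing
negative values is shifted by its global minimum before fitting (the
input scale of the original analysis is unstated; min-shifting
preserves the sample geometry that clustering uses and the shift is
recorded in the model). Factors are named F0..F(k-1). Samples are
assigned to the factor with the largest coefficient in their column of
$H$, ties to the lowest index.

One normalization point deserves a note: a specification of "H columns
L1-normalized with scale absorbed into W" is not realizable — a
per-sample column scale cannot be absorbed into a shared $W$. The
package instead L1-normalizes the *columns of W* (absorbing scale into
the rows of $H$), which preserves $WH$ and the objective trace, and
exposes per-sample factor weights (columns of $H$ renormalized to sum
to one) through `sampleWeights()`; clustering and map projection
consume those weights, which is what column normalization was for.

Because NMF is non-unique, the independent-oracle test compares the
*objective value* (not the factors) against scikit-learn's NMF on
random fixtures, requiring agreement within 1%.

## Onco-GPS style state maps

The map is a reference decomposition of an oncogene-responsive module:
the reference matrix restricted to the module genes (at least 80%
present) is factorized at `kNodes = 9` (the node count of the published
Ras map), each factor becomes a node placed at equally spaced positions
on the unit circle ordered by factor index (a deterministic convention
replacing force-directed layout — only relative geometry is ever
interpreted), and reference samples are grouped into `nStates`
transcriptional states by k-means on their factor-weight profiles. The
k-means is a seeded in-package Lloyd implementation with k-means++
initialization and 50 restarts, checked against `stats::kmeans` inertia
within 1%.

New samples are projected by non-negative least squares onto the frozen
basis (multiplicative updates on $H$ only, deterministic uniform
initialization), giving weights $w$ that sum to one, and placed at the
power-normalized pull position

$$xy = \frac{\sum_j c_j\, w_j^{\,p}}{\sum_j w_j^{\,p}}, \qquad p = 2,$$

a convex combination of node coordinates, so projections always lie in
the node hull; larger $p$ sharpens the pull toward dominant nodes.
Each projected sample inherits the state of its nearest reference
sample in weight space rather than being re-clustered: states are
defined by the reference panel. State labels on synthetic maps are
numeric; naming states after pathways requires the external compendium
and is out of scope.

## Differential expression and signatures

Per-gene two-sample t-tests on the log-scale matrix, BH-adjusted across
genes. The default is the classical pooled-variance Student test: with
three samples per group it holds its nominal size, whereas the Welch
correction is noticeably conservative at that depth (empirical level
near 0.03); Welch remains available (`test = "welch"`), and both modes
are oracle-checked against `stats::t.test` to $10^{-10}$. Alongside the
t statistics, a signal-to-noise ratio
$(\mu_A - \mu_B)/(s_A + s_B)$ is reported with each group sd floored at
$\max(0.2\,|\mu|,\ 0.2)$ — the long-standing GSEA convention that keeps
the statistic stable when variances are estimated from three values.

Signatures are derived one-vs-rest: the focal cell type against all
other samples of its panel pooled, genes ranked by SNR descending and
the top $n$ (default 100) kept. Upregulated-only ranking is the
default, because the signatures are consumed as enrichment probes where
positive markers are standard; ranking by $|SNR|$ is available
(`direction = "abs"`). Ties break lexicographically by gene id, making
derivation deterministic and invariant to sample order. Increasing
$n$ yields nested signatures.

## Bench quantifications

Fold change follows the delta-delta-CT rule
$FC = 2^{-\Delta\Delta CT}$ with
$\Delta CT = CT_{target} - CT_{housekeeping}$ per condition and
$\Delta\Delta CT = \Delta CT_{treated} - \Delta CT_{control}$;
replicate CTs are averaged before normalization (the per-replicate
alternative is not used; the source protocol does not specify). The
printed form of the rule in the source protocol subtracts a raw $CT$
from a $\Delta CT$, which is dimensionally inconsistent; it is read as
the standard $\Delta CT$ difference.

Gating assigns each cell a population label from the $\pm$ sign
pattern of its marker intensities against fixed thresholds; the rule
table must partition the sign-pattern space, counts are conserved and
percentages sum to exactly 100. Thresholds are inputs (no automatic
gate inference); the default gate uses midpoints between the synthetic
negative and positive marker levels. Population fractions are compared
with a Haldane-corrected odds ratio and a two-sided Fisher exact test
(`stats::fisher.test`, verified against full hypergeometric enumeration
in the tests).

# The synthetic-data module

All generators are pure functions of (parameters, seed); a global seed
fans out to per-operation child seeds by fixed offsets.

**Study matrix.** Log2-scale model: per-gene baseline mean
$\sim N(5, 1)$, plus planted program shifts per group, plus Gaussian
noise. The default design mirrors the source study at desk scale:
2,000 genes, three groups of three samples (typeI, typeII, dualpos),
and three disjoint 150-gene programs — a typeI program up (+2 log2) in
typeI *and* dualpos, a typeII program up in typeII *and* dualpos, and
an embryonic-progenitor program up only in dualpos. That is the level
at which "dual-positive cells share properties of both single-positive
types" is literally true of the generator: planted effect signs. The
per-gene noise sd of 0.3 log2 units is a typical between-replicate
variability for sorted-population bulk RNA-seq; +2 log2 is a strong
marker-grade effect. A log2-Normal model is used rather than
negative-binomial counts because every consumer is either rank-based
(ssGSEA), geometry-based on shifted-positive values (NMF), or a plain
t-test on log values — count-level detail would add machinery without
adding test power.

**Reference panels.** Three panels on the same 2,000-gene universe,
each with two cell types of four samples and one 150-gene program
(+3 log2, sd 0.2) per type: an early-progenitor panel (progenitor
program = the study's embryonic genes; differentiated = the typeII
program), a late-progenitor panel (program half-overlapping the
embryonic one; differentiated = typeI program), and an adult panel
(AT1 = typeI program, AT2 = typeII program). The deliberate half
overlap mirrors the biology in which dual-positive cells resemble both
early and late progenitors — with the consequence, visible in the
association output, that the two derived progenitor signatures separate
the dual-positive group equally well and their ICs tie to within
$10^{-4}$. Tests therefore assert the recoverable form of the ranking
claim: both progenitor signatures above every differentiated signature,
and the unambiguous planted-program version (via `programGeneSets()`)
strictly first.

**Cell-line module panel.** The module rows (1,000 genes by default,
drawn from the same universe so study samples can be projected) carry
an exact nonnegative rank-3 structure — three latent states, each cell
line one-hot on its state plus a small uniform leak — scaled and
perturbed by clipped Gaussian noise (sd 0.05 by default; zero noise
gives an exactly factorizable matrix, which the tests exploit). 200
background genes carry unstructured positive values.
`addStateActivity()` plants one state's standardized mean module
profile into chosen study samples (default amplitude 2 log2 units) so
that projection can be validated as label recovery.

**Cells and CT tables.** Cell labels are multinomial in the requested
fractions; marker intensities are independent Gaussians per label on a
log10 scale (sd 0.5), with the negative level at 0.5 and the positive
at 4.5 so that midpoint gates at 2.5 sit four sds from either
population and misclassification is negligible against the binomial
sampling error the recovery tests allow (3 standard errors at
$n = 10^5$). Dual-positive cells are high on both markers. The default
dual-positive abundance is the 2.6% reported for oncogene-activated
mouse lung epithelium, with the remainder split roughly 1:2 between AT1
and AT2 as in alveolar epithelium. CT tables are built by inverting the
delta-delta-CT rule (housekeeping CT 18, control target CT 24), so the
zero-noise round trip is exact by construction.

**What the generator does not emulate.** Count noise and
library-size effects, gene–gene correlation beyond the planted block
structure, batch effects, dropout, and the actual distributions of any
deposited dataset. Passing tests demonstrate that the implementations
recover what was planted under the stated models — they are correctness
and calibration evidence, not evidence about any particular real
dataset.

# Problem sizes and runtime choices

The default desk-scale sizes — 2,000 genes, 9 study samples, 8-sample
panels, 60 cell lines, $10^5$ gated cells, 1,000 permutations in the
pipeline — keep a full pipeline run around twenty seconds and the whole
test suite around two minutes on a single core, while leaving every
recovery property comfortably identified. `buildMap()` defaults to 10
NMF restarts (the rank-9 module fit is the heaviest step and the
planted rank-3 structure needs far fewer); `fitNmf()` keeps 20.

# Known limitations

- The IC estimator's bandwidth constants are validated against the
  Gaussian closed form, not against any particular historical
  implementation; ICs on strongly non-Gaussian data may differ from
  other IC codebases in the second decimal.
- With nine samples the permutation p-value floor (~0.013 for a
  three-vs-six phenotype) and the BH correction over a handful of sets
  limit attainable significance; this matches the source setting and
  is documented rather than worked around.
- NMF restarts make the *objective* reproducible; the factors
  themselves are identified only up to permutation and scale, which is
  why cluster assignments and weight profiles (not raw factors) are the
  tested artifacts.
- No count-model differential expression (no dispersion shrinkage): at
  three replicates of sorted bulk populations the t-test on log values
  is the method being reproduced, not improved upon.
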