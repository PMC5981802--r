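---
title: "Methods: individual morphological networks from energy distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual morphological networks from energy distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `morphnet`, the
assumptions behind them, and the design choices made where the underlying
methodology leaves room. It states no empirical result beyond what the
package's test suite and `scripts/acceptance.R` themselves compute.

## The edge statistic

A subject's network has one node per cortical region of a parcellation
(default: the 68-region Desikan-Killiany atlas, 34 gyral regions per
hemisphere) and an edge weight for every region pair. The weight is built
from the two-sample energy distance between the regions' vertex-wise
feature multisets $A = \{a_1,\dots,a_{n_1}\}$,
$B = \{b_1,\dots,b_{n_2}\}$, $a_i, b_j \in \mathbb{R}^d$:

$$ e(A,B) = \frac{n_1 n_2}{n_1+n_2}\left(
  \frac{2}{n_1 n_2}\sum_{i,j}\lVert a_i-b_j\rVert_2
  - \frac{1}{n_1^2}\sum_{i,j}\lVert a_i-a_j\rVert_2
  - \frac{1}{n_2^2}\sum_{i,j}\lVert b_i-b_j\rVert_2\right). $$

Three properties matter here. It is symmetric; it is non-negative, with
equality exactly when the two empirical distributions coincide (the energy
statistic property); and it is sensitive to the whole distribution, so a
focal abnormality inside a region is not washed out by averaging, unlike
mean-based similarity measures. It is translation-invariant in feature
space and scales linearly under uniform feature scaling — both asserted as
property tests.

Per subject, off-diagonal distances are affinely rescaled so their
minimum is 0 and maximum 1 (removing per-subject range differences), then
mapped through $c = \exp(-e_n)$. Two consequences are deliberate:

- **The min/max is taken over off-diagonal entries only.** Including the
  structural zero diagonal would force the minimum to 0 for every subject
  and degrade the normalisation to a pure max-scaling. As a result the
  off-diagonal similarities occupy $[e^{-1}, 1]$, not $(0, 1]$; the most
  dissimilar pair of regions in every subject maps to exactly $e^{-1}$.
  The diagonal is pinned to 1 by definition.
- **Feature standardization defaults on for $d > 1$.** Thickness (mm),
  area (mm²) and volume (mm³) have incommensurable units; without
  harmonisation the largest-scaled feature dominates the 2-norm. Each
  feature column is z-scored with mean/SD pooled over all vertices of the
  subject. For $d = 1$ the distance is scale-equivariant and the
  subsequent min-max normalisation removes the scale entirely, so
  standardization is a no-op and defaults off. The flag is recorded in the
  matrix's provenance so either behaviour is reproducible.

Numerical choices: pairwise norm sums are computed from coordinate
differences (`stats::dist`) rather than the Gram expansion
$\lVert a\rVert^2+\lVert b\rVert^2-2a^\top b$, which loses enough
precision on near-duplicate vertex pairs to matter at the $10^{-10}$ level;
summation order is fixed, so rebuilds are bit-identical (vertex row order
in the input is irrelevant by construction). Energy distances in
$[-10^{-10}, 0)$ — floating-point noise around the theoretical lower bound
of 0 — are clipped to 0; anything more negative raises an error rather
than being silently repaired.

## Graph analysis

Weighted matrices are binarised by **sparsity**: at sparsity $S$ the
$\mathrm{round}(S \cdot V(V-1)/2)$ strongest edges are kept. Ties at the
cutoff are broken by lexicographic (row, column) order so graphs are
reproducible. Analyses sweep $S$ from 20% to 40% in 1% steps — below ~20%
graphs of this size start to fragment, above ~40% topology differences
wash out — with 23% used as the conventional single operating point.

Metrics are computed on the binary graph (via igraph): Watts–Strogatz
clustering $C_p$ (nodes of degree < 2 contribute 0), characteristic path
length $L_p$ as the mean over reachable ordered pairs (unreachable pairs
are excluded and counted; an alternative would be harmonic means, but
exclusion matches common connectome toolkits), exact betweenness with even
splitting over tied shortest paths, and hubs as nodes whose betweenness
exceeds the mean plus one **population** (divide-by-N) standard deviation —
a fixed convention chosen for reproducibility.

Small-world indices are referenced to a null ensemble with the same
number of nodes and edges. The default null additionally preserves each
node's degree (Maslov–Sneppen double-edge swaps, $10\lvert E\rvert$
attempted swaps, 100 null graphs), the field-standard stricter choice; an
Erdős–Rényi $G(n,m)$ null is available where only node/edge counts should
be matched. $\gamma = C_p/\bar C_p^{null} > 1$ together with
$\lambda = L_p/\bar L_p^{null} \approx 1$, summarised as
$\sigma = \gamma/\lambda > 1$, indicates small-world organisation.

## Test-retest reliability

Reliability of a graph property across two scan sessions uses the one-way
random-effects intraclass correlation (single-rater ICC(1,1)), the direct
estimator of $\sigma^2_b/(\sigma^2_b+\sigma^2_w)$: with $n$ subjects and
$k$ sessions, $\widehat{ICC} = (MSB - MSW)/(MSB + (k-1)MSW)$, with an F
test of the between-subject effect ($p < 0.05$ flags significance).
Sessions are not modelled as a fixed factor — the variance decomposition
has exactly two components, so more elaborate two-way variants would
estimate parameters the model does not contain. Negative estimates
(possible when true between-subject variance is near zero) are reported
as computed and flagged, never truncated, since truncation hides exactly
the information a reliability analysis is after. For per-node betweenness
the node-wise ICCs are averaged into one curve point per sparsity, with
the per-node table returned alongside; values above 0.75 are
conventionally rated excellent and 0.59–0.75 good.

## Classification

Edges (the 2278 upper-triangle entries at $V = 68$, in fixed row-major
order) are the features; labels are +1 (patients) and −1 (controls), and
sensitivity is defined on the +1 class. Per leave-one-out fold:

1. columns are standardized using the training rows only;
2. the Lasso $\min_w \tfrac12\lVert Xw-y\rVert_2^2 + \lambda\lVert
   w\rVert_1$ is solved on the training rows (glmnet, mapped exactly onto
   this objective: no intercept, no internal standardization,
   $\lambda_{glmnet} = \lambda/n$, convergence threshold $10^{-14}$);
3. both sets are restricted to the selected edges and a soft-margin SVM
   with kernel $K(x_1,x_2) = \exp(-\lVert x_1-x_2\rVert^2/2\sigma^2)$ is
   trained; the held-out prediction and decision value are recorded.

$\lambda$ defaults to per-fold selection by inner 5-fold cross-validation
over a logarithmic path; a fixed-$\lambda$ mode is available. If a fold
selects nothing, it falls back to all edges (logged) so the LOOCV total
stays intact. The $(C, \sigma)$ grids default to $2^{-5..15}$ and
$2^{-15..3}$ by powers of 4.

Two grid-search protocols are implemented. The **literal** default picks
$(C, \sigma)$ maximising the LOOCV accuracy itself — the protocol common
in the applied literature, which is optimistically biased because the
selection sees every fold's outcome. The **nested** mode chooses
hyperparameters per fold by inner cross-validation on the training set
only, giving an unbiased estimate. Reports carry the protocol tag.
Because the literal protocol's max-over-grid step is biased upward under
the null by construction, the package's permutation control (shuffled
labels) is evaluated at a single fixed hyperparameter point, where LOOCV
accuracy is expected to fall in the binomial chance band; only then does
the control isolate information leakage rather than selection optimism.

Aggregation: an edge is **discriminative** only if selected in *every*
fold (strict intersection); discriminative edges are tagged intra-left /
intra-right / inter-hemispheric and correlated (Pearson, two-sided,
unadjusted $p < 0.05$) with clinical scores. AUC is the Mann–Whitney
pair-counting statistic (ties half-weighted), identical to the area under
the threshold-sweep ROC curve.

## Comparison similarity measures

Five published single-feature alternatives run behind the same pipeline,
taking each region's thickness summary (mean $T$, SD $\sigma$, mean
absolute deviation, vertex count):

- **Distribution KL** (`kong`): symmetric Kullback–Leibler divergence
  between Gaussian-kernel density estimates of the two thickness samples,
  $c = e^{-KL}$. KDE uses Silverman's bandwidth per region, a shared
  512-point grid spanning the pooled range ± 3 bandwidths, and a density
  floor of $10^{-12}$ before logs.
- **Mean z-score** (`kim`): $c = (Z(i,j)+Z(j,i))/2$ with
  $Z(i,j) = (T_i-T_j)/\sigma_j$. As printed this is symmetric under
  swapping $(i,j)$ — the two Z terms merely exchange — but signed;
  thresholding ranks by magnitude while the signed value is kept as a
  classification feature.
- **Spread-scaled Gaussian** (`wee`):
  $c = \exp(-(T_i-T_j)^2 / 2(\sigma_i+\sigma_j)^2)$.
- **Free-scale Gaussian** (`dai`): $c = \exp(-(T_i-T_j)^2/\eta)$ with
  $\eta$ an input parameter; the default self-tunes $\eta$ to the median
  squared mean difference over the subject's region pairs, placing the
  similarity scale mid-range for any cohort.
- **Dispersion ratio / squared difference** (`zheng`): two statistics,
  $c_{precision} = \overline{|t_i - T_i|}/\overline{|t_j - T_j|}$
  (reciprocal under swap) and $c_{rough} = (T_i-T_j)^2$. The source
  defines no fusion into a single network; the default network passes
  $c_{rough}$ (distance-like) through the same min-max + exponential map
  as the energy construction, with the $c_{precision}$ matrix attached as
  an auxiliary attribute — flagged prominently in provenance since this
  fusion is this package's choice.

## The synthetic cohort generator

The generator emulates what the pipeline consumes — FreeSurfer-like
per-vertex feature tables — with known ground truth. Per region, vertex
features are i.i.d. Gaussian with region-specific means (drawn once per
spec seed around realistic bases: thickness ≈ 2.5 ± 0.3 mm, area ≈ 0.6 ±
0.2 mm², volume ≈ 1.5 ± 0.5 mm³, sulcal depth / metric distortion /
curvature dimensionless) so the mixed-unit standardization question is
genuinely exercised. Subject, session, and group effects shift regional
means in units of the per-vertex spread; defaults are a between-subject
scale of 0.2 and a test-retest session scale of 0.1, modest parameter
perturbations of the kind short-interval rescanning produces. Vertex
counts per region are drawn uniformly from 40–120, a deliberately
down-sampled surface that keeps the $O(n^2)$ distance sums desk-scale.

Test-retest pairs share the subject's vertex *realization* (counts and
standardized deviates); session noise perturbs the regional mean
parameters, not the sampled vertices. This models the two scans as
re-measurements of the same anatomy under parameter drift, and gives the
clean limit that zero session noise yields identical tables — so any
deterministic property has ICC exactly 1, which anchors the reliability
tests. Two-group cohorts scale the planted shift per patient by a
positive severity factor, and clinical scores are coupled to severity
(MMSE-like, clipped to [0, 30]; CDR-like, snapped to {0, 0.5, 1, 2, 3})
so discriminative edges genuinely correlate with scores.

What the generator does **not** emulate: spatial autocorrelation across
the cortical surface, non-Gaussian feature distributions, scanner/site
effects, realistic vertex counts (thousands per region), or registration
and smoothing artefacts. Passing tests therefore demonstrate correctness
of the statistics and the pipeline's behaviour under its assumed model,
not performance on real scans.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale by choice: oracle
equivalence on 200 random region pairs ($n \le 30$, $d \le 6$);
small-world checks on 68-node Watts–Strogatz graphs ($k = 14$, rewiring
0.1, 100 nulls); ICC parameter recovery on a 3×3 grid of variance
components at $n = 500$ subjects; classification on an 80-subject planted
cohort with reduced hyperparameter grids; KDE-vs-closed-form KL at
$n = 10{,}000$ samples. Every stochastic step is seeded, and generators,
rewiring, and fold assignment restore the caller's RNG state.

## Known limitations

- Binary graph metrics only; weighted variants are out of scope.
- The energy construction needs every atlas region non-empty; missing
  regions are an error, not imputed.
- Global $C_p$/$L_p$ reliability on default synthetic cohorts is modest —
  global summaries of an 80%-sparse graph are insensitive to the small
  parameter perturbations the generator plants, while per-node
  betweenness retains more between-subject signal; real-cohort ICC values
  need not match.
- The literal grid-search protocol overstates accuracy; use the nested
  mode when an unbiased estimate matters.
- KDE-based KL (`kong`) is biased slightly downward at finite $n$
  (smoothing makes densities more alike); comparisons against analytic
  divergences carry a KDE-level tolerance.
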