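---
title: "Liking product landscapes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liking product landscapes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(lpland)
```

A liking product landscape (LPL) is a way of reading an entire consumer
panel off one picture. Consumers rate a set of products for overall liking
on a 9-point hedonic scale and for the intensity of sensory attributes on
5-point just-about-right (JAR) scales, coded −2 (far too little) through 0
(just about right) to +2 (far too much). Each consumer thereby becomes a
vector $x_i \in \mathbb{R}^d$; the package maps those vectors to the plane,
estimates where consumers concentrate, and fits one regression landscape
per evaluation over the shared map. Because every landscape uses the same
coordinates, the analyst can ask located questions: do the consumers who
dislike this wine also find it too sweet?

This vignette records the models the package implements, the parameters
that matter, and the design decisions taken where the methodology is
genuinely open.

## The consumer map

Three embedding techniques are provided, all returning consumers as rows of
an $n \times 2$ coordinate matrix.

**PCA** (`embed_pca()`) projects the column-centered consumer matrix onto
its first two principal components. Columns are centered but not scaled by
default: hedonic values (1–9) and signed JAR values (−2..+2) have
comparable dispersion in practice, and standardization would inflate
near-constant attributes. A `standardize` flag exists for panels where the
mixing is a concern. Component signs are fixed (the largest-magnitude
loading of each component is made positive) so maps are reproducible across
runs and BLAS implementations.

**IPM** (`embed_ipm()`) is the classic internal preference map: a PCA of
the products-by-consumers overall-liking matrix, products as observations
and consumers as variables. Products become score points; each consumer
becomes a preference vector, its loading on each component multiplied by
the variance of the product scores on that component. "Variance of the
product points" admits several readings (variance vs. standard deviation,
per component vs. total); the per-component variance was chosen and is
recorded in the embedding metadata so alternates can be compared. The
biplot inner product between a consumer vector and a product point then
reconstructs that consumer's centered grade, which is what "arrows point
toward preferred products" means operationally.

**Metric MDS** (`embed_mds()`) preserves the Euclidean distances $d_{ij}$
among consumer vectors. The implementation is SMACOF majorization of the
raw stress $\sum_{i<j} (d_{ij} - \hat d_{ij})^2$, started from the
classical (Torgerson) solution; the Guttman transform guarantees the raw
stress never increases, which the test suite asserts on every fitted
trace. Fit quality is reported as normalized Kruskal stress-1,
$\sqrt{\sum_{i<j}(d_{ij}-\hat d_{ij})^2 / \sum_{i<j} d_{ij}^2}$. The
classical start makes the procedure deterministic in practice; the `seed`
only jitters rank-deficient starting configurations. Because any MDS
solution is free to rotate and reflect, the final configuration is rotated
to its own principal axes with the same sign convention as PCA, so figures
are comparable across runs.

Data modes select what feeds the map: `OL` (overall liking only,
$d = P$), `JAR` (attribute perceptions, $d = P\cdot A$) or `OLJAR` (both,
$d = P(A+1)$). Column order is products-major, measures-minor, both
lexicographic — one fixed contract so that every downstream matrix is
bit-for-bit reproducible regardless of input row order.

## The consumer distribution map

Consumer density on the map is a sum of isotropic bivariate Gaussian
kernels,

$$p(x) = \frac{1}{2\pi n h^2} \sum_{i=1}^n
  \exp\!\left(-\frac{\lVert x - x_i^*\rVert^2}{2h^2}\right),$$

with the Scott-rule bandwidth $h = n^{-1/6}$. Two readings of the kernel
exponent circulate; only the $2h^2$ denominator makes the stated
$1/(2\pi n h^2)$ prefactor normalize to unit mass, so that is the default,
and the tests verify unit mass by trapezoid quadrature and the closed-form
single-kernel peak $1/(2\pi h^2)$. The alternative reading (exponent
divided by $2h$) is available behind `as_printed = TRUE` for side-by-side
comparisons; the two coincide only at $h = 1$. Note that $n^{-1/6}$ is
Scott's bivariate rule for unit-variance data; coordinates are deliberately
used unstandardized, exactly as the rule is stated for this methodology, so
the effective smoothing depends on the spread of the embedding.

The evaluation grid (`make_grid()`) spans the consumer bounding box
expanded by 15% per side with 200 × 200 nodes — finer than any plotted
figure, and shared between the density field and every acceptance surface
so the layers superimpose without interpolation.

## Acceptance surfaces and the percentage error

For one evaluation (one product's overall liking, or one product ×
attribute JAR) with grades $g_1,\dots,g_n$, the package fits either

* **QUA**, the Danzart-style quadratic
  $f(d_1,d_2)=\alpha_0+\alpha_1 d_1+\alpha_2 d_2+\alpha_3 d_1^2
  +\alpha_4 d_2^2+\alpha_5 d_1 d_2$ by ordinary least squares (rank
  checked; collinear maps are refused with a rank error), or
* **SVM**, ε-insensitive support-vector regression with a Gaussian kernel
  over the 2-D coordinates.

Fit quality is the percentage error
$100 \cdot \mathrm{MAE} / s$, where $\mathrm{MAE} = \frac1n \sum_i
|f(x_i^*) - g_i|$ and $s$ is the number of points of the evaluation scale
(9 hedonic, 5 JAR — the category count, not the range; a `use_range` flag
gives the range variant). Two properties deserve emphasis. First, the
error is computed on the training consumers: it is a descriptive measure
of how faithfully the landscape renders the panel, not a generalization
estimate. Second, dividing JAR MAEs by 5 and hedonic MAEs by 9 makes the
two families comparable on one 0–100 axis, which is what the benchmark
averages.

SVR hyperparameters default to cost $C = 1$ and tube width
$\varepsilon = 0.1$ scale units, with the kernel width
$\gamma = 1/(2\,\bar v)$, where $\bar v$ is the mean per-axis variance of
the map coordinates. This is the variance-scaled default of mainstream SVR
implementations, and it is what keeps the support-vector landscapes more
flexible than the quadratic at realistic noise levels; a wider kernel
(e.g. one derived from the mean pairwise squared distance,
`svm_pairwise_gamma()`) oversmooths two-segment panels to the point where
the quadratic can match it. Computing $\bar v$ axis-wise makes the default
invariant under rigid motions of the map, so the percentage error does not
depend on the arbitrary orientation of the embedding. Hyperparameters are
recorded in every output; `svm_grid_search()` exists for exploration but is
never applied implicitly, so default results stay deterministic.

## The composite landscape

`compose_lpl()` overlays the acceptance surface and the consumer
distribution: surface color follows the evaluation's key (hedonic:
diverging blue 1 → red 9; JAR: dark blue −2, blue −1, green 0, yellow +1,
red +2, continuously interpolated), and per-node opacity is the density
normalized by its own maximum. Max-normalization is one of several
possible alpha mappings; it is the one that guarantees both stated
endpoint behaviors — regions without consumers are fully white, the
densest region fully opaque. Density contours (equally spaced levels in
$(0, \max p]$) and the consumer points, colored by their own grades, are
drawn on top. Annotations (mean grade, percentage of consumers at JAR = 0,
percentage error) are recomputed from the raw table and tested to agree
with it to $10^{-9}$.

Three analysis views arrange these figures: per-product overall liking
(`overall_liking_analysis()`), all measures of one product
(`product_analysis()`), one attribute across products
(`attribute_analysis()`). All figures within a view share one embedding
and one density — the point of the method is that consumer positions
coincide across maps.

## The panel simulator

`experiment1_spec()` encodes the packaged two-segment red-wine design: two
segments (women, men) of 50 consumers each, five wines, overall liking
plus five JAR attributes, with fixed segment mean profiles (shipped as a
CSV fixture, `experiment1_profiles()`). `simulate_panel()` adds i.i.d.
Gaussian noise to the segment mean of every (consumer, product, measure)
cell, in a fixed draw order (consumer-major, then product, then measure)
so one seed pins the exact table.

Choices the design leaves open, fixed here once:

* **Noise sd defaults to 0.5 scale units.** The design's segment mean gaps
  are 1–5 units; 0.5 keeps the segments separable while producing visible
  within-segment spread. It is an explicit parameter, and claims that
  depend on it are treated as parameter sweeps, not single facts.
* **Clipping on, rounding off.** Values are clipped to their scale bounds
  so every simulated table validates; rounding to discrete scale
  categories is available (`round_to_scale`) for realism studies but off
  by default, because the methodology's landscapes are continuous.
  Clipping biases a segment mean only when the design mean sits at a scale
  bound (e.g. a design mean of 9 on the 9-point scale can only be eroded
  downward); recovery checks therefore apply to interior means.

What the simulator does *not* emulate: correlated noise across attributes,
consumer-specific scale usage (some panelists compress the scale),
non-Gaussian response styles, and incomplete designs. Passing tests on
simulated panels therefore demonstrate that the machinery recovers known
structure under clean conditions — not that real panels are this well
behaved.

## Segmentation and the benchmark

`cluster_consumers()` runs Ward-linkage agglomerative clustering
(Euclidean distances, `ward.D2`) on the consumer vectors. Rather than
cutting the dendrogram by eye, the number of clusters is chosen to
maximize the mean silhouette width over $k = 2,\dots,\min(8, n-1)$, which
makes the choice algorithmic and testable; a forced `k` is accepted too.

`run_benchmark()` scores all fourteen admissible technique/data/regressor
combinations — {IPM_OL, PCA_OL, PCA_JAR, PCA_OLJAR, MDS_OL, MDS_JAR,
MDS_OLJAR} × {QUA, SVM} (IPM is defined on overall liking only) — by
fitting every evaluation of the table with every combination and averaging
percentage errors per evaluation family (overall liking; JAR), then
averaging the two family means. Averaging per evaluation first, then per
family, weights each evaluation equally regardless of family size; the
pooled-residual alternative would weight JAR evaluations five times
heavier in this design. Ranking ties break lexicographically by label.

Two structural findings are stable under the packaged design at noise 0.5
and are asserted by the test suite as medians over seeds: every
support-vector combination scores at or below its quadratic counterpart,
and MDS_OLJAR_SVM sits at or below the 14-combination median — the basis
for the recommended default pipeline (MDS + OLJAR + SVM).

One claim deserves honesty rather than a green checkmark: with *this*
two-segment design, the OL-only IPM map separates the segments about as
well as the OLJAR-fed maps, simply because the designed segments disagree
strongly about overall liking itself. The often-cited advantage of
attribute-fed maps appears exactly when segments share liking levels but
differ in perception; the test suite demonstrates that mechanism directly
(segments with identical OL profiles and different JAR profiles: IPM
separation collapses below 1 while PCA-JAR exceeds 3).

## Numerical choices and degenerate inputs

* Orderings: consumers, products and measures are sorted with a
  locale-independent (radix) lexicographic sort everywhere.
* MDS: up to 300 majorization iterations, relative raw-stress tolerance
  $10^{-10}$; monotonicity asserted.
* Degenerate inputs fail loudly, not silently: zero-variance panels
  (PCA/MDS), fewer than 3 products (IPM), fewer than 6 or collinear
  consumers (QUA), identically rated panels (clustering warns and returns
  one cluster), zero density fields (contours).
* Complete-block validation reports the exact offending cell for missing,
  duplicated and out-of-range entries; JAR files coded 1–5 are recentred
  behind an explicit flag rather than guessed.

## Problem sizes used by the checks

The packaged design (100 consumers × 5 products × 6 measures) is the
reference size for end-to-end checks; recovery and ordering claims use 10
to 20 simulation seeds, and oracle comparisons (normal equations, Torgerson
scaling, quadrature) run on panels of 12–200 consumers. These sizes were
chosen so the full suite exercises every claim at the scale the design
itself specifies.

## A short worked example

```{r example, eval = FALSE}
tab <- simulate_panel(experiment1_spec(noise_sd = 0.5, seed = 7))
cl <- cluster_consumers(to_vectors(tab, "OLJAR"))
cl$chosen_k # 2: the designed segments

bench <- run_benchmark(tab, seed = 7)
bench # 14 combinations ranked by average percentage error

ana <- overall_liking_analysis(tab, combo = "MDS_OLJAR_SVM", seed = 7)
ana$figures$wine1 # split landscape: men high, women low
```

## Known limitations

* Product points cannot be placed on PCA/MDS consumer maps (only IPM
  locates products); product comparison happens across maps instead.
* The percentage error is a training-set fit measure by construction;
  model selection by that number alone rewards interpolation.
* Scott's $n^{-1/6}$ assumes unit-variance coordinates; on very spread-out
  embeddings the density map is undersmoothed relative to the rule's
  intent.
* The simulator's independence assumptions above.
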