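---
title: "Semi-supervised causal edge classification with mrcl"
author: "mrcl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised causal edge classification with mrcl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcl)
```

## The problem and the model

Given data on $p$ variables (for instance expression levels of $p$ genes),
`mrcl` asks, for every *ordered* pair $(i, j)$, whether variable $i$ exerts a
causal influence on variable $j$. Rather than fitting a generative causal
model, the package treats the entries of the unknown binary adjacency matrix
as *labels* in a machine-learning sense. Background knowledge — typically
the outcome of interventional experiments such as gene knockouts, or
curated mechanistic knowledge — supplies labels $y_{[k]} \in \{-1, +1\}$ for
a subset $\mathcal{L}$ of the $m$ pairs; the remaining pairs
$\mathcal{U}$ are unlabelled, and a transductive classifier estimates their
labels. Pairs with estimated label $+1$ become directed edges. Cycles are
permitted, and the output graph inherits the *semantics* of its labels:
ancestral (total) effects when the labels come from interventions, direct
effects when they come from mechanistic literature. The classifier itself is
agnostic to the semantics; the tag is carried through unchanged so that the
user cannot accidentally mix interpretations.

### Featurization

Each ordered pair is represented by the bivariate histogram of its scatter
plot. The data matrix is column-standardized and truncated (clipped) to
$[-3, 3]$, and the $n$ points $(z_i^{(l)}, z_j^{(l)})$ are binned on a
regular $M \times M$ grid with bin width $0.2$, giving $M = 30$ and a
$900$-dimensional count vector per pair. The count vector, divided by
$n h^2$, is a density estimate that integrates to one; the Euclidean
distance between two count vectors is proportional to the $L^2$ distance
between the density estimates because $n$, and the grid, are common to all
pairs. That proportionality is why clipping, and not sample removal, is the
right truncation rule here: dropping samples would give pairs different
effective $n$ and silently break the correspondence between count distance
and density distance.

Two properties back this construction up, and both are verified numerically
by the test suite:

* the estimator-composed distance is a pseudo-metric on scatter plots
  regardless of the density estimator (checked exactly on 1000 random
  triples), and for samples from two fixed smooth densities it converges to
  the true $L^2$ distance between those densities as $n$ grows;
* with the bandwidth schedule $h \asymp n^{-1/4}$ the $L^2$ estimation
  error of the bivariate histogram for a twice continuously differentiable
  density decays as $n^{-1/4}$. The rate experiment
  (`histogramRateExperiment()`) fits the log–log slope of the mean error
  over $n \in \{2^8, \dots, 2^{16}\}$ with 20 replicates per size and
  midpoint quadrature on a bin-aligned grid; the fitted slope sits near
  $-0.23$, within the $\pm 0.10$ band around $-1/4$ that the asymptotics
  predict.

The $900$-dimensional counts are reduced to 100 dimensions by PCA before
graph construction. Three conventions are deliberate choices, since any of
them could have been made differently: PCA mean-centers but does not
whiten (whitening would distort the distance proportionality that motivates
the features); it is fitted jointly on all pairs, labelled and unlabelled,
which is legitimate because the estimator is transductive and never claims
out-of-sample validity; and component signs are fixed by making the
largest-magnitude loading positive, so results are bit-reproducible.
Raw counts, not normalized densities, are the PCA input — with a shared $n$
the two differ only by a constant factor, and counts are the more literal
reading of the featurization.

Missing values are rejected, not imputed: imputation would silently move
feature distances, and the right imputation is a modelling decision the
caller should make explicitly.

### The manifold graph and the classifier

Pairs are embedded in a similarity graph with squared-exponential weights
$W_{[k],[k']} = \exp(-\|x_{[k]} - x_{[k']}\|^2 / 2\sigma_1^2)$. The length
scale $\sigma_1$ is set to the average distance to the nearest 50 points in
feature space, estimated over a subsample of at most 1000 rows (the
subsample is seeded and the seed is echoed in the run configuration; for
problems with $m \le 1000$ the computation is exhaustive and deterministic).
The nearest-neighbour count is capped at $m - 1$ for small problems, where
50 neighbours would be undefined. The kernel $K$ has the same form with
scale $\sigma_2 = \sigma_1$ unless the user overrides it. $W$ is kept
dense: the method's cost is dominated by $m = O(p^2)$ and sparsification
would change the estimator, not merely accelerate it.

Scores solve the Laplacian-regularized least-squares problem

$$\hat f = \arg\inf_{f \in \mathcal{H}_K}
  \frac{\|y^{\mathcal L} - f^{\mathcal L}\|^2}{m_{\mathcal L}}
  + \frac{\lambda_1}{m^2} f^\top L f
  + \lambda_2 \|f\|_{\mathcal H_K}^2,$$

with the normalized Laplacian
$\tilde L = D^{-1/2} L D^{-1/2}$ in place of $L$ by default (the
un-normalized form is available by flag). The representer form
$f = K\alpha$ has the closed-form solution

$$\hat f = K\,(J K + \lambda_2 m_{\mathcal L} I
  + \tfrac{\lambda_1 m_{\mathcal L}}{m^2} L K)^{-1}\,[y^{\mathcal L}; 0],$$

where $J$ selects the labelled entries. Defaults
$\lambda_1 = \lambda_2 = 0.001$ are small positive values; performance is
broadly insensitive to them, and $\lambda_2 > 0$ is what guarantees a
unique minimizer. The system matrix is generally non-symmetric, so a
general dense LU solve is used (never an explicit inverse), with a
relative-residual check at $10^{-8}$ and a condition estimate reported in
the diagnostics; correctness is preferred over speed at the problem sizes
the method targets. Unlabelled entries of the label vector are exactly
zero. Squared-error loss is kept deliberately — it is what makes the
closed form possible at $m = O(p^2)$ scale — and no hinge-loss variant is
offered.

The sign of the score classifies a pair; a score of exactly zero is
classified $-1$, the conservative "no edge" call. In-sample scores at
labelled pairs are computed for diagnostics but are never part of the
estimator's output. Real-valued scores are retained for ranking, which is
what the ROC evaluation thresholds.

Numerical cross-checks in the suite: the closed form agrees with a
gradient-only conjugate-gradient minimization of the representer objective
to better than $10^{-6}$ relative error on random instances; with
$\lambda_1 = 0$ and no unlabelled pairs it reproduces kernel ridge
regression to $10^{-8}$; labels propagate across well-separated feature
clusters; and the fit is equivariant under within-block permutations of
the pairs.

## Gold standards and evaluation

With paired observational/interventional data the package builds the causal
reference the way a knockout compendium is typically scored: a robust
z-score $\zeta_{ij} = |Z^{\text{int}}_{ij} - M_j| / \text{IQR}_j$ compares
the measurement of variable $j$ after intervening on variable $i$ with the
observational median and inter-quartile range of $j$, and declares an edge
when $\zeta_{ij} > \tau$ with $\tau = 5$, *strictly* — a score exactly at
the threshold is a non-edge. Medians and IQRs come from a random half of
the observational samples; the other half is reserved as training data so
that nothing used to build the truth leaks into the features. Quantiles use
the linear-interpolation convention (R type 7); some convention must be
fixed for reproducibility and this is R's default. A single interventional
value per pair is required; if replicates exist, how to aggregate them is a
scientific decision left to the caller.

Two label-sampling designs are provided. *Random* sampling labels
$\lfloor \rho m \rfloor$ pairs uniformly; *row-wise* sampling labels all
pairs whose source is among $\lfloor \rho p \rfloor$ sampled variables, so
the test set consists of entire rows — the harder and more realistic task
of predicting the effects of interventions never seen in training.
Evaluation is always restricted to unlabelled, non-self pairs (asserted by
disjointness checks). AUC is the midrank Mann–Whitney statistic, which the
suite verifies equals the trapezoidal area under the ROC curve to
$10^{-12}$ even with heavy ties. MRCL scores are thresholded raw (the sign
carries the class); symmetric signed baselines such as correlations are
thresholded by absolute value. Correlation (Pearson/Kendall) and a k-NN
vote on the same features are the in-package baselines; graphical-model
methods have input/output contracts different enough that wrapping them
here would misrepresent them.

Variable subsets with too few causal effects cannot support a true-positive
rate, so `sparsityScreen()` reproduces the selection rules used with
knockout compendia: at least 2.5% of ordered pairs must show an effect,
and, for row-wise designs, at least half the rows must contain one.

## The synthetic knockout study

`simulateSystem()` generates the full study the rest of the package
expects, from a linear structural-equation system $z = B^\top z +
\varepsilon$: equilibrium observational samples
($z = (I - B^\top)^{-1}\varepsilon$), a knockout panel, and ground truth.
Equilibrium semantics are used so that cyclic systems (explicitly in
scope: feedback is ubiquitous in biology) are well defined; stability is
enforced by keeping the spectral radius of $B$ at or below $0.9$. Edge
weights have magnitude uniform in $[0.5, 1.5]$ with random sign — strong
enough to be scientifically "relevant", variable enough that detection is
not trivial — and unit Gaussian noise. Ancestral truth thresholds the
total-effect matrix $(I - B)^{-1} - I$ at $0.1$, encoding the view that
many small-magnitude total effects are irrelevant in practice; direct
edges are always retained in the ancestral truth.

A knockout is modelled as clamping the target to $-20$ on the standardized
scale and solving the reduced system (graph surgery). The clamp value is
the one genuinely free constant in the generator and was fixed by a
coherence argument: a gene deletion drives expression far outside the
observational range — tens of robust units, not a mild shift — and the
gold-standard threshold $\tau = 5$ presumes interventions of that
magnitude. A clamp within the truncation bounds (e.g. $-3$) would make
$\zeta > 5$ essentially unreachable and the reference graph empty; $-20$
yields reference graphs with roughly 4–8% edge density under the default
system parameters, comfortably past the sparsity screens, with every
detected edge a true ancestral effect. The panel records a single
measurement per knockout, as a deletion compendium does.

All randomness flows from one seed through a fixed splitting scheme, so
every simulated study, label draw and fit is exactly replayable.

What the generator emulates — and what it does not: linear effects,
independent Gaussian noise, hard single-target interventions, and complete
intervention coverage. Real expression data are non-linear, heteroscedastic,
confounded by latent factors and batch structure, and interventions have
off-target effects. Passing the end-to-end tests therefore shows that the
pipeline is implemented correctly and can recover structure under its own
assumptions; it is not evidence about any particular biological data set.

One structural limitation is worth stating plainly: after
column-standardization, a bivariate Gaussian scatter plot is nearly
exchangeable under coordinate transposition, so for linear Gaussian systems
the features of $(i, j)$ and $(j, i)$ are close to identical and edge
*direction* is only weakly identifiable from the observational scatter
alone. The estimator still ranks causally connected pairs far above
unconnected ones — which is why the synthetic benchmark AUCs sit well above
chance — but a portion of its false positives are reversed true edges.
Directional information enters through the labels, and in real data through
non-Gaussian asymmetries the generator does not produce.

## Problem sizes and numerical choices in the checks

The shipped verification uses: the rate experiment at
$n \in \{2^8,\dots,2^{16}\}$, 20 replicates, 40 quadrature subcells per bin
per axis; distance consistency at $n \in \{10^2, 10^3, 10^4\}$, 15
replicates; oracle equivalence on 20 random instances with $m \le 30$; and
the end-to-end benchmark at $p = 20$, $n_\text{obs} = 1000$ (500 for the
gold-standard statistics, 500 for training), edge density $0.1$,
$\rho = 0.3$ row-wise labels, 10 seeds, against a permuted-label null of
the same pipeline. These sizes were chosen so each check is decisive —
Monte-Carlo error well below the assertion margins — while a full run of
suite plus benchmark completes in well under a minute on one core; the
experiment functions accept larger sizes unchanged.

Degenerate inputs are errors, not warnings: zero-variance columns (no
z-score exists), missing values, points outside the truncation bounds
(binning would be undefined), zero observational IQR (no robust scale),
label values outside $\{-1, +1\}$, conflicting duplicate labels, empty
label sets (the estimator is undefined without background knowledge), and
single-class evaluation sets. Contradictory information across the two
orientations of a pair is *not* an error — mutual causation is a cycle,
which the method permits — but mutual $+1$ labels are flagged with a note.

## A worked example

```{r example}
sys <- simulateSystem(p = 15, edgeDensity = 0.12, nObs = 600, seed = 2)
gs <- goldStandard(sys@interventionPanel, sys@observational,
                   tau = 5, splitSeed = 2)
gs
sparsityScreen(adjacency(gs), rowwise = TRUE)   # enough effects to score?

labels <- sampleLabelsRowwise(adjacency(gs), rho = 0.4, seed = 2)
train <- sys@observational[trainingIndices(gs), ]
fit <- runMRCL(train, labels, mrclConfig(seed = 2))
fit

idx <- buildPairIndex(15, varNames = colnames(train))
ut <- unlabelledTruth(labels, adjacency(gs), idx)
rocAuc(edgeScores(fit)$score[ut$k], ut$truth,
       testSet = ut$k, design = "rowwise", rho = 0.4)
```

The AUC is computed only on pairs whose sources were never seen in
training. `syntheticBenchmark()` repeats exactly this loop over seeds, with
system redraws until the sparsity screens pass.
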