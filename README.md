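# mrcl — Manifold Regularized Causal Learning

`mrcl` estimates directed causal relationships among a fixed set of
variables by treating the problem as semi-supervised classification of
ordered variable pairs. It is aimed at settings common in systems biology:
a data matrix over $p$ variables (e.g. gene expression or protein levels),
plus partial causal knowledge — outcomes of interventional experiments such
as gene knockouts, or curated mechanistic literature — covering some pairs.
The method learns the causal status of the remaining pairs and returns a
directed graph (cycles allowed) together with a real-valued score per edge.

## The method

For each ordered pair $(i, j)$ of the $m = p(p-1)$ pairs (or $p^2$ with
self-pairs), the scatter plot of the standardized, truncated samples
$(z_i, z_j)$ is binned on a $30 \times 30$ grid over $[-3,3]^2$ (bin width
0.2), giving a 900-dimensional bin-count feature $x_{[k]}$, reduced to 100
dimensions by PCA. The Euclidean distance between count vectors is
proportional to the $L^2$ distance between the underlying bivariate
density estimates, which is a pseudo-metric on scatter plots and converges
to the true inter-density distance as $n$ grows.

Known labels $y^{\mathcal L} \in \{-1,+1\}^{m_{\mathcal L}}$ are propagated
to unlabelled pairs by Laplacian-regularized least squares over the
similarity graph
$W_{[k],[k']} = \exp(-\|x_{[k]}-x_{[k']}\|^2/2\sigma_1^2)$:

$$\hat f = \arg\inf_{f \in \mathcal H_K}
 \frac{\|y^{\mathcal L} - f^{\mathcal L}\|_2^2}{m_{\mathcal L}}
 + \frac{\lambda_1}{m^2}\, f^\top \tilde L f
 + \lambda_2 \|f\|_{\mathcal H_K}^2,$$

solved in closed form via the representer theorem
($\hat f = K (JK + \lambda_2 m_{\mathcal L} I +
\frac{\lambda_1 m_{\mathcal L}}{m^2} \tilde L K)^{-1} [y^{\mathcal L}; 0]$),
with $\tilde L$ the normalized graph Laplacian, squared-exponential kernel
$K$, $\sigma_2 = \sigma_1$ set to the mean distance to the 50 nearest
feature points, and $\lambda_1 = \lambda_2 = 0.001$. Edges are the pairs
with $\mathrm{sign}(\hat f) = +1$; scores rank candidates.

The package also provides: interventional gold standards via robust
z-scores ($\zeta_{ij} = |Z^{\text{int}}_{ij} - M_j|/\mathrm{IQR}_j > \tau$,
$\tau = 5$, strict), random and row-wise label-sampling designs, midrank
ROC/AUC evaluation restricted to held-out pairs, correlation and k-NN
baselines, and a linear structural-equation simulator that emulates a
knockout compendium so the whole pipeline can be exercised end to end
without external data.

## Worked example

Simulate a knockout study, build the interventional gold standard, train on
40% of the adjacency rows, and score the entirely unseen rows:

```r
library(mrcl)

sys <- simulateSystem(p = 15, edgeDensity = 0.12, nObs = 600, seed = 2)
gs  <- goldStandard(sys@interventionPanel, sys@observational,
                    tau = 5, splitSeed = 2)
gs
#> GoldStandard: 15 x 15, tau = 5, 13 edges (6.2% of off-diagonal pairs)
sparsityScreen(adjacency(gs), rowwise = TRUE)
#> [1] TRUE

labels <- sampleLabelsRowwise(adjacency(gs), rho = 0.4, seed = 2)
train  <- sys@observational[trainingIndices(gs), ]
fit    <- runMRCL(train, labels, mrclConfig(seed = 2))
fit
#> MRCLResult: 210 pairs scored (126 unlabelled), sigma1 = 20.74
#> CausalGraph (ancestral semantics): 15 vertices, 3 directed edges

idx <- buildPairIndex(15, varNames = colnames(train))
ut  <- unlabelledTruth(labels, adjacency(gs), idx)
rocAuc(edgeScores(fit)$score[ut$k], ut$truth,
       testSet = ut$k, design = "rowwise", rho = 0.4)
#> EvalResult: AUC = 0.7000 on 126 test pairs [rowwise design, rho = 0.4]
```

An AUC of 0.70 on 126 pairs whose source variables were never seen in
training means the classifier ranks true causal pairs above non-causal
ones well above chance, using only observational scatter-plot shape plus
the labelled rows. `syntheticBenchmark()` repeats this protocol across
seeds (mean AUC ≈ 0.7–0.8 at the default $p = 20$ study size);
`nullBenchmark()` confirms chance-level AUC when the data carry no signal.

A thin command-line wrapper is installed at `inst/scripts/mrcl` with
subcommands `simulate`, `featurize`, `run` and `evaluate` over delimited
text files; see its header for usage.

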