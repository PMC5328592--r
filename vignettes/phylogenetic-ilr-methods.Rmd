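---
title: "Phylogenetic ILR balances: model, weights and validation"
author: "phyloilr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic ILR balances: model, weights and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloilr)
```

## The model

Sequencing-based microbiome surveys are compositional: the counts
$c = (c_1, \dots, c_D)$ for a sample inform only about relative
abundances $x = \mathcal{C}[c] = c / \sum_j c_j$ (the *closure*).
Standard multivariate statistics misbehave on the simplex, so we map
compositions to an unconstrained Euclidean space with an isometric
log-ratio (ILR) transform whose sequential binary partition is a rooted
binary phylogeny of the $D$ taxa.

The partition is encoded by a sign matrix $\Theta \in \{-1,0,+1\}^{(D-1)
\times D}$: row $i$ corresponds to internal node $i$; entries are $+1$ or
$-1$ for tips descending from the node's two children and $0$ elsewhere.
Given strictly positive taxon weights $p$ and the shifted composition
$y = x / p$, the balance at node $i$ is

$$
y^*_i \;=\; \sqrt{\frac{n_i^+ n_i^-}{n_i^+ + n_i^-}}\;
\log \frac{g_p(y_{i+})}{g_p(y_{i-})},
\qquad
g_p(y_{i\pm}) = \exp\!\left(
\frac{\sum_{\theta_{ij}=\pm1} p_j \log y_j}{\sum_{\theta_{ij}=\pm1} p_j}
\right),
\qquad
n_i^{\pm} = \sum_{\theta_{ij}=\pm1} p_j .
$$

With $p = (1,\dots,1)$ this is the textbook ILR: $n_i^\pm$ count
descendant tips and $g_p$ is the ordinary geometric mean. The same map in
matrix form is $y^* = \mathrm{clr}_p(y)\,\mathrm{diag}(p)\,\Psi^\top$
where $\mathrm{clr}_p(y)_j = \log y_j - \sum_k p_k \log y_k / \sum_k p_k$
and the contrast matrix $\Psi$ has $\psi_{ij} = \pm s_i / n_i^\pm$ on the
$\pm1$ clades with $s_i = \sqrt{n_i^+ n_i^- / (n_i^+ + n_i^-)}$. The
square-root prefactor is forced by the unit-norm requirement
$\Psi\,\mathrm{diag}(p)\,\Psi^\top = I$: with the unsquare-rooted factor
the rows would not have unit length in the weighted inner product, which
one can confirm directly from `buildContrastMatrix()` whose orthonormality
is asserted at $10^{-10}$ in the test suite. The exact inverse is
$x = \mathcal{C}[\exp(y^* \Psi) \odot p]$.

All logarithms are natural; balances rescale linearly with the log base,
so this only fixes the unit of the coordinates. The generalized clr is
computed by log-space subtraction of the weighted mean log, never through
products, so the transform is stable for tables with $10^4$ taxa.
Samples are rows in every table.

## Determinism: canonical child order and node naming

Which clade sits in the numerator of a balance is a pure convention;
swapping it only flips the balance's sign. To make every output
byte-reproducible regardless of how the input Newick was rotated, the
package canonicalizes the tree before anything else: the children of each
node are ordered so that the child containing the lexicographically
smallest descendant tip label (radix order, locale-independent) comes
first, and that first child is the $+1$ (numerator) clade. Internal nodes
are named `n1..n(D-1)` in preorder from the root of the canonical tree.
Multichotomies are resolved in this canonical order into series of
dichotomies with inserted branches of length exactly zero; repeated
resolution of the same input yields identical trees.

Missing branch lengths are recorded as absent, never silently set to 0.
Trees without complete lengths are accepted only when no length-dependent
feature (branch weighting, depth analyses) is requested; otherwise the
operation fails with an explicit error, because silently imputing lengths
would corrupt the branch factors.

## Taxon weights

Zero and near-zero counts carry little information but dominate log-ratio
variability. Beyond the pseudocount (default 1; moderate alternatives
such as 2, 3 or 10 behave similarly), the `gm_norm` scheme soft-thresholds
unreliable taxa with

$$
p_j = \Big[\textstyle\prod_s (c_{js} + 1)\Big]^{1/N} \cdot \lVert x_j \rVert_2 ,
$$

the geometric mean of the taxon's pseudocounted counts across the $N$
samples times the Euclidean norm of its relative-abundance profile. The
norm term is computed on the closure of the *raw* counts, following the
two factors literally: the pseudocount appears only inside the geometric
mean. A `normOnPseudocounted` switch closes $c + 1$ instead, and an
Aitchison-norm variant is available behind `norm = "aitchison"`; neither
is the default. A taxon with zero counts everywhere would receive weight
0, which is not a valid weight — this is an error directing the user to
`filterTaxa()` rather than a silent repair.

## Branch-length weights

Each balance may be scaled by $f(d_+, d_-)$ of its node's two child
branch lengths: `none` ($f \equiv 1$), `sum` ($d_+ + d_-$) or the default
`sqrt_sum` ($\sqrt{d_+ + d_-}$). The factor multiplies only its own
coordinate, is recorded in the balance table's metadata, and is divided
out before inversion, so the round trip stays exact. With branch
weighting on, the map is no longer an isometry — distances in balance
space then mix abundance contrasts with evolutionary divergence, which is
precisely the point of the weighting but should be kept in mind when
interpreting coordinates numerically. Resolved multichotomies can give
$d_+ = d_- = 0$ and a zero factor that would annihilate the balance;
this is an error by default, with an optional `blEpsilon` floor added to
both child lengths.

## Preprocessing rules

Filters follow strict/non-strict inequalities literally: a taxon is kept
iff it is seen with **more than** `minCount` counts in **at least**
`minPrevalence` of samples (defaults 3 and 1%); a sample is dropped when
its total is **fewer than** `minSampleDepth` (1000 for community-level
work, 50 in the variance analysis). The filter order is configurable by
composing the functions; for variance–depth work the convention is
taxa-then-samples, for community-level preprocessing samples-then-taxa.
Pseudocounts are added last, after filtering, on the raw counts.
`matchTableTree()` restricts table and tree to their common taxon set,
reports both asymmetric differences, and reorders columns to the
canonical tip order. Depth standardization to the median and
coefficient-of-variation filtering are dataset-specific preprocessing
conventions, not defaults, and are left to the user's pipeline.

## Balance variance and phylogenetic depth

Whether closely related clades covary more than distant ones is tested on
a deliberately stripped-down transform: no taxon weights, no branch
weights, no zero replacement. Instead of pseudocounts, balance values are
*conditioned on non-zero counts*: at node $i$ a sample qualifies iff each
child clade has at least one non-zero count, and the geometric means run
over the non-zero components only (closure cancels in the ratio, so raw
counts are used directly; the unweighted geometric mean of the non-zero
components is our reading of the procedure — closing the subcomposition
first differs only by a constant that cancels between numerator and
denominator). Balances qualifying in fewer than `minSamples` samples
(default 40) are excluded.

A balance's depth $d$ is its node's mean phylogenetic distance to its
descendant tips. The trend is summarized by OLS on the log–log scale,
$\log \mathrm{var}(y^*) = \beta \log d + \alpha$, with zero-variance or
zero-depth balances excluded (with a logged count) rather than floored,
since flooring would distort $\beta$. The null distribution of $\beta$ is
generated by permuting tip labels on the fixed topology — equivalently
permuting taxon columns — so every permutation sees exactly the observed
per-taxon count vectors, and any zero-handling bias affects observed and
null statistics identically. The two-tailed p-value uses the add-one
estimator $(1 + \#\{|\beta_\text{null}| \ge |\beta_\text{obs}|\}) /
(1 + n_\text{perm})$, which cannot be exactly zero; the permutation
stream derives from a single recorded integer seed. When several groups
(body sites) are tested, `adjustGroupPvalues()` applies
Benjamini–Hochberg FDR — the procedure is our choice among FDR methods.

## Taxonomy integration

A clade's label is decided by voting over its tips' rank-prefixed
lineages (`k__` … `s__`), scanning from species up: the first rank at
which a single identifier covers at least 95% of the tips (missing
entries count against consensus) names the clade; otherwise
"Unclassified". A balance's name is the `numerator/denominator` pair of
its $+1$ and $-1$ clade labels. For rank-depth summaries, each internal
node is labeled by the consensus over **all** its descendant tips and the
median of the mean tip depths is taken per rank; ranks with no labeled
node are simply absent from the result.

## The simulator and what validation shows

`simulateCounts()` draws per-sample log-abundances
$z \sim \mathcal{N}(0, \Sigma)$ with
$\Sigma_{jk} = \sigma^2 e^{-\lambda\, d_\text{phylo}(j,k)}$ — the
stationary covariance of an Ornstein–Uhlenbeck process on the tree —
closes $\exp(z)$, and samples multinomial counts with Poisson-distributed
depth. Taken literally at $\lambda = 0$ that formula degenerates to
perfect correlation between all taxa, so $\lambda = 0$ is defined here as
the no-signal case $\Sigma = \sigma^2 I$: independent, hence
tip-exchangeable, log-abundances with the same marginal variance
$\sigma^2$ for every $\lambda$. The logistic-normal-multinomial family is
chosen because the transform's geometry is exactly Gaussian in balance
space under it, enabling closed-form checks; it does not emulate
zero-inflation beyond multinomial sampling, batch effects, or real
phylogenetic branch-length distributions, so passing tests demonstrate
the correctness and operating characteristics of the machinery, not
fidelity to any particular real dataset.

Validation sizes were chosen to give tight Monte-Carlo error at desk
scale: calibration uses 200 independent replicates of $D = 32$ taxa,
$N = 100$ samples at mean depth 5000 with $\sigma^2 = 1$, $\lambda = 0$,
and 199 permutations per test (type-I error at nominal 0.05 lands near
0.05 with binomial SE 0.015; the null-$\beta$ symmetry check uses one
null draw per replicate to keep draws independent). Power uses 50
replicates of the structured fixture, frozen once at $\sigma^2 = 2$,
$\lambda = 3$ after a one-off calibration run: at those settings sibling
tips correlate at roughly $e^{-3 \cdot 0.2} \approx 0.55$ while clades
across the root are nearly independent, a strong but not caricatural
signal, and the observed slope is recovered positive in effectively all
replicates. Algebraic properties (orthonormality, round trip, isometry,
matrix-vs-per-node agreement) are checked against independent oracles at
$10^{-10}$/$10^{-8}$ over random trees with $D$ up to 50.

## Degenerate inputs and numerical policy

* Uniform compositions (and any composition whose shifted version is
  constant on a clade) give exactly zero balances; a zero balance vector
  inverts to $\mathcal{C}[p]$.
* The transform is exactly scale-invariant when the pseudocount is 0 and
  the table strictly positive.
* Taxon/tip mismatches are hard errors with the offending names listed;
  reconciliation is explicit via `matchTableTree()`.
* `var` over fewer than 2 qualifying samples is undefined, so
  `minSamples < 2` is rejected; permutations in which fewer than 3
  balances survive conditioning yield no slope, and if more than half of
  the permutations degenerate this way the test aborts with diagnostics
  instead of reporting a p-value from a crippled null.

## Known limitations

Branch weighting breaks the isometry (documented above); taxon weights
are a heuristic, not an inferential model of count precision; all zeros
are treated as rounded zeros except in the conditional-variance analysis;
the simulator is a convenience family rather than a realistic microbiome
generator; and trees are assumed rooted and (after resolution) strictly
binary — networks and negative branch lengths are out of scope.
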