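---
title: "Signed topological overlap networks: model, inference and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed topological overlap networks: model, inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtonet)
```

## The model

For a system of N nodes observed over S samples, the adjacency is the
pairwise correlation with zero diagonal, $a_{ij} = \rho_{ij}$ for
$i \neq j$, $a_{ii} = 0$. The link score between nodes $i$ and $j$ is the
signed weighted topological overlap

$$\omega_{ij} = \frac{\sum_{u=1}^{N} a_{iu}a_{uj} + a_{ij}}
                     {\min(k_i,k_j) + 1 - |a_{ij}|},
  \qquad k_i = \sum_{j=1}^{N}|a_{ij}|.$$

The numerator rewards agreement between the two correlation profiles
across the whole system; the denominator normalizes by the weaker node's
strength so that $|\omega_{ij}| \le 1$. Because the adjacency keeps
correlation signs, the numerator terms can cancel: a pair linked through
both positive and negative intermediaries shrinks toward zero, while the
unsigned overlap (the same ratio on $|a_{ij}|$) does not. The provable
relation $|\omega^{signed}_{ij}| \le \omega^{unsigned}_{ij}$ makes the
scatter of one against the other a cancellation diagnostic, which is what
`plot.wto_network()` draws.

Two conventions worth stating explicitly:

* The numerator sum runs over *all* $u = 1..N$, including $u = i, j$ —
  with a zero diagonal those terms vanish, so no exclusion logic exists.
  Restricting the fit to a subset of nodes of interest restricts which
  pairs are *reported*, never the sums; this is tested by comparing a
  subset fit to the corresponding entries of the full fit.
* The self-overlap diagnostic `wto_self()` uses
  $\omega_{ii} = \sum_u a_{iu}^2 / (k_i + 1)$ with
  $k_i = \sum_u |a_{iu}|$. The absolute-value strength is the reading
  consistent with deriving $\omega_{ii}$ from the pair formula above; for
  nonnegative adjacencies the two readings coincide.
* The denominator $\min(k_i,k_j) + 1 - |a_{ij}|$ is bounded below by 1
  for any consistent adjacency (since $k_i \ge |a_{ij}|$), so no
  numerical guard is needed in practice; the code still defines
  $\omega_{ij} = a_{ij}$ in the formal degenerate case as the continuity
  limit.

## Link significance

The package offers three resampling schemes, chosen by the data design:

**Bootstrap** (`resampling = "bootstrap"`) resamples the S samples with
replacement and recomputes every link weight. The reported p-value is the
*δ-band instability fraction* $p_{ij} = P(|\omega^*_{ij} -
\hat\omega_{ij}| \ge \delta)$, with $\delta = 0.2$ by default: the
probability that the link weight is not stable within a band of ±δ. This
is deliberately a stability measure, not a classical null-hypothesis
p-value — it answers "how much should I trust this weight", which is the
question a network-pruning threshold needs. δ is on the scale of ω
itself (dimensionless, bounded by 1); halving it roughly doubles the
strictness. A link that never leaves the band gets p floored at $1/n$
(the resolution of an n-resample empirical probability) rather than 0, so
log-based combination downstream stays defined.

**Blocked bootstrap** (`resampling = "block_bootstrap"`) is the variant
for replicate-free time series: overlapping moving blocks of `lag`
consecutive time points are drawn with replacement and concatenated
(truncated to S columns), preserving within-block autocorrelation that a
plain bootstrap would destroy. With `lag = 1` it degenerates to the plain
bootstrap. `suggest_lag()` picks the block length as the median over
nodes of the largest lag L such that the sample autocorrelation exceeds
the 95% white-noise band $1.96/\sqrt{S}$ at *every* lag up to L. The
consecutive-run rule is used rather than the largest significant lag in
isolation, because under white noise about 5% of lags exceed the band by
chance, and the largest of those spurious lags would systematically
inflate the suggestion; the run rule returns 1 for white noise, as it
should. The partial autocorrelation function would be a defensible
alternative; the plain acf matches how block lengths are commonly chosen
for abundance series.

**Permutation** (`resampling = "reshuffle"`) permutes values across nodes
within each sample independently, destroying all inter-node dependence
while preserving each sample's value distribution — a genuine null for
$H_0: \omega_{ij} = 0$. The p-value is two-sided with the add-one
correction, $p = (1 + \#\{|\omega^*| \ge |\hat\omega|\})/(n+1)$, so it is
never exactly zero and retains finite-sample validity. On independent
Gaussian data these p-values are close to uniform (checked by a
Kolmogorov–Smirnov statistic in the test suite), which is what makes the
downstream false-discovery-rate adjustment meaningful.

Both signed and unsigned channels get p-values and Benjamini–Hochberg
adjusted p-values (Bonferroni and Holm are options); whether the signed
or unsigned channel is more appropriate depends on whether sign conflicts
are themselves evidence against a link in the user's biology, so the
table reports both. Empirical quantiles (0.1%, 2.5%, 10%, 90%, 97.5%,
99.9%) of both the resampled and the observed weight distributions are
reported as data-driven pruning thresholds; quantile type 7 (linear
interpolation) is fixed so results are bit-reproducible.

**Reproducibility.** Each resample draws from its own RNG seed derived
from the master seed by resample index. Worker scheduling therefore
cannot change results: the same seed gives byte-identical output for 1 or
many threads, which the suite asserts.

## Consensus aggregation

Independent studies of the same system yield different networks through
technical and biological noise. The consensus network combines $k$ edge
tables by the magnitude-weighted convex combination

$$\Omega_{ij} = \sum_k \alpha^k_{ij} \omega^k_{ij}, \qquad
  \alpha^k_{ij} = \frac{|\omega^k_{ij}|}{\sum_k |\omega^k_{ij}|}.$$

Consequences, each tested: $\Omega$ lies between the per-network minimum
and maximum; equal inputs reproduce themselves; same-sign inputs land
above their arithmetic mean, pulled toward the stronger network; and
sign-conflicting inputs shrink toward zero — a perfect conflict of equal
magnitudes gives exactly 0. Shrinkage, not removal, is what the equation
does; `threshold_consensus()` provides the removal step for links whose
$|\Omega|$ ends up near zero.

Decisions where the design was genuinely open:

* **Node alignment.** Only nodes present in every network enter the
  consensus — no statement can be made about a factor that was not
  measured in one study. A *pair* missing from a subset of networks while
  both endpoints are present is zero-filled ($\omega = 0$, $p = 1$) by
  default, consistent with treating insignificant weights as zero; a
  `missing_link = "drop"` flag restricts instead to pairs reported
  everywhere.
* **Significance filter.** `alpha` zeroes the weight of links whose
  (adjusted, when available) p exceeds it before combination, so an
  insignificant network contributes nothing to that link's $\Omega$ while
  its p still enters the Fisher combination.
* **Combined p.** Fisher's method, $X = -2\sum\log p_k \sim \chi^2_{2k}$.
  Inputs of exactly 0 are floored (`p_floor`) before the logs. The
  combined p is *not* re-adjusted for multiple testing by default; a flag
  enables BH on the combined values.

## Community detection and export

Most modularity-based community detection algorithms require nonnegative
weights, so all nine offered methods cluster on $|\omega|$ as the link
strength, with the sign retained as an edge attribute (in visual terms:
width is magnitude, color is sign). Cluster ids are normalized to
contiguous integers from 0, and stochastic methods are seeded. GraphML
export carries signed weight, magnitude, sign, p-value, cluster and node
class, and round-trips through `read_graphml()` exactly.

## Synthetic data

The generators are the package's study conditions, not tuning knobs:

* `make_block_expression()` draws multivariate normal samples with a
  block correlation structure — `rho_within` inside planted modules
  (default 0.7), `rho_between` across (default 0), unit variances, an
  optional fraction of sign-flipped nodes — after verifying the implied
  correlation matrix is positive semi-definite. This emulates the
  co-regulated-module skeleton of expression data; it does *not* emulate
  counts, library-size variation or heavy tails, so passing tests speak
  to the method's statistical behavior, not to preprocessing of raw
  sequencing data. Monotone transforms of the Gaussian draws are the
  intended route for exercising the Spearman option.
* `make_ar1_series()` draws stationary AR(1) rows
  ($x_t = \phi x_{t-1} + \epsilon_t$, default $\phi = 0.8$, marginal
  variance $1/(1-\phi^2)$), optionally with module-correlated
  innovations — the regime the blocked bootstrap exists for.

Every fixture is fully determined by its arguments plus the seed.

## Problem sizes and numerical choices

The package is dense by design — every pair is correlated, and the
overlap numerator is accumulated in double precision as one matrix
product restricted to the subset rows/columns. The test suite runs its
statistical checks at moderate sizes chosen to give stable verdicts in
seconds (30–60 nodes, 50–100 samples, 100–1000 resamples; the scale
check fits 500 nodes with 100 bootstraps), and the acceptance script
mirrors those sizes. A two-block separation ratio measured on a single
60-node fixture draw is noticeably seed-dependent — the between-module
overlap inherits the block factor's finite-sample correlation with
outside nodes as common-mode noise — so the acceptance script averages
that ratio over five fixture replicates.

Edge tables are written with 12 significant digits; node pairs are
stored with lexicographically sorted endpoints everywhere, which is what
makes A–B/B–A duplication across networks detectable and byte-identical
reproducibility achievable.

## Known limitations

* Correlation-based adjacency only (Pearson/Spearman); no mutual
  information and no soft-thresholding powers.
* The bootstrap p is a stability probability; users wanting a classical
  null test should use the permutation scheme.
* Zero-variance rows are dropped, not imputed; missing values are
  rejected outright.
* The consensus treats input networks as exchangeable replicates; no
  weighting by study size or quality beyond the magnitudes themselves.
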