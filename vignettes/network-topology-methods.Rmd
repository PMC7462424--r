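---
title: "Methods: task-evoked network topology from beta-series connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-evoked network topology from beta-series connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betanet)
```

## Overview

`betanet` implements a complete analysis path for asking whether, and where,
the functional network organization of the brain reconfigures between two
intermixed task conditions measured with event-related fMRI. The pipeline is

1. **trial-level activation (beta series)** — one GLM per trial
   (least-squares-separate), giving for every region a series of trial
   activation estimates per condition;
2. **connectivity** — Pearson correlation of beta series between regions,
   Fisher Z transformed and scaled to z-scores, separately per condition;
3. **community structure** — signed modularity maximization (Q*) with a
   generalized Louvain algorithm, aggregated by consensus clustering at the
   subject and group levels;
4. **resolution selection** — a sweep of the structural resolution
   parameter gamma, with the working value chosen to balance stable and
   changing community assignments between conditions;
5. **inference** — Monte Carlo permutation tests of within- and
   between-community allegiance differences, and a region-level analysis of
   allegiance-profile dissimilarity across the whole gamma range,
   summarized by significance counts, a negative-binomial fit and QQ
   outlier detection.

Each stage is exposed as ordinary R functions; `run_pipeline()` chains
them deterministically from a single configuration object.

## The model and its assumptions

### Beta series and LS-S

For trial $t$ the LS-S design matrix contains the HRF-convolved stick for
trial $t$, one regressor combining all other trials, optional per-volume
nuisance covariates, and an intercept. Censored volumes are deleted row-wise
before each fit; trials whose design becomes rank deficient get missing
betas and count as scrubbed.

Two modelling notes matter for interpretation:

* The single combined-others regressor is an *approximation*: when trial
  responses overlap and other-trial amplitudes differ, a small residual
  leaks into the trial estimate (this is the standard trade-off that makes
  LS-S more stable than one-regressor-per-trial under noise). On noise-free
  data the estimate is exact only when the per-trial GLM spans the signal,
  e.g. in a two-trial design; with separated multi-trial designs the
  residual coupling through the intercept is below 2% of the amplitude
  scale. The test suite pins both facts.
* The double-gamma response kernel (gamma-density difference, peak shape 6,
  undershoot shape 16, ratio 1/6) is truncated at the single-trial response
  span (13.1 s, i.e. 6–7 volumes at TR = 2 s). Truncation makes the set of
  volumes a trial touches identical to the set the scrubbing rule counts,
  and the simulator and estimator share the same kernel, so estimation is
  unbiased with respect to the simulated response shape. Any other kernel
  can be passed via the `hrf` argument.

### Scrubbing and normalization

A trial is excluded when its response span contains **two or more**
censored volumes. Within each condition, each region's retained betas are
normalized to mean 0, SD 1; the population SD (divide by $n$) is the
default, following the pattern-analysis convention — the choice is
configurable (`sd_type = "sample"`) and irrelevant to the correlations
computed downstream (Pearson is scale invariant).

### Connectivity

Pairwise Pearson correlations over retained betas are mapped to
$z = \operatorname{atanh}(r)\sqrt{N-3}$ with $N$ the number of retained
trials of that condition (listwise: a single retained set per condition).
Correlations at $|r| = 1$ are clamped to $1 - 10^{-12}$ with a warning.
The diagonal is zero and matrices are exactly symmetrized.

### Signed modularity Q*

Functional connectivity matrices are signed. Positive and negative weights
carry different neurobiological meaning, so the quality function treats
them asymmetrically:

$$
Q^* = \frac{1}{v^+}\sum_{ij}\left(w^+_{ij} - \gamma e^+_{ij}\right)
\delta_{M_i M_j}
- \frac{1}{v^+ + v^-}\sum_{ij}\left(w^-_{ij} - \gamma e^-_{ij}\right)
\delta_{M_i M_j},
$$

with $w^\pm$ the positive/negative parts, $s^\pm_i$ their strengths,
$v^\pm = \sum_{ij} w^\pm_{ij}$, and the per-sign configuration-model null
$e^\pm_{ij} = s^\pm_i s^\pm_j / v^\pm$ (zero when $v^\pm = 0$). Positive
weight contributes at full scale; negative weight is down-weighted by the
total weight. The double sums include the diagonal null term (a node always
shares a community with itself), which is what makes the community-wise
contributions $Q_c^*$ sum exactly to $Q^*$.

The maximizer is a two-phase generalized Louvain: greedy single-node moves
over a seeded random permutation (ties broken by the first strictly
improving move in scan order), then aggregation, repeated to convergence.
It is deterministic given the seed, and the returned `qstar` is recomputed
from the returned partition so the two always agree exactly. The move phase
operates on the dense modularity matrix, which is exact (no resolution
shortcut) and fast for the few-hundred-node networks this package targets.

### Consensus clustering

Because Louvain solutions are degenerate, each subject's network is
partitioned many times (1000 at analysis scale); the **allegiance matrix**
records the fraction of iterations in which two regions share a community.
Consensus clustering thresholds the allegiance at `tau = 0.5`, re-partitions
the thresholded agreement matrix repeatedly, and iterates until all
repartitions coincide (cap: 50 iterations, after which an error carrying
the last agreement matrix is raised). The same procedure, applied to the
across-subject allegiance of final subject partitions, gives the group
partition; the same `tau` is used at both levels. The agreement matrix is
re-clustered at resolution 1 regardless of the gamma used on the raw
networks — the agreement scale is a probability, not a z-score, and
re-scaling the null there would distort the consensus; `consensus_partition()`
exposes the argument for users who want otherwise.

Thresholding can disconnect the agreement matrix; disconnected components
are then free to become separate communities, which is the desired
behavior (singleton communities are meaningful at high gamma).

### Choosing the resolution gamma

Louvain's gamma fixes the topological scale: low gamma yields few large
communities, high gamma fragments the network into singletons. The sweep
covers gamma = 0.05–5.0 in steps of 0.05 by default (the range over which
z-scored functional networks typically evolve from one module to
all-singletons; the stability of partitions across the sweep can be checked
with `vi_stability_curve()`, mean pairwise normalized variation of
information in a ±0.35 window). The working value gamma* maximizes the SD
across regions of the between-condition **flexibility** vector (1 where a
region's community differs between conditions after optimal label matching)
— the point balancing stable and changing assignments, maximal when half
the regions change. Repeats are paired by index between conditions when the
SD is averaged; ties break toward smaller gamma, and an identically zero
curve (no differences anywhere) returns the smallest grid value with a
warning.

Normalized VI uses natural logs normalized by $\ln n$ (the base cancels).
Label matching solves the optimal assignment on the contingency table
exactly (Hungarian algorithm); unmatched communities receive fresh labels.

### Community-level inference

Group communities are first screened for subject-level support: the
observed statistic is the mean over subjects of the community's $Q_c^*$ in
the subject networks, compared against size-matched uniformly random region
sets (the null is pooled across subjects by the same mean; 99th percentile
cutoff by default). This keeps only communities that are expressed in
individuals rather than being artifacts of group aggregation. The null
model resamples region identities, not edges; it is deliberately simple,
documented here, and swappable.

Allegiance differences between conditions are tested per community pair:
the below-diagonal vector of region-pair allegiance values (within one
community, or spanning two) is compared across the two group matrices with
a paired t statistic ($T_{true}$); a community with exactly one region pair
uses the simple difference. The null exchanges each subject's condition
labels with probability 1/2 per iteration and rebuilds both group matrices
(50,000 iterations at analysis scale; the add-one convention
$p = (\#\{|T_{null}| \ge |T_{true}|\} + 1)/(n_{perm} + 1)$ avoids p = 0).
Effect sizes are $z = (T_{true} - \mu_{T_{null}})/\sigma_{T_{null}}$;
Benjamini–Hochberg flags are reported over all $k(k+1)/2$ tests. A
zero-variance difference vector (identical matrices) yields z = 0, p = 1
with a warning rather than an undefined t.

### Region-level inference

A region's allegiance profile is its row of the group allegiance matrix
(self entry excluded; symmetry means each counterpart contributes once).
Profiles are correlated between conditions, Fisher Z transformed with the
shared clamp, and **negated** so larger values mean greater dissimilarity.
A zero-variance profile (a region alone in its community in every subject
at that gamma) is undefined: it is returned as missing and excluded from
counting at that step. Significance per gamma uses the same subject-level
condition-exchange null (10,000 reshufflings at analysis scale), one-tailed
for greater-than-null dissimilarity, uncorrected — robustness comes from
counting significant steps across the whole sweep rather than from
per-step correction.

The per-region counts are modelled with a maximum-likelihood negative
binomial (counts of exceedances across a dependent sweep are overdispersed).
When the method-of-moments dispersion is at the boundary (variance ≤ mean)
the fit falls back to Poisson; all-zero counts return a degenerate point
mass with a warning. Outliers — regions whose profile differences are
robust across topological scales — are flagged when their QQ residual
(sorted counts minus fitted quantiles at `ppoints(n)` plotting positions)
exceeds 2 × the interquartile range of residuals **and** their upper-tail
probability $P(X \ge \text{count})$ is below 0.05. The original analysis
identified outliers visually on the QQ plot; this two-part rule is the
implementable surrogate, and both thresholds are arguments.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
imaging data. It emulates:

* an intermixed two-condition event-related design — 80 trials per
  condition by default, numerosities {2, 4, 6, 8} balanced within
  condition, ISIs 3300–7300 ms in 1000-ms steps (mean 5300 ms)
  counterbalanced across condition × numerosity cells, no more than 3
  consecutive trials sharing a condition or a numerosity. Ordering uses
  constrained sequential sampling with restarts (capped at 10,000
  attempts, then an explicit infeasibility error); any constraint-
  satisfying order is acceptable. With a single configured numerosity the
  numerosity run constraint is vacuous and waived.
* planted community structure — two condition-wise partitions, largely
  shared, with a designated set of regions changing membership. Per trial,
  a region's amplitude is
  $\sqrt{\rho_b}\,g_0 + \sqrt{\rho_w - \rho_b}\,g_{c} +
  \sqrt{1-\rho_w}\,\varepsilon_i$ (global, community, and region factors),
  so trial-level correlations converge to `rho_within` inside communities
  and `rho_between` across them. Optional per-community multipliers on
  `rho_within` plant condition-specific allegiance effects.
* volume-level Gaussian noise (`sigma_noise`) after HRF convolution, and
  i.i.d. per-volume censoring at `censor_rate` (default 0.04, matching the
  ~4% censored-volume rate typical of motion scrubbing). The empirical
  motion process of real data is autocorrelated; i.i.d. censoring is a
  deliberate simplification.
* a fast path, `generate_connectivity_cohort()`, that skips time series
  entirely and samples each subject's condition network as a planted
  Fisher-Z block matrix plus symmetric Gaussian edge noise.

What the generator does **not** emulate: voxel-level data, physiological
or autocorrelated noise, hemodynamic variability across regions, real
motion processes, and atlas geometry. Passing tests therefore demonstrate
that the algorithms recover planted structure under idealized sampling
noise — they do not certify performance on real fMRI data.

## Parameters that matter

| parameter | default | units / range | role |
|---|---|---|---|
| `gamma` grid | 0.05–5.0 step 0.05 | resolution | topological scale of communities |
| `tau` | 0.5 | probability | consensus agreement threshold (both levels) |
| `n_iter` (subject Louvain) | 1000 final, 100 sweeps | iterations | allegiance resolution |
| sweep repeats | 100 (analysis), 5 (default config) | repeats | flexibility-SD distribution per gamma |
| `n_perm` community / region | 50,000 / 10,000 (analysis); 1000 / 200 (default config) | iterations | permutation-null resolution |
| `n_null`, `percentile` | 1000, 99 | draws, % | community-selection screen |
| `alpha` | 0.05 one-tailed | level | per-step region significance for counting |
| `rho_within`, `rho_between` | 0.6, 0.1 | correlation | planted community strength |
| `censor_rate` | 0.04 | probability | per-volume censoring |
| QQ rule | 2 × IQR and p_obs < 0.05 | — | region outlier surrogate |

`pipeline_config()` defaults are sized for a single-CPU synthetic run
(20 subjects, 60 regions, 25-step grid, reduced iteration counts; about
ten minutes end to end); the analysis-scale settings above are reachable
by raising the corresponding fields. For connectivity cohorts the default
edge noise (`sigma_noise = 4`, roughly two-thirds of the planted
within-community z weight) is chosen so that subject-level partitions
vary realistically across subjects; near-noiseless cohorts make every
region's allegiance profile change detectable and are useful only for
exact-recovery checks. The problem sizes used in the test suite are
smaller still (5–12 subjects, 18–202 regions, short grids) and are the
package's own choice of desk-scale experiment.

## Numerical choices and degenerate inputs

* Correlation clamp $|r| \le 1 - 10^{-12}$ shared by connectivity and
  profile dissimilarity keeps `atanh` finite; clamped connectivity warns.
* Louvain tie-break: first strictly improving community in scan order of a
  seeded random permutation; gains below $10^{-10}$ count as no
  improvement.
* Consensus non-convergence raises an error carrying the last agreement
  matrix instead of returning silently.
* Zero-SD beta series name the offending region; fully censored or
  rank-deficient trials are missing, never zero.
* Permutation p values use the add-one convention; with `n_perm = 10` the
  granularity is 1/11 — choose `n_perm` accordingly.
* All randomness flows through R's RNG (the compiled Louvain draws its
  node orders from it), so a single `set.seed` or the config's stage seeds
  reproduce every result bit-identically.

## Known limitations

* Empirical results obtained on a real cohort (the working resolution
  gamma*, the number of communities and singletons, specific community
  z-scores, the identity of outlier regions) are properties of that
  cohort and cannot be reproduced from synthetic data; this package
  validates the *procedures* on planted structure, and real-data values
  require the real measurements.
* LS-S is an approximation under overlapping responses (see above).
* The community-selection null (size-matched random region sets) is one of
  several defensible choices; edge-rewiring nulls would test a different
  hypothesis.
* The QQ outlier rule is a surrogate for a visual judgement; its two
  thresholds should be reported alongside any use.
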