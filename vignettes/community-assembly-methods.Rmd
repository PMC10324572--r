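---
title: "Methods: inferring stochastic and deterministic community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring stochastic and deterministic community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

# The scientific question

Microbial communities along strong environmental gradients — for example
archaea along an estuarine salinity gradient from river to shelf — are shaped
by a mixture of *stochastic* processes (drift, dispersal, ecological
equivalence) and *deterministic* processes (environmental filtering, species
interactions). `ecoassembly` implements the standard inferential toolkit for
weighing these two forces from an OTU count table alone:

1. the **Sloan neutral community model (NCM)**, which asks how much of the
   occurrence-frequency structure is explained by pure immigration–drift
   dynamics;
2. **checkerboard (C-score) null-model analysis**, which asks whether taxa
   co-occur less (segregation) or more (aggregation) than expected under
   randomized assembly with fixed richness and incidence;
3. **Levins niche breadth**, which summarises whether a community is built
   from habitat generalists or specialists;
4. community description: alpha diversity, Bray–Curtis/UPGMA, ANOSIM, PCA,
   and environmental heterogeneity;
5. **co-occurrence networks** from thresholded Spearman correlations, with
   topology, random-graph ensembles, modules, and natural-connectivity
   robustness.

Because raw survey data rarely come with ground truth, the package also ships
two seeded generators — a forward neutral simulator and a Gaussian-niche
simulator — so that every inference stage can be validated against data whose
assembly regime is known. All analysis functions return tibbles or small S3
objects with `tidy()`, `glance()` and `autoplot()` methods.

# The neutral community model

## Model

A local community holds `N` individuals (in sequencing practice: `N` reads
after rarefaction). On each death, the replacement is an immigrant from the
metacommunity with probability `m`, otherwise the offspring of a local
individual. For a taxon with metacommunity relative abundance `p`, the
stationary local relative abundance is approximately

\[ x \sim \mathrm{Beta}\big(Nm\,p,\; Nm\,(1-p)\big), \]

so the probability of *detecting* the taxon — its expected occurrence
frequency across local communities — is the upper tail of that Beta above a
detection limit `d` (`predict_frequency()`). `fit_ncm()` estimates the single
composite parameter `Nm` by nonlinear least squares of observed occurrence
frequencies on mean relative abundances, reports `m = Nm/N`, and measures fit
quality with the Östman coefficient `R² = 1 − SSres/SStot`, which is 1 for a
perfect neutral fit and can be negative when the neutral curve does worse
than a constant. Taxa whose observed frequency falls outside a Wilson
binomial band (level `ci_level`, `n` = number of samples) around their
prediction are partitioned as occurring *above* or *below* the neutral
expectation.

## Numerical choices

The objective is one-dimensional in `log(Nm)`, so the optimiser is a coarse
log-spaced grid on `[10^{-3}N, 10N]` refined by `stats::optimize()`
(tolerance `1e-8`) — deterministic, and immune to the local minima that
motivate multi-start schemes in higher dimensions. Taxa observed nowhere
(`f = 0`) carry no information about `Nm` and are dropped; taxa with `f = 1`
are retained.

## The detection limit

The conventional detection limit for a rarefied table is one read,
`d = 1/N`. A taxon at true relative abundance `x` is, however, detected in a
sample of `N` reads with probability `1 − (1−x)^N` — a smooth curve, not a
step at `1/N`. Approximating that kernel by a step is best done at its
median, the abundance at which detection probability is exactly one half:

\[ d = 1 - 2^{-1/N} \approx \ln(2)/N. \]

This is the package default. The choice matters: in forward simulations
(below) with `N = 1000` and true `m ∈ {0.1, 0.3, 0.6}`, fitting with
`d = 1/N` overestimates `m` by roughly 35–45% (median fitted values
0.14/0.43/0.78 over ten seeds), while the median-detection limit is nearly
unbiased (0.11/0.29/0.52). Users who need the one-read convention for
comparability with other software can pass `detection_limit = 1/N`.

A related, irreducible consequence of the step approximation is visible in
the partition: even on perfectly neutral data a minority of taxa
(typically 15–30% at 40–200 samples) fall outside the 95% Wilson band,
because the band shrinks with the number of samples at the same rate as the
sampling noise while the model's small taxon-level lack of fit does not.
Partition fractions should therefore be read comparatively (between groups
or against simulated baselines), not as absolute percentages of
non-neutral taxa.

## The forward simulator and its immigration convention

`simulate_neutral_communities()` runs Moran-type dynamics: a generation is
`N` death–replacement events, each sample is an independent local community
coupled to a fixed metacommunity vector (default: Dirichlet with
concentration `∝ 1/rank`, giving realistic long-tailed rank-abundance
curves), and the default burn-in is 50 generations — more than ten relaxation
times at the immigration rates considered here, verified against the
closed-form stationary mean, variance and absence probability.

One subtlety is documented rather than hidden. If the per-event immigrant
probability is exactly `m`, the chain's exact stationary distribution is
beta-binomial with composite parameter `m(N−1)/(1−m)·p` — which equals the
`Nm·p` assumed by the occurrence-frequency model only for small `m` (the
diffusion approximation behind the Beta form drops a `(1−m)` factor in the
variance). At `m = 0.3` the discrepancy is ~43%. The generator therefore
exposes two conventions:

* `convention = "sloan"` (default): the per-event immigrant probability is
  set to `Nm/(N−1+Nm)` so that the stationary composite parameter is
  **exactly** `N·m` — the nominal `m` is the true immigration rate in the
  sense of the model being fitted. Use this for parameter-recovery studies.
* `convention = "per_event"`: the immigrant probability per replacement is
  literally `m`; useful for studying the dynamics themselves (`m = 1` gives
  iid multinomial samples, `m → 0` gives drift to monodominance).

# C-score null models

For every unordered taxon pair the number of checkerboard units is
`CU_ij = (R_i − S_ij)(R_j − S_ij)` (`R` row totals, `S_ij` shared samples);
the C-score is the mean over pairs. Observed scores are compared against a
fixed-row, fixed-column null generated by **sequential swap**: repeatedly
pick two random rows and two random columns and, when they form a 2×2
checkerboard, flip it — a Markov chain on the set of matrices with the given
margins. A useful identity: a matrix admits a swap iff its C-score is
positive (some pair has `CU > 0`).

Defaults follow the common convention for this chain: 1,000 accepted swaps of
burn-in, then the C-score recorded after each of 30,000 further accepted
swaps (rejected proposals are free; "simulations" counts recorded states).
The standardized effect size `SES = (C_obs − mean_null)/sd_null` uses the
sample standard deviation; `SES > 2` is read as segregation (deterministic
exclusion), `SES < −2` as aggregation, `|SES| ≤ 2` as consistent with
stochastic assembly. The chain's scores are updated incrementally in C++
(only pairs involving the two swapped rows change), so a 30,000-state null
on a few-hundred-taxon table takes well under a second. Calibration is
tested by drawing matrices from their own null via a long independent chain:
|SES| ≤ 2 in ≥ 90% of replicates, with the SES ensemble mean within ±0.3 and
sd within [0.7, 1.3].

The niche simulator provides the positive control: taxon `j` has expected
abundance `∝ capacity_j · exp(−(g_i − opt_j)²/(2 tol_j²))` along a
salinity-like gradient `g`, with multinomial read sampling. Two opposed
guilds (optima at the gradient ends, small tolerance) produce the
checkerboarded incidence structure of environmentally filtered assembly and
yield SES far above 2.

# Levins niche breadth

For taxon `j` with usage proportions `u_ij` across samples,
`B_j = 1/Σ_i u_ij²` (inverse Simpson concentration; 1 for a single-sample
specialist, `n_samples` for a perfectly even generalist), and `Bcom` is the
mean over taxa with positive totals. In paired niche simulations differing
only in tolerance (25 ‰ vs 2 ‰), the generalist community's `Bcom` exceeds
the specialist's in every replicate — the qualitative pattern expected when
high-salinity communities harbour generalists and low-salinity communities
specialists.

# Diversity, ordination, and environmental heterogeneity

Shannon diversity uses natural logarithms by default (`base` argument
available); Bray–Curtis distances come from `vegan::vegdist`; UPGMA is
average-linkage `hclust` returned as an `ape` tree (ultrametric node heights
equal half the merge distance). ANOSIM is implemented from its definition —
`R = (mean between-group rank − mean within-group rank)/(M/2)` with
permutation p-value `(1 + #{R_perm ≥ R_obs})/(1 + n_perm)`, default 9,999
permutations — and is cross-checked in the tests against both an exhaustive
enumeration of label assignments on a six-sample toy set and
`vegan::anosim`. PCA centres but does not scale relative abundances (the
usual convention for proportion data). Environmental heterogeneity
z-standardises the chosen abiotic variables (default: salinity and the three
nutrients) jointly over all samples and reports the mean pairwise Euclidean
distance within each group; constant variables are dropped with a warning.

`generate_group_metadata()` reproduces the study design the package targets:
low-salinity samples uniform on [0, 14.58) ‰ with wide nutrient ranges
(nitrate 67.47–494.4, silicate 1.13–157.64, phosphate 4.155–26.885 μM) and
high-salinity samples above 21.08 ‰ with narrower ranges (0.139–149.223,
0.22–65.031, 0.016–6.481 μM). The upper salinity bound of 33 ‰ is a
realistic shelf endmember; only the lower bound is constrained by the
grouping rule. Because the low-salinity ranges are much wider,
heterogeneity(low) > heterogeneity(high) on generated metadata — a property
the tests assert.

# Co-occurrence networks

Edges are screened on relative abundances within each group: Spearman's rank
correlation (average ranks on ties) for every taxon pair, two-sided p-value
from the t approximation, and the conventional validity rule |r| > 0.6 with
p < 0.05, applied after a prevalence/abundance pre-filter (present in more
than two samples, mean relative abundance above 0.2%). No multiple-testing
correction is applied by default, matching that rule; Benjamini–Hochberg is
available behind `p_adjust = "BH"`. Topology reports density, diameter and
average path length over reachable pairs (component-wise, weighted by pair
counts), mean local clustering (isolates contribute 0), greedy-modularity
modules (deterministic `cluster_fast_greedy`, relabelled by decreasing
size), and the positive-edge fraction. `er_ensemble()` draws G(n, m) graphs
with identical node and edge counts and reports z-scores of the real
network's clustering, path length and modularity — the small-world, modular
signature is clustering and modularity above the ensemble mean.
`degree_distribution_fit()` compares a least-squares power law on log–log
frequencies with a maximum-likelihood Poisson; both R² values are computed
on the linear proportion scale (log-scale comparison breaks down where the
Poisson pmf underflows), and the better family is reported.

Robustness uses **natural connectivity**,
`ln((1/V) Σ_i e^{λ_i})` over adjacency eigenvalues, computed with
log-sum-exp to avoid overflow; `robustness_curve()` removes growing random
node fractions (default grid 0–0.8 by 0.05, 100 repetitions) and averages
the surviving subgraph's natural connectivity, starting exactly at the
intact value at `f = 0`.

# Pipeline and reproducibility

`run_full_analysis()` chains the stages — load or simulate, rarefy
(default depth 1,732 reads; samples below depth dropped with a warning,
rarefaction before the group split), split by metadata group, per-group NCM
/ null model / niche breadth / network, plus cross-group diversity, UPGMA,
ANOSIM, PCA and heterogeneity — from a single `run_config()` (YAML-loadable;
flags override file values in the CLI wrapper under `inst/cli`). Every
stochastic step is seeded from the single config seed, so identical configs
produce byte-identical JSON reports; `make_report()` renders a Markdown
table per group from the same numbers.

# Problem sizes used in validation

The test-suite and acceptance-script simulations use: 40 local communities
of 1,000 reads over a 300-taxon metacommunity for NCM recovery (with
`m ∈ {0.1, 0.3, 0.6}` and ten seeds for the monotonicity check); 20×20
half-filled binary matrices with 3,000-state null chains (50 replicates) for
SES calibration; two 50-taxon guilds over 20 samples spanning 0–35 ‰ for the
segregation positive control; and 30,000-state chains for single headline
runs. These sizes give stable Monte-Carlo behaviour for the properties being
checked while keeping the whole suite fast.

# What the generators do and do not emulate

The neutral simulator produces independent equal-size local communities at
stationarity under a fixed metacommunity — no spatial structure, no temporal
autocorrelation, no varying sequencing depth. The niche simulator imposes a
single environmental axis with Gaussian responses and multinomial sampling —
no interactions, no compositional coupling beyond the fixed read total, no
phylogenetic signal. Passing the validation suite therefore shows that the
estimators recover truth under their own assumptions; it does not show that
real estuarine communities satisfy those assumptions. In particular,
compositionality (Spearman on relative abundances), uneven true community
sizes, and PCR/primer biases are real-data complications deliberately
outside the generators' scope.

# Known limitations

* The NCM fit inherits the Beta approximation to the full beta-binomial
  sampling model; the median-detection limit removes most, not all, of the
  resulting bias, and `m` near 1 is estimated with large variance.
* The sequential-swap chain mixes slowly for very dense or very structured
  incidence matrices; the per-swap proposal budget guards against stalls but
  extremely degenerate margins may still need a custom `burn_in`.
* Greedy modularity is deterministic but not optimal; module identities are
  comparable across runs, not across algorithms.
* ANOSIM p-values are sampled permutations, not exact, except in the tests
  where exhaustive enumeration is feasible.
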