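---
title: "Methods: MEA spike-train network analysis in meanet"
author: "meanet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA spike-train network analysis in meanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meanet)
```

# Overview

`meanet` analyzes sorted spike trains recorded with a multielectrode array
(MEA) from the same preparation under two paired conditions — typically a
baseline recording and a recording after an acute pharmacological
manipulation such as bath-applied amyloid-beta. The pipeline runs, per slice
and condition:

1. unit firing statistics and population-burst detection on the summed
   raster;
2. K-means classification of single units into putative pyramidal neurons
   (PPyrN) and putative interneurons (PIN);
3. cross-correlogram functional connectivity with a noise-based
   significance threshold;
4. graph-theoretic metrics and centralities on the binary link graph;
5. small-world sigma and omega against random and lattice null ensembles;
6. a weighted spectral-scaling (Estrada-index) classification of nodes and
   networks into topological classes I–IV.

Slices are the statistical unit for network endpoints: study-level
comparisons pair each slice's baseline value with its treated value.

# Time base and discretization

All timestamps are in milliseconds. Rasters use half-open bins
`[t, t + dt)`: a spike at exactly `t = 1.0` ms with 1-ms bins belongs to the
second bin. Spike occupancy is binary at the 1-ms analysis resolution; with
the 2-ms refractory period enforced at sorting time no unit can occupy a
1-ms bin twice, so binarization loses nothing. Burst analysis re-aggregates
the 1-ms raster into 500-ms bins.

# Population bursts

The burst statistic is the per-500-ms-bin sum of occupied 1-ms bins over
all units ("popsum"). The noise level is defined deterministically as the
root-mean-square of the mean-subtracted popsum over the whole record; burst
events are local maxima at least five times that RMS above the popsum mean.
A constant popsum has zero RMS and, by convention, no events. Both the
event count (and count per minute) and the mean peak height are reported,
since either can serve as the "bursting activity" summary; the count is the
more robust of the two when a condition has no events at all.

# Cell typing

Single units are clustered in the plane of trough-to-peak waveform width
(ms) and firing rate (Hz). The rate is log10-transformed — firing rates are
approximately log-normal across a population — and both features are
z-scored so neither dominates the Euclidean metric. K-means with k = 2 and
50 restarts under a fixed seed makes the partition reproducible. Cluster
labels are anchored by waveform width: the broader-waveform cluster is
always PPyrN. Group comparisons use Mann–Whitney tests plus Cohen's d
(pooled-SD definition).

# Functional connectivity

For each unordered unit pair the cross-correlogram counts co-occupied 1-ms
bins at lags up to ±50 ms and is normalized by `sqrt(N_i * N_j)`, the
geometric mean of the two units' occupied-bin counts. This normalization
bounds weights by 1 (a train against itself gives exactly 1 at lag zero)
and removes the first-order dependence of coincidence counts on firing
rate, so that condition-induced rate changes do not masquerade as coupling
changes. "Correlation noise" is estimated from the flanking lags
`10 < |lag| <= 50` ms — far enough from zero lag to exclude monosynaptic
synchrony, wide enough (80 bins) for a stable mean and SD, and fully
deterministic (no surrogate resampling in the default path). A pair is a
positive link when the peak within ±5 ms exceeds the flank mean by more
than 5 flank SDs; the stored weight is the normalized peak excess
(peak − flank mean). Troughs below the mirror-image threshold give negative
links. If both are significant the larger absolute excess wins. Pairs with
fewer than 10 spikes in either train are skipped: the normalization is
unstable there. The zero-lag bin can be excluded (for same-electrode pairs
where zero-lag coincidences can be sorting artifacts) but is included by
default. Both SUA and MUA units enter the correlation analysis.

# Graph metrics

Metrics are computed on the binary adjacency derived from the positive
link matrix (an edge wherever the weight is nonzero). The experimental
graphs routinely have several connected components, so the package fixes
the following conventions: the characteristic path length averages
shortest-path lengths over connected pairs only (the excluded fraction is
reported); closeness is the reciprocal of the total hop distance to the
nodes reachable from a node; eccentricity is per component; and eigenvector
centrality is the leading eigenvector of the full adjacency matrix, which
concentrates on the dominant component — a property inherited by the
spectral classification below. Betweenness is unnormalized, endpoints
excluded, each unordered pair counted once; local clustering is zero for
nodes of degree < 2. The leading eigenvector comes from a full symmetric
eigendecomposition rather than an iterative sparse solver: the matrices are
small (tens of nodes) and the decomposition is exact and deterministic.

# Small-world indices

`sigma = (C/C_rand) / (L/L_rand)` and `omega = L_rand/L − C/C_latt`.
"Equivalent random networks" are degree-preserving double-edge-swap
randomizations (about 10·m accepted swaps per surrogate); "equivalent
lattices" come from swap-based latticization, which accepts only swaps that
do not increase the total distance of edges from the diagonal of the
adjacency matrix under a random node ordering. Both null kinds therefore
preserve n, m and the degree sequence exactly, and both inherit the
connected-pairs convention for L. The default ensemble size is 1,000; the
package's validation profile uses 100 (30 inside the full pipeline), which
changes sigma by under 2% on a Watts–Strogatz benchmark. Omega is clipped
to [−1, 1] with a warning; values in (−0.3, 0.3) are read as small-world.

# Spectral scaling and topological classes

For the non-negative weighted positive-link matrix `W` with eigenvalues
`lambda_1 >= ... >= lambda_n` and orthonormal eigenvectors `phi_j`, the
odd-subgraph centrality `SC_odd(i) = sum_j phi_j(i)^2 sinh(lambda_j)`
counts odd closed walks (local communicability), and the principal
eigenvector component `x_i` measures global communicability. In a
homogeneous network the two are linked by the ideal scaling line

```
log10 x_i = 0.5 * (log10 SC_odd(i) − log10 sinh(lambda_1))
```

Each node's vertical log10 distance from this line is its residual `r_i`.
The class-I band half-width is `tau = sqrt(mean(r_i^2))`, the RMS distance
to the line (a "variance of distances" read in the same units as the
residuals; a squared-units variant is available as `threshold_mode =
"variance"`). Nodes with `|r_i| <= tau` are class I; `r_i < −tau` is class
II (structural holes: strong local, weak global communicability); `r_i >
tau` is class III (central cores). A network is class IV when at least 5%
of classified nodes fall in each of II and III, class II/III when only the
respective side does, and class I otherwise.

Two numerical choices deserve emphasis:

* **Threshold floor.** `tau` is floored at 0.01 log10 units, the classical
  good-expansion tolerance of spectral scaling. Homogeneous networks (e.g.
  dense Erdős–Rényi graphs) satisfy the scaling law almost perfectly — the
  residual spread collapses to ~1e-5 — and a purely relative band would
  then classify numerical noise as topology. Below the floor the network
  is simply homogeneous. Experimental-scale weighted matrices have
  residuals orders of magnitude above the floor, so it never binds there.
* **Degenerate regular graphs.** In a vertex-transitive graph all residuals
  are equal, so `tau` equals the common `|r_i|` and every node sits exactly
  on the class-I boundary; a 1e-9 slack keeps them class I rather than
  letting floating-point ties split the classes.

Nodes with `SC_odd` or `x` at or below 1e-12 are reported unclassified —
every node of a bipartite graph has zero odd closed walks, and such inputs
fail with an explicit message. Disconnected weighted matrices are
classified whole, via the Perron vector of the full matrix; this mirrors
the eigenvector-centrality convention above and means the classification
reflects which block spectrally dominates.

# The synthetic-data generator

No public recordings accompany the analysis this package implements, so a
generator produces paired-condition studies with known ground truth.

**Baseline.** Each unit fires as a homogeneous Poisson process with
refractory deletion (2 ms). Single units belong to two classes drawn as
Gaussian clusters in (trough-to-peak, log10 rate): broad/slow
(0.76 ms, 3.2 Hz) versus narrow/fast (0.22 ms, 6.9 Hz), with 78.9% in the
broad class. The waveform spread (0.10 ms) is set so that the
post-clustering effect size on waveform width lands in the d ≈ 4–5 range
reported for this kind of separation; the log-rate spread (0.4) leaves the
rate dimension informative but overlapping, as in real populations.
Multi-unit channels are superpositions of 2–4 hidden trains and are
excluded from cell typing. Pairwise coupling is planted by common-parent
coincidence injection: a latent parent train of rate `c * min(rate_i,
rate_j)` contributes one spike to each member with independent ≤1-ms
jitter (≤2-ms relative jitter — inside the ±5 ms analysis window). Each
unit's background rate is reduced by its expected injected load so
realized rates stay near the class means. The default baseline coupling
has four communities (within-community coupling probability 0.55,
strengths 0.12–0.2), giving graphs with average degree ≈ 6, density ≈
0.14, 1–3 components, clustering ≈ 0.5 and sigma ≈ 3 — the regime of the
experimental networks this emulates.

**Treated condition.** Unit directions (62% decrease, 37% increase, 1%
unchanged — apportioned deterministically, assigned randomly) scale rates
by thinning (factor 0.4) or superposition (factor 1.5). When the baseline
ground truth is available, the thinning distinguishes background from
planted-coincidence spikes: background spikes are thinned per unit, while
each pair's shared parent events are kept or dropped *jointly* with
probability `sqrt(s_i s_j)`. Because the correlogram normalization is also
the geometric mean of the spike counts, planted weights are invariant
under rate changes — synchrony rides on shared drive and is not destroyed
by independent deletion, which is both the biologically sensible model and
the regime in which observed correlation strengths survive a global rate
decrease. Population-synchrony epochs (one per minute, 100–500 ms, half
the units participating at 8× rate) create the burst peaks; the epoch
count is deterministic so it is recoverable up to detection error. Network
reconfiguration is injected as a coupling delta: mild global potentiation
(+0.03), stronger potentiation (+0.25) inside the two communities that
already carry the largest coupling mass (synchrony reorganizes around the
dominant assemblies), and four hub units inside those cores attaching to
80% of their community and 5% elsewhere. Injected load is capped at 50% of
a unit's rate and compensated above a free allowance of 25%, so coupling
changes do not masquerade as rate changes.

**What the generator does not emulate.** Oscillatory structure and
spike–LFP locking, bursting cell intrinsics (all background trains are
Poisson), distance-dependent connectivity and electrode geometry, spike
sorting errors, and non-stationarities other than the injected epochs.
Passing recovery tests on this generator therefore validates the
*estimators* (binning, thresholds, nulls, spectral classification), not
robustness to those real-data complications. The LFP synthesizer shapes
white noise in the frequency domain to a requested Delta/Theta/Beta/Gamma
band profile and exists to validate the band-power estimator, not to model
hippocampal field potentials.

# Statistical conventions

Paired endpoints use Shapiro–Wilk on the paired differences to choose
between the paired t-test and the Wilcoxon matched-pairs signed-rank test;
both the choice and the result are reported, and all-zero differences give
p = 1 by convention. Chi-square tests of cell-type × change-direction
tables are Pearson without continuity correction (a Yates flag exists), and
Fisher's exact test backs the class-IV network contingency. Cumulative
degree distributions are compared with Kolmogorov–Smirnov. The "unchanged"
rate category uses a 1% relative tolerance: genuinely unchanged units are
rare, so the bound is deliberately near-exact and is logged with every
report. No multiple-testing correction is applied by default; a
Benjamini–Hochberg flag is available and off by default.

# Problem sizes used in validation

The test suite and the acceptance script use 10-minute recordings with
40–60 single units plus 2–4 multi-unit channels per slice, 8-slice
studies, 30-null ensembles inside the pipeline and 100-null ensembles for
the small-world benchmark, and 25-graph ensembles for the spectral-class
construct checks. These sizes put every estimator comfortably in its
asymptotic regime (e.g. planted couplings of strength 0.1 are detected
with z-scores far above the 5-SD threshold at 600 s) while keeping a full
run in minutes.

# Known limitations

* The correlogram noise model assumes flank lags are coupling-free;
  couplings with genuine structure beyond ±10 ms would inflate the noise
  estimate and reduce sensitivity (by design: the method targets tight,
  putatively monosynaptic synchrony only).
* Eigenvector-based quantities (centrality, spectral classes) are
  dominated by the largest component / strongest block in disconnected or
  strongly modular graphs; per-component analysis is possible but changes
  the interpretation and is not the default.
* The class-II/III split depends on which communities spectrally dominate;
  in studies where the treated condition strengthens an already dominant
  assembly only mildly, the class-I percentage can move little even when
  class III grows.
* Small-world indices on graphs with very low clustering or near-empty
  lattices can push omega outside [−1, 1]; the package clips and warns
  rather than failing.
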