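# meanet

Network analysis of multielectrode-array (MEA) spike recordings under
paired experimental conditions.

`meanet` is written for electrophysiologists who record spontaneous
activity from tissue slices (e.g. hippocampal CA1) with an MEA, sort it
into single-unit (SUA) and multi-unit (MUA) spike trains, and want to ask
how an acute manipulation — a drug wash-in, a peptide such as amyloid-beta,
a stimulation protocol — reorganizes the *functional network*, not just the
firing rates. The package takes sorted timestamps for two paired conditions
per slice and runs the complete analysis chain; a synthetic-data module
generates paired recordings with planted ground truth so every stage can be
validated without access to raw data.

## What it computes

**Activity.** Per-unit firing rates; population bursts as local maxima of
the summed raster in 500-ms bins exceeding the popsum mean by ≥ 5× the RMS
of the mean-subtracted signal; classification of units into
increased / decreased / unchanged between conditions; K-means typing of
single units into putative pyramidal neurons and interneurons from
trough-to-peak waveform width and log10 firing rate; LFP band power
(Delta 0.5–4, Theta 4–10, Beta 10–25, Gamma 25–50 Hz) from a Hann-tapered
periodogram.

**Connectivity.** Cross-correlograms at 1-ms lag resolution, normalized by
√(NᵢNⱼ) so weights lie in [0, 1] and are rate-independent to first order.
A pair is functionally connected when its peak within ±5 ms exceeds the
flank noise mean (10 < |lag| ≤ 50 ms) by more than 5 SD; weights are the
normalized peak excess, and signed binary/weighted link matrices are built
per condition.

**Graphs.** Degree kᵢ = Σⱼ Aⱼᵢ, average degree, density ρ = 2m/(n(n−1)),
components, characteristic path length (connected pairs), local and average
clustering, betweenness, closeness, eigenvector centrality, eccentricity,
degree distributions. Small-world σ = (C/C_rand)/(L/L_rand) and
ω = L_rand/L − C/C_latt against degree-preserving random and latticized
null ensembles.

**Topological classes.** The Estrada index EE = Σᵢ exp(λᵢ), odd-subgraph
centralities SC_odd(i) = Σⱼ φⱼ(i)² sinh(λⱼ), and a spectral-scaling
classification on the weighted positive-link matrix: each node's log10
distance from the ideal line log₁₀ xᵢ = ½·log₁₀[SC_odd(i)/sinh(λ₁)] is
compared with a data-derived threshold; nodes below the band are class II
(structural holes), above it class III (central cores), inside it class I,
and networks containing both II and III nodes are class IV.

**Orchestration.** `run_pipeline()` runs everything per slice per
condition, pairs the endpoints across slices (Shapiro–Wilk-gated paired
t / Wilcoxon, chi-square/Fisher for categorical endpoints,
Kolmogorov–Smirnov for degree distributions) and writes JSON/CSV/GEXF
outputs. A thin command-line wrapper lives in `inst/cli/meanet.R`.

## Worked example

```r
library(meanet)

# one synthetic slice: 40 SUA + 4 MUA units, 10 min, community coupling
sim <- simulate_study(n_slices = 1, seed = 42)
s   <- sim[[1]]
print(s$baseline)
#> SpikeTrainSet: slice slice01, condition baseline
#>   44 units (40 SUA, 4 MUA), 180553 spikes, 600.0 s span

mean(unit_rates(s$baseline))
#> 6.84  (Hz)

conn <- build_connectivity(cross_correlogram_set(s$baseline))
c(conn$n_pos, conn$sum_pos)
#> 130 positive links, weight sum 4.56

G <- as_mea_graph(conn$A_pos)
network_metrics(G)[c("avg_degree", "density", "char_path_length")]
#> avg degree 5.91, density 0.137, L 3.05

small_world_indices(G, n_nulls = 100, seed = 42)[c("sigma", "omega")]
#> sigma 2.86, omega 0.01   (highly clustered, short paths: small-world)

nc <- classify_network(classify_nodes(conn$W_pos))
nc$percentages; nc$network_class
#> I 70.5%, II 0.0%, III 29.5%  -> network class III
```

The mean rate sits near the population the generator emulates (mostly
pyramidal-like units around 3 Hz plus faster interneuron-like units and
multi-unit channels); 130 of 946 possible pairs cross the 5-SD correlogram
threshold, giving a sparse graph (density 0.14) that is strongly
small-world (σ ≫ 1, ω ≈ 0); and the spectral classification finds a
dominant-core structure in this particular slice. Applying the default
treatment effect (`apply_condition()` with majority rate decrease, 1
synchrony epoch/min, and the hub-creating coupling delta) and re-running
detects ~8 population-burst events per 10 minutes where the baseline has
none.

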