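# cinet — functional network analysis of calcium imaging time series

Calcium imaging yields one fluorescence trace per cell. After traces have
been extracted (by Suite2p, CaImAn, Fiji, ...), the scientific questions
shift downstream: which cells fire together, how is the population organized
as a network, and how does a genetically labeled subset interact with the
rest? `cinet` is an R package for exactly this downstream stage. It takes a
cells-by-time trace matrix, a cell coordinate table (with an optional
`Label` column marking a subset), and the acquisition frame interval, and
runs a single deterministic pipeline:

1. **Preprocessing** — per-cell min-max normalization
   `x'ₜ = (xₜ − min x) / (max x − min x)` (z-score optional), then
   binarization into active/inactive states at `μ + 2σ` per cell (custom
   rules supported).
2. **Population activity** — percentage of active cells over time, mean
   calcium-event frequency (rising-edge onsets per minute), and a raster
   ordered by Ward hierarchical clustering.
3. **Functional connectivity** — lagged cross-correlation
   `ρᵢⱼ(τ) = Kᵢⱼ(τ)/(σᵢσⱼ)` for lags τ ∈ {−1, 0, +1} (configurable), with
   edge weight `ρ_max = max_τ |ρᵢⱼ(τ)|`.
4. **Network analysis** — an undirected graph with edges
   `{(i,j) : ρ_max ≥ θ}` (θ = 0.3 by default), node degrees and mean degree
   ⟨k⟩, average clustering coefficient C(g), global efficiency G(g)
   (hop-count shortest paths, unreachable pairs contribute zero), and
   leading-eigenvector community detection with an exactly evaluated
   modularity Q.
5. **Subset analysis** — the induced network of labeled cells, their event
   frequency, and the labeled-to-unlabeled connection proportion
   `LtU = cross edges / (n_labeled × n_unlabeled)`.
6. **Spectra and dimensionality** — PCA of the traces (variance captured by
   the top five components) and per-cell Welch power spectral density.

Every stage is also exported as a standalone function
(`normalize_minmax()`, `binarize()`, `connectivity_matrix()`,
`build_graph()`, `detect_communities()`, `ltu_proportion()`,
`pca_traces()`, `welch_psd()`, ...), and a seedable synthetic-population
generator with planted assemblies and a labeled subset
(`synth_spec()` / `generate_population()`) provides ground truth for
validation.

## Worked example

```r
library(cinet)

# a synthetic recording: 60 cells, 450 frames at 2 s, 3 planted assemblies,
# 15% of cells labeled "RFP"
sim <- generate_population(synth_spec(seed = 7))

report <- run_pipeline(sim$traces, sim$cells,
                       config = cinet_config(`subset.label` = "RFP"),
                       out_dir = "run1")
report
#> <pipeline_report>
#>   60 cells x 450 time points
#>   Top-5 PC variance (%)                      75.687
#>   Clustering coefficient                     1
#>   Global efficiency                          0.32203
#>   Mean degree                                19
#>   Modularity                                 0.66667
#>   Large communities (> threshold members)    3
#>   Event frequency (events/min)               1.4633
#>   Labeled-to-unlabeled proportion (LtU)      0.32026
#>   Labeled event frequency (events/min)       1.3778
```

Reading the numbers: the three planted 20-cell assemblies appear as three
large communities with modularity 2/3 — each assembly is internally fully
connected at θ = 0.3 (clustering coefficient 1, mean degree 19) and
disconnected from the others, giving a global efficiency of about 0.32
(within-assembly pairs are 1 hop, cross-assembly pairs unreachable).
Correlated activity concentrates variance in a few principal components
(top-5 ≈ 76%). The labeled subset here is unperturbed, so its event
frequency matches the population and roughly a third of possible
labeled-unlabeled pairs are connected (the labeled cells sit inside
assemblies).

`run1/` then contains every intermediate (`normalized.csv`, `raster.csv`,
`connectivity.csv`, `graph.graphml`, `edges.csv`, `membership.csv`,
`activity.csv`, `scree.csv`, `psd.csv`), the summary `report.json`, the
echoed `config.yaml` and a `manifest.json`. Figures:

```r
render_figures(report, "run1/figures")   # activity, raster, network, scree, PSD
```

Real data enter through `read_traces("traces.csv", frame_interval_s = 2)`
and `read_cells("cells.csv")` (columns `X`, `Y`, `Cell`, optional `Label`).
A thin command-line front-end ships in `inst/exec/cinet`
(`run`, `simulate`, `report` subcommands).

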