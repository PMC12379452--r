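---
title: "Methods and design notes for cinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for cinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinet)
```

cinet analyzes populations of pre-extracted calcium-imaging fluorescence
traces — one trace per cell/ROI, sampled at a fixed frame interval — and
characterizes the population as a functional network. This vignette explains
the model behind each stage, the conventions and tunable parameters, what
the synthetic generator does and does not emulate, and the design decisions
that were genuinely open.

## The analysis model

### Normalization

Fluorescence amplitude mixes biology with indicator expression level, so
traces are normalized per cell before any cross-cell comparison. The default
is min-max scaling,

$$x'_t = \frac{x_t - \min(x)}{\max(x) - \min(x)},$$

which maps every cell onto $[0, 1]$ with both bounds attained. It is simple
and interpretable but sensitive to outlier frames, which define the bounds.
A z-score alternative (`normalize_zscore()`: mean 0, unit sample variance,
unbounded) is available and selectable via `normalization.method`; the two
are deliberately kept as distinct, explicitly chosen routes rather than
silently merged, because they answer different questions about amplitude.
Constant traces have no range; min-max maps them to all zeros with a warning
rather than NaN, so matrix shapes survive downstream.

### Binarization and events

A cell is *active* at frame $t$ when its normalized signal strictly exceeds
$\mu + k\sigma$, with $\mu$ and $\sigma$ (sample standard deviation,
denominator $n-1$) taken over that cell's full recording and $k = 2$ by
default. Because the threshold co-varies with the trace's own statistics,
binarization is invariant to per-cell affine rescaling — the raster does not
depend on indicator expression level. A custom per-cell rule can replace the
threshold entirely. A calcium *event* is defined as a rising edge of the
binarized trace (a 1 in the first frame counts as an onset); the frequency
report is mean onsets per minute, with recording duration taken as
`n_time * frame_interval_s`. An occupancy variant (`events.mode = "frames"`)
counts active frames instead and is not claimed equivalent.

### Functional connectivity

Coupling between cells $i, j$ is the lagged cross-correlation

$$\rho_{ij}(\tau) = \frac{K_{ij}(\tau)}{\sigma_i \sigma_j}, \qquad
K_{ij}(\tau) = \frac{1}{T} \sum_{\text{valid } t}
  (x_i(t+\tau) - \mu_i)(x_j(t) - \mu_j),$$

with means and standard deviations over the full series ($1/T$
normalization) and the lag sum truncated to the overlap — the classical
estimator conventions, identical to `stats::ccf()`. A consequence worth
knowing: a perfect one-frame-shifted copy scores slightly below 1 at its
true lag, because the overlap is one frame short. The connection strength is
$\rho_{\max} = \max_{\tau \in \text{Lag}} |\rho_{ij}(\tau)|$ over
$\tau \in \{-1, 0, +1\}$ by default (`connectivity.lag_max`), accommodating
single-frame response delays; the attaining lag is recorded with a fixed
tie-break (smallest $|\tau|$, then negative first) so reports are
deterministic. Whether the correlation is computed on the binarized raster
(default, `connectivity.source = "binarized"`) or on the continuous
normalized traces is an explicit configuration choice: both conventions are
defensible — binarization suppresses noise floors before correlating, the
continuous route retains amplitude information — and the package supports
both without privileging either in its documentation. Constant cells are
assigned zero connectivity (isolated) with a warning.

### Network construction and metrics

The graph keeps an edge for every pair with $\rho_{\max} \ge \theta$
(inclusive, per the set definition $E = \{(i,j) : \rho_{ij,\max} \ge
\theta\}$); `network.threshold` defaults to 0.3, `"none"` disables
filtering, and the `"strict"` preset uses 0.6. Isolated nodes stay in the
vertex set. All topological metrics are computed on the *unweighted*
thresholded topology — the defining formulas below are binary-adjacency
formulas, and weights are retained for display and export only:

- degree $k_i$ and mean degree $\langle k \rangle = 2|E|/N$;
- average clustering coefficient
  $C(g) = \operatorname{mean}_i \; 2e_i / (k_i(k_i-1))$, where $e_i$ counts
  edges among the neighbors of $i$. The formula divides by zero for nodes
  with $k_i < 2$; such nodes are excluded from the average (the local-average
  convention of the standard graph library), with `count_low_degree = TRUE`
  offering the count-as-zero alternative. An empty average returns 0;
- global efficiency
  $G(g) = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$ with hop-count shortest
  paths and unreachable pairs contributing zero. This zero-contribution
  convention matters: on sparse, fragmented networks it drives $G(g)$
  toward zero, which is the regime typical of thresholded whole-population
  calcium networks.

### Community detection

Communities are found with the leading-eigenvector method: the modularity
matrix $B_{ij} = A_{ij} - k_ik_j/2m$ is split along the sign pattern of its
leading eigenvector, recursively on each part via the generalized modularity
matrix, stopping when the leading eigenvalue is non-positive (tolerance
$10^{-10}$) or the modularity gain is not positive (tolerance $10^{-12}$).
The method is deterministic by construction here: dense symmetric
eigendecomposition, eigenvector sign fixed (first nonzero component
positive), zero components grouped with the negative side, and communities
renumbered by first node occurrence. The reported modularity is always a
direct evaluation of $Q = \sum_c (e_c/m - (d_c/2m)^2)$ on the returned
partition, never a by-product of the recursion. A community is counted
"large" when it has more than five members (`community.large_threshold`).

### Labeled-subset analysis

When a label marks a subset (e.g. cells carrying a second reporter), three
views are reported: the induced subgraph on labeled cells with the same
metrics; the labeled event frequency; and the labeled-to-unlabeled
proportion

$$\mathrm{LtU} = \frac{\#\{\text{edges with exactly one labeled endpoint}\}}
  {n_{\text{lab}} \cdot n_{\text{unlab}}},$$

i.e. realized cross edges over all possible cross pairs. With an undirected
graph this is the natural reading of "connections from labeled to unlabeled
over total possible"; each undirected cross edge is counted once. Cells
with any other label count as unlabeled.

### PCA and spectra

PCA runs with cells as observations and time points as (centered, unscaled)
variables — the literal behavior of handing the cells-by-time matrix to
`stats::prcomp()`. The orientation and the centering-without-scaling choice
are conventions, flagged as such; `pca.orientation = "time"` exposes the
transpose analysis without claiming equivalence. The headline number is the
percentage of variance in the top $\min(5, n_{\text{components}})$
components, with $n_{\text{components}} = \min(n_{\text{cells}}-1,
n_{\text{time}})$.

The per-cell power spectral density uses Welch's method: overlapping
segments (default `min(256, n_time)` samples, 50% overlap), per-segment
demeaning, a periodic Hann taper, and averaging of one-sided modified
periodograms scaled per unit frequency ($1/(f_s \sum w^2)$, interior bins
doubled), so the integrated spectrum approximates signal variance. The
segment length, overlap and taper are artifact defaults — standard Welch
practice — since only the method itself is prescribed. With a rectangular
window and a single full-length segment the estimate reduces exactly to the
plain periodogram, which is one of the test oracles.

## The pipeline

`run_pipeline()` executes load → normalize → binarize → population activity
(active-cell percentage, event frequency, Ward-ordered raster) →
connectivity → graph → metrics + communities → subset analysis (when a
label is configured) → PCA + PSD → report, writing every intermediate as
plain text and a summary report with the six headline fields
(`top5pc_var_percent`, `clustering_coeff`, `global_efficiency`, `ltu`,
`freq_events_per_min`, `freq_labeled`). Nothing in the pipeline draws
random numbers, so two runs on identical inputs are byte-identical; the
manifest stores run-relative file names to keep run directories comparable
and relocatable. A failing stage aborts with a stage-tagged message after
flushing a manifest that marks the run incomplete.

Raster ordering uses agglomerative clustering on the normalized traces,
default Ward (squared-update formulation on Euclidean distances, i.e.
`ward.D2`), which favors compact clusters; `complete`, `average` and
`single` are selectable because Ward's compactness bias can hide broader
co-activation structure.

## The synthetic generator

`generate_population()` exists so that every stage can be validated against
known ground truth. The model: each of `n_assemblies` assemblies carries a
Bernoulli shared-event train (per-frame probability
`event_rate_hz * frame_interval_s`); members express each shared event with
probability `within_coupling` (0.9), non-members with `cross_coupling`
(0.02); spike trains are convolved with an exponential kernel
(`decay_s`, truncated at five decay constants — the tail beyond is
negligible and the convolution stays cheap); a per-cell gain drawn from
`amplitude_range` (0.5–2) deliberately exercises min-max normalization;
Gaussian noise (`noise_sd = 0.1`) is added; same-assembly cells are placed
in spatial blobs; a `labeled_fraction` (0.15) of cells is marked `"RFP"`.

The defaults — 60 cells, 450 frames at 2 s per frame, 3 assemblies, shared
events at 0.03 Hz, 1.5 s decay — emulate a population recording at the
hundreds-of-frames, 0.5 Hz scale. The event rate and kernel are chosen
together so transients stay sparse relative to their width: in that regime
a mean-plus-2-standard-deviations detector sees onsets in proportion to the
true rate. At substantially higher rate-kernel products, calcium summation
raises the per-cell threshold toward the single-event peak and onset
detection saturates or even inverts rate contrasts — a real phenomenon in
slow-indicator recordings, but the wrong regime for a fixture whose labeled
subset must display its planted rate elevation. The problem sizes used in
the validation suite (60 cells, 450 frames, 20 seeds for stochastic
checks) are the package's chosen fixture scale: large enough for stable
network statistics, small enough to iterate on.

Two perturbation dials mirror a treatment-versus-control contrast: a
`labeled_rate_multiplier > 1` gives labeled cells additional private
(uncorrelated) events, raising their event frequency without raising their
coupling; `labeled_coupling < 1` scales labeled cells' expression of
assembly events, weakening their integration with the rest of the network
and hence lowering LtU. Under the validated conditions
(`labeled_rate_multiplier = 1.8`, `labeled_coupling = 0.5`), the perturbed
fixture shows higher labeled event frequency and lower LtU than its matched
control in 20/20 paired seeds, and community detection recovers the planted
assemblies with median adjusted Rand index 1.

What the generator does *not* emulate: biophysical calcium-binding
kinetics, photobleaching and drift, movement artifacts, spatially
correlated imaging noise, heterogeneous per-cell event rates, or
overlapping assembly membership. Passing tests on this fixture therefore
demonstrate that the pipeline's inference machinery is correct under its
own model assumptions — not that those assumptions cover every real
recording. In particular, baseline drift (no detrending/ΔF/F correction is
performed) will widen per-cell standard deviations and depress event
detection on real data.

## Numerical choices and degenerate inputs

- Sample standard deviation ($n-1$) in binarization; population ($1/T$)
  normalization inside the correlation estimator — each matching the
  convention of the standard routine for that step.
- Strict `>` in the binarization comparison; inclusive `>=` in edge
  thresholding.
- Constant traces: all-zero after min-max (warning), all-zero raster row
  (warning), zero connectivity row/column (warning), z-score refuses with
  an error naming the cell.
- Connectivity matrices are symmetrized exactly (averaging the two float
  triangles) and clamped to $[0, 1]$; the diagonal is pinned at 1.
- Eigen-split tolerances as above; merge heights from Ward are
  non-decreasing by construction; hclust tie-breaking is deterministic
  given input order.
- Traces with missing values are rejected with the offending row and
  column named, never imputed.
- CSV layout auto-detection: a header row is assumed when the first row
  has non-numeric fields beyond the first column; an id column is assumed
  when the first column is non-numeric. A purely numeric time-index header
  is indistinguishable from data and should be omitted; `transpose = TRUE`
  handles cells-in-columns exports.

## Known limitations

- No baseline correction, deconvolution or spike inference; the event
  definition is threshold-crossing on the full-recording statistics.
- No significance testing of correlations (no shuffle/surrogate nulls) and
  no group-level inferential statistics — per-sample reports are emitted
  for external statistical comparison.
- Metrics are unweighted by design; weighted clustering/efficiency
  variants are out of scope.
- The leading-eigenvector recursion is a heuristic: it never exceeds the
  true modularity optimum (verified exhaustively on small graphs) but may
  fall short of it on adversarial inputs.
- Dense eigendecomposition bounds practical community detection at a few
  thousand cells.

## A worked example

```{r example, eval = FALSE}
library(cinet)
sim <- generate_population(synth_spec(seed = 7))
report <- run_pipeline(sim$traces, sim$cells,
                       config = cinet_config(`subset.label` = "RFP"),
                       out_dir = "run1")
report
render_figures(report, "run1/figures")
```
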