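---
title: "Benchmarking confound-regression pipelines for dynamic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking confound-regression pipelines for dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcbench)
```

## The problem

Head motion contaminates resting-state fMRI connectivity estimates, and it
does so even in cohorts screened for gross motion: micromovements well
below 0.2 mm leave residual structure in the data that correlates with
subject-level traits such as age. In *dynamic* functional connectivity the
problem compounds, because sliding-window statistics respond to transient
artifact, and multilayer network measures (modularity, flexibility,
promiscuity) inherit whatever the windows contain. `dfcbench` packages the
machinery needed to score nuisance-regression de-noising pipelines on
exactly these dynamic measures: it generates synthetic cohorts whose
contamination structure is known, runs each pipeline, and reports how much
metric-motion association survives.

Because the ground truth of real data is unknowable, the package is built
around a generative model: every benchmark is validated on cohorts where
the artifact can be switched off (`beta_spike = 0`) or dialed up, and
where the planted community structure is known.

## The synthetic cohort model

A cohort consists of subjects with ages uniform on 8-22 years, balanced
sex, and motion levels log-normally spread around 0.07 mm mean relative
RMS displacement, correlated with age (default target r = -0.3; younger
subjects move more) to exercise the covariate adjustment in the
benchmarks. Every subject passes the micromovement inclusion rule: mean
relative RMS displacement at most 0.2 mm and at most 20 frames above
0.25 mm. Acquisition defaults mirror a typical developmental resting-state
protocol: 120 retained frames at a 3 s TR.

**Clean signals.** Node time series are mixtures of a shared process,
per-community factors and idiosyncratic noise, with weights chosen so
that within-community correlations target `rho_in` (default 0.4) and
between-community correlations target `rho_out` (default 0.05). All
latent processes are AR(1) innovations band-limited to 0.01-0.08 Hz, so
the clean signals live in the analysis band. The community assignment
follows the atlas schedule: a default of three epochs per scan, with 20%
of nodes reassigned between consecutive epochs, gives the sliding windows
genuine community reconfiguration to detect.

**Atlas.** Nodes (default 264, configurable; the package also accepts the
270 sometimes quoted for the same style of parcellation) are placed inside
a 70 mm-radius sphere, spatially clustered by subnetwork (default 11
systems) so short-range edges are preferentially within-system — the
geometry that makes distance-dependent artifact measurable.

**Motion.** The framewise displacement series is a bounded, slowly varying
baseline plus occasional spike frames (0.26-0.34 mm), rescaled so the
series mean equals the subject's target exactly. Translational
realignment parameters are integrated from the framewise series, so the
norm of their frame-to-frame increments reproduces it; rotations are
small independent drifts.

**Artifact.** Contamination enters additively with two motion-coupled
components sharing five randomly placed spatial sources:

* a *displacement-coupled* term `beta_spike * fd(t) * s(t) * w_i`, where
  `s(t)` is a shared slowly varying series of amplitude `artifact_scale`
  (signal units per mm) and `w_i = sum_k exp(-d(i, source_k)/lambda_d)`
  decays over `lambda_d = 40` mm;
* a *realignment-coupled* term linear in the realignment parameter time
  series, scaled by the subject's mean displacement, with a sharper
  kernel (`lambda_rp = 20` mm) and twice the relative amplitude
  (`rp_artifact_frac = 2`).

Both kernels are normalized to a mean node weight of 1, so the decay
lengths shape only the spatial profile while `artifact_scale` alone sets
the amplitude. Subnetwork centres sit on a jittered Fibonacci sphere —
quasi-uniform coverage of the head volume, as real parcellations have —
so the distance distribution of edges does not depend on lucky placement.

The second component exists because it is the part of motion artifact
that realignment-parameter regression can remove in principle —
spin-history and interpolation effects follow head position — and without
it a six-parameter pipeline has no structural advantage over doing
nothing: ordinary least squares on regressors independent of the artifact
removes the same expected share of artifact and signal. A slow global
drift (also gated by `beta_spike`) is added uniformly to all nodes. With
`beta_spike = 0` the contaminated signals equal the clean signals
exactly, which is how the null-calibration checks are built.

The defaults `artifact_scale = 8` and `rp_artifact_frac = 2` were chosen
once, with the margins of the whole benchmark family in view.
`artifact_scale` is strong enough that the raw (no-regression)
dispersion-motion association stands far above the finite-sample floor,
yet weak enough that short-range window correlations do not saturate at
the Fisher-z clip: in the saturated regime the distance profile of the
artifact inverts (short edges stop fluctuating because they are pinned
near r = 1), and partial de-noising can then *increase* the apparent
distance-dependence. `rp_artifact_frac` trades off two effects of the
realignment-coupled component — it is what realignment regression can
remove, but its steady within-subject amplitude inflates edge means (the
dispersion denominator) and so partially cancels the raw association; at
2 the removable component dominates the distance profile without
cancelling the raw benchmark. The sign of the distance-dependence correlation
under this mechanism is positive — short-range edges, already saturated
toward their community baseline and closest to the artifact sources, gain
less dispersion per unit motion than long-range edges — which sits inside
the mostly positive range reported for real cohorts.

**Nuisance channels.** Each subject carries the channels the pipelines
consume: the true global mean of the contaminated data; 20 CSF-like
channels loaded on the artifact time courses; 30 white-matter-like
channels with coordinates whose artifact loading decays with distance to
the same sources; and a pool of 500 high-variance channels of which ~3%
carry strong artifact, so temporal-variance channel selection has
something real to find.

**What the generator does not emulate.** No voxel geometry, no
hemodynamic response, no physiological (cardiac/respiratory) cycles, no
scanner drift families beyond a single low-frequency drift, and no
relationship between the artifact and the planted communities. Passing
benchmarks on these cohorts therefore demonstrates that the machinery
measures what it claims to measure under the stated contamination model —
not that any pipeline will behave identically on real data.

## The de-noising pipelines

`pipeline_spec()` resolves names from a registry of regression-based
strategies: `2P` (WM + CSF means), `6P` (realignment parameters), `9P`
(6P + tissue means + global signal), `24P` (Friston expansion), `36P`
(24P + tissue/global terms with derivatives, squares and squared
derivatives), `36P_DESPIKE`, `ACOMPCOR` (realignment parameters and
derivatives + 5 WM + 5 CSF principal components), `TCOMPCOR` (6
components of the top-2%-variance channel pool), `WMMEAN` and `WMLOCAL`
(realignment parameters and derivatives plus a mean or 15 mm-local WM
regressor, with despiking), plus `NONE` as the no-regression baseline and
a `gsr` flag that appends the global signal to any of them.
ICA-based strategies are out of scope: they operate on voxel-level
decompositions with trained component classifiers that have no node-level
analogue.

Processing order per subject: despike (if the pipeline prescribes it),
band-pass data *and* regressors with the same zero-phase Butterworth
filter (first-order design, 0.01-0.08 Hz passband, applied
forward-backward, so the effective order doubles — the zero-phase choice
keeps windowed correlations free of phase distortion), then per-node OLS
residualization with an intercept. Filtering the regressors identically
to the data avoids frequency-dependent mismatch during regression;
rank-deficient designs drop collinear columns with a warning rather than
failing. Despiking is a running-median/MAD shrink: residuals beyond
2.5 scaled-MAD are compressed by a saturating tanh map capped at 4 MAD.
The thresholds are configurable; the cited voxelwise tool does not
publish its parameters, so these were fixed once at values that leave
spike-free series untouched. Despiking precedes filtering (interpolating
outliers before they ring through the filter); the order is a
configuration choice, not a claim about any particular reference
implementation.

## Dynamic networks and dispersion

Residual series are divided into 20-frame windows with 50% overlap —
with 120 frames that yields exactly 11 windows — and edges are Pearson
correlations within each window. Negative correlations are zeroed by
default (a `retain` policy is available), correlations are clipped to
`1 - 1e-6` in magnitude before the Fisher z-transform (the transform
diverges at |r| = 1), and diagonals are zeroed. Edge dispersion is the
variance of an edge's z values across windows divided by their mean
(sample variance, denominator T-1; a population-variance switch exists).
Edges with no fluctuation get dispersion 0; under the retain policy an
edge mean can vanish with nonzero variance, and such degenerate edges are
zeroed and flagged rather than dropped, keeping the edge set comparable
across pipelines.

## Multilayer modularity

The window stack becomes a multilayer network: layers are the windowed
networks and each node is linked to itself in adjacent windows by
identity edges of weight `omega` (default 1). Quality is

$$Q = \frac{1}{2\mu} \sum_{ijlr} \left[ (A_{ijl} - \gamma_l P_{ijl})\,\delta_{lr} + \delta_{ij}\,\omega_{jlr} \right] \delta(g_{il}, g_{jr}),$$

with the Newman-Girvan intralayer null
$P_{ijl} = \kappa_{il}\kappa_{jl} / 2m_l$ (the standard choice for this
multilayer framework; zero-weight layers contribute a zero null matrix),
$\gamma_l = 1$ by default, and $\mu$ the total multilayer edge weight
(intralayer weight plus coupling weight). Maximization uses a
generalized Louvain heuristic over the dense supra-modularity matrix,
implemented in C++: randomized sweep order, greedy single-slot moves
(ties keep the current community; a move must improve the raw quality by
more than 1e-10), aggregation, repeat. The heuristic is nondeterministic
by design and is run 100 times by default with seeds derived from one
master seed; per-subject results report all Q values and their mean.
Labels are canonicalized to first-appearance order so serialized
partitions are reproducible. An exhaustive optimizer over all set
partitions (restricted growth strings, at most 12 node-layer slots)
serves as the in-package oracle; the test suite checks that the heuristic
attains the exhaustive optimum on random small instances, and that
single-layer quality agrees with an independent graph library.

Flexibility is the fraction of possible between-window transitions at
which a node changes community, `f_i = m/(T-1)`; promiscuity is the
fraction of all communities a node ever joins, `psi_i = k_i/K`. `K`
counts distinct communities anywhere in the partition (all nodes, all
layers); a per-layer reading of "total communities" is possible, but the
global count is the one that makes `psi_i = 1` mean "this node visited
everything", and no singleton-community exclusion is applied. Both
measures are averaged across optimization iterations on the measure
vectors, never by building a consensus partition; the global summaries
F and Psi are node means of the averaged vectors.

## Benchmark statistics

For each pipeline the report computes: (a) edgewise partial correlations
between dispersion and motion, controlling age and sex (Pearson on OLS
residuals, t-based two-sided p with df = n - q - 2), with
Benjamini-Hochberg FDR masks at alpha = 0.05, percentages significant
with and without correction, and the median absolute and SD of the r
distribution; (b) the correlation across edges between inter-node
Euclidean distance and the edgewise motion correlation, with Steiger
equality tests between pipelines (two dependent correlations sharing the
distance vector; Fisher z with the common-element covariance correction
at the back-transformed mean z — implemented in-package and validated by
Monte-Carlo calibration); (c) mean multilayer Q and its partial
correlation with motion; and (d) nodewise and global flexibility and
promiscuity motion associations with per-subnetwork significant
proportions. Pairwise pipeline contrasts use paired t tests on the
edgewise r vectors (reported unadjusted, as is conventional for these
supplementary tables). Constant metric units are kept with r = 0, p = 1
and a flag so percentage denominators match across pipelines. Sex is
coded 0/1 and the covariate design always contains an intercept.

## Numerical and design choices

* Backward-difference temporal derivatives with a leading zero (the
  convention is not standardized; this one keeps frame counts aligned).
* Perfect-correlation clip at `1 - 1e-6`; zeroing negatives before the
  Fisher transform (equivalent to zeroing after, since atanh(0) = 0).
* Windows are 0-based half-open intervals; trailing frames that cannot
  fill a window are dropped so all windows have equal length.
* Degenerate statistics (zero-variance residuals, constant difference
  vectors) are returned flagged instead of erroring, so cohort loops
  never die mid-run.
* All randomness flows from one master seed through a deterministic
  seed-derivation map; two runs of the full chained study with the same
  seed are byte-identical on disk.
* The community-free comparator for the subnetwork-identifiability check
  sets `rho_in = rho_out = 0.4`: the same pairwise dependence strength
  applied uniformly, removing only the modular organization. A
  mean-weight-matched comparator (`rho_in = rho_out ~ 0.09`) gives the
  same ordering with a smaller margin; the dependence-matched control is
  used because sparser fluctuation-dominated noise networks support
  substantial spurious modularity, which is precisely what the check
  must not reward.

## Problem sizes in the shipped checks

The test-suite and acceptance-script cohorts use 100 nodes, 8
subnetworks, 120 frames and 200 subjects for the association benchmarks
(the size at which the covariate-adjusted edgewise machinery is
exercised meaningfully), 12 subjects with 10 Louvain restarts for the
modularity identifiability comparison, and 10-subject runs for the
determinism check. These sizes are the package's own desk-scale choices:
large enough for each property to be decided by signal rather than
noise, small enough to keep a full verification run in minutes.

## Known limitations

The generator's artifact is additive and low-rank in time; real motion
artifact includes multiplicative and spin-history effects with richer
temporal structure. Window-level statistics are Pearson-only (no
coherence or wavelet variants), windows are rectangular and untapered,
and no censoring-based strategies beyond despiking are included —
frame-removal methods interact badly with fixed-length sliding windows
and are deliberately out of scope. Pipeline scores on these cohorts rank
the pipelines' ability to remove *this* contamination model; real-data
rankings can differ wherever real artifact violates the model.
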