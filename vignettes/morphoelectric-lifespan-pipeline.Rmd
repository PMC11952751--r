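---
title: "Morphoelectric feature extraction and lifespan cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphoelectric feature extraction and lifespan cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
```

```{r setup, message = FALSE}
library(lifespanephys)
library(dplyr)
```

## What the package computes

Human cortical layer 2/3 pyramidal cells change their intrinsic physiology
across the lifespan: recordings from surgically resected tissue show that
cells from the first year of life have a depolarized resting potential, much
higher input resistance and longer membrane time constant, a lower rheobase,
and slower, wider action potentials than cells from older donors, while the
oldest donors show the largest sag ratios. `lifespanephys` implements the
full analysis chain behind such a study as reusable, tested R functions:

1. **Feature extraction** — 32 intrinsic electrophysiological features per
   cell from current-clamp step recordings (800 ms steps from −100 pA in
   +20 pA increments): subthreshold passive properties, per-spike waveform
   and afterpotential metrics, and sweep-set firing-pattern indices.
2. **Morphometry** — dendritic-arbor metrics on SWC reconstructions
   (lengths, bifurcation counts, extents, terminal-segment lengths), spine
   densities per inter-bifurcation branch, and geometric spine typing.
3. **Cohort statistics** — seven lifespan age groups, Monte-Carlo Lilliefors
   normality testing, Kruskal–Wallis omnibus tests with Dunn post-hoc
   comparisons, normality-gated pairwise tests, and standardized 2D
   embeddings of the feature table.
4. **Synthetic data** — a seeded membrane simulator and a random morphology
   generator with ground-truth manifests, so every downstream stage is
   testable without access to patient recordings.

## The membrane model

Synthetic sweeps come from an adaptive exponential integrate-and-fire
(AdEx) membrane extended with a hyperpolarization-activated (h) current:

$$C \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - w
  - g_h \, m \,(V - E_h) + I(t)$$
$$\tau_w \dot w = a (V - E_L) - w, \qquad
  \tau_h \dot m = m_\infty(V) - m, \qquad
  m_\infty(V) = \bigl(1 + e^{(V - V_h)/k_h}\bigr)^{-1}$$

A spike is logged when $V$ crosses 0 mV; then $V \to V_r$ and
$w \to w + b$. Integration is fixed-step explicit Euler at the protocol's
sampling interval (0.05 ms by default), with the exponential term clipped
at $V_T + 5\Delta_T$ so the update stays finite at any step size; the
passive limit is validated against the RC closed form to within 0.5%.
Voltage noise is additive Gaussian per step, scaled by $\sqrt{dt}$
(diffusion convention, units mV/$\sqrt{\text{ms}}$), drawn from R's seeded
RNG so identical seeds give bit-identical traces.

Two consequences of this abstraction matter for interpreting synthetic
features. First, the clipped exponential bounds the attainable up-stroke at
$g_L \Delta_T e^5 / C$ — a few tens of mV/ms, an order of magnitude below
real somatic up-strokes — so the synthetic waveform features are valid for
*relative* comparisons (group contrasts, shift/scale invariances, oracle
agreement), not as absolute physiological values. Second, the spike has no
biophysical repolarization: the reset truncates the falling phase, so
synthetic half-widths are dominated by the rise. Passing tests therefore
demonstrate that the extraction code measures what it claims on traces
whose ground truth is known; they do not certify absolute agreement with
patch-clamp waveforms.

```{r sim-example}
p <- membrane_params(C = 120, g_L = 11, E_L = -69, Delta_T = 4.5, g_h = 1,
                     noise_sd = 0.1, seed = 7)
rec <- simulate_membrane(p, step_protocol(), cell_id = "demo", age = 30)
rec
round(t(extract_cell_features(rec)[, ephys_feature_names()]), 3)
```

## Feature definitions and the choices inside them

The analysis windows are conventional: baseline = mean over the 100 ms
before step onset; steady state = mean over the last 100 ms of the step.
Both are arguments on every entry point.

* **Resting Vm** averages all pre-step baselines; a nonzero holding current
  is compensated ohmically with the cell's own input resistance.
* **Input resistance** is the mean of $\Delta V / I$ over all
  hyperpolarizing sweeps; **tau** is the interpolated time to 63.2% of the
  steady-state deflection (a single-exponential fit is carried along as a
  diagnostic, not the primary value — the 63.2% reading matches the
  measured quantity directly and is robust to the sag relaxation).
* **Sag ratio** on the −100 pA sweep is $(V_{ss} - V_{min})/(V_b -
  V_{min})$ — an amplitude ratio in $[0,1]$. Values reported for human
  cells (≈ 0.075–0.12) are on this scale, which is why the definition is a
  ratio of deflection amplitudes, not of raw voltages. Note the minimum is a
  raw extremum, so recording noise biases sag upward by roughly the extreme
  value of the noise process; group comparisons are unaffected because the
  bias is common to all groups.
* **Rebound** is referenced to the pre-step baseline (the alternative,
  steady-state-referenced value is also returned as
  `rebound_from_steady`); the rebound–sag ratio divides it by the sag
  amplitude of the same sweep.
* **AP detection** uses a fixed-slope onset criterion (dV/dt ≥ 20 mV/ms,
  configurable), the standard reproducible operationalization of "spike
  threshold" for cortical neurons; events below 20 mV amplitude or peaking
  below −20 mV are rejected as noise. The peak is the *first* local maximum
  after the onset crossing that passes acceptance — taking the first rather
  than the tallest keeps one event per spike even when an up-stroke only
  grazes the slope criterion.
* **Half-width** uses linearly interpolated half-amplitude crossings
  (sub-sample accuracy at 20 kHz); derivatives are central differences on
  raw samples, with an optional 5-point smoothing flag for noisy data.
* **AHP windows** run from a spike's peak to the next spike's threshold, or
  for the last spike to the step end capped at 100 ms (the cap is our
  choice; published definitions leave the no-next-spike case open).
  `velocity_at_min_dvdt` is searched in the same threshold-to-next-threshold
  window.
* **Rheobase** is the smallest positive grid amplitude whose sweep contains
  a detected AP within the step. The **F-I slope** is the OLS slope of
  (count / 0.8 s) against amplitude from rheobase upward; sweeps above
  rheobase where spiking ceased are excluded by default as depolarization
  block (flag `include_silent` reverses this).
* **Adaptation** is the mean of $(x_{i+1}-x_i)/(x_{i+1}+x_i)$ over
  consecutive values — ISIs for the cell-level feature (sweeps with ≥ 3
  APs), per-AP amplitude / half-width / threshold sequences for the
  per-feature variants. **Accommodation** is first-minus-last within a
  sweep. Per-AP features pool all accepted APs of all positive sweeps.

## The synthetic lifespan cohort

`lifespan_cohort_spec()` encodes the study conditions: seven age groups
(infant < 1 y through late adulthood ≥ 60 y), 30 cells per group by
default, and group-level parameter means chosen so the extracted features
reproduce the reported lifespan pattern:

* $E_L$, $g_L$, $C$ per group reproduce the reported group means of resting
  Vm (−61 to −69 mV), input resistance (257 MΩ infant vs 65–90 MΩ older)
  and tau (24 ms infant vs 8.5–10.4 ms) via Rin = $1/g_L$, tau = $C/g_L$.
* The infant group's spike slope factor is smaller (4.3 vs 4.5 mV), which —
  combined with its threefold longer membrane time constant — yields the
  slower up-stroke and roughly twofold wider half-width seen in infant
  recordings. Both values keep every group's up-stroke safely above the
  20 mV/ms detection criterion, which the clipped exponential would
  otherwise violate at infant-like $g_L/C$.
* $g_h$ is largest in late adulthood (4.2 nS vs 1.3–2.6 nS), producing the
  elevated sag of the oldest group. The per-group values were scaled against
  pilot simulations because the measured sag ratio is not proportional to
  $g_h$ alone — it mixes the h-current relaxation with the extreme-value
  noise bias of the raw minimum, and the bias scales inversely with the
  deflection size (so it hits low-Rin groups hardest). Realized group means
  run ≈ 0.05–0.085 with late adulthood on top; the cohort noise level
  (0.05 mV/√ms ≈ 0.15 mV stationary SD, a clean whole-cell recording) was
  fixed together with this calibration, since at triple that noise the bias
  swamps the programmed h-current contrast.
* The adaptation machinery is shared across groups ($a = 0$, $\tau_w =
  150$ ms) and the spike-triggered increment $b$ is calibrated per group
  (37.3–42.2 pA) so the F-I slope is *programmed flat* — mirroring the one
  firing-pattern feature reported as not differing across age groups. The
  calibration compensates the residual influence of the passive parameters
  on the realized slope; with a uniform $b$ the infant slope runs ~10% low
  and a 210-cell omnibus test detects it.
* Within-group SDs are moderate biological coefficients of variation
  (15% on $g_L$, 12% on $C$, 8% on $\Delta_T$, 3 mV on $E_L$, 1.5 mV on
  $V_T$, 20% on $g_h$), chosen once. The published per-group SDs are not
  used directly because they fold in patient-level confounds (pathology,
  and the rapid 0–1 y maturation inside the infant group) that a
  parameter-level generator should not imitate.

What the generator does **not** emulate: series-resistance artifacts,
bridge-balance errors, electrode drift, seal quality, true AP waveforms
(see above), morphology-dependent filtering, or patient-level clustering of
cells. Statistical conclusions drawn from synthetic cohorts therefore test
the *pipeline*, not the biology.

```{r cohort, eval = FALSE}
study <- run_lifespan_study(lifespan_cohort_spec(n_per_group = 30, seed = 1))
tidy(study$comparison)                 # omnibus table
tidy(study$comparison, "posthoc")      # Dunn pairwise table
autoplot(study$comparison, study$features)
```

(The full 7 × 30 study simulates 210 cells × 26 sweeps and takes a few
minutes on one core; the test suite runs it once.)

## Morphometry

Arbor metrics operate on SWC-style node tables: lengths are summed
Euclidean inter-node distances with each edge assigned to the child's
compartment (axon excluded), bifurcation count is the number of dendritic
nodes with two or more dendritic children, and terminal segment length is
the path from a tip back to the last branch point (the soma anchors
unbranched stems). Extents default to the slice-plane convention: vertical
along the annotated pia direction (+y unless a layer annotation says
otherwise), horizontal along the orthogonal in-slice axis with z collapsed
— a 3D radial alternative is a flag. Zero-length duplicate points are
pruned before measurement.

Spine density follows the per-branch definition (spines per µm between two
bifurcations); compartment aggregates are unweighted means of branch
densities, with the length-weighted pooled alternative behind a flag.
Geometric spine typing applies explicit thresholds in a fixed decision
order (branched → stubby → filopodium → mushroom → thin; defaults
`l_stub` 1 µm, `l_filo` 3 µm, `d_mush` 0.6 µm, head/neck ratio 1.2),
because published criteria are qualitative; the defaults recover ≥ 95% of
the generator's labels from geometry alone. Spines flagged as partially
visible are excluded before typing, and per-branch type percentages always
sum to 100.

```{r morpho}
m <- generate_morphology(seed = 5)
arbor_metrics(m)
spine_density(m)$per_compartment
```

## Statistics

* **Age groups**: infant < 1, early childhood 1–6, late childhood 7–12,
  adolescence 13–19, young adulthood 20–39, middle adulthood 40–59, late
  adulthood ≥ 60 (years). Printed ranges leave boundary membership
  implicit; integer boundaries belong to the group whose range starts
  there.
* **Lilliefors test**: KS statistic against the normal with estimated
  moments; p by seeded Monte Carlo (10,000 replicates by default) because
  the statistic's null distribution is location/scale-free and simulation
  is exact at any n. `lilliefors_null()` exposes the null so repeated tests
  at one n reuse it.
* **Kruskal–Wallis** (tie-corrected, χ² reference) is the omnibus test;
  **Dunn post-hoc** z statistics come from the pooled ranks with tie
  correction, Bonferroni-adjusted over all 21 pairs by default (Holm and
  unadjusted available) — the multiplicity correction is our choice, made
  conservative deliberately.
* **Pairwise policy `auto`** formalizes "t-test or Mann–Whitney": Welch's t
  when both samples pass Lilliefors at α = 0.05, Mann–Whitney otherwise
  (exact when combined n ≤ 20 and tie-free).
* **Embedding**: features are z-scored, then handed to a pluggable backend
  — nonmetric MDS (`MASS::isoMDS`, initialized from classical MDS) by
  default, PCA as the fallback; the embedding algorithm itself is
  deliberately external to this package. Duplicate rows are collapsed and
  re-expanded so they receive identical coordinates.

Significance is flagged at p < 0.05 throughout. With 30 cells per group the
programmed infant contrasts (Rin ~3×, tau ~2.5×, resting Vm ~5 mV,
half-width ~2×) are detected in every infant pair after Bonferroni
adjustment, while the flat F-I slope stays non-significant; the omnibus
type-I rate on null cohorts calibrates to 0.05 within binomial error (the
acceptance script recomputes both).

## Quality control

`qc_filter()` applies the series-resistance gate (default 30 MΩ) used
before analysing fast AP-waveform parameters, where access resistance
distorts measurements most; cells without a recorded series resistance are
kept by default.

## Numerical conventions and degenerate inputs

Times ms, voltages mV, currents pA, conductances nS, capacitance pF,
resistances MΩ throughout; converters live only at I/O boundaries. Missing
features are `NA` with a recorded reason, never zero. Undefined cases are
contracts, not crashes: no hyperpolarizing sweep → Rin/tau undefined; no
−100 pA sweep → sag undefined; fewer than two spiking sweeps → F-I slope
undefined; sweeps with fewer than three APs contribute no ISI statistics;
clipped spikes yield NA waveform features; constant samples make the
Lilliefors test degenerate (flagged, p at machine floor). The fixture JSON
format stores doubles at 17 significant digits so write → read round trips
are bit-exact.

## Known limitations

* NWB files are not read directly in this build; convert recordings to the
  fixture JSON format upstream.
* The simulator is a point-neuron abstraction: no dendritic filtering, no
  conductance-based AP shape, no bursting; about 10% of real pyramidal
  cells burst, which this generator does not emulate.
* Sag and rebound use raw extrema and therefore carry a small
  noise-dependent positive bias (common across groups).
* Spine typing assumes annotated geometry; no image segmentation is
  attempted, and truncated terminal segments are included in terminal-length
  means unless excluded by flag.
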