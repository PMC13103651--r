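---
title: "Seed-based FC targeting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based FC targeting: models, parameters and design choices}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chronic fatigue syndrome has no established cortical target for
non-invasive brain stimulation (TMS/tDCS). One candidate strategy starts
from the thalamus — a hub strongly implicated in fatigue — and asks where
on the cortex thalamic functional connectivity (FC) is most extreme, on
the reasoning that the positive and negative FC peaks of a thalamic seed
map are the cortical sites most strongly coupled (or anti-coupled) to
thalamic activity and hence candidate stimulation entry points.

`fctarget` implements that analysis end to end:

1. **Denoising** of resting-state BOLD time series (frame dropping,
   motion censoring, 36-parameter nuisance regression, band-pass,
   smoothing).
2. **Seed FC mapping**: Pearson correlation of every location with the
   mean thalamic seed signal, Fisher r-to-z, and averaging of z maps
   across a normative population.
3. **Surface targeting**: projection of the normative map to a cortical
   surface, identification of the positive and negative peaks, expansion
   of each peak into a 6 mm geodesic sphere, and quantification of
   cross-subject overlap for individually defined peaks.
4. **Surrogate stimulation**: projection of a target to the scalp, a
   distance-decay field magnitude map, a top-30% cortical mask, and the
   pre/post comparison of masked mean FC against symptom change.
5. **Inference**: pooled two-sample t tests, Pearson correlations with
   Fisher 95% CIs, and the ΔFC–ΔFS14 correlation, at vertex and sphere
   level.

Because the corresponding clinical datasets are not public, the package
is *synthetic-first*: a generator plants a known connectivity–symptom
structure, and every pipeline stage is validated by recovering it.

## The generative model

**Connectivity field.** The true seed correlation at location $v$ is

$$\rho_v \;=\; b_0 + A_+\,e^{-d_+(v)^2/2\sigma_f^2}
                  - A_-\,e^{-d_-(v)^2/2\sigma_f^2},$$

with $d_\pm(v)$ the geodesic (surface) or Euclidean (volume) distance to
the planted positive/negative peak. Defaults: $b_0 = 0.05$ (weak diffuse
thalamocortical coupling), $A_+ = 0.45$, $A_- = 0.50$, $\sigma_f =
18$ mm. The constructor verifies that the field extrema fall exactly on
the planted vertices, so peak recovery is well defined. The default peak
directions place the negative peak laterally-occipitally and the positive
peak medial-frontally, matching where thalamic FC extremes are typically
reported.

**BOLD synthesis.** Location $v$'s series is
$x_v(t) = \rho_v\, s(t) + \sqrt{1-\rho_v^2}\,\eta_v(t)$ with $s$ (the
seed signal) and $\eta_v$ independent, unit-variance, band-limited
Gaussian noise, so the population correlation of $x_v$ with $s$ is
exactly $\rho_v$. Noise is synthesized spectrally (complex-Gaussian
Fourier coefficients on the 0.01–0.08 Hz bins, Hermitian symmetry,
inverse FFT): BOLD-like autocorrelation, exact band limits, and a single
matrix FFT per run.

Band-limiting has a statistical price that the test suite accounts for
explicitly: with TR = 2 s the series carry roughly
$n_\mathrm{eff} = n\,(f_2-f_1)/f_\mathrm{Nyq} \approx 0.28\,n$
independent samples, so a 230-frame run supports correlation estimates
with the sampling variability of $\approx 64$ independent observations
(SD $\approx 0.13$ per location under the null). All sampling-band
checks in the tests use $n_\mathrm{eff}$, not the raw frame count.

**Between-subject variation.** Each subject's field is the group field
plus a spatially smooth perturbation: a random combination of real
spherical harmonics of degree 1–2 evaluated on the vertex directions.
Because $\sum_{\ell m} Y_{\ell m}^2$ is constant on the sphere, i.i.d.
coefficients give an exactly uniform vertex-wise jitter SD (default
0.18 on the correlation scale). Smooth jitter makes individual peaks
scatter across subjects — the individual-variability phenomenon the
individual analysis quantifies — while leaving the group-mean field
intact.

**Symptom coupling.** The fatigue total (0–14 binary-scored scale) of
patient $i$ is
$\mathrm{FS14}_i = \mathrm{clip}(\mathrm{round}(a + b\,z_i + \varepsilon_i), 0, 14)$,
where $z_i$ is the subject's true Fisher-z at the planted negative peak.
$b$ and $\mathrm{SD}(\varepsilon)$ are derived from the requested
cross-subject coupling (default $r = -0.3$) and score SD (default 2.90
around a mean of 10.35; controls 3.96 around 4.73, uncoupled) via the
delta-method SD of $z_i$, so the planted correlation is recoverable by
construction. Rounding and clipping attenuate the realized coupling by
roughly 1%, which is far inside the sampling band at $n = 100$.

**Longitudinal cohorts.** Treatment shifts each patient's field inside
the target region by $\delta_i \sim N(0.12, 0.15)$ (correlation scale,
decaying with $\sigma_f$ from the negative peak; positive mean = FC moves
toward zero), and
$\Delta\mathrm{FS14}_i = c\,\overline{\Delta z}_i + \nu_i$ with $c$
derived from the planted Δ–Δ correlation (default $-0.4$) and
$\mathrm{SD}(\Delta\mathrm{FS14}) = 2.5$. The pre-treatment arm is
generated by exactly the same code path as the patient arm of a
cross-sectional cohort, and shares its per-subject substreams.

**Confound contamination** is injected as random spatial loadings on the
six motion parameters and three tissue signals — i.e. inside the span of
the 36P regressor family — so nuisance regression provably removes it;
the test suite compares the denoised maps of the same subject with and
without contamination.

## Denoising choices

* **FD** is Power's sum of absolute parameter differences with rotations
  converted to arc length on a 50 mm sphere (the convention of the
  standard preprocessing toolchain); the 0.01 rad → 0.5 mm conversion is
  a test anchor.
* **Censoring** is strictly greater-than at 0.5 mm and purely logical:
  data are never deleted, frames are flagged and excluded from every
  statistic.
* **Regression** fits OLS with an intercept on retained frames only
  (rank-deficient designs drop collinear columns with a warning), then
  fills censored frames by linear interpolation of residuals so that
  zero-phase filtering sees a continuous series; the flags are kept and
  censored frames never re-enter statistics. Residual–confound
  correlations are below 1e-8 by construction.
* **Band-pass** is a 4th-order Butterworth applied with zero phase.
  Rather than time-domain forward–backward filtering per location, the
  FFT of each (mean-removed, interpolated) series is multiplied by
  $|H(f)|^2$ evaluated from the Butterworth transfer function — the
  identical magnitude response, exactly zero phase, and one matrix FFT
  for thousands of locations. The frequency-response contracts (DC ≥ 99%
  attenuated, 0.2 Hz ≥ 80% attenuated, 0.05 Hz ≤ 20% attenuated at
  TR = 2 s) are asserted in the tests.
* **Smoothing** uses a separable discrete Gaussian over the voxel
  lattice (σ = FWHM/2.3548; rows renormalized so constants are exact at
  the edges) in volume space, and a row-normalized Gaussian kernel over
  the one- and two-ring vertex neighbourhood (Euclidean distances, a
  good local approximation to the geodesic at sub-edge-length σ) on
  surfaces. Surface smoothing is an extension: the reference protocol
  smooths in volume space only.
* Two denoising recipes are exposed: `"36p"` (study data) and `"gsr"`
  (global signal + derivative + squares — the normative dataset's own
  convention). The normative and study arms deliberately use different
  recipes by default; the mismatch is inherited from the source
  protocols and is not harmonized silently.

Subjects with multiple runs can be combined either by averaging their
per-run Fisher-z maps (`combine_run_maps`, the default convention) or by
concatenating the retained frames before mapping (`concatenate_runs`);
normative datasets differ on this point, so both are exposed rather than
harmonized.

## Targeting choices

* A "surface-based sphere" is read as a **geodesic disc**: vertices
  within 6 mm shortest-path (edge-graph) distance of the peak. Graph
  distance slightly overestimates true surface geodesics; the oracle
  tests use the same metric, and an exhaustive Dijkstra implementation
  independent of the package's graph library verifies membership on
  meshes up to 500 vertices.
* Sphere-level FC is the **unweighted mean** over member vertices
  (linear, hence compatible with map averaging); peak ties break toward
  the lowest vertex index for determinism.
* The **overlap rate** of individually defined spheres is not
  standardized; the package reports the maximum over vertices of the
  fraction of subjects whose sphere covers that vertex
  (`"max_coverage"`), with a mean pairwise Jaccard alternative. The
  choice is explicit in the API and logged with results.
* Individual peaks are found with no spatial restriction (whole-mesh
  argmax/argmin), as in the reference analysis.
* How per-patient values are extracted at normative sites is
  underdetermined in the source protocol; the package assumes the same
  template vertex for every subject.

## The field surrogate

A finite-element E-field solver (tissue conductivities, coil windings)
is out of scope by design. The surrogate preserves the pipeline logic
with a declared stand-in: field magnitude
$\exp(-d^2/2\sigma^2)$ of the Euclidean distance to the coil position
(the scalp projection of the target), $\sigma = 20$ mm, chosen so the
top-30% mask on a brain-scale mesh is one contiguous patch containing
the target. The mask takes the `ceiling(0.3 N)` highest-field *vertices*
(the vertex-count reading of "top 30%"; a quantile reading would differ
only through ties). Everything downstream — masked mean FC, pre/post
Δ-correlation — follows the reference procedure. Surrogate field values
are arbitrary units; only their ranks matter for the mask.

## Inference choices

The two-sample test defaults to the pooled-variance Student t
(df $= n_1+n_2-2$), computable from summary statistics alone so printed
group summaries can be checked without raw data; Welch is available.
(Of the published demographic rows, only the age row is arithmetically
consistent with its summaries under either variant, and only it is used
as a numeric anchor.) Pearson tests use the t transform for p and the
Fisher transform for the 95% CI. No multiplicity correction is applied
anywhere — mirroring the reference analysis — and results tables carry
the count of tests performed.

## Desk-scale problem sizes

The synthetic cortex is an icosphere: subdivision 3 (642 vertices,
~12 mm edges, 80 mm radius) is the working resolution for cohort-scale
runs, subdivision 2 (162 vertices) for exhaustive oracles. At 12 mm edge
length a 6 mm geodesic sphere usually contains only its centre vertex,
so vertex- and sphere-level results coincide; on finer meshes
(subdivision 4+) they separate. The scalp is a 95 mm icosphere.
Cohorts default to 100 patients / 100 controls and 35 longitudinal
patients (the study design); the normative population is generated at
100 subjects, a desk-scale stand-in for a 1000-subject public cohort.
Acquisitions are 240 frames at TR = 2 s, of which the first 10 (study)
or 4 (normative) are dropped.

Under these conditions the analytic power of the vertex-level coupling
test at the planted $r=-0.3$, $n=100$ is about 0.86 *before* measurement
attenuation — the recovery tests therefore compare empirical success
rates against the generator's own analytic power with binomial error,
rather than demanding rates the design cannot deliver.

## What the generator does not emulate

No scanner artifacts, multi-site effects, anatomical images, real
cortical geometry (gyrification, medial wall), item-level
questionnaires, or physiological noise spectra. Passing recovery tests
therefore demonstrate the *pipeline's* correctness — that each stage
preserves and extracts the planted structure — not that the planted
structure is an accurate model of clinical data. Real-data claims
(specific MNI coordinates, specific correlation magnitudes) require the
original cohorts and are outside what this package can or does
reproduce.
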