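---
title: "EEG biomarkers for Fmr1-KO mouse models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG biomarkers for Fmr1-KO mouse models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fxeeg` implements the EEG biomarker battery used in preclinical Fragile X
studies with *Fmr1* knockout mice: resting power spectral density with
canonical band summaries, Morlet-wavelet inter-trial phase coherence (ITPC)
and baseline-corrected single-trial power (STP) for three sound-evoked
paradigms (noise-burst trains, 40 Hz auditory steady-state response,
1–100 Hz upsweep chirp), a Monte Carlo cluster-based permutation test on
binned time–frequency matrices, and movement-covariate-adjusted band
statistics with Bonferroni control. Because animal recordings of this kind
are rarely deposited, the package ships a synthetic-EEG generator with
known ground truth; every statistical claim the test suite makes is
established on that generator.

This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open — the things a maintainer would
otherwise have to reverse-engineer from the code.

# Resting power spectral density

`resting_psd()` splits each channel into non-overlapping 2 s segments,
tapers each segment, and averages one-sided periodograms scaled to
µV²/Hz. With 2 s segments the grid resolution is exactly 0.5 Hz.

The taper is a Tukey window whose cosine ramps together occupy 10% of the
segment ("10% Hanning" in the lineage of the acquisition software this
battery comes from; 5% ramp at each end). `taper_fraction = 1` recovers a
full Hann window for users who prefer that convention.

Normalization uses the window power correction `sum(w^2)`, which makes
the estimator Parseval-consistent: integrated density equals signal
variance (the suite checks this within 5% on white noise). The price of
power normalization is that a pure tone's height in its single bin is a
few percent below A²/2 divided by the bin width, because the taper leaks
a little energy into neighbouring bins; integrating the peak
neighbourhood recovers A²/2 (checked within 2%). A window cannot have
unit coherent and unit incoherent gain simultaneously unless it is
rectangular; we chose the noise-faithful normalization because band power
of broadband EEG, not tone amplitude, is the quantity of interest.

Band summaries (`bin_bands()`) use theta 4–8, alpha 8–13, beta 13–30,
low gamma 30–55, high gamma 65–100 Hz. The printed band edges share
boundaries (8 Hz belongs to theta or alpha?), so a convention is forced:
intervals are half-open `[lo, hi)`, with high gamma closed at 100 Hz.
The 55–65 Hz region belongs to no band — it is excluded, not
interpolated, as it contains the 60 Hz power-line vicinity. Band power is
the *mean* density over the band's bins (µV²/Hz) rather than the
integral; the choice only rescales each band by its width and cancels in
the KO:WT group ratios (`group_ratio()`).

# Morlet time–frequency analysis

`morlet_tfr()` convolves each trial with unit-energy complex Morlet
wavelets

$$\psi_f(t) = (\sigma_t\sqrt{\pi})^{-1/2}
  \exp\!\left(-\tfrac{t^2}{2\sigma_t^2}\right) e^{i 2\pi f t},
  \qquad \sigma_t = \frac{m}{2\pi f},$$

with the "Morlet parameter" m interpreted as the number of cycles, m = 10
by default — the convention of the wavelet implementations this analysis
lineage uses. The spectral bandwidth is then σ_f = f/m. The default bank
has 100 layers linearly spaced from 1 to 100 Hz, matching the 100
frequency rows of the cluster-test matrix one-to-one.

Convolution is done by FFT with reflection padding. Samples within
3 σ_t of an epoch edge are flagged in an edge mask and excluded from
downstream statistics. A consequence taken deliberately: the 10-cycle
1 Hz wavelet has σ_t ≈ 1.6 s, so on a 2–3 s evoked epoch its layer has
*no* reliable samples. Rather than refusing to analyze standard epochs,
`morlet_tfr()` computes every layer, returns fully masked rows for
layers whose edge zones cover the whole epoch (with a message), and
rejects an epoch only when even the highest-frequency layer has no
reliable sample. This matches how the protocol is actually run in the
field: the full 1–100 Hz bank is applied and the unreliable low-frequency
corner is simply masked.

ITPC is the resultant length of per-trial unit phasors,
$\mathrm{ITPC}(f,t) = |N^{-1}\sum_n W_n(f,t)/|W_n(f,t)||$ — the standard
estimator; it is a pure phase statistic (invariant to per-trial positive
rescaling) and for N uniform-phase trials has expectation
$\sqrt{\pi}/(2\sqrt{N})$, which the tests exploit as a closed-form
oracle.

STP takes per-trial power |W|², subtracts the per-frequency mean over
the baseline window [−250, −150) ms *per trial*, then averages trials
with equal weights (no trial rejection). Total power is used — the
evoked component is not subtracted — so STP captures background plus
sound-evoked power. By construction the baseline-window mean of the
result is zero at every frequency; the suite asserts this to float
tolerance.

`evoked_measures()` computes both statistics by streaming trials in
chunks and accumulating sufficient statistics (sum of unit phasors; sum
of corrected power), because materializing the full 200-trial × 100-layer
complex array for a 2 s epoch would need gigabytes. Results are
identical to `compute_itpc()`/`compute_stp()` on the full array.

# Cluster-based permutation test

`cluster_permutation_test()` compares two groups of binned
time–frequency matrices (canonically 100 frequency × 256 time bins;
`bin_tf()` makes near-equal contiguous time bins, spreading any
remainder over the leading bins). The procedure:

1. pixel-wise Welch t statistic (group A − group B);
2. suprathreshold pixels at two-sided p < 0.05 under the Welch-df t
   distribution, separately for positive and negative t;
3. clusters by 4-connectivity; cluster statistic = size (pixel count);
4. null distribution: the maximum cluster size per direction over random
   relabelings of subjects preserving group sizes;
5. a cluster is significant when its Monte Carlo p-value
   $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$ is at most the
   per-tail α (0.025 by default, i.e. a two-tailed 0.05) — equivalently,
   when its size exceeds the 97.5th percentile of the null, with ties
   resolved conservatively.

Three of these choices were genuinely open and are exposed as arguments:
the pixel-forming threshold (protocol descriptions in this literature
rarely state one; 0.05 two-sided is the common default), the cluster
statistic (size follows the protocol's own wording; cluster *mass* — the
sum of |t| — is available, and is the variant much of the cluster-test
methodology literature prefers), and connectivity (4 as the strict
reading of "contiguous"; 8 optional). Edge-masked bins are excluded from clustering.

Pixels where both groups have (numerically) zero variance get t = 0 and
never form clusters. With `enumerate = TRUE` the Monte Carlo null is
replaced by all `choose(nA+nB, nA)` assignments and p-values are exact;
the suite verifies exact agreement with an independent brute-force
oracle (per-pixel `t.test` plus an R flood fill) on 3-vs-3 toys, and the
type-I error simulation (`cluster_test_fwer()`) verifies that the
realized per-direction family-wise rate stays at or below 0.025 over 400
null datasets. That simulation runs at a reduced scale — 8 + 8 subjects,
12 trials each, 256 Hz, 30 wavelet layers from 10–100 Hz, 30 × 64 binned
grids, 500 permutations — chosen so hundreds of repetitions are
affordable on a single core; the statistic's calibration does not depend
on grid size or permutation count beyond Monte Carlo granularity.

# Covariate-adjusted band statistics

The resting-power inference is described in the source protocols as a
one-way MANCOVA with movement as covariate, yet results are reported per
band. The exact multivariate-to-univariate protocol is ambiguous, so
`ancova_band_test()` makes the per-band ANCOVA the primary output —
`power ~ group + movement`, Type II sums of squares for the group term
(via `car::Anova`), significance at the Bonferroni-effective per-band
α = 0.01 for five bands — and reports a Wilks' lambda omnibus across the
five bands (via `stats::manova`) alongside, without gating the
univariate tests on it. Band powers are analyzed untransformed (a
log-power option exists but is off by default, since the protocol states
no transformation). The suite checks the group F against a brute-force
nested-residual-sums-of-squares oracle and the null rejection rate at 1%
over 1000 simulated null tables.

`movement_summary()` mirrors the design check that movement does not
differ between groups: group means/SDs plus a Welch t test (one-way
ANOVA for >2 groups); all-zero-variance input is reported without a
test.

# The synthetic-EEG generator

`sim_config()` fixes the study conditions; the generator is not a tuning
surface. Defaults, chosen once to resemble awake mouse epidural EEG:

- **Background**: 1/f^β Gaussian noise synthesized in the frequency
  domain, β = 1, total SD 8 µV. Real resting EEG has roughly 1/f-shaped
  broadband background; β and the SD are free parameters because the
  protocols never characterize background quantitatively.
- **Band components**: narrowband noise (band-passed white noise rescaled
  to a target SD) at 6, 10, 20, 40 and 80 Hz with SDs 12, 8, 6, 9 and
  7 µV. The gamma components sit well above the background in their
  bands so that an amplitude elevation is expressed as a near-quadratic
  band-power elevation.
- **Gamma elevation**: KO-like subjects have the amplitudes of all
  components centred at ≥ 30 Hz multiplied by `gamma_elevation`
  (1 = null). An amplitude factor of 2 implies a band-power ratio near 4;
  the suite recovers it within 15% at 20 subjects per group, with the
  shortfall from exactly 4 coming from the 1/f background share of the
  band.
- **Evoked responses**: for ASSR and chirp, an oscillation following the
  stimulus modulation (40 Hz constant, or the linear 1→100 Hz sweep
  φ(t) = 2π(f₀t + (f₁−f₀)t²/2T)), amplitude 10 µV, phase-locked to
  stimulus onset in a Bernoulli(ρ) fraction of trials and uniform-random
  phase otherwise. This mixture is the simplest mechanism with a
  closed-form ITPC expectation at every ρ, which is what makes parameter
  recovery testable. For the noise-burst paradigm, a damped-sinusoid ERP
  (40 µV, 30 ms latency, 8 Hz, 60 ms decay) — the protocols do not
  parameterize ERP shape, and only its presence/timing matters here.
- **Movement**: per-subject fraction from a normal (mean 0.4, SD 0.1)
  truncated to [0, 1], independent of group unless an offset is
  requested.
- **Stimulus timing**: noise bursts of 100 ms with 5 ms rise/fall in
  trains of ten at 1 or 2 Hz, 100 trains, 8 s between trains; 1 s click
  trains at 40 Hz (1 ms clicks — click width is unstated in the
  protocols and configurable), 200 repetitions; 2 s chirps, 300
  repetitions. The 8 s inter-train interval is anchored at the last-burst
  *offset* (the anchoring is unstated; this choice is configurable).
  The chirp envelope is a raised cosine ½(1 − cos φ) so modulation depth
  is 100% and the envelope starts at zero; over 2 s the 1→100 Hz sweep
  accumulates (f₀+f₁)T/2 = 101 modulation cycles.

What the generator deliberately does **not** emulate: biophysical
cortical circuitry (PV-interneuron dynamics, E/I balance), volume
conduction and channel cross-talk (the two channels are independent by
default), movement/EMG artifacts, and any genotype effect on evoked
responses unless configured. Consequently, a green test suite shows that
the *estimators and tests are correct and calibrated* on data with the
assumed statistical structure — it does not show that real *Fmr1*-KO
recordings would reproduce the published biological effect sizes, which
would require the animal data.

# Preprocessing chain

Recordings are band-limited 0.5–100 Hz with a 4th-order Butterworth
applied forward-backward (zero phase); the corner frequencies come from
the acquisition hardware description, the family and order are our
documented choice. Filtering removes the mean first and uses reflection
padding proportional to the slowest filter time constant, so
zero-initial-condition transients never reach the returned samples.
Downsampling (2.5 kHz → 1024 Hz in the emulated chain) applies a
zero-phase anti-alias low-pass at 0.4 × target rate, then interpolates
the filtered signal onto the new grid; events are remapped to the
nearest new sample. Epoching is half-open `[t_min, t_max)` with t = 0 at
the event sample; windows default to (−500, 1000) ms for noise bursts,
(−500, 1500) ms for ASSR and (−500, 2500) ms for chirp — the protocols
show analysis windows only in figures, so these are package defaults,
sized to contain the stimulus plus the −250 to −150 ms baseline.

On-disk interchange uses a plain-text container (CSV samples + JSON
header + TSV events) written by `write_recording()`; events round-trip
exactly and samples to text precision.

# Numerical and degenerate-input policy

- All simulators are bit-reproducible from `(seed, subject)`; derived
  seeds stay below 2³¹.
- Zero-magnitude wavelet coefficients are excluded from ITPC at that
  pixel and counted in the result metadata.
- Degenerate pixel variance in the cluster test → t = 0 (never
  suprathreshold). Constant covariate or a single group level →
  rejected with a diagnostic before fitting.
- Half-open interval conventions throughout (epoch windows, baseline
  window, band edges) so shared boundaries are never double-counted.
- Permutation sampling does not enforce uniqueness of relabelings
  (standard Monte Carlo practice); exact enumeration is available up to
  10⁵ assignments.

# Problem sizes used by the tests

The suite establishes calibration at reduced but statistically faithful
scales: 400 null datasets × 500 permutations on 30 × 64 grids for the
family-wise error rate; 1000 null tables for ANCOVA calibration; 20
subjects per group for gamma-elevation recovery; 200 trials for the
ITPC oracles, pooled across 23 wavelet layers and 24 repetitions because
a single pixel's resultant has Monte Carlo SD far above the tolerance
band. The full-scale analysis (100 × 256 grids, 2000 permutations, 200+
trials) uses the same code paths; only the loop counts differ.

# Known limitations

- The ITPC/STP group pipeline assumes equal epoch geometry across
  subjects; no handling of unequal trial counts beyond each subject's
  own average.
- No artifact rejection, re-referencing or bad-channel handling — the
  emulated protocols describe none.
- `downsample()` interpolates the anti-aliased signal rather than using
  a polyphase decimator; for EEG-band signals the difference is well
  below the filter's own passband ripple (the suite bounds the error on
  an in-band tone at < 1% of amplitude).
- The Wilks omnibus is computed per channel only when all five bands are
  present with enough subjects; it accompanies, and never gates, the
  per-band tests.
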