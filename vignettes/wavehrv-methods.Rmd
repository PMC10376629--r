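---
title: "Extracting heart rate variability from pulse traces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting heart rate variability from pulse traces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Heart rate variability (HRV) — the beat-to-beat fluctuation of the cardiac
rhythm — is a sensitive autonomic biomarker, and it is exactly this
sensitivity that makes it hard to measure without contact. A camera pointed
at a face sees a minute periodic colour change (remote photoplethysmography,
rPPG), but the pulse component is buried under motion, illumination and
sensor noise, and an error of a few tens of milliseconds in a handful of
beat positions is enough to corrupt RMSSD entirely. `wavehrv` implements a
denoising chain built around the wavelet scattering transform that turns a
raw pulse trace (contact PPG or an rPPG candidate) into refined inter-beat
intervals (IBIs) and HRV metrics.

The package deliberately starts *after* video analysis: its inputs are
either a 1-D pulse trace or a per-frame mean-RGB trace. Face detection and
skin segmentation are out of scope.

## Pipeline overview

1. **POS projection** (`pos_rppg`): a mean-RGB trace is projected onto the
   plane orthogonal to the standardized skin tone. In sliding windows
   (default 1.6 s, the customary choice for this projection) each channel is
   normalized by its window mean, projected on the axes (0, 1, −1) and
   (−2, 1, 1), combined with the sigma ratio, and overlap-added. The window
   length is exposed because the literature varies; the dominant pulse
   frequency is insensitive to values between 1 and 2 s.
2. **Power-of-two resampling** (`resample_to_pow2`): cubic-spline
   interpolation onto the power-of-two rate nearest the input rate (ties go
   up, to avoid discarding bandwidth; 30 fps becomes 32 Hz). Cubic rather
   than linear interpolation preserves peak timing, which the IBI stage
   depends on. When frame rate is not a power of two, the POS projection is
   applied first and the interpolation second.
3. **Pre-cleaning** (`butter_bandpass`): zero-phase Butterworth band-pass,
   design order 7, pass-band 0.7–5 Hz (42–300 bpm). Forward–backward
   application is essential: a causal pass would shift peaks by a
   frequency-dependent delay and corrupt the IBIs. The stated order is the
   design order of the one-pass filter.
4. **First-order scattering** (`build_filterbank`, `scatter_first_order`):
   20 Morlet wavelets, log-spaced over 0.7–5 Hz, convolved with the signal;
   modulus; average pooling over non-overlapping 16 s frames. The result is
   a translation-stable energy-density map of frequency over coarse time.
5. **Adaptive narrow-band filtering** (`adaptive_narrowband_filter`):
   sliding windows of 14.5 s advance in 2 s steps. For each window the
   scattering energies are interpolated to the window end, a narrow band
   around the momentary heart rate is selected by K-means (below), the
   window is band-passed with that band and mean-centred, and all windows
   are summed back (overlap-add). Record edges, covered by fewer windows,
   are re-amplified (below).
6. **Beat detection** (`detect_peaks_ampd`): automatic multiscale-based
   peak detection — no amplitude threshold, deterministic (below).
7. **IBI refinement** (`refine_ibis`): three ordered rules remove
   physically impossible or misplaced-peak intervals.
8. **Metrics** (`hrv_report`): SDNN, RMSSD, Baevsky stress index, LF/HF.

## The scattering front-end

Each wavelet is a complex Morlet
\(\psi(t) = K\,\pi^{-1/4} e^{i\omega_0 t/s} e^{-(t/s)^2/2}\), L2-normalized,
with scale \(s\) set by its centre frequency. The dimensionless frequency
\(\omega_0\) is tied to the bank geometry: for a geometric spacing ratio
\(r\), \(\omega_0 = \sqrt{\ln 2}\,(r+1)/(r-1)\) makes adjacent filters cross
at −3 dB, so the bank tiles the band without gaps or excessive overlap. With
20 wavelets over 0.7–5 Hz this gives \(\omega_0 \approx 16\): narrow-band
filters, appropriate because heart-rate resolution matters more here than
temporal resolution. A `bandwidth_factor` argument widens or narrows all
filters if a different trade-off is wanted.

Convolutions run over a reflection-padded copy of the signal (FFT-based), so
record edges do not produce wrap-around transients. A 16 s pooling window
balances time against frequency resolution at typical record lengths of one
to a few minutes; a trailing partial frame is dropped. The transform keeps
the pooled *modulus*; where an energy is needed downstream, the coefficient
is squared.

Only first-order coefficients are computed. Higher orders would add
amplitude-modulation detail that the band-selection step does not use.

## Band selection: K-means around the first harmonic

For each sliding window, per-wavelet energies at the window end are obtained
by linear interpolation between the two bracketing pooled frames (the
interpolation weight is the offset divided by the pooling spacing). The
clustering then runs on the *neighbourhood of the first harmonic*: the
energy argmax locates the beat frequency, and only wavelets within a factor
of `harmonic_radius` (default 1.6) of it are clustered. This restriction is
load-bearing. A K = 3 partition of the full 0.7–5 Hz grid always places its
leftmost centroid near one sixth of the band (~1.3 Hz), so any heart rate
below ~78 bpm would fall outside the selected band; restricted to the peak's
neighbourhood, the outer centroids straddle the peak by construction.

Clustering features are (log-frequency, squared energy), both min-max
normalized to [0, 1]. Log-frequency because the bank is geometric — on a
linear axis the low-frequency wavelets bunch together and the partition is
driven by the sparse high end; squared energy because the pooled scattering
coefficient is an amplitude. K-means uses k-means++ seeding with a fixed
seed, Lloyd iterations (cap 300), and 10 restarts, making the whole pipeline
deterministic; `stats::kmeans` performs the Lloyd iterations, the seeding is
implemented in the package. Centroids are sorted by frequency (geometric
cluster means) and the band is the span from leftmost to rightmost centroid
frequency, clamped to 0.7–5 Hz. An alternative rule, the frequency extent of
the highest-energy cluster, is available as `band_rule = "peak_cluster"`.
Degenerate clusterings (too few distinct frequencies, empty clusters) fall
back to the full band with a warning; degenerate bands narrower than
0.05 Hz are widened to 0.1 Hz before filtering.

## Butterworth filtering in second-order sections

All band-pass filtering uses a Butterworth design computed analytically —
prototype poles, band-pass transformation, bilinear transform — and applied
as a cascade of biquads. The usual single transfer-function polynomial is
numerically unstable at the rates and bandwidths this pipeline needs (an
order-7 band-pass of 0.7–5 Hz at 256 Hz has 14 poles clustered near
\(z = 1\); in polynomial form, round-off pushes them outside the unit
circle and the filter diverges). Zero-phase response is obtained by
forward–backward application over odd-reflection padding; the pad length
defaults to twelve periods of the low band edge, which lets the order-7
step transient settle below 10⁻⁶ before the retained samples begin.

## Overlap-add and edge amplification

Window segments are summed as-is; with window length \(w\) and step \(s\),
interior samples are covered by about \(w/s\) windows while the slice
\([js, (j+1)s)\) at the head is covered by only \(j+1\). Samples within one
window length of either end are therefore multiplied by the
coverage-equalizing gain \((w/s)/\mathrm{coverage}\), capped below at 1. At
the head this equals the per-slice rule \(c_j = (w/s)/(j+1)\); at the tail
the coverage steps fall at the clipped window *ends*, offset by
\(w \bmod s\), so the gain follows the exact per-sample coverage count
rather than mirrored fixed slices. With the defaults (\(w/s = 7.25\)) the
interior coverage itself alternates between 7 and 8 within each step
period; an envelope measured as RMS over step-length blocks is uniform,
which is what the edge gain is meant to restore at the ends.

The defaults \(w = 14.5\) s, \(s = 2\) s keep roughly seven overlapping
estimates per sample while letting the pass-band adapt every 2 s; both are
config keys, as the optimal values are data-set dependent.

## Deterministic AMPD

A sample is a scale-\(k\) local maximum when it exceeds the samples exactly
\(k\) positions away on both sides. The scalogram of these indicators over
\(k = 1..L\) is summed per row; the operating scale \(\lambda^*\) is the
row-sum argmin (the scale exposing the most maxima), and peaks are samples
that are maxima at *every* scale up to \(\lambda^*\). The original
formulation fills non-maxima entries with small uniform random numbers whose
only effect is tie-breaking in the argmin; the package uses the constant 1
and resolves ties toward the smallest scale, which makes detection exactly
reproducible. \(L\) is capped at 1.5 s of lag (`ampd_max_scale_s`) — about
half again the slowest plausible beat interval — which bounds the cost
without affecting the selected scale. The signal is linearly detrended
first; peaks of the *detrended* signal are reported, which for the
band-passed, zero-mean reconstruction is the signal itself.

Peak times are refined to sub-sample precision by a three-point parabolic
fit around each sample maximum (`subsample_peaks`, on by default). At 32 Hz
the sample quantization alone is 31 ms, which would otherwise dominate
RMSSD; with the refinement the quantization contribution drops well below
the physiological signal.

## IBI refinement rules

Three rules run once, in order, on the detected intervals:

1. intervals outside 400–1300 ms (46–150 bpm; suited to seated adults, both
   bounds are config keys) are dropped;
2. intervals outside mean ± 0.4·mean are dropped, the mean computed once
   over the survivors of rule 1 — computing it after rule 1 keeps a single
   500 %-outlier from dragging the mean;
3. the survivors are partitioned into consecutive blocks of 10 (final
   partial block included; singletons trivially pass) and intervals outside
   blockmean ± 0.2·blockmean are dropped.

A single forward pass is used; re-applying the procedure can remove a few
more intervals (rules 2–3 see new means), and the tests check it reaches a
fixed point within three passes on plausible series. Every removal is
logged with its rule, and a series emptied by refinement flags the report
unreliable rather than erroring.

## HRV metric conventions

* **SDNN, RMSSD**: sample standard deviation (N−1) and RMS of successive
  differences (N−1 differences), in ms.
* **Baevsky stress index** \(= AMo/(2\,Mo\,MxDMn)\): the IBI histogram uses
  50 ms bins with *centres* at integer multiples of the bin width, so modes
  land on round values (0.80 s); Mo and MxDMn enter in seconds and AMo in
  percent. These conventions yield the customary 50–1500 resting range and
  reproduce the worked value 93.75 for a 60 %-mode, 400 ms-range series.
  Bin width is a config key.
* **LF/HF**: the tachogram (interval vs beat time) is cubic-spline
  interpolated onto a uniform 4 Hz grid (standard HRV practice; config
  key), linearly detrended, and a single FFT periodogram is integrated over
  0.04–0.15 Hz (LF) and 0.15–0.4 Hz (HF). No Welch averaging, keeping the
  estimate literally a windowless FFT spectrum. Records spanning less than
  30 s are refused — one LF cycle does not even fit in them.

Records shorter than 16 s are refused outright (`min_duration_s`):
meaningful HRV cannot be computed below ~15 s of signal.

## Ground-truth cleaning and agreement statistics

Contact-PPG reference recordings fail in characteristic ways (dropped
sensor, loose electrode, finger motion), so `clean_ground_truth` applies
four criteria: a covered face (metadata flag) invalidates the record; any
instantaneous heart rate outside 45–200 bpm invalidates it — evaluated on
the *raw* intervals, since a disconnection is exactly what outlier removal
would mask; intervals off by more than 30 % from their 25-interval segment
mean are removed as misplaced beats; and SDNN or RMSSD above 100 ms on the
*cleaned* series (beyond the plausible short-term range) invalidates the
record. The segment length 25 sits inside the customary 20–30; all
thresholds are arguments.

`agreement_stats` reports MAE, the RMS of the paired differences (labelled
`sd` — deliberately the uncentred RMS, pinned by a regression test, not a
mean-centred standard deviation), Pearson r, a two-sided paired t-test, and
Bland–Altman bias with 1.96·SD limits of agreement.

## The synthetic generator

`synth_spec`/`generate_ibi_series`/`render_ppg` produce recordings with
exact ground truth. Intervals follow an AR(1) model
\(RR_n = \mu_n + \varphi(RR_{n-1} - \mu_{n-1}) + \varepsilon_n\) with
optional sinusoidal respiratory modulation and an optional linear ramp of
\(\mu\) (drifting heart rate), truncated to 400–1300 ms (a warning fires if
truncation distorts more than 20 % of intervals). Defaults — 800 ms mean,
\(\varphi = 0.8\), 25 ms innovations, 120 s at 32 Hz, 30 dB SNR, 0.2
relative drift at 0.15 Hz — give SDNN/RMSSD in the normal resting range and
a camera-like frame rate. Each beat renders a fixed asymmetric pulse (a
difference of two gamma-like lobes, \(v^3 e^{-v/0.10}\) minus
0.35·\(v^5 e^{-v/0.11}\) on the unit interval, peak-normalized), its
maximum placed exactly at the beat time and its width scaled to 0.4 of the
local interval; sinusoidal baseline drift and white Gaussian noise at a
prescribed clean-to-noise power ratio are added. `inject_artifacts`
deterministically adds flatlines, spikes, or interval outliers with a log,
so the cleaner can be tested against known corruption.

What the generator does *not* emulate: motion artifacts correlated with the
pulse, illumination changes, waveform-shape variability between subjects,
ectopic beats with compensatory pauses, or camera compression noise.
Passing the synthetic recovery tests therefore demonstrates that the chain
is consistent and unbiased under its own model assumptions, not that it
reaches any particular accuracy on real video data.

## Problem sizes used by the tests

The test-suite and the acceptance script work at sizes chosen to exercise
every code path while staying comfortably reproducible on a laptop: 120 s
records at 32 and 256 Hz (10 seeds each) for parameter recovery and band
coverage, 60 s records for peak timing and cleaner checks, 256-sample
signals for the brute-force scattering oracle and 200-sample signals for
the AMPD oracle, and 1000 random series for the metric oracles.

## Known limitations

* The band selector follows the energy argmax; on signals whose second
  harmonic genuinely dominates the fundamental (unusual for PPG after
  0.7–5 Hz pre-filtering) it would lock onto the harmonic.
* Rule-based IBI refinement removes intervals rather than correcting them;
  a missed beat produces one dropped (double-length) interval, not an
  interpolated pair, biasing the usable-interval count down on noisy
  records.
* LF/HF from records barely over 30 s has one to three LF cycles of
  support; treat it as indicative only.
* The POS projection assumes a linear skin-reflection model; strongly
  saturated or clipped channels violate it and are only caught indirectly
  by the downstream cleaning.
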