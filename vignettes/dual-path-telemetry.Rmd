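---
title: "Dual-path separation, spike compression and telemetry accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-path separation, spike compression and telemetry accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikewire)
```

## The problem

Wireless head-mounted electrophysiology platforms must move multichannel
neural data over a link that is far too slow for the raw stream: 32 channels
at 20 ksps and 16 bits are 10.24 Mb/s, while a low-power 2.4 GHz transceiver
sustains roughly 1.4 Mbps of effective payload. The standard way out exploits
the structure of the signals themselves. Extracellular **action potentials
(APs)** are sparse, brief (about 2.4 ms) transients living in the
300–5,000 Hz band; **local field potentials (LFPs)** and **EMG** are
continuous but slow (1–500 Hz and 10–300 Hz), so they survive aggressive
decimation. Splitting the digitized stream into those two paths — detect and
compress the spikes, decimate the slow band — reduces the data volume by
roughly an order of magnitude with no loss of the information that matters
for spike sorting and spectral analysis.

`spikewire` is a desk-scale simulator of that whole chain. Every embedded
stage (analog front-end, dual FIR paths on a time-multiplexed datapath,
adaptive detection, wavelet compression, 28-byte packetization) and every
offline stage (decoding, reconstruction, sorting, band powers) is an ordinary
R function operating on synthetic, ground-truthed signals, so each link of
the chain can be tested against an oracle.

## The synthetic signal model

`synthesis_config()` / `synthesize_multimodal()` emulate a playback
experiment: known waveforms applied to the recording inputs.

* **APs**: biphasic 48-sample templates (sharp negative peak, slower positive
  rebound), band-pass shaped to 300–5,000 Hz, placed at the events of a
  refractory-thinned Poisson train (`generate_spike_train()`; the expected
  rate of the thinned process is $\lambda/(1+\lambda\tau)$ for dead time
  $\tau$). Peak amplitudes are drawn per unit from 50–500 µV.
* **LFP**: Gaussian noise synthesized in the frequency domain, masked to
  1–500 Hz with a $1/f^2$ power slope, plus a ~1 Hz sinusoid mimicking the
  slow cortical oscillation that dominates anesthetized recordings; scaled to
  a 250–5,000 µV peak-to-peak target. The spectral slope matters: a
  spectrally *flat* 1–500 Hz surrogate would push unrealistic amounts of
  power into the 300–500 Hz overlap region where no 41-tap high-pass can
  reject it, and the whole premise of band separation would fail; real LFP
  is strongly low-frequency dominated.
* **EMG**: flat-spectrum 10–300 Hz band noise (muscle activity genuinely is
  broadband within its band), 50–500 µV peak-to-peak, on designated channels.
* **Noise**: white Gaussian, default σ = 20 µV.

The generator stores every component and the noise, so
`mixture == ap + lfp + emg + stim + noise` holds sample-exactly — the basis
of the decomposition tests. A fixed seed makes the output bit-identical.

What the surrogates do **not** capture: spike-waveform diversity and drift,
non-stationary firing statistics, 1/f noise in the electrode interface,
movement and chewing artifacts, or correlated activity across channels.
Passing tests therefore demonstrate the correctness of the processing chain
under its stated signal model, not detector or sorter performance on any
particular in vivo dataset.

## Front-end emulation

The analog chip is emulated at 20 ksps by bilinear-transform equivalents of
its 1st-order high-pass (0.1–500 Hz configurable) and 3rd-order Butterworth
low-pass (100 Hz–20 kHz configurable). A low-pass cutoff at or above ~fs/2
is treated as transparent: in a sampled emulation its effect lies entirely
above Nyquist. The ADC is a saturating mid-tread two's-complement quantizer
mapping ±5 mV to 16-bit codes (LSB ≈ 0.153 µV).

## Dual-path FIR separation under a cycle budget

Both digital filters are Kaiser-window sinc designs (`design_kaiser_fir()`):

| path | kind | cutoff | taps | β |
|---|---|---|---|---|
| AP | high-pass (spectral inversion) | 300 Hz | 41 | 0.1 |
| LFP/EMG | low-pass | 500 Hz | 39 | 3 |

Conventions fixed here: the low-pass is normalized to exactly unit DC gain,
the high-pass is the spectral inversion of the complementary low-pass (unit
gain at Nyquist, odd tap count required), and the −6 dB point sits at the
cutoff, as for any windowed-sinc design. Coefficients are exactly symmetric,
which buys two things: linear phase (group delay $(n-1)/2$ samples), and a
halved multiplier count, since the two delay-line samples sharing a
coefficient can be added before the single multiplication
(`multiplication_count()`: 21 instead of 41).

The budget arithmetic is explicit: with a 20 MHz datapath clock serving 32
channels at 20 ksps, `cycle_budget()` gives 31.25 cycles per sample, so a
symmetric 41-tap filter (21 multiplications) fits and a 63-tap one would
not; `design_kaiser_fir(budget = ...)` refuses infeasible designs.
`filter_multiplexed()` executes the filter through a model of the shared
datapath — one coefficient memory, one delay-line bank with per-channel
state, round-robin channel visits (C++ under the hood) — and is tested
sample-exact against direct per-channel convolution. The LFP path is then
decimated by 10 (phase 0 retained) to 2 ksps; the 500 Hz low-pass leaves
nothing near the 1 kHz post-decimation Nyquist.

The first `n_taps - 1` output samples are the causal settling transient and
are flagged via an attribute rather than trimmed, keeping sample indices
aligned across the chain.

## Adaptive detection

The detector (`detect_aps()`) thresholds `|x|` at `k × σ` with `k = 4` and a
robust sigma, `median(|x|)/0.6745`, re-estimated on 1 s windows — the median
keeps the estimate honest even when spikes occupy ~10% of samples. A
detection freezes the detector for 48 samples (one snippet), and the snippet
spans 16 samples before to 31 after the crossing. Timestamps wrap at
2^24 samples (≈ 839 s at 20 ksps); the base station unwraps them per channel.

## The wavelet codec

Each 48-sample snippet is transformed with a 4-level discrete wavelet
transform, using the orthonormal sym4 filter bank by default (db4 and Haar
are selectable). Two design choices deserve explanation:

* **Periodized boundary handling.** The transform is implemented as a cached
  orthogonal 48×48 operator composed of per-level circulant analysis
  matrices. Periodization keeps exactly 48 coefficients — a prerequisite for
  the fixed-budget bitmap layout below — and the operator is exactly
  orthogonal at every level (including the 6-point level, where the wrapped
  autocorrelation argument still closes), so the inverse is the transpose
  and unquantized round-trips are exact to ~1e-12. Symmetric extension, the
  common alternative, would inflate 48 samples to 74 coefficients and break
  the fixed layout.
* **Fixed 184-bit budget.** The payload is 4 bits of shared power-of-two
  scale exponent, a 48-bit retention bitmap, and 22 six-bit two's-complement
  codes for the largest-magnitude coefficients: 4 + 48 + 132 = 184 bits.
  With 48 × 16 = 768 raw bits this fixes the compression ratio at
  768/184 ≈ 4.17. Energy compaction does the real work: for biphasic spikes
  the top 22 of 48 coefficients carry almost all the energy, and the
  measured round-trip error (range-normalized RMSE ≈ 0.03 at SNR 10) is
  dominated by the 6-bit quantization, not the truncation.

The quantizer scale is the smallest power of two that brings every retained
coefficient into the 6-bit range, so the codec is exact on all-zero input
and deterministic everywhere.

## Packets and accounting

Both streams travel in 28-byte records. AP packets: type byte `0x01`,
24-bit little-endian timestamp, 5-bit channel, 184-bit payload. LFP/EMG
packets: type byte `0x02`, first-sample channel, thirteen 16-bit samples
taken from the time-major channel interleave (13 is forced by
28 bytes − 2 header bytes). Little-endian order and zeroed reserved bits are
fixed here so serialization tests can be bit-exact. LFP packets carry no
timestamp; they are ordered by stream position, a documented limitation.

The headline metric is the combined data reduction ratio,

$$\mathrm{CDRR} = \frac{f_{SH}}{\mathrm{NFR} \cdot S_{AP}/\mathrm{CR} + f_{SL}},$$

(`compute_cdrr()`), 7.77 at the nominal operating point (20 ksps, 50 AP/s,
48 samples, CR 4.17, 2 ksps), and its session-level form
(`compute_recording_cdrr()`) which replaces the nominal rate with the
session's actual AP count: 9.38 for a 30 s, 16-channel recording with 5,547
detections, taking 5.12 Mbps of raw data down to 0.55 Mbps — comfortably
inside a 1.4 Mbps link (`check_link_budget()`; the ceiling is inclusive).

## Offline analyses

* `refilter_and_center()`: zero-phase 300–5,000 Hz band-pass on snippets
  (symmetric padding to tame 48-sample edge effects), then a circular shift
  of the absolute peak to a fixed index.
* `sort_spikes()`: PCA (2 components by default) + k-means. k defaults to a
  mean-silhouette selection over 2–4 with a single-cluster fallback below
  0.5. To honor order-invariance, k-means runs on canonically sorted scores
  with sign-canonicalized components, and clusters are relabeled by size.
* `band_power()`: Hann-windowed, detrended FFT; the one-sided magnitude
  spectrum is normalized by its 2-norm so squared magnitudes sum to one, and
  band percentages are taken over the configured bands (delta 1–4, theta
  4–8, alpha 8–12, beta 12–30, gamma 30–100 Hz by default).
* `firing_rate()`: counts per 0.25 s bin divided by the bin width.
* `threshold_events_gated()`: fixed dual thresholds (60 µV inside
  stimulation pulses, 45 µV outside) selected per sample by schedule
  membership — the stimulation-artifact-aware variant of simple
  thresholding.
* `emg_differential()`: two-wire subtraction for EMG background rejection.

## Numerical choices and degenerate inputs

* All-zero signals produce zero thresholds and no detections (σ = 0 is not
  special-cased into false positives).
* Snippets that would extend past either end of the signal are dropped at
  detection; events decoded beyond the session length are dropped with a
  warning and counted.
* Overlapping reconstructed snippets resolve last-writer-wins.
* Decimation keeps sample 0 of each block; ties in coefficient magnitude
  during codec retention resolve to the lower index.
* The stimulation scheduler places the first pulse at t = 0 and keeps a
  pulse only if it ends within the span.

## Problem sizes in the test-suite

Unit tests run on 1–4 channel sessions of a few seconds. The two long
checks mirror the platform's own validation scales: a 30 s single-channel
detection run at 50 AP/s and SNR 8 (precision and recall ≥ 0.95), and a
30 s, 16-channel end-to-end session whose reported reduction ratio must
agree with a hand evaluation of the session formula to 1e-6. Monte-Carlo
assertions (spike-train mean counts, white-noise band powers) state their
tolerances in standard errors of the simulated quantity.

## Known limitations

* The adaptive-threshold update rule and the embedded quantizer of the
  original hardware are documented here as this package's own substitutes
  (MAD sigma on 1 s windows; top-22/6-bit/power-of-two scale); no bit-exact
  equivalence with any FPGA implementation is claimed.
* Fixed-point datapath effects are reduced to an optional 16-bit coefficient
  quantization mode in `design_kaiser_fir()`.
* LFP/EMG packets are implicitly timed; a lost packet would shift the
  de-interleave, and no transport-loss model is included.
* Whether sorting in practice should fix k per channel or select it is
  data-dependent; both modes are provided.
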