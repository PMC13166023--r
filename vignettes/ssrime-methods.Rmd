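---
title: "SS-RIME: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SS-RIME: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ssrime)
```

This vignette is the package's own account of the science it implements:
what the SS-RIME descriptor assumes, which knobs matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## The pipeline

For one channel of one epoch `x(t)` sampled at `fs`:

1. **Decomposition.** `ceemdan()` splits `x` into intrinsic mode functions
   (IMFs) plus a residual trend, `x = Σ_k IMF_k + r`. Each mode is obtained
   by sifting: the mean of the cubic-spline envelopes through the maxima and
   minima is subtracted until the mode is locally symmetric. CEEMDAN
   stabilizes plain EMD by averaging, at each stage, the first mode
   extracted from an ensemble of noise-perturbed copies of the current
   residual, with the perturbation at stage *k* taken from the (k−1)-th EMD
   mode of each stored white-noise realization (the Torres scheme; raw noise
   at the first stage). Because the residual is updated by subtracting the
   ensemble-mean mode, reconstruction is exact by construction — the test
   suite checks `Σ IMF + r = x` to 1e−8 relative on random epochs, and in
   practice it holds to machine precision.

2. **Hilbert layer.** `analytic()` forms the analytic signal of each mode by
   FFT (positive frequencies doubled, negatives zeroed) and derives the
   instantaneous amplitude `A(t)`, the unwrapped phase, and the
   instantaneous frequency `f(t)` as the central difference of the phase
   over `2π`. This is meaningful for near-monocomponent series — which is
   exactly what sifting is designed to produce — and degrades gracefully
   otherwise: multicomponent or noisy modes show frequency jitter and
   occasional negative `f(t)`, which the descriptor *uses* (below) rather
   than hides. Negative values are therefore preserved; they also fall
   outside every physiological band, so they never contribute band energy.

3. **Descriptor.** Per mode, over interior samples:
   * stabilization `S = exp(−α·σ/|μ|)` with `μ`, `σ` the mean and standard
     deviation of `f(t)`;
   * delta/theta weight `W`, the fraction of Hilbert spectral energy
     `Σ A²(t)` whose instantaneous frequency lies in `[1,4) ∪ [4,7.5)` Hz;
   * relative energy `Ē_k = E_k/(Σ E + ε)`.
   Modes are reordered by descending median instantaneous frequency before
   assembly, so feature position encodes oscillatory scale, not extraction
   accident. The feature is `S·W·Ē`, padded/truncated to `K` values; the
   per-channel vectors are concatenated channel-wise.

The assumptions worth stating: epochs are long enough to hold several
cycles of the slowest band of interest (3 s covers three cycles at 1 Hz);
the signal is band-limited well below Nyquist (preprocess to 1–40 Hz
first); and class structure expresses itself through the *distribution* of
oscillatory energy across scales, not through absolute amplitude — the
descriptor is amplitude-invariant by design.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 1 | — | weight of the dispersion penalty; `σ/μ` is dimensionless, so `α = 1` penalizes a 20 % dispersion ratio to `exp(−0.2) ≈ 0.82`. 0 disables. Monotonicity in both `α` and `σ/μ` is tested on a grid. |
| `delta_band`, `theta_band` | [1,4), [4,7.5) | Hz | canonical EEG band edges; half-open intervals avoid double counting at the shared 4 Hz edge. |
| `K` | 8 | modes | typical mode count for 1–40 Hz EEG at these epoch lengths; decompositions are additionally capped at `⌊log2 N⌋ − 1`. Shorter decompositions are zero-padded, flagged in the result. |
| `epsilon` | 1e−12 | — | keeps all-zero energy vectors valid; induces a relative deviation of `ε/ΣE` from exact unit sum, far below the 1e−9 the tests require. |
| `weight_mode` | `spectral_energy` | — | the energy-fraction definition of `W`; `time_proportion` (fraction of samples with `f(t)` in band) is the alternative reading and is selectable. For narrowband modes the two nearly coincide; the energy form is the formally defined quantity. |
| `energy_mode` | `raw_imf` | µV²·s | `Σ IMF(t)²·Δt`; `analytic_amplitude` (`Σ A²·Δt`, about twice the raw value for a tone) is selectable. Ratios differ little for narrowband modes, and relative energies cancel the factor entirely. |
| `dispersion_as_variance` | FALSE | — | the dispersion is taken as a standard deviation so that `σ/μ` is unit-free; the variance reading is selectable for comparison. |
| `edge_trim_frac` | 0.05 | — | Hilbert end effects corrupt roughly the first and last cycle; all statistics (median frequency, dispersion, band energies, mode energies) use interior samples only. |
| `n_realizations` | 100 | — | CEEMDAN ensemble size; 20–30 already yields stable modes at test scale and is used throughout the test suite for speed. |
| `noise_scale` | 0.2 | ×SD | noise amplitude relative to the current residual's standard deviation — the conventional CEEMDAN setting, and the choice that makes the decomposition exactly scale-equivariant. |
| `sift_sd_threshold` | 0.2 | — | Cauchy-type stop `Σ env²/Σ h² < 0.2`, the conventional EMD default; `max_sift_iters = 100` is a safety cap (2–3 iterations are typical). |

Hilbert-spectrum binning defaults to 0.5 Hz × 50 ms; out-of-range samples
go to an explicit overflow accumulator so the binned grid plus overflow
always equals the interior energy exactly.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of workload EEG so
the full pipeline is testable with no recording: per channel, narrowband
oscillators near 2, 6, 10 and 20 Hz — random phase, ±0.5 Hz frequency
jitter, slow Hann-burst envelopes — on a `1/f` background, with frontal
theta amplitude scaled up and posterior alpha scaled down across conditions,
and a log-normal per-subject global gain. Oscillators are bursty rather than
pure tones deliberately: pure tones make decomposition trivially clean and
would overstate pipeline robustness. Default geometry is 8 channels at
desk scale (a 64-channel configuration is one argument away), 3 s epochs.
The generator's default sampling rate is 1000 Hz, matching common
acquisition; the test suite and acceptance script generate at 250 Hz —
comfortably oversampled for a 1–40 Hz analysis band — to keep thousands of
decompositions affordable, and state their epoch counts explicitly
(60–100 epochs per condition).

What the generator does **not** emulate: volume conduction and electrode
geometry, ocular/muscular artifacts, non-stationary band coupling, and
realistic inter-channel correlation. Passing tests on this data therefore
demonstrate the pipeline's *mechanics* — completeness, invariances,
calibration, effect recovery, component ordering — not clinical-grade
performance on real EEG.

## Numerical choices

* **Envelope boundaries.** Two extrema are mirrored past each end of the
  series before spline fitting, the standard anti-edge-swing device; the
  splines are natural cubics solved by the Thomas algorithm.
* **Degenerate inputs.** Constant or monotone series are not siftable and
  return a K = 0 decomposition whose residual is the input; `sift()` on
  such input raises a typed error (`ssrime_trend_error`). All-zero modes
  have undefined instantaneous frequency: they are flagged, excluded from
  ranking (they sort last), and receive `S = W = 0`.
* **Ties and stability.** Median-frequency reordering uses a stable sort,
  so equal-frequency modes keep extraction order; reordering is idempotent
  and the descriptor is invariant to the storage order of the modes.
* **Determinism.** All randomness flows through R's RNG. One master seed
  derives independent sub-seeds for generator, per-(epoch, channel)
  ensemble noise, and CV shuffles; two runs under one seed produce
  byte-identical feature files and reports (tested).
* **Filtering.** Preprocessing uses a zero-phase forward–backward FIR
  band-pass (default 1–40 Hz, the analyzed-acquisition setting; 0.5 Hz low
  edge selectable) and FIR notch (default 50 Hz), applied by FFT
  convolution with edge reflection; ±100 µV peak rejection follows
  filtering.

## Open design points and how they were resolved

* **`α` is the method's central free parameter and has no published value.**
  It defaults to 1 and is exposed in configuration; the tests pin its
  closed-form behaviour and monotonicity rather than any particular value.
* **Two readings of RIME.** As a standalone baseline, RIME is the
  relative-energy vector in extraction order (`rime_vector()`, normalized,
  sums to one). In the ablation study, RIME is the *fully ablated* variant —
  raw energies without stabilization, weighting, or normalization
  (`rime_vector(normalize = FALSE)`) — so that the baseline also exposes
  sensitivity to global amplitude, which is precisely the failure mode the
  ablation is designed to show. Both are exported; the ablation table
  documents which it uses.
* **Condition-difference maps.** Two z-normalization conventions are
  offered. The default standardizes each feature within subject across
  epochs, so a null contrast stays near zero — the calibration-friendly
  choice. The alternative standardizes the per-condition channel pattern
  across channels, which emphasizes topography but rescales even pure noise
  to unit variance. `delta_map(z_mode =)` selects; the frontal-vs-posterior
  conclusions on synthetic effect data agree under both.
* **Cross-validation pools epochs across subjects** before stratified fold
  assignment (the evaluation design this pipeline is built around), which
  is optimistic relative to subject-held-out validation; the per-subject
  structure is retained in the containers, so grouped schemes can be built
  on top of `stratified_folds` if needed.
* **Fisher scores for three conditions** are computed per pairwise
  contrast (the two-class ratio is the defined quantity); the evaluation
  harness reports them per contrast rather than inventing a multi-class
  form.
* **Statistics.** Wilcoxon signed-rank on paired per-fold scores;
  Bonferroni family = the number of full-vs-variant comparisons in the
  report; Cohen's d on the paired differences (mean/SD). All-zero
  difference vectors return p = 1, flagged degenerate.

## Known limitations

* EMD-family decompositions have no convergence theory; mode mixing is
  reduced by the ensemble, not eliminated. An oscillator falling between
  the roughly dyadic mode centers splits across two modes — visible in the
  worked example, where 6 Hz energy spans the ≈9 Hz and ≈4 Hz modes. The
  delta/theta weighting is what makes the descriptor robust to this.
* The stabilization penalty conflates noise-induced jitter with genuine
  frequency modulation (e.g. a chirp is penalized).
* Runtime is dominated by CEEMDAN: cost grows linearly in ensemble size,
  epoch length and channel count (roughly 10 ms per 3 s × 250 Hz channel at
  `n_realizations = 20` on one core).
* The EDF reader covers the plain EDF profile used for continuous
  recordings (16-bit records, one rate across kept channels); EDF+
  annotations are skipped, not parsed.
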