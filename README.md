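# ssrime

Scale-stabilized relative intrinsic mode energy (SS-RIME) features for EEG
cognitive-workload decoding, in R.

## The problem

Working-memory load (e.g. in an N-back task) modulates EEG rhythms in
well-characterized ways: frontal-midline theta (4–7.5 Hz) power rises with
load, posterior alpha (8–13 Hz) desynchronizes, and slow delta (1–4 Hz)
activity accompanies sustained attention. Data-driven decompositions such as
CEEMDAN (complete ensemble empirical mode decomposition with adaptive noise)
adapt to the non-stationary, burst-like character of these rhythms better
than fixed-basis spectra, but their intrinsic mode functions (IMFs) are
unstable: the mode that carries theta in one epoch or subject may be a
different index in the next, instantaneous-frequency estimates jitter, and
raw mode energies track global amplitude rather than oscillatory structure.

SS-RIME addresses all three instabilities at the feature level. For each
channel of an epoch, the signal is decomposed into IMFs, each mode is mapped
to its Hilbert analytic form, and the per-mode descriptor is

```
SS-RIME_k = S_k · W_k · Ē_k
```

where, over the interior (non-edge) samples of mode *k*,

* `S_k = exp(−α·σ_k/|μ_k|)` penalizes instantaneous-frequency dispersion
  (`μ_k`, `σ_k`: mean and standard deviation of the instantaneous frequency;
  `α` ≥ 0, default 1),
* `W_k` is the fraction of the mode's Hilbert spectral energy inside the
  union of the delta (1–4 Hz) and theta (4–7.5 Hz) bands, and
* `Ē_k = E_k / (Σᵢ Eᵢ + ε)` is the mode's relative energy.

Modes are first reordered by descending median instantaneous frequency so
that "mode *k*" means the same oscillatory scale across epochs and subjects.
The per-channel K-vectors are concatenated channel-wise into the epoch's
feature vector.

The package is aimed at researchers who want a reproducible, fully seeded
reference implementation of this pipeline: the decomposition (EMD sifting and
Torres-scheme CEEMDAN, implemented in C++), the Hilbert layer, the descriptor
and its ablation variants, the RIME / relative-wavelet-energy / PSD
band-power baselines, a Fisher-score + stratified repeated-CV evaluation
harness, a synthetic workload-EEG generator for end-to-end validation without
any recording, plain-text and EDF input, and a command-line interface.

## Worked example

Simulate a small three-condition N-back-style dataset, decompose one frontal
channel, and inspect the descriptor:

```r
library(ssrime)

cfg <- synth_config(fs = 250, n_epochs_per_condition = 30,
                    conditions = c("0-back", "2-back", "3-back"),
                    theta_gain = c(1, 1.5, 2), alpha_gain = c(1, 0.8, 0.65),
                    seed = 7)
eeg <- generate_dataset(cfg)
eeg
#> <epoched_eeg> 90 epochs x 8 channels x 750 samples @ 250 Hz
#>
#> 0-back 2-back 3-back
#>     30     30     30

x <- signal_epoch(eeg$data[1, 1, ], fs = eeg$fs, channel_id = "Fz")
dec <- ceemdan(x, params = ceemdan_params(n_realizations = 30, seed = 7))
dec
#> <imf_set> ceemdan: K = 7 modes + residual, 750 samples @ 250 Hz

fv <- ssrime_vector(dec)
round(fv$per_imf_metadata, 4)
#>   median_freq      S      W        E   Ebar
#> 1     70.3185 0.5895 0.0054  69.9320 0.1191
#> 2     38.1658 0.6440 0.0022   3.4472 0.0059
#> 3     18.9560 0.5062 0.0875 123.5690 0.2104
#> 4      8.9981 0.5823 0.4518 173.9194 0.2961
#> 5      3.8629 0.6604 0.9990 123.4954 0.2103
#> 6      1.9047 0.6289 0.2857  63.4886 0.1081
#> 7      0.5871 0.5852 0.0918  29.4976 0.0502
#> 8      0.0000 0.0000 0.0000   0.0000 0.0000
```

The metadata reads top-to-bottom from fast to slow modes: the gamma/beta
modes (rows 1–2) carry almost no delta/theta weight, the theta-range modes
(rows 4–5, median frequencies ≈ 9 and ≈ 3.9 Hz straddling the 6 Hz
oscillator) combine high `W` with substantial relative energy, and the final
row is zero-padding up to the configured `K = 8`. The feature values
`S·W·Ē` therefore concentrate on the physiologically informative modes.

Decode workload and localize the contrast:

```r
f <- extract_features(eeg, "ssrime",
                      cparams = ceemdan_params(n_realizations = 20), seed = 7)
keep <- attr(f, "labels") %in% c("0-back", "2-back")
cross_validate(f[keep, ], droplevels(attr(f, "labels")[keep]), "svm",
               n_folds = 10, n_repeats = 2, seed = 7,
               grid = data.frame(cost = 1, gamma = 1/ncol(f)))
#> <cv_result> svm: accuracy 85.00 +- 14.20 %, macro-F1 0.845 (2 x 10-fold)

round(delta_map(f, high = "2-back", low = "0-back", imf_select = 4:5), 2)
#>   Fz  FCz   Cz   C3   C4   Pz   O1   O2
#> 1.02 0.82 1.17 0.85 0.19 0.02 0.38 0.15
```

At this deliberately small size (30 epochs/condition) the 0-back vs 2-back
contrast decodes at 85 %, and the theta-mode condition difference is largest
over the frontal-midline channels (Fz, FCz, Cz) — the spatial pattern the
generator builds in. Larger datasets (see `scripts/acceptance.R`) push the
accuracy above 95 %.

The same pipeline is scriptable from a shell via the installed `ssrime`
executable (`simulate`, `decompose`, `features`, `evaluate`, `ablate`
subcommands; `--config`, `--seed`, see `ssrime_cli()`).

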