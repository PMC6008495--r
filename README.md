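# tfarr

Detection of life-threatening ventricular arrhythmia from single-lead ECG
using a digital Taylor–Fourier filter bank and a least-squares support
vector machine (LSSVM).

Ventricular fibrillation (VF), rapid ventricular tachycardia (VT) and
ventricular flutter are *shockable* rhythms: they call for immediate
defibrillation, and automated detectors must separate them from normal
sinus rhythm (NSR) and other non-shockable activity within a few seconds
of ECG. `tfarr` implements, end to end:

* **Taylor–Fourier mode decomposition.** A frame *s* is projected by least
  squares onto harmonic carriers at center frequencies
  *f_j = 0, 5, …, 45 Hz* whose complex envelopes are Taylor polynomials of
  degree *K* in time: *ŝ = B ξ̂*, *ξ̂ = B⁺ s*, where the columns of **B**
  are *tⁿ*-weighted cosines and sines and **B**⁺ is the Moore–Penrose
  pseudoinverse. Sliding the analysis window one sample at a time and
  keeping the window-center (order-0) coefficient is FIR filtering with
  rows of **B**⁺ — a bank of maximally flat harmonic filters. Each mode *j*
  yields a dynamic phasor with instantaneous amplitude *â_j(n)* and phase
  *φ̂_j(n)*.
* **Features.** Per mode, the magnitude feature *MF_j = ‖â_j‖₂* and the
  phase-difference feature
  *PD_j = mean |wrap(φ̂_j(l+1) − φ̂_j(l))|* — 20 features per frame for the
  10-mode grid.
* **Classifier.** An LSSVM (linear or RBF kernel) whose training is one
  symmetric KKT linear system
  `[[0, yᵀ], [y, Ω + γ⁻¹I]] [b; β] = [0; 1]`, with stratified 65/35
  hold-out and 5-fold cross-validation reporting accuracy, sensitivity and
  specificity.
* **Data paths.** A seeded synthetic generator of NSR-, VT- and VF-like
  rhythms (so everything is testable offline), plain-CSV records, and a
  minimal WFDB-style reader (headers, signal formats 16/212, MIT rhythm
  annotations) for PhysioNet-layout databases.

## Worked example

```r
library(tfarr)

# 40 synthetic 4-s frames per class at 250 Hz, band-pass 0.5-45 Hz
ds <- gen_dataset(40, classes = c("NSR", "VF"), frame_s = 4, seed = 1)
ds$signal <- lapply(ds$signal, bandpass, fs = 250)

basis <- build_basis(fs = 250, grid_spacing = 5, n_modes = 10,
                     taylor_order = 2)
fm <- feature_matrix(ds, basis)          # 80 x (rhythm + 20 features)

y <- as.integer(fm$rhythm == "VF")
feats <- dplyr::select(fm, dplyr::starts_with("mf_"),
                       dplyr::starts_with("pd_"))
holdout_experiment(feats, y, kernel = "rbf", gamma = 10, seed = 1)
#> <eval_report> Acc 100.00%  Sen 100.00%  Spe 100.00%  (tp 14, tn 14, fp 0, fn 0)

ft <- feature_ttest(feats, y)
attr(ft, "n_significant")                # features with p < 0.001
#> [1] 15
```

The perfect hold-out score reflects how cleanly the surrogate VF (an
irregular 3–8 Hz broadband oscillation) separates from surrogate NSR in
the mode-feature space; it is a property of the synthetic generator, not a
claim about clinical recordings. The t-test screen says 15 of the 20
features differ between the classes at *p* < 0.001.

A single frame's decomposition can be inspected directly:

```r
d <- decompose(basis, ds$signal[[1]])
tidy(d)              # long tibble: sample, mode, amplitude, phase, value
autoplot(d)          # one facet per mode with its amplitude envelope
plot_filter_bank(basis)
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "tfarr.R", package = "tfarr")` with subcommands
`simulate`, `preprocess`, `decompose`, `response`, `features`, `ttest`,
`train`, `eval`, `experiment`, `pipeline` and `reproduce`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","tfarr.R",package="tfarr"))')" \
  simulate --class vf --fs 250 --duration 8 --seed 7 --out sig.csv
```

`run_reproduction()` (or the `reproduce` subcommand) runs the full
pipeline over a local directory of WFDB-layout records with rhythm
annotations; it reports rather than asserts, since episode-selection
rules and hyperparameters of published database experiments are not fully
specified.

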