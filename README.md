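# tdlda — time-decoupled covariance estimation for ERP classification

Linear discriminant analysis (LDA) is the workhorse classifier for
event-related potentials (ERPs) in EEG-based brain-computer interfaces:
each stimulus-locked epoch is summarized by the mean voltage of `C`
channels in `K` post-stimulus time intervals, and a two-class LDA separates
attended (*target*) from ignored (*non-target*) epochs. The classifier
needs the feature covariance `Σ`, a `D × D` matrix with `D = C·K` and
`D(D+1)/2` free parameters — 12 090 for a 31-channel, 5-interval montage —
while a calibration run may provide fewer than 100 epochs.

This package implements **time-decoupled covariance estimation** for that
regime. Assuming the background EEG noise is not time-locked to the
stimulus (homoscedastic across the epoch), the between-channel covariance
is the same in every time interval and can be estimated *once* from all
intervals jointly: the class-centered feature matrix is rearranged into a
`C × (N·K)` channel matrix (interval `m` scaled by `√|T_m|`), its sample
covariance `Σ̂ᶜ` is rescaled per block to match the block's determinant,

    Σ̂ᶜ_m = (det B_m / det Σ̂ᶜ)^(1/C) · Σ̂ᶜ,

and substituted into the `K` within-interval diagonal blocks of the
shrinkage-regularized pooled covariance. The resulting `Σ̇` feeds the LDA
weights `w = Σ̇⁻¹(μ₁ − μ₀)` with the bias set at the class-mean midpoint.

The package also provides:

* the baseline LDA variants (`p-cov`: pooled + Ledoit–Wolf shrinkage;
  `c-covs`: class-wise covariances averaged, then shrunk),
* ERP preprocessing: zero-phase Butterworth band-pass, Fourier resampling,
  epoching, optional baseline correction, interval-averaged features with
  the standard visual/tone and word-paradigm interval sets,
* a synthetic ERP epoch simulator with spatially correlated,
  temporally colored (two-timescale AR mixture) Gaussian noise whose
  feature covariance is known in closed form — every statistical claim in
  the test suite is checked against that ground truth,
* a benchmark harness: virtual data subsets, stratified cross-validated
  AUC, hierarchical aggregation, paired Wilcoxon signed-rank tests with
  Holm correction, and learning curves over training-set size and channel
  subsets,
* a thin command-line front end (`inst/cli/tdlda.R`) with `simulate`,
  `benchmark` and `learning-curve` subcommands.

## Worked example

Simulate one 90-epoch oddball calibration run (31 channels, 1:5 target
ratio), extract 5-interval features, and compare the LDA variants:

```r
library(tdlda)

cfg    <- sim_config(seed = 7)          # 31 channels, 15/75 epochs, 100 Hz
epochs <- generate_epochs(cfg)
epochs
#> <epoch_collection> 90 epochs (15 target / 75 non-target), 31 channels,
#>   100 samples @ 100 Hz, t = [0.000, 0.990] s

fm <- extract_features(epochs, default_intervals("visual", 5))
fm
#> <feature_matrix> D = 155 (31 channels x 5 intervals), N = 90 epochs (15 target)

dot <- time_decoupled_covariance(fm)
dot
#> <cov_estimate> 155 x 155, kind = time_decoupled, layout = 31 channels x 5
#>   intervals, gamma = 0.1043
#>   PSD repairs: clipped 97 eigenvalue(s); smallest eigenvalue -3.259e+01 is
#>   below the positivity floor; floor 5.655e+00

for (v in c("p-cov", "c-covs", "imp-p-cov")) {
  folds <- stratified_folds(fm$labels, 5, seed = 1)
  cat(sprintf("%-10s CV AUC = %.3f\n", v,
              mean(stratified_cv_auc(fm, v, folds = folds))))
}
#> p-cov      CV AUC = 0.684
#> c-covs     CV AUC = 0.684
#> imp-p-cov  CV AUC = 0.667
```

The printed covariance shows the estimator at work: the Ledoit–Wolf
intensity (`gamma = 0.104`) regularizes the pooled matrix, and the block
substitution left the assembled matrix indefinite, so its eigenvalues were
clipped at the shrinkage ridge level (5.66 µV²) — the repair is recorded in
the estimate's log. Because the simulator knows the generating covariance,
the improvement the method claims can be measured directly:

```r
tru <- true_feature_covariance(cfg, default_intervals("visual", 5))
#  Frobenius distance to truth: shrunk 1138.6, time-decoupled 1105.3
```

The time-decoupled matrix is the closer estimate — on this generator it is
closer in every one of 50 replicate sessions (see below), while the
cross-validated AUC of the two variants is statistically indistinguishable
at this operating point; the vignette
(`vignettes/time-decoupled-covariance.Rmd`) discusses why those two
findings coexist on Gaussian simulation.

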