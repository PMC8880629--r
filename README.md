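# dissolvenet

Deep-learning prediction of in-vitro pharmaceutical formulation
properties from tabular formulation descriptors, built for the
small-and-imbalanced datasets typical of formulation science.

Two pipelines are implemented end to end:

* **OFDF** — predicts the disintegration time (0–100 s) of oral fast
  disintegrating films from 24 features (molecular descriptors, encoded
  excipient types, process parameters). The features are min–max
  normalized, rotated by PCA fitted on the training part, reduced to the
  scree-elbow component count (5), and fed to a compact fully-connected
  network (50, 25, 16 hidden units, dropout 0.05, He-uniform init,
  sigmoid output; Adam, lr 0.01, 800 epochs, batch 32). The reduction
  shrinks the network from 2958 to 2008 trainable parameters and removes
  the multicollinearity between descriptor columns.
* **SRMT** — predicts the 4-point cumulative dissolution profile
  (% released at 2, 4, 6, 8 h) of sustained-release matrix tablets from
  21 features with a multi-output network (150, 130, 100, 50, 30 hidden
  units, dropout 0.1 on the first two layers, normal init; Adam,
  lr 0.001, 2000 epochs, batch 32). Because the training data are small
  and imbalanced over binned final-dissolution classes, the training part
  is augmented: by class-balanced oversampling (ROS / SMOTE / ADASYN on
  the concatenated feature‖profile rows) or by a weight-clipped
  Wasserstein GAN that learns the joint 25-dimensional row distribution
  (RMSProp 5e-5, clip 0.01, 5 critic steps per generator step), whose
  candidates are screened by the physical validity filter: a cumulative
  profile must be non-decreasing in time.

Evaluation uses the field's criteria rather than generic regression
scores. OFDF: fraction of predictions within 10 s. SRMT: fraction of
samples whose predicted profile is similar to the observed one under the
FDA f2 similarity factor,

    f2 = 50 log10( 100 [1 + (1/4) Σ_t (R_t − T_t)²]^(−1/2) ),

with success at f2 ≥ 50 (identical profiles give 100; a uniform
10-percentage-point error gives 49.89 — about 50, but below the hard
cutoff). A 2-D PCA projection diagnostic (`project_2d`) quantifies GAN
mode collapse via the ratio of generated-to-real score dispersion.

Seeded synthetic-data generators (`gen_ofdf`, `gen_srmt`) emulate both
dataset structures — correlated feature blocks with a planted scree elbow
at 5; Weibull release kinetics with an exact, configurable class
imbalance — so every stage runs and is tested without any external data.

## Worked example

```r
library(dissolvenet)

audit_params()$totals
#>     ofdf_existing     ofdf_proposed ofdf_proposed_pca     srmt_existing
#>             24251              2958              2008              8224
#>     srmt_proposed
#>             42734

run_ofdf(seed = 1)   # synthetic 131-sample film dataset, split 91/20/20
#> <ofdf_run> k = 5 components, 2,008 parameters, 2400 updates
#>   train      <eval_report ofdf> n = 91 | accuracy 100.0% | RMSE 0.0042 | MAE 0.0034
#>   validation <eval_report ofdf> n = 20 | accuracy 100.0% | RMSE 0.0348 | MAE 0.0266
#>   test       <eval_report ofdf> n = 20 | accuracy 100.0% | RMSE 0.0349 | MAE 0.0286
```

The run reports: `k` components kept (the scree elbow of the training
features), the trainable-parameter count of the reduced network (2008;
2958 without PCA), the optimizer updates actually performed
(800 × ⌈91/32⌉ = 2400), and per-part accuracy (fraction of predictions
within 10 s, on the seconds scale) with RMSE/MAE on the normalized scale.

The tablet pipeline is one call with the augmentation method of choice:

```r
r <- run_srmt(method = "wgan", seed = 1,
              wgan = wgan_config(iterations = 2000), n_candidates = 1000)
#> <srmt_run wgan> 375 training rows (270 generated, 730 filtered out), 42,734 parameters
```

Here 1000 generated candidates were screened by the cumulative-release
filter; the 270 surviving rows joined the 105 original training rows, and
accuracy is the fraction of samples with f2 ≥ 50 against the observed
profiles.

A thin CLI wraps the same functions
(`inst/cli/dissolvenet.R`: `simulate`, `train-ofdf`, `train-srmt`,
`augment`, `evaluate`, `audit-params`), with YAML configs and run
directories containing CSV/JSON artifacts and a reproducibility manifest.

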