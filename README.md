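# strokesight

Functional-outcome prognosis for ischemic stroke patients from admission
head CT, in R. Ninety days after a stroke, disability is graded on the
modified Rankin Scale (mRS, 0–6) and dichotomised into good (mRS ≤ 2) and
poor (mRS > 2) outcome. `strokesight` implements, end to end, the model
families used to predict that dichotomy from MNI-registered CT together
with the statistical harness to compare them:

* **Image-only 3D CNN classifiers** over non-contrast CT (NCCT): a plain
  baseline; a *mirror* variant fed `v − mirror_msp(v)`, the volume minus
  its midsagittal reflection; three **Siamese** variants that encode both
  hemispheres with one weight-shared encoder and merge by
  `|pool(E(L)) − pool(E(R))|` (After), `pool(|E(L) − E(R)|)` (Before) or a
  learned grouped-convolution comparison of interleaved channels (Tangle);
  and **multiple-instance-learning** models over bags of axial slices with
  mean, max or attention aggregation
  (`a_k ∝ exp(wᵀ tanh(V h_k))`, a learned weighted mean).
* **Occlusion classifiers** over axial maximum-intensity projections (MIP,
  slices 45–100 of the MNI 1 mm grid, a 218×182 image) of CT angiography,
  with single-encoder and three Siamese variants, including frozen
  ImageNet-style 2D encoders.
* **Hybrid logistic regressions** fusing clinical variables (age, NIHSS,
  delay, visual defect, consciousness, glucose) with imaging biomarkers
  (ASPECTS; occlusion — expert or network-predicted), tuned by
  Gaussian-process Bayesian optimisation inside 10-fold cross-validation and
  compared to the ASTRAL clinical score with fold-paired t-tests (α = 0.05),
  normalised-coefficient importance profiles and VIF diagnostics.

Encoders include a compact 3D CNN (8/16/32/64 filters, strides 1/2/1/2,
≈73 K parameters), a four-module 3D inception encoder, cubified ResNets
18/34/50 (a 91×109×91 NCCT leaves the last stage as a 3×4×3 map), their
planar twins and EfficientNets B0–B2. No deep-learning framework is
required: the package ships its own C++-backed convolution, batch-norm,
pooling, backprop and Adam core, verified against brute-force and
finite-difference oracles in the test suite.

A synthetic-data module makes the whole pipeline testable without patient
data: NCCT phantoms (mirror-symmetric brains with strictly unilateral
hypodense lesions and recorded ground truth), CTA phantoms (symmetric
vessel trees with unilateral attenuation) and a cohort generator with
realistic admission marginals and a known logistic outcome model.

## Worked example

Generate phantoms, train a Siamese hemisphere classifier at reduced
resolution, and evaluate on held-out phantoms:

```r
library(strokesight)

ph <- gen_ncct_phantoms(phantom_spec("mni-2mm", n_subjects = 120,
                                     lesion_prob = 0.5, seed = 21),
                        downscale = 4)
sp <- stratified_split(ph$labels, c(0.6, 0.15, 0.25), seed = 2)

clf <- assemble_siamese(classifier_spec("siamese_before",
                                        build_custom_cnn3d(filters = c(4, 8, 16, 32)),
                                        pooling = "GMP"))
fit <- train(clf,
             list(x_train = ph$volumes[sp$train], y_train = ph$labels[sp$train],
                  x_val = ph$volumes[sp$val], y_val = ph$labels[sp$val]),
             train_config(epochs = 8, learning_rate = 1e-3,
                          weight_decay = 1e-4, batch_size = 16, seed = 11))
m <- evaluate(predict(fit$model, ph$volumes[sp$test]), ph$labels[sp$test])
cat(sprintf("held-out AUC %.3f, F1 %.3f (best epoch %d)\n",
            m$auc, m$f1, fit$best_epoch))
#> held-out AUC 0.995, F1 0.762 (best epoch 3)
```

An AUC near 1 says the planted unilateral lesions (−15 HU spheres against
2 HU noise) are essentially separable from the hemisphere-difference
features at this scale — the architecture recovers exactly the asymmetry
signal it was designed around (the F1 of 0.76 reflects the untuned 0.5
operating point, not the ranking). On the tabular side:

```r
gen <- gen_cohort(cohort_spec(n = 1000, seed = 93))
res <- run_lr_experiment(experiment_def("lr_8vars"), clean_cohort(gen$cohort),
                         k = 10, seed = 7)
ast <- run_lr_experiment(experiment_def("astral"), clean_cohort(gen$cohort),
                         k = 10, seed = 7)
cat(sprintf("LR 8vars AUC %.3f ± %.3f | ASTRAL AUC %.3f ± %.3f\n",
            mean(res$metrics$auc), sd(res$metrics$auc),
            mean(ast$metrics$auc), sd(ast$metrics$auc)))
#> LR 8vars AUC 0.794 ± 0.039 | ASTRAL AUC 0.743 ± 0.057
paired_t_test(res$metrics$auc, ast$metrics$auc)$p_value
#> [1] 0.002617613
normalized_coefficients(res$coefficients)[1:3, ]
#>            variable      mean          sd
#> nihss         nihss 0.3051519 0.008344956
#> age             age 0.1914709 0.008075899
#> occlusion occlusion 0.1843603 0.010023120
```

Mean ± sd here are over the 10 cross-validation folds; the paired t-test
compares the two experiments fold by fold (the fitted model beats the
integer score significantly on this synthetic cohort), and the coefficient
profile is each fold's |coefficients| normalised to sum to 1 — NIHSS and
age dominating is exactly what the cohort generator's coefficients encode.

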