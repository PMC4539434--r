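# pdaseq

Dynamic ODE modeling of per-base RNA-seq coverage profiles.

## The problem

Summarizing a gene's RNA-seq signal by a single count discards the shape
of the read-coverage profile along the gene body — the positional
structure that carries information about splicing, alternative
transcription starts/ends, and isoform usage.  `pdaseq` treats the
per-base expression profile of one gene in one sample as a *function* of
genomic position and models it as the trajectory of a linear dynamical
system in position rather than time.

After mapping the gene to the canonical interval `t ∈ [0, 100]` and
log-normalizing counts (`y = log(count / scale_factor + 1)`, so
uncovered bases map to exactly 0), the observed profile is

    y(t) = x(t) + e(t),

where the hidden state `x(t)` is assumed to be annihilated by a
second-order linear differential operator with location-varying
coefficient functions:

    L(x) = x''(t) + w1(t) x'(t) + w0(t) x(t) = 0.

The pair `(w0(t), w1(t))` is the learned, interpretable representation
of the gene's transcription profile.  It is estimated by **principal
differential analysis (PDA)**: alternate between

1. penalized Fourier-basis smoothing of the curves, where the roughness
   penalty is `λ ∫ L(x̂)² dt` — curves are pulled toward the operator's
   null space — with closed-form per-sample coefficients
   `C_i = (Φ̃ᵀΦ̃ + λ J_φh)⁻¹ Φ̃ᵀ Y_i`, and
2. a closed-form least-squares update of the operator coefficients,
   `h = −[∫ Gᵀ C*ᵀC* G dt]⁻¹ ∫ Gᵀ C*ᵀC* φ'' dt`,

until the expansion vector `h = (h1, h0)` stabilizes.

The fitted operator then supports:

- **Curve prediction** — solve the fitted ODE as a two-point boundary
  value problem (Chebyshev spectral collocation) given only the two
  endpoint values of a held-out sample's smooth, scored by per-fold
  RMSPE under stratified k-fold cross-validation;
- **Feature extraction** — functional PCA scores of the per-sample
  `w0`, `w1` curves, interleaved into a feature matrix for L1-penalized
  logistic classification (IRLS + coordinate descent, KKT-verified) and
  hierarchical clustering with Newick export;
- **Response analysis** — the unit-step response (solution of
  `L(x) = 1`) per sample, compared between groups with a Hotelling T²
  statistic on pooled FPCA scores, referred to a χ²_k null.

A synthetic-data module generates curves with exactly the model's
assumed structure (states solving a known varying-coefficient ODE plus
iid Gaussian measurement noise), so every stage is testable without any
external data.

## Worked example

```r
library(pdaseq)

# two groups of 12 samples; group 2 has its w0 shifted by 0.5*(2*pi/100)^2
spec <- simulation_spec(noise_sd = 0.1, n_samples = 12, seed = 1)
tg   <- generate_two_group(spec)

# per-sample operator fits, coefficient curves and unit-step responses
ps <- fit_per_sample(tg$curves, lambda = 100)

# group-difference test on the unit-step responses (k = 3 scores)
hotelling_response_test(ps$response[ps$groups == "normal", ],
                        ps$response[ps$groups == "tumor", ],
                        k = 3, t = ps$t)
#> Hotelling T^2 = 5.003 on k = 3 components; p = 0.1715 (chisq null)

# FPCA score features of (w0, w1) -> cross-validated lasso classification
feats <- coefficient_features(ps, K_pc = 3)
classify_cv(feats$Z, factor(feats$groups), k_folds = 4, seed = 2)
#> classification (positive = tumor): sensitivity 1.000, specificity 0.917, accuracy 0.958

# pooled fit of the first group
fit_pda(tg$curves[1:12], lambda = 100)
#> pda_fit: 12 sample(s), K = 11, lambda = 100; 11 iteration(s), converged, final SSE_p = 0.001801
```

The Hotelling p-value of 0.17 at n = 12 per group reflects the modest
power of the k = 3 response test at this sample size; the classifier on
the same fits separates the groups almost perfectly (23/24 correct)
because the constant `w0` shift moves the leading FPCA scores of the
coefficient curves directly.

## Command-line interface

```sh
Rscript inst/cli/pdaseq.R simulate   --seed 1 --two-group --out sim/
Rscript inst/cli/pdaseq.R fit        --curves sim/curves.tsv --lambda 100 --out fit/
Rscript inst/cli/pdaseq.R predict-cv --curves sim/curves.tsv --k-folds 5 --out cv/
Rscript inst/cli/pdaseq.R respond    --curves sim/curves.tsv --out resp/
Rscript inst/cli/pdaseq.R classify   --curves sim/curves.tsv --out cls/
Rscript inst/cli/pdaseq.R cluster    --features Z.tsv --n-groups 9 --out clus/
```

Options may also come from a JSON file (`--config cfg.json`; flags
override it).  Every run writes `run_config.json` and `run.log` as a
provenance record; all numeric output uses 17 significant digits, so
seeded runs are byte-identical.

## Known limitations

- With a Fourier state basis on `[0, 100]`, any curve family whose
  members differ at the two endpoints lies outside the (periodic) basis
  span; the truncation ringing this induces contaminates second
  derivatives and biases coefficient recovery.  Ground-truth recovery of
  `(w0, w1)` from the default synthetic world therefore fails its 10%
  target (left red in the acceptance tests), even though the fit is
  self-consistent and the downstream classification pipeline is
  accurate.
- The default synthetic truth accumulates ≈1.97π of oscillation phase
  across the domain, so its two-point BVP sits close to a Dirichlet
  resonance: small operator errors are amplified ~20× in reconstructed
  curves.  The fit-then-solve round trip misses its 5% target in this
  world for that reason.
- The χ²_k Hotelling reference is anti-conservative at small n (the
  exact null is a scaled F); at N1 = N2 = 20, k = 3 the intrinsic CDF
  gap to χ²_3 is 0.040, which leaves the 0.05 QQ acceptance bound
  essentially no sampling room at 500 replicates.

All three are analyzed quantitatively in the methods vignette.
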