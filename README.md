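# bforient

Orientation estimation for neural sources with scalar LCMV beamformers.

Applications such as individually targeted transcranial electric
stimulation need the spatial *orientation* of a neural target population,
because stimulation is most effective when the injected current flows along
it. Beamformers can estimate that orientation from EEG/MEG data — but the
three common scalar LCMV variants behave very differently. `bforient` is a
simulation-and-analysis package for quantifying those differences and for
computing the closed-form theory that explains them. It is aimed at
EEG/MEG methods researchers and at anyone choosing a beamformer variant for
orientation reconstruction.

## The estimators

For a leadfield `L` (channels × 3) and data second moment
`R = (1/T) Σ d(t) d(t)ᵀ`, the power-optimal orientation of each variant is
the eigenvector of the smallest (generalized) eigenvalue:

* **Unit-Gain (UG)** `η̂ = ν_min{ Lᵀ R⁻¹ L }`
* **Unit-Noise-Gain (UNG)** `η̂ = ν_min{ Lᵀ R⁻² L, Lᵀ R⁻¹ L }`
* **Array-Gain (AG)** `η̂ = ν_min{ Lᵀ R⁻¹ L, Lᵀ L }`

For the single-source model `R = Q² (Lη)(Lη)ᵀ + σ² I`, UNG and AG are
exactly unbiased — for the full orientation from EEG and for the tangential
component from the SVD-reduced MEG leadfield. UG is biased at every noise
level: as `σ → ∞` it converges to the leadfield's weakest singular
direction (data-independent), and in the MEG case even the `σ → 0` limit
misses the tangential truth by an amount given by a rank-one secular
equation. The package implements the estimators, the EEG+MEG fusion, the
closed-form limits, the pseudo-Z/NAI score equivalences, and seeded
Monte-Carlo experiment drivers (random orientations, EEG/MEG noise sweep,
bootstrapped fixed-orientation grid).

## Worked example

```r
library(bforient)

eeg <- generate_synthetic_leadfield(60, c(1, 0.6, 0.1), seed = 301)
meg <- generate_synthetic_leadfield(60, c(1, 0.8, 0.05), seed = 302,
                                    modality = "MEG")
frame <- make_target_frame(meg, source_leadfield_for_condition = eeg)
frame
#> <target_frame 'synthetic'> singular values 1 0.8 0.05, condition number 10

eta <- drop(sample_random_orientations(1, seed = 11))   # ground truth
round(eta, 4)
#> [1] -0.3631  0.0163 -0.9316

sim <- simulate_data(eeg, eta, sim_config(sigma = 2, seed_noise = 12))
R <- estimate_covariance(sim, regularization_fraction = 0.05)
R
#> <second_moment> 60 x 60, sample, T = 36000, regularized 0.05

for (m in c("UG", "UNG", "AG")) {
  est <- estimate_orientation(eeg, R, m)
  cat(sprintf("%-4s error: %6.2f deg\n", m, estimation_error(est$eta_hat, eta)))
}
#> UG   error:   9.80 deg
#> UNG  error:   0.40 deg
#> AG   error:   0.44 deg
```

At this medium noise level (`sigma = 2`) the unbiased variants recover the
truth to better than half a degree, while UG is 9.8° off. The UG estimate
is not noise — it has already converged to the leadfield's weakest singular
direction, which happens to lie 9.8° from this particular truth:

```r
lim <- ug_high_noise_limit(eeg)
estimation_error(estimate_orientation(eeg, R, "UG")$eta_hat, lim)
#> [1] 0.2680636
```

Distribution-level comparisons come from the experiment drivers:

```r
cfg <- experiment_config(eeg_leadfield = eeg, meg_leadfield = meg,
                         methods = c("UNG", "AG"), modalities = "EEG",
                         sigma_list = c(0.5, 2), n_orientations = 50,
                         duration = 10)
res <- run_random_orientation_experiment(cfg)
res$summary[, c("sigma_e", "method", "value", "ci_lo", "ci_hi", "n")]
#>   sigma_e method value ci_lo ci_hi  n
#> 1     0.5     AG  2.95  2.21  3.69 50
#> 2     0.5    UNG  2.99  2.24  3.74 50
#> 3     2.0     AG 22.67 17.42 27.92 50
#> 4     2.0    UNG 22.95 17.55 28.34 50
```

`value` is the mean angular error in degrees with a 95% interval: errors
grow with the noise level, and UNG/AG stay within a fraction of a degree of
each other.

A command-line wrapper (`inst/exec/bforient`) exposes the same pipeline as
subcommands `make-leadfield`, `simulate`, `exp-random`, `exp-sweep`,
`exp-grid` and `theory-check`; every run writes long-form CSV records, a
summary CSV and a `manifest.json` with all resolved settings and seeds,
from which the run can be reproduced bit-identically.

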