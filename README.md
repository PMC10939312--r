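# esfm — forward models of expectation suppression in visual cortex

Expected visual stimuli evoke weaker fMRI responses than unexpected ones
(*expectation suppression*). Two opposite neural mechanisms can produce it:
**dampening** (suppression of neurons tuned *toward* the expected feature —
local gain modulation) and **sharpening** (suppression of neurons tuned
*away* from it — remote gain modulation). Because each fMRI voxel pools many
differently tuned neurons, both mechanisms — and four further variants
(global gain; local/remote/global *tuning*, i.e. width narrowing) — can
produce similar voxel-level results. `esfm` is for cognitive-neuroscience
researchers who want to test which modulation accounts for their data by
explicit forward modelling rather than qualitative reasoning.

The package simulates populations of feature-tuned neurons (von Mises curves
on a circular orientation axis, Gaussians on linear complexity/similarity
axes, eight populations, peak-normalised), applies one of six expectation
modulations

- gain: `f_i(j) = c(i,j) · g(x_j; μ_i, σ)`
- tuning: `f_i(j) = g(x_j; μ_i, c(i,j) · σ)`

with distance profiles `c = min(1, a + |d/b|(1−a))` (local),
`max(a, 1 − |d/b|(1−a))` (remote) or `a` (global), forms voxels by biased
sampling of populations, adds Gaussian noise calibrated to a target decoding
accuracy, computes seven outcome metrics (mean amplitude modulation; within-
and between-class correlations against a localizer; classification
performance; amplitude modulation by voxel amplitude and selectivity; image
preference), and compares simulated to empirical results by sign matching
and a grand-median-scaled, reliability-weighted MSE over a parameter grid
(`a`, `b`, `σ`; 7820 combinations per local/remote family by default),
filtered by three biological-plausibility criteria. RSA utilities
(Gabor orientation energy, shape-complexity PCA, 1-D MDS, partial Spearman,
Mantel tests) validate the one-dimensional feature spaces.

## Worked example: recovering a known modulation

Generate pseudo-empirical data from a known dampening model and ask the grid
search which of the six families explains them:

```r
library(esfm)
sp   <- feature_space("circular")        # orientation axis, period pi
des  <- design_6x6()                     # 240 trials, 50% reliability
grid <- build_grid(sigma = c(0.3, 0.5, 0.8), a = seq(0.2, 0.9, 0.1),
                   b = c(0.1, 0.3, 0.5, 0.8, 1.2, 1.7, 2.3))
stim <- make_synthetic_stimuli(6, sp, seed = 1)

truth <- modulation_model("gain", "local", a = 0.6, b = 0.5)  # dampening
rec <- run_recovery(truth, sigma_truth = 0.5, sp, des,
                    positions = stim$position, grid = grid,
                    target_accuracy = 0.4, n_truth_participants = 20,
                    n_participants = 10, n_repetitions = 2, seed = 1)
rec
#> <esfm_recovery> truth: local gain (a = 0.6, b = 0.5, sigma = 0.5)
#>   winner: local gain [recovered]
#>   best parameters of the generating family: a = 0.7, b = 1.2, sigma = 0.8
summary(rec$fit)
#> Model ranking (weighted MSE against the empirical summary):
#>          family n_plausible top_k best_mse mean_top   ci_lo   ci_hi best_sign_matches
#> 1   global gain          24     1  0.14711   0.1471 0.11419 0.18335                 7
#> 2    local gain         168     3  0.07655   0.0900 0.05761 0.09609                 7
#> 3   remote gain         168     3  0.15559   0.1769 0.11951 0.19473                 7
#> 4 global tuning          24     1  0.45005   0.4501 0.35412 0.55881                 5
#> 5  local tuning         168     3  0.16200   0.2182 0.12562 0.20353                 5
#> 6 remote tuning         168     3  0.45462   0.4771 0.35665 0.55616                 5
#> winner: local gain (entire top set beats all competitors)
```

The generating dampening family attains the lowest weighted MSE (0.077),
beats the sharpening account (0.156) across its entire top set (bootstrap
95% CIs across simulated participants shown), and — note `best_sign_matches`
— three different families can match the *sign* of all seven outcome
metrics, which is exactly why the quantitative comparison is needed. The
plausibility screen itself is data-free:

```r
rejection_rates(plausibility_table(feature_space("circular")))$per_family
#>   global gain global tuning    local gain  local tuning   remote gain remote tuning
#>         10.00          4.12          0.20          0.68          1.97          2.39
```

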