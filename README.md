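# cinerecon

Reconstruction of undersampled **dynamic cardiac cine MRI** with a learned
cardiac-motion dictionary: a predictive signal model that lets a Kalman
filter or a compressed-sensing solver track the beating heart *without*
assuming a periodic rhythm, so that arrhythmic events and heart-rate changes
survive reconstruction instead of being averaged away by conventional CINE
rebinning. The package is aimed at MRI reconstruction researchers who want a
self-contained, fully testable implementation — every experiment runs on a
built-in contracting-heart phantom, no clinical data required.

## The model

A single fully sampled cardiac cycle of `T` frames (`N x N`, complex) is the
training scan. Treating each pixel as a wide-sense-stationary temporal
process, the per-lag covariance matrices

```
C_l[(i,j),(p,q)] = (1/T) * sum_t (B(i,j,t+l) - mu_ij) * conj(B(p,q,t) - mu_pq)
```

(circular in `t`, `l = 0 ... T-1`, with `C_{-l} = C_l^H`) define an LMMSE
(Wiener) affine transition between any two cardiac phases:

```
x_t = f_t x_{t-1} + b_t,    f_t = C_l pinv(C_0),    b_t = mu - f_t mu
```

where `l` is the signed phase difference — negative lags step backwards in
time, which is how a single training cycle models the jump from phase T to
phase 1 of the next heartbeat, or an arrhythmic early return to systole.

Two reconstruction frameworks consume the dictionary:

* **Two-stage Kalman filter** — stage one predicts the next frame from the
  dictionary; stage two updates the prediction with the acquired k-space
  through the gain `K = P F^H E^H (E F P F^H E^H + R)^+`, with process
  covariance `Q = diag(C_0)`. A random-walk baseline (`f = I`,
  difference-image `Q`) is included for comparison.
* **Two-stage compressed sensing** — nonlinear conjugate gradient on
  `||HX - y||^2 + lambda_spar * TTV(X) + lambda_ss * sum_m ||f_m X_{m-1} + b_m - X_m||^2`,
  where the last term keeps the reconstruction consistent with the signal
  model; `lambda_ss = 0` recovers conventional temporal-total-variation CS.

When the test scan has `V` times the temporal resolution of the training
scan, sub-step transitions are derived by assuming intermediate frames fall
linearly between dictionary anchors, giving a per-fine-step affine map from
`f_V`, `b_V` alone.

Measurement operators cover Cartesian phase-encode masks, golden-angle
radial and Archimedean spiral trajectories; non-Cartesian sampling uses
apodization-free bilinear gridding whose adjoint is the exact conjugate
transpose (no density compensation).

## Worked example

A single arrhythmic heartbeat (early return to systole after phase 12 of
20) reconstructed from 5-spoke golden-angle radial k-space at N = 32:

```r
library(cinerecon)
cfg <- list(
  phantom  = list(N = 32, T = 20, seed_train = 1, seed_test = 2),
  scenario = list(kind = "arrhythmia", n_cycles = 3, truncate_at_phase = 12),
  sampling = list(kind = "radial", n_spokes = 5, noise_sigma = 0.02, seed = 7),
  recon    = list(variants = list("two_stage", "random_walk")))
res <- run_experiment(cfg)
print(res$summary, digits = 3)
#>       variant mean_mse  max_mse median_mse    verdict acceleration
#> 1   two_stage 0.000214 0.000323   0.000211 convergent         10.1
#> 2 random_walk 0.000705 0.002145   0.000584 convergent         10.1
print(res$reports$two_stage)
#> <convergence_report> convergent (slope -2.79e-11, p 0.999)
#> per-cycle mean MSE: 0.0002086 0.000226
```

The two-stage filter tracks the arrhythmia with ~3x lower mean squared
error than the random-walk baseline; both MSE traces are stationary
("convergent" by the variance-trend diagnostic), and the acceleration
estimate `pi*N / (2*n_spokes) = 10.1` is reported alongside. Per-frame MSE
traces and reconstructed series are in `res$results`; pass an `out_dir` to
write CSV/JSON artifacts.

A command-line front end with `simulate` / `train` / `recon-kf` /
`recon-cs` / `report` subcommands lives at `inst/cli/cinerecon.R`; a ready
arrhythmia configuration ships in `inst/extdata/configs/`.

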