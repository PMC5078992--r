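# sptdiff

Single-particle-tracking (sptPALM) diffusion analysis for membrane proteins
on rod-shaped bacteria, with a matched Monte Carlo track simulator.

Typical use case: a peptidoglycan synthase (or any membrane protein) is
tracked molecule-by-molecule under TIRF illumination at tens of
milliseconds per frame. Tracks are short (a handful of points before
photobleaching or exit from the evanescent field), so per-molecule fitting
is hopeless and the information lives in ensemble statistics. `sptdiff`
provides the standard ensemble toolkit:

- **Ensemble MSD and apparent diffusion constant.** The mean-squared
  displacement per lag is the per-track mean over all overlapping frame
  pairs, averaged over tracks (tracks are the independent units, so the
  s.e.m. over tracks is well defined). The apparent diffusion constant is
  `D_app = slope/4` of an OLS line through the first four MSD points; the
  free intercept absorbs the localization-error offset `4σ²`. Uncertainty
  comes from bootstrap resampling of tracks; condition differences are
  tested with a track-label permutation test.
- **Step-size (jump-distance) CDF mixture fit.** For free 2D diffusion the
  squared displacement over a lag `t` is exponential with mean
  `4Dt + 4σ²`, so the step-size CDF is `P(r² ≤ x) = 1 − exp(−x/(4Dt + 4σ²))`.
  Empirical CDFs at lags of 1–4 frames (30, 60, 90, 120 ms at the default
  frame interval) are fit *jointly* by one parameter vector — pooling lags
  is what separates `D` (scales with `t`) from `σ` (does not) — to a
  one-species model `{D, σ}` or a two-species mixture
  `{D₁, D₂, α, σ}` where `α` is the mobile fraction carried by the fast
  constant `D₁`. Models are compared by BIC (from the exponential-mixture
  likelihood of the steps) with a nested F-test as a secondary diagnostic.
- **A generative simulator** of the observation process: Brownian motion on
  a cylindrical membrane lying on the coverslip, two-state fast/slow
  switching (continuous-time Markov chain, or a static mixture), visibility
  restricted to a TIRF window of ~100–150 nm above the coverslip,
  projection to the image plane, i.i.d. Gaussian localization noise,
  geometric photobleaching, and the 4–12-point track-length filter. It is
  the test bed for every estimator above and quantifies, e.g., how small
  the cell-curvature correction to the in-plane MSD is (<10% at lag 1 for a
  0.5-µm-radius cell and a 125-nm window).

## Worked example

Simulate a static 60/40 mixture of mobile (`D₁ = 0.05 µm²/s`) and immobile
molecules with 30-nm localization error, then run the full analysis:

```r
library(sptdiff)

cfg <- simulation_config(
  geometry = cell_geometry(radius = 0.5, length = 50, tirf_depth = 1),
  model = diffusion_model(d_fast = 0.05, d_slow = 0, alpha = 0.6,
                          sigma_loc = 0.03,
                          rate_fast_to_slow = 0, rate_slow_to_fast = 0),
  n_molecules = 3000, n_frames_max = 14, mixture_mode = "static",
  observe = "surface", seed = 42)
sim    <- simulate_tracks(cfg)
tracks <- filter_by_length(sim$tracks, 4, 12)

est <- bootstrap_diffusion(tracks, n_boot = 1000, seed = 42)
#> <diffusion_estimate> d_app = 0.02762 um^2/s (intercept 0.00391 um^2,
#>   bootstrap SD 0.00115 over 1000 resamples), 1817 tracks

steps <- collect_step_sizes(tracks, lags = 1:4)
fit2  <- fit_cdf(steps, "two_species")
#> <cdf_fit two_species> D1 = 0.04824, D2 = 0 um^2/s, alpha = 0.587,
#>   sigma = 0.03027 um
compare_models(fit_cdf(steps, "one_species"), fit2)$chosen
#> "two_species"
```

Read the numbers the way an experimentalist would: the *apparent* ensemble
diffusion constant is `α·D₁ ≈ 0.6 × 0.05 ≈ 0.028 µm²/s` (the MSD fit says
0.0276 ± 0.0012) and its intercept `0.0039 µm²` is the `4σ² = 0.0036 µm²`
noise floor. The CDF decomposition recovers the generative truth: a mobile
fraction of 0.59 moving at 0.048 µm²/s, an immobile species
indistinguishable from zero, and `σ = 30 nm`.

## Command line

```sh
./exec/sptdiff simulate --config sim.json --out tracks.csv --truth truth.csv
./exec/sptdiff msd --tracks tracks.csv --seed 1 --out msd.json
./exec/sptdiff fit-cdf --tracks tracks.csv --out fit.json
./exec/sptdiff report --config run.json --out outdir
./exec/sptdiff compare --config-a a.json --config-b b.json --out outdir
```

Configs are JSON or YAML; a seed is mandatory wherever randomness enters.
Exit codes: 0 success, 2 validation failure, 3 convergence failure. Track
tables are plain CSV (`track_id,condition,frame,x_um,y_um`, 6-decimal µm,
0-based frames) with a `<name>.meta.json` sidecar for the frame interval
and provenance.

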