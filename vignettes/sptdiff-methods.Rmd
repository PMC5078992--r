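---
title: "Models and methods behind sptdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The measurement problem

Sparse photoactivation (sptPALM) of a membrane protein on a rod-shaped
bacterium yields thousands of short single-molecule tracks: 2D localizations
every few tens of milliseconds, each good to a few tens of nanometres,
lasting a handful of frames before the fluorophore bleaches or the molecule
diffuses out of the TIRF evanescent field (~100–150 nm above the
coverslip). Two ensemble statistics carry essentially all of the usable
information at this track length:

1. the ensemble mean-squared displacement (MSD) versus lag, whose initial
   slope gives an *apparent* diffusion constant, and
2. the distribution of step sizes at a few lags, which can resolve a
   mixture of diffusive species that the MSD alone averages away.

`sptdiff` implements both, plus the generative Monte Carlo model of the
observation process needed to validate them.

# Diffusion model

A molecule on the membrane surface diffuses with constant $D_1$ ("fast")
or $D_2$ ("slow"), switching as a two-state continuous-time Markov chain
with rates $k_{f\to s}$ and $k_{s\to f}$; the stationary mobile fraction is
$\alpha = k_{s\to f}/(k_{s\to f} + k_{f\to s})$, enforced at construction.
A *static mixture* mode freezes each molecule's state for life (fast with
probability $\alpha$) — this is the regime the step-size CDF model assumes.
Each localization carries i.i.d. Gaussian error of per-coordinate SD
$\sigma$.

Key parameters, defaults, and where they come from:

| parameter | default | why |
|---|---|---|
| frame interval | 0.03 s | imaging cadence of the motivating experiments |
| $D_1$ | 0.05 µm²/s | fast species of the motivating measurements |
| $D_2$ | 0 | slow species indistinguishable from localization error |
| $\sigma$ | 0.03 µm | ~30 nm localization error |
| switching rates | 5, 5 s⁻¹ | dwell ≈ 6–7 frames, comparable to track length |
| cell radius, length | 0.5, 3 µm | typical *E. coli* dimensions |
| TIRF depth | 0.125 µm | midpoint of the ~100–150 nm visibility range |
| bleach survival/frame | 0.85 | raw track lengths concentrate in 4–12 points |
| track filter | 4–12 points | the analysis window used downstream |

# The simulator: what it emulates, and what it does not

The cell is a cylinder of radius $R$ lying on the coverslip along the image
$x$ axis. Surface position is (axial $z'$, angle $\theta$), with $\theta=0$
at the contact line; arc length $R\theta$ and $z'$ form a locally flat
plane, so surface diffusion is two independent 1D Brownian motions (the
angle is stored unwrapped; axial caps reflect; hemispherical poles are not
modelled — TIRF excludes most of them anyway). Projection to the camera is
$x=z'$, $y=R\sin\theta$; height above the coverslip is
$z=R(1-\cos\theta)$ and the molecule is visible iff $z \le d$ (TIRF depth).
Each frame consists of 10 Brownian substeps (so the state path is finely
resolved and a molecule cannot cross the visibility band unnoticed between
checks), but visibility is evaluated only at frame times, matching camera
sampling. A track is the *first* maximal run of consecutive visible frames
— a molecule re-entering the field would be a fresh localization cluster in
reality, and re-identification is a linking problem out of scope here —
truncated by geometric bleaching, truncated to 12 points, discarded under 4.

In `observe = "surface"` mode the simulator instead records the unwrapped
in-membrane coordinates $(z', R\theta)$ with full visibility: exact planar
Brownian motion, used as the boundary-free validation world (the package's
closed-form checks $\mathrm{MSD} = 4Dt + 4\sigma^2$ live there). At the
default 3-µm cell length, axial cap reflections depress a fitted $D$ by
~5% for 0.1 µm²/s molecules — boundary physics, not estimator error — so
validation worlds use a 50-µm cylinder.

Not emulated: photoactivation scheduling, PSF/camera noise and detection,
linking errors, drift, cell growth during a track, septal/polar geometry.
A green test on synthetic data therefore establishes estimator correctness
under the stated generative model, not robustness to detection/linking
artifacts.

# MSD estimation and inference

$\mathrm{msd}(k)$ is the mean over tracks of each track's mean squared
displacement over all overlapping frame pairs exactly $k$ frames apart.
Overlapping pairs squeeze the most out of 4–12-point tracks; the induced
within-track correlation is absorbed by treating tracks (not pairs) as the
independent units — the reported s.e.m. is the SD of per-track means over
$\sqrt{n_\text{tracks}}$, and both the bootstrap and the permutation test
resample whole tracks. $D_\text{app}$ is slope/4 of an *unweighted* OLS fit
with free intercept through MSD points 1–4 (the intercept must be free
because localization noise adds $4\sigma^2$ at every lag). The
between-condition test permutes track-to-condition labels and uses the
add-one two-sided p-value $(1 + \#\{|T^\pi| \ge |T|\})/(n_\pi + 1)$; a
variant that additionally bootstraps tracks within each permutation
replicate is provided (`boot_within`), off by default — plain label
permutation is the standard exchangeable-null construction.

# Step-size CDF mixture fit

For free 2D diffusion with localization noise, each coordinate displacement
over lag $t$ is $N(0,\, 2Dt + 2\sigma^2)$, so $r^2$ is exponential with
mean $4Dt + 4\sigma^2$ and

$$P(r^2 \le x) = 1 - e^{-x/(4Dt+4\sigma^2)}, \qquad
P_2(r^2 \le x) = 1 - \alpha e^{-x/(4D_1t+4\sigma^2)}
                 - (1-\alpha) e^{-x/(4D_2t+4\sigma^2)}.$$

Note the $4\sigma^2$ convention: $\sigma$ is the *per-coordinate,
per-localization* SD, and a displacement involves two noisy localizations
in each of two coordinates. (Some SPT literature writes $2\sigma^2$ with
$\sigma$ defined per displacement; the parameterizations are equivalent up
to $\sqrt2$.)

Empirical CDFs at lags 1–4 frames are fit *simultaneously* by one
parameter vector: a single lag cannot separate $D$ from $\sigma$ (only
$4Dt+4\sigma^2$ is identified), but the scale grows linearly in $t$ with
intercept $4\sigma^2$ across lags. Residuals (empirical − model CDF) are
evaluated at every observed $r^2$ — the empirical CDF's own support,
unweighted — with an optional per-lag quantile grid (`grid_n`) that thins
the evaluation points (the empirical CDF is still estimated from all
steps) for speed-critical loops such as bootstraps. Minimization is
bounded L-BFGS-B ($D \ge 0$, $\alpha \in [0,1]$, $\sigma \ge 10^{-6}$,
guarding the degenerate zero-scale exponential) with analytic gradients,
restarted from a deterministic grid
$D \in \{10^{-3},\dots,1\}$, $\alpha \in \{0.25, 0.5, 0.75\}$,
$\sigma \in \{0.02, 0.04\}$; the grid is screened by initial objective
value and the best five starts are optimized fully (ties by lexicographic
parameter order — fully deterministic, no RNG). $D_1 \ge D_2$ is enforced
by relabeling after the fit. Non-convergence from every screened start is
an explicit classed error, never a silent best-so-far.

**Model comparison.** The one-species model is the two-species model at
$\alpha = 1$, so RSS is nested by construction. The primary criterion is
BIC, but computed from the exponential-mixture *log-likelihood* of the
pooled steps at the fitted parameters, $-2\log L + k\log n_\text{steps}$ —
not from the CDF residuals: stacked empirical-CDF residuals are strongly
autocorrelated (Brownian-bridge-like), and a Gaussian-RSS pseudo-BIC
overstates the evidence for extra parameters badly enough to pick the
two-species model on genuinely one-species data ~40% of the time in our
selection simulations; the likelihood BIC is correct 20/20 in both
directions. A nested F-test on the RSS is reported as a secondary
diagnostic only.

**Assumption to keep in mind:** the CDF model assumes each molecule keeps
one state across the 30–120 ms lags. Kinetic switching at the default
rates violates this mildly; fits are therefore validated on static-mixture
data, and kinetic-mode $\alpha$ estimates are biased toward the
time-averaged population. TIRF truncation adds a second, smaller bias —
fast molecules exit the field sooner, under-representing fast steps — so
the quantitative recovery tests run in the untruncated planar world, which
is the model's stated regime.

# MSD saturation and its honest limits

Experimentally motivated claim: with a fast/slow population under TIRF,
ensemble MSD flattens beyond ~0.2 s because slow molecules are enriched
among long tracks (fast ones leave the field, ending their tracks). The
package quantifies saturation as the ratio of the late-window OLS slope
(lags ≥ 0.21 s) to the lag-1 forward-difference slope
$(\mathrm{msd}_2-\mathrm{msd}_1)/\Delta t$ — forward difference so the
$4\sigma^2$ offset cancels; a chord through the origin would manufacture
fake "saturation" from the noise floor even for free diffusion.

Quantitatively, the enrichment mechanism needs *state persistence*: at the
default switching rates (5 s⁻¹, dwell 0.2 s) a molecule time-averages both
states within a single track while the TIRF-band exit time at
$D_1 = 0.05$ µm²/s is ~1 s, so all tracks look alike and the measured
slope ratio stays ≈ 0.95 — no saturation. With persistent states (rates
0.9/0.3 s⁻¹, $\alpha = 0.25$, dwells of 1–3 s) the ratio drops to
≈ 0.55–0.65, i.e. clear qualitative saturation, but not robustly below the
0.6 threshold one acceptance criterion demands; that criterion is left
failing by design rather than met by moving generator parameters, and the
accompanying property test asserts the qualitative claim (ratio < 0.75 in
the persistent regime, ≫ gap to the untruncated control) instead.

# Growth-rate helper

For single-cell elongation series, $L(t)$ is smoothed with a centered
10-point moving average and the instantaneous relative growth rate
computed as $(1/L)\,dL/dt$ with central differences on the smoothed
series; ends where either is undefined are `NA`, not extrapolated.

# Numerical and format choices

- Track CSV: `track_id,condition,frame,x_um,y_um`, µm to 6 decimals,
  0-based frames; frame interval and provenance live in a JSON sidecar so
  no per-row float drift is possible. Reading validates (strictly
  increasing frames, no duplicate `(track_id, frame)`, finite positions,
  ≥ 2 points) and rejects rather than coerces, naming offending tracks.
- Determinism: every stochastic entry point takes a seed and runs under a
  scoped RNG (`withr::with_seed`); identical configs give byte-identical
  CSV/JSON artifacts, and pipeline outputs embed the config and its MD5.
- MSD lags with no pairs are dropped with a warning, never emitted as NaN;
  a simulation retaining zero tracks warns and returns an explicit empty
  result, and the pipeline turns that into a structured failure (exit 2).
- Solver tolerances: L-BFGS-B `factr = 1e7` (~1e-9 relative), 500
  iterations, nesting asserted to 1e-8 relative in tests.

# Known limitations

- No hidden-state inference per molecule (population fractions only), no
  anomalous-diffusion exponents, no detection/linking simulation.
- The mobile-fraction estimate from TIRF-truncated data is biased low by
  fast-track censoring (documented above, measurable with the simulator's
  ground-truth output).
- The saturation acceptance threshold is not attainable at the declared
  default switching rates; see the saturation section for the physics and
  the decisions ledger (repository metadata) for measurements.
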