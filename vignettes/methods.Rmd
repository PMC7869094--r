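---
title: "Models and methods: from tone clouds to effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from tone clouds to effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfgdcm)
```

`sfgdcm` implements an analysis chain that links behavioral difficulty in
two auditory tasks — figure-ground detection in tone clouds and
speech-in-noise (SPIN) comprehension — to changes in directed (effective)
connectivity among subregions of auditory cortex.  This vignette explains
each model in the chain, the assumptions behind it, the tunable parameters
and their defaults, and the design choices made where several reasonable
implementations exist.  Nothing stated here goes beyond what the package's
tests and `scripts/acceptance.R` actually compute.

## 1. Stochastic figure-ground stimuli

A stimulus is a sequence of 62 abutting 50-ms chords (3100 ms total), each
gated by 10-ms raised-cosine ramps.  Chord tones are drawn from a
logarithmic grid of 129 frequencies between 179 and 7246 Hz at 1/24-octave
spacing.  Every chord holds 5–15 background tones redrawn independently per
chord; a *figure* of 3 fixed frequencies (drawn once per trial, without
replacement) is added to chords 10–51 (0-based; onset 500 ms, duration
2100 ms).  A 4-chord (200-ms) gap is placed uniformly at chords 20–42,
clipped so it ends inside the figure: in the gap-in-figure condition the
figure tones are omitted there; otherwise 3 randomly chosen background
tones are removed from each gap chord, so both conditions lose exactly 12
tone slots and differ only in *where* coherence is interrupted.

Choices the stimulus description leaves open:

* **Figure tones add to the background count** rather than replacing
  background tones; figure and background frequencies may coincide, so the
  figure is not detectable by spectral separation.
* **TMR referent.**  The target-to-masker ratio is applied as the RMS ratio
  of the summed figure render to the summed background render over the
  whole stimulus, with equal per-tone amplitude within each class.
* Background tones within a chord are drawn without replacement (the grid
  has 129 entries, so collisions would otherwise double tone amplitudes).

`synthesize_waveform()` renders at 44.1 kHz by default and refuses sample
rates below the Nyquist limit of the grid; `write_wav()`/`read_wav()`
round-trip 16-bit PCM.

## 2. Adaptive psychophysics

Thresholds are estimated with a weighted up-down staircase: the TMR rises
by the base step after an incorrect response and falls by `base/ratio`
after a correct one, so the track equilibrates where
$p(\text{correct}) = R/(R+1)$ — 0.90 for the 9:1 preset.  The base step
starts at 1 dB, halves to 0.5 dB after the 3rd reversal, and the track
stops after 10 reversals; a run's threshold is the median of its last 6
reversal TMRs, and a block averages two interleaved runs.

Two readings of "step-size ratio 9:1" exist: base step = down-step (up
jumps of 9 dB) or base step = up-step (down steps of 1/9 dB).  Simulation
shows the first biases the reversal median upward by roughly half an
up-jump (~+1.5 dB, i.e., the recovered point sits near 96% correct), while
the second recovers the 90% point to within a few tenths of a dB.  Since
the procedure exists to estimate 90% thresholds, the package uses the
second convention.

Finite tracks also carry a transient: starting at 0 dB, the recovered
threshold is accurate when the observer's 90% point lies within about
±1 dB of the start (measured 89–91% correct at the recovered point) and
degrades as the true threshold moves away (≈86% at 2.4 dB away).  This is
why the simulated-observer checks place the observer's 90% point near
0 dB — the same logic by which the experimental procedure starts tracks at
the expected threshold range.

The simulated listener is a logistic observer,
$p(c \mid x) = \gamma + (1-\gamma-\lambda)\,\sigma(s(x - \theta))$ with
guess rate $\gamma = 0$, lapse $\lambda = 0.02$ and slope $s = 1$/dB by
default.  In-scanner yes/no behavior is summarized by $d' = z(H) - z(F)$
and criterion $c = -(z(H)+z(F))/2$ with the loglinear correction (+0.5 per
cell, +1 per total), which keeps both finite at perfect performance.
Threshold correlations across subjects use Spearman's rank coefficient
with a Fisher-z interval (SE $1/\sqrt{n-3}$); the interval method is a
package choice.

## 3. The generative model of sparse-sampled BOLD

Neural dynamics of $n$ regions follow the bilinear form
$$\dot z = \bar A(u)\, z + C u,$$
where off-diagonal entries of $\bar A(u)$ are $A_{ik} + \sum_j u_j
B^{(j)}_{ik}$ (extrinsic coupling, Hz) and diagonal entries are
parameterized as log-scalings of a $-0.5$ Hz baseline,
$-0.5\,\exp(a_{ii} + \sum_j u_j b^{(j)}_{ii})$.  Self-connections therefore
stay negative for any input, and a *negative* modulation value means
disinhibition: slower decay, higher regional gain.

Four inputs are built from the event table: *all trials*, *task* (±½ for
SPIN/figure-ground), *difficulty* (±½ for the 60%/90%-threshold
conditions), and their product (*interaction*).  All four may drive any
region (the `C` matrix); only difficulty and the interaction also modulate
connections (the `B` matrices).  Events enter as boxcars of the stimulus
duration; regressors are piecewise constant on the integration grid, so
onsets snap to it.

Each region's neural state drives a balloon model — vasodilatory signal
$s$, inflow $f$, venous volume $v$, deoxyhemoglobin $q$:
$$\dot s = z - \kappa s - \gamma(f-1),\quad \dot f = s,\quad
\tau \dot v = f - v^{1/\alpha},\quad
\tau \dot q = f\,\frac{1-(1-E_0)^{1/f}}{E_0} - v^{1/\alpha}\frac{q}{v},$$
with canonical constants $\kappa = 0.64\,s^{-1}$, $\gamma = 0.32\,s^{-1}$,
$\tau = 2$ s, $\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$, $\epsilon = 1$.
The BOLD observation is the classical three-compartment equation
$y = V_0\!\left(k_1(1-q) + k_2(1-q/v) + k_3(1-v)\right)$ in percent signal,
with $k_1 = 4.3\,\vartheta_0 E_0 T_E$, $k_2 = \epsilon r_0 E_0 T_E$,
$k_3 = 1-\epsilon$, $\vartheta_0 = 40.3$ Hz, $r_0 = 25$ Hz and echo time
$T_E = 30$ ms (3-T values; the data source does not pin $T_E$, so it is a
documented constant).

Integration uses fixed-step 4th-order Runge–Kutta (default `dt = 0.05` s;
any step up to 0.1 s is accepted) with the hemodynamic states carried in
log space so positivity is structural.  The integrator is compiled (Rcpp)
because the inversion differentiates through it; a pure-R reference
implementation (`engine = "r"`) is kept for cross-checks, and step-halving
agreement at $10^{-4}$ relative error is part of the test suite.  Each run
restarts from rest, and the predicted signal is read out only at the
sparse acquisition times (one volume per 8-s trial, acquisition starting
4.64 s into the trial, TR 3.36 s) — the model predicts the unobserved
moments too, but only the sampled ones enter the likelihood.

## 4. Subject-level inversion: variational Laplace

`variational_laplace()` maximizes the free energy
$$F = \mathbb E_q[\log p(y\mid\theta)] - \mathrm{KL}(q \,\|\, p)$$
over a Gaussian $q(\theta)$ by Gauss–Newton ascent with
Levenberg–Marquardt regularization, alternating with Newton updates of
per-region noise log-precisions.  Jacobians come from finite differences
on the integrator (step $10^{-4}$; central by default, one-sided optionally
at half the cost).  Iterations stop when $|\Delta F| < 0.01$ nats three
times in a row, when no damped step improves $F$ (a regularized optimum),
or after `max_iter`.  On linear-Gaussian problems with fixed noise the
scheme reproduces the conjugate posterior to $10^{-6}$ and the exact log
evidence to $10^{-4}$ (because the expected-log-likelihood trace correction
is included); these equivalences are asserted in the tests.

Priors (all zero-mean Gaussians) are arguments of `dcm_priors()`:
extrinsic $A$ entries $N(0, 1/64)$; self log-scalings $N(0, 1/256)$;
driving weights $N(0, 1)$; hemodynamic log-scalings of $\tau$ and $\kappa$
$N(0, 1/256)$; modulations $N(0, 1/4)$.  The modulation variance deserves
a note: a prior SD of 0.5 makes self-modulations of the size this analysis
is about (≈0.5 in magnitude) about one prior SD, where a variance of 1/16
would shrink subject-level estimates to roughly 40% of their generating
values and starve the group model of evidence.  Noise log-precisions get a
weakly informative $N(0, 16)$ prior — BOLD residual SDs here are of order
0.1–0.3%, so precisions span orders of magnitude and a tight prior at
precision 1 would misweight the likelihood.  Run intercepts and motion
covariates are projected out of data and prediction alike before the
likelihood is formed.

## 5. Group inference: PEB, model reduction, averaging

The selected first-level parameters (by default every modulation entry)
enter a hierarchical model: subject $s$'s posterior mean is treated as a
noisy observation of $X_s\beta$ with covariance $C_s + \gamma I$, where
$X$ holds the group mean and the four per-condition TMR covariates
(mean-centered so the intercept stays the group mean), and $\gamma$ is the
between-subject variance, MAP-estimated on its log scale under an
$N(0, 16)$ prior.  Conditional on $\gamma$, the group posterior and model
evidence are closed-form.

Bayesian model reduction then scores nested models analytically: switching
a group parameter "off" replaces its prior with a near-delta at zero
(variance $10^{-8}$), and the reduced posterior and evidence change follow
from Gaussian algebra — verified in the tests against direct re-inversion
under the reduced prior to $10^{-6}$.  The greedy search starts from the
full model, repeatedly removes the single parameter whose removal raises
the evidence most (rank-one updates keep each sweep cheap), and stops when
no single removal helps.  It then takes the 8 candidates with the smallest
absolute single-parameter evidence contribution in the full model — the
least decisive ones — and scores all $2^8 = 256$ on/off combinations.  How
the terminal 8 are selected is an implementation choice; this rule is
deterministic and guarantees the enumeration covers exactly the parameters
the data cannot decide.  Model averaging weights the 256 models by the
softmax of their free energies, accumulates Gaussian mixture moments, and
reports per-parameter posterior probabilities $P_p$ (the summed weight of
models in which the parameter is on).  Parameters with $P_p \ge 0.95$ are
retained.

## 6. The synthetic experiment

The generator emulates the statistical structure the analysis assumes:

* **Design**: 8 runs × 24 trials (6 per condition, shuffled per run),
  8-s trials, TR 3.36 s, 4.64-s silent gap, stimulus onsets jittered
  uniformly 0.4–2.4 s after the previous scan ends.
* **Thresholds**: per-subject TMRs for SFG-60/90 and SPIN-60/90 from a
  Gaussian copula with rank correlations 0.55 within task and 0.35 between
  tasks (converted to Pearson correlations via $2\sin(\pi r_s/6)$), means
  (−4, 0, −8, −4) dB and SD 2 dB; rare draws violating the 90-above-60
  ordering (or with gaps under 0.5 dB, which would give degenerate
  psychometric slopes) are redrawn.  Observers are constructed to pass
  exactly through (60%, 90%) at their thresholds.
* **Connectivity ground truth**: a within-hemisphere hierarchy (core →
  belt → higher cortex at 0.2 Hz bottom-up, 0.1 Hz top-down), driving
  input (0.4) to core during trials, difficulty-induced disinhibition of
  left core (−0.47) and left posteromedial belt (−0.51), *no* interaction
  modulations, and between-subject SD 0.1 on the nonzero entries only —
  zeros stay zero so sparsity recovery is well-posed.  With these values
  the simulated responses peak at 2–4% signal change.
* **Noise**: white Gaussian per region with SD = signal SD / SNR
  (default SNR 2); sparse sampling justifies the independence assumption.
  Motion covariates are smooth low-amplitude nuisance series added to the
  design, not the signal.

All randomness flows from one master seed through per-subject substreams,
and regenerating with the same configuration is bit-identical — asserted
in the tests.

What the generator does **not** emulate: structured physiological noise,
scanner drift, between-region noise correlations, hemodynamic variability
beyond $\tau$/$\kappa$, and any acoustic linkage between the stimulus
waveforms and the neural drive (conditions enter only as design labels and
TMR covariates).  Passing tests therefore show that the estimator chain is
correct and well-calibrated under its own assumptions — not that those
assumptions hold in real fMRI data.

## 7. Problem sizes and observed behavior

The simulation studies in the test suite and the acceptance script run at
desk scale, chosen once:

* Group recovery: 10 seeded groups of 8 subjects, SNR 2, the full 8-run
  session, a 4-region left-hemisphere network with intrinsic-only
  modulation masks, generation at `dt = 0.05` s and inversion at
  `dt = 0.1` s with one-sided Jacobians.  Across exploratory seeds the two
  left intrinsic difficulty modulations are retained at $P_p \ge 0.95$ in
  the large majority of runs, interaction modulations are pruned in nearly
  all, and retained modulations are negative (disinhibition).  A known
  failure mode at this scale: a downstream region occasionally absorbs
  propagated gain as a spurious intrinsic modulation.
* The terminal-enumeration count (256) uses the full 8-region network,
  8 subjects and a single run — the count is structural and does not
  depend on fit quality.
* Subject-level recovery correlation between posterior means and
  generating modulations, pooled over seeds, measures ≈0.8 at SNR 4; it
  is limited by a genuine degeneracy of the specified model — a direct
  difficulty input to a driven node mimics most of an intrinsic gain
  modulation at that node.

## 8. Known limitations

* Identifiability of gain modulation versus direct drive (above) at small
  $n$; the full study scale (44 subjects) pools much more evidence.
* The greedy search is a local procedure; the terminal 256-model
  enumeration is a documented heuristic, not an exhaustive model search.
* The hemodynamic constants are fixed at canonical 3-T values except for
  $\tau$ and $\kappa$; systematic hemodynamic differences between regions
  would be absorbed by those two parameters only.
* The 6:1 staircase preset equilibrates at $6/7 \approx 86\%$ correct, not
  at 60%; the ratio is exposed as a free parameter and no 6:1 → 60%
  mapping is asserted.
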