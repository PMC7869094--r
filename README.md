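# sfgdcm

Effective-connectivity analysis of auditory figure-ground and
speech-in-noise difficulty, as a reusable, fully simulatable R package.

People who struggle to follow speech in background noise also tend to
struggle with a much more basic task: detecting a "figure" of
fixed-frequency tones repeating inside a random tone cloud.  One candidate
explanation is that both tasks lean on the same early cortical grouping
machinery, and that when either task gets harder, early auditory cortex
*disinhibits* — its self-connections weaken, raising regional gain.
`sfgdcm` implements the full analysis chain needed to ask that question
quantitatively, plus a synthetic-experiment generator so every stage runs
and is testable without any external data:

* **Stimuli** — stochastic figure-ground tone clouds (62 × 50-ms chords,
  5–15 background tones per chord, a 3-component figure, 4-chord gaps),
  rendered to WAV at a controlled target-to-masker ratio (TMR).
* **Psychophysics** — weighted up-down adaptive staircases (the 9:1 preset
  converges at 90% correct), threshold estimation from reversal medians,
  d′/criterion with the loglinear correction, Spearman correlations with
  Fisher-z intervals.
* **Forward model** — bilinear neural dynamics for 8 auditory regions
  (left/right Te1.0, Te1.1, Te1.2, Te3) coupled to a balloon hemodynamic
  model, integrated by compiled fixed-step RK4 and sampled at the sparse
  acquisition times (one volume per 8-s trial, TR 3.36 s):

  dz/dt = Ā(u) z + C u, with self-connections −0.5·exp(a + Σⱼ uⱼ bⱼ) Hz,

  so negative modulations b mean disinhibition (slower decay, more gain).
* **Inversion** — variational Laplace (Gauss–Newton with
  Levenberg–Marquardt damping on the free energy F = accuracy −
  complexity), exact on linear-Gaussian benchmarks.
* **Group inference** — parametric empirical Bayes over subject-level
  modulations with per-condition TMR covariates, analytic Bayesian model
  reduction, a greedy search that terminates by scoring 256 reduced
  models, Bayesian model averaging, and retention at posterior
  probability Pp ≥ 0.95.
* **First level** — canonical-HRF design matrices for sparse sampling, GLM
  contrasts, principal eigenvariates, canonical variate analysis with
  Fisher's method at the group level.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.

## Worked example

```r
library(sfgdcm)

## one figure-ground stimulus, rendered at -2 dB TMR
stim <- sample_stimulus(sfg_params(), gap_in_figure = TRUE, seed = 1)
stim <- synthesize_waveform(stim, tmr_db = -2)
stim
#> SFG stimulus: 62 chords x 50 ms, figure of 3 components,
#>   gap of 4 chords at chord 21 (in figure), synthesized at TMR -2.0 dB

## the 9:1 staircase recovers the observer's 90% point
obs <- observer(threshold_db = -2.5, slope = 1)
tracks <- simulate_staircase_batch(obs, n_tracks = 1000, step_ratio = 9,
                                   seed = 1)
mean(tracks$threshold_db)                  # -0.07 dB
observer_quantile(obs, 0.9)                # -0.08 dB (true 90% point)
100 * observer_p(obs, mean(tracks$threshold_db))   # 90.1 % correct

## simulate a group and run the whole chain: fit each subject's DCM,
## pool with PEB, prune with Bayesian model reduction, average
res <- simulate_and_recover(seed = 211, regions = dcm_regions(4),
                            n_subjects = 8, n_runs = 8, snr = 2)
head(subset(bma_table(res$bma), covariate == "mean"), 4)
#>   covariate                 parameter strength   Pp
#> 1      mean  B.difficulty.lTe1.1.self   -0.273 1.00
#> 2      mean  B.difficulty.lTe1.0.self   -0.260 1.00
#> 3      mean  B.difficulty.lTe1.2.self   -0.086 0.55
#> 5      mean B.interaction.lTe1.2.self   -0.031 0.38
res$retained
#> "mean:B.difficulty.lTe1.0.self" "mean:B.difficulty.lTe1.1.self"
```

The generator's ground truth puts difficulty-induced disinhibition on the
self-connections of left Te1.0 and left Te1.1 and no task-by-difficulty
interaction anywhere; the chain retains exactly those two modulations at
Pp ≥ 0.95, with negative (disinhibitory) strengths, and prunes the
interaction modulations — the signature the analysis is designed to
detect.  (`strength` is the model-averaged change in the log self-scaling
of the decay rate; estimates at this desk scale are shrunk toward zero
relative to the generating values.)

A full pipeline with file outputs (dataset directory, per-subject
posterior JSONs, a TSV report, logs) is available as
`run_pipeline(pipeline_config(...))` or from the shell via
`inst/cli/sfgdcm.R`.

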