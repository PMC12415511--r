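# probselect

Simulation and model-based analysis of probabilistic feedback learning
in **active** and **observational** (yoked) task variants, aimed at
performance-monitoring research in computational psychiatry — e.g.
comparing clinical groups (OCD, social anxiety, healthy controls) on
choice behavior and on feedback-locked (FRN) and response-locked
(ERN/CRN) single-trial ERP amplitudes.

Such studies chain together many fragile steps: a 400-trial selection
task with probabilistic contingencies, reinforcement-learning model
fitting on held-out phases, win-stay/lose-shift and learning-status
coding, composite-waveform ERP scoring, and trial-level mixed-effects
contrasts. probselect implements every step as a tested, tidyverse-style
function (data frames in, tibbles out) and — crucially — ships a
synthetic-data generator for both behavior and EEG, so the entire
pipeline can be validated end-to-end against known ground truth.

## The models in brief

**Task.** Four 60-trial learning blocks (feedback shown) alternate with
four 30-trial test blocks (no feedback), followed by a 40-trial transfer
phase: 400 trials. Stimulus pairs carry reciprocal win probabilities
A/B = 80/20, C/D = 70/30, E/F = 60/40; wins/losses are worth +20/−10
points. Observational sessions replay a yoked active learner's choices
and outcomes during learning; test and transfer are identical across
variants.

**Learning model.** Values start at Q₀ = 0.5 and update on feedback
r ∈ {0, 1} by a delta rule with valence-specific learning rates,

    Q ← Q + α± (r − Q),   α⁺ for wins, α⁻ for losses,

choices follow a softmax with inverse temperature β, and on
feedback-free choices values either stay put, decay toward Q₀ (rate γ),
or undergo **choice-induced preference change** (CIPC, rate ε):
Q꜀ ← Q꜀ + ε(1 − Q꜀), Qᵤ ← Qᵤ − ε Qᵤ. The likelihood covers valid
test/transfer choices only (comparable across agency variants); models
are compared by BIC = k ln n + 2 NLL. The dual-rate + CIPC variant
(`"dual_cipc"`) is the reference winning model.

**ERP scoring.** After baseline correction and artifact rejection
(±100 μV, flatline < 0.5 μV/100 ms, range > 200 μV/200 ms, steps
> 50 μV), a *condition-unweighted* composite waveform — the equal-weight
mean of the pooled-cluster win and loss grand averages — locates the
component minimum inside an a priori window (FRN 200–350 ms
post-feedback; ERN/CRN 0–100 ms post-response), and single-trial scores
are mean amplitudes in the minimum ± 30 ms, per electrode.

**Statistics.** Deviation coding (−0.5/+0.5), centered continuous
predictors, OCD-referenced group contrasts whose coefficients *are* the
planned contrasts, maximal random effects with a deterministic backoff
(correlations first, then slopes by interaction order, never the
participant intercept), Satterthwaite/Wald inference, and
Benjamini–Hochberg FDR within contrast families.

## Worked example

```r
library(probselect)

# a small cohort: 6 participants per group, two sessions each
spec   <- cohort_spec(n_per_group = c(OCD = 6, HC = 6, SAD = 6))
cohort <- simulate_cohort(spec, task_design(), seed = 7)

# fit the winning RL variant to one active session
p7  <- dplyr::filter(cohort, participant_id == "P007", agency == "active")
fit <- fit_rl(p7, "dual_cipc", n_starts = 10, seed = 1)
fit
#> <rl_fit> dual_cipc | NLL 28.443 | BIC 77.137 | n_ll 158
#> alpha_pos alpha_neg      beta   epsilon
#>    0.0614    0.5568   10.0000    0.1096
```

158 valid test/transfer choices entered the likelihood; β sitting at its
box bound flags a near-deterministic test-phase policy (see the methods
vignette on what held-out-phase likelihoods can and cannot identify).
`extract_latents(fit, p7)` returns per-trial Q values, signed and
unsigned prediction errors and ΔQ for ERP regressions.

```r
# score synthetic feedback-locked epochs with the composite procedure
gen    <- erp_gen_model(valence_effect = -3, noise_sd = 6)
active <- dplyr::filter(cohort, agency == "active")
epochs <- generate_epochs(active, gen, seed = 11) |>
  baseline_correct() |> qc_epochs()
win <- find_peak_window(composite_waveform(epochs), search = c(200, 350))
win
#> <scoring_window> peak 262 ms, extraction 232..292 ms

# trial-level mixed model on the single-trial scores
dat <- code_predictors(score_trials(epochs, win))
m <- fit_mixed(amplitude ~ group_HC + group_SAD + valence_dev +
                 (1 + valence_dev | participant_id) + (1 | electrode),
               dat, family = "gaussian")
planned_contrasts(m, terms = c("group_HC", "group_SAD", "valence_dev"))
#> # A tibble: 3 × 9
#>   term      estimate std.error conf.low conf.high     df statistic p.value p.adj
#> 1 group_HC   -0.0546    0.0517   -0.165    0.0555 1.50e1    -1.06    0.308 0.357
#> 2 group_SAD  -0.0491    0.0517   -0.159    0.0610 1.50e1    -0.951   0.357 0.357
#> 3 valence_…  -2.97      0.0173   -3.01    -2.94   2.14e4  -172.      0     0
```

The composite procedure placed the window at 232–292 ms around the
recovered 262 ms peak; the model recovers the generator's configured
−3 μV loss-minus-win valence effect (estimate −2.97, CI −3.01 to −2.94)
and correctly reports null group contrasts, since no group effect was
built into these epochs. `delta_sensitivity(code_wsls(cohort))` likewise
returns per-participant win/loss sensitivity scores to misleading
feedback, and `learning_status()` segments each pair's trials into pre-
and post-learning phases.

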