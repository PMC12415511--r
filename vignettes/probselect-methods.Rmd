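---
title: "Models and methods in probselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in probselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

probselect is a simulation and analysis toolkit for probabilistic
selection ("feedback learning") experiments run in two agency variants:
*active* sessions, where the learner chooses and receives the feedback,
and *observational* sessions, where the learner watches a yoked replay of
another participant's choices and outcomes and is tested on what it
learned vicariously. The package covers the full analysis chain such
studies use — task and cohort simulation, reinforcement-learning (RL)
model fitting with information-criterion comparison, behavioral coding,
single-trial ERP scoring, and trial-level mixed-effects contrasts — so
that every stage can be validated end-to-end on synthetic data before it
touches real recordings. This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
benchmarks can show.

## The task model

A session interleaves learning blocks (default 4 × 60 trials, feedback
shown) with test blocks (4 × 30 trials, no feedback), followed by a
40-trial transfer phase, 400 trials in total. Three fixed stimulus pairs
carry reciprocal win probabilities (A/B = 80/20, C/D = 70/30,
E/F = 60/40); the transfer phase pairs the best stimulus A and the worst
stimulus B with the four stimuli they were never paired with (8 novel
pairs, 5 presentations each). Wins and losses are worth +20 and −10
points; the points are score bookkeeping only and never enter the
learning model, which codes reward 1/0 so that learned values remain
interpretable as win probabilities. Within a block, each eligible pair
appears equally often and the order is an unconstrained shuffle; the
left/right placement of the two stimuli is randomized per trial. All of
this is configurable through `task_design()`, which validates
divisibility of block lengths and reciprocity of the contingencies.

Simulated agents (`agent_params()`) choose by a softmax over their
current values, learn by a delta rule, and emit response times from a
normal distribution truncated below at the 200 ms validity bound.
No-response and rushed (< 200 ms) responses are injected at configurable
rates (1% each by default) so that the validity filter downstream has
realistic work to do; real data sheds a comparable fraction of trials.
Observational sessions copy the learning phase of their yoked source
verbatim — the observer responds only in test and transfer — and insert
attention catch prompts after learning trials at the design's catch
rate. In `simulate_cohort()`, each participant's observational session is
yoked to the active session of the preceding participant in the roster
(circularly), a deterministic stand-in for the yoking schedule of a real
study, and session order is counterbalanced across participants. The
default cohort (27 OCD, 27 HC, 29 SAD participants) gives the OCD group
a lower positive learning rate and inverse temperature, so group
deficits in accuracy and more indecisive, shift-prone choices are
present in the synthetic data and recoverable by the analysis stages.

## The RL model family

Values start at $Q_0 = 0.5$ for every stimulus (an uninformative win
probability). After feedback $r \in \{0, 1\}$ on a chosen stimulus,

$$Q \leftarrow Q + \alpha \,(r - Q), \qquad
  \alpha = \begin{cases}\alpha^{+} & r = 1\\ \alpha^{-} & r = 0,\end{cases}$$

with a single rate $\alpha$ collapsing the two in the single-rate
variants. Choices follow a softmax with inverse temperature $\beta$:
$P(\text{left}) = \operatorname{logit}^{-1}\!\big(\beta\,(Q_\text{left} -
Q_\text{right})\big)$. On feedback-free (test/transfer) choices the
model family differs in how values evolve: `static` leaves them
untouched; `decay` relaxes the two involved values toward $Q_0$ at rate
$\gamma$; `cipc` (choice-induced preference change) spreads them toward
the bounds, $Q_c \leftarrow Q_c + \varepsilon(1 - Q_c)$,
$Q_u \leftarrow Q_u - \varepsilon Q_u$. The exact functional form of
choice-induced revaluation is not settled; this bounded spreading form
is isolated behind `feedbackfree_update()` so alternatives are
pluggable. CIPC (and decay) apply after every *valid* feedback-free
choice in both test and transfer phases.

The likelihood of a session is evaluated on the held-out phases only:
learning-phase outcomes (own or observed) update values but contribute
no likelihood terms; every valid test/transfer choice contributes
$-\log$ of its softmax probability and then triggers the feedback-free
update. Restricting the likelihood to phases both agency variants share
makes active and observational fits directly comparable — observers
never choose during learning, so learning-phase choices could only ever
enter one variant. Sessions are fitted separately per agency.
`fit_rl()` minimizes the negative log-likelihood by bounded L-BFGS-B
from Latin-hypercube multistarts (20 by default, all recorded), and
`compare_rl_models()` ranks model variants by BIC summed over
participant-sessions, with $\mathrm{BIC} = k \ln n + 2\,\mathrm{NLL}$
and $n$ the number of valid likelihood trials. The inner trial loop is
compiled (Rcpp); the test suite verifies it against an independent,
naive R re-implementation to $10^{-10}$.

### Parameter bounds

Learning rates and the CIPC/decay rates live in $[0, 1]$. The inverse
temperature is bounded at $\beta_\max = 10$ by default (`rl_model()`
exposes the bound). The choice is deliberate: on a value scale where
$|\Delta Q| \le 1$, $\beta = 10$ already produces choice probabilities
around 0.9999, so larger values are behaviorally indistinguishable — and
a wide-open box does real damage. The held-out-phase likelihood has a
ridge along which a small learning rate (hence compressed $\Delta Q$)
trades off against a large $\beta$; with a generous bound, maximum
likelihood occasionally drifts far along this ridge (we observed optima
with $\beta$ of 16–50 beating the truth-region optimum by 1–5 nats on
simulated sessions), which wrecks parameter recovery while changing the
predicted behavior imperceptibly. The cap removes only that degenerate
tail.

### What recovery simulations can and cannot show

The package's recovery study (in the acceptance tests) simulates 100
participants from the dual-rate + CIPC model and refits them. The
generating distributions were fixed a priori at
$\alpha^{\pm} \sim U(0.1, 0.9)$, $\beta \sim U(1, 6)$,
$\varepsilon \sim U(0.01, 0.15)$: wide learning-rate coverage, inverse
temperatures that reproduce the 60–85% test-accuracy band typical of
this task, and small positive revaluation rates. Under these conditions
the CIPC rate recovers with correlation above 0.5, and model recovery is
reliable — the generating dual-rate + CIPC variant wins the summed-BIC
comparison in a clear majority of simulated cohorts.

The learning rates and inverse temperature, however, are only partially
identified by a held-out-phase likelihood, and we report this rather
than hide it: at the study scale (160 likelihood trials per participant)
their generating-versus-recovered correlations plateau around 0.4–0.6.
Two diagnostics show the limit is informational, not numerical. First,
local optimization started *at the generating parameters* reproduces the
same estimates as the multistart, so the optimizer is not at fault.
Second, enlarging the test phase eightfold drives $\beta$ recovery to
$r = 0.96$ while the learning rates saturate near 0.75 — because
$\alpha^{\pm}$ are constrained only through the single 240-trial
learning history that shapes the values the test choices reveal, and
with ~20 feedback trials per stimulus the value trajectories of slow and
fast learners have largely converged before the first test block.
Latent-trace regressors ($Q$, prediction errors) are much less affected
than the raw parameters, because the ridge moves parameters along
directions that approximately preserve the predicted behavior. Users
who need well-identified individual learning rates should include
learning-phase choices in the likelihood (at the cost of
active/observational comparability) or use hierarchical estimation,
both outside this package's scope.

### Latent traces

`extract_latents()` replays a fitted (or supplied) parameter vector and
returns per trial: the pre-update chosen and unchosen values, the signed
prediction error $\mathrm{PE} = r - Q_c$ on feedback trials, the
salience (unsigned) prediction error $\mathrm{SPE} = |\mathrm{PE}|$
together with a mean-centered copy for regression use, and the
predictive-accuracy index $\Delta Q = Q_c - Q_{\bar c}$, which is
already meaningfully centered at zero.

## Behavioral coding

`filter_valid()` implements the validity rule: a trial is invalid when
no response was made or the RT is below 200 ms, with the boundary read
strictly (200 ms is valid). Win-stay/lose-shift coding (`code_wsls()`)
compares each valid repeat encounter of a pair with the most recent
valid prior encounter, skipping invalid encounters as comparison points;
the previous feedback is *authentic* when it aligned with that choice's
objective accuracy (win after correct, loss after incorrect) and
*misleading* otherwise. Per-participant sensitivity scores
(`delta_sensitivity()`) are shift-rate differences, misleading minus
authentic, within each previous-feedback valence; effective adaptation
implies a positive win delta and a negative loss delta.

Learning-status segmentation (`learning_status()`) works per participant
and pair over the valid learning-phase trials: the first candidate
position whose preceding 10 valid trials have mean accuracy strictly
above 0.9 (which a 10-trial window makes 10/10) is accepted as the
breakpoint only if mean accuracy over all remaining trials stays
strictly above 0.65; otherwise the search continues at the next
candidate. The first trial after a qualifying window is the first
post-learning trial, so post-learning trials always form a suffix;
pairs with no qualifying candidate stay entirely pre-learning. Both
thresholds and the window length are arguments. Whether the windows
should also span test trials is not settled; the default uses learning
trials only (the response-locked analyses concern learning-phase
responses), switchable via the `phases` argument. An exhaustive
candidate-scan oracle cross-checks the search on a thousand random
sequences in the tests.

## Synthetic EEG and scoring

`generate_epochs()` builds single-trial epochs over a five-electrode
fronto-central cluster (Fz, FCz, FC1, FC2, Cz) from −200 to 600 ms
around the locking event, at 500 Hz by default (half the typical
recording rate, for test speed; configurable). Each epoch is a negative
Gaussian-bump component at a fixed latency plus baseline drift, a
per-participant DC offset, shared cluster noise, and small independent
per-electrode noise — the last two matching the pooled-cluster scoring
assumption. The bump's single-trial amplitude carries the condition
structure the trial-level models assume: a loss-minus-win valence
effect, multiplicatively attenuated for observational agency (an
attenuation of 1 preserves the active effect), and a prediction-error
coupling applied with the sign of the feedback valence, i.e. to the
signed PE. One deliberate convention makes the generator directly
checkable: the bump shape is normalized so that its mean over the
latency ± 30 ms window is exactly 1, so amplitude parameters are
expressed in *scored* microvolts and a noiseless run must return the
configured valence effect to machine precision — which the tests
assert. Artifacts violating each QC rule can be injected at configured
rates. The generator emulates none of the physics of real EEG — no
head-model mixing, no ocular or muscle artifacts, no 1/f background —
so passing pipelines demonstrate the *statistical* correctness of
scoring and regression stages, not robustness to real-world
preprocessing problems, which remain out of scope.

Scoring follows a composite-waveform procedure. After per-epoch
baseline correction (subtract the mean of the pre-event interval) and
artifact rejection — an epoch is dropped if, on any cluster electrode,
amplitude exceeds ±100 μV, peak-to-peak activity stays below 0.5 μV
within any 100 ms span, the voltage range exceeds 200 μV within any
200 ms span, or consecutive samples jump by more than 50 μV — the
cluster-pooled, condition-wise grand averages are averaged with equal
weight regardless of trial counts. This condition-unweighted composite
locates the component peak (the minimum, given the negative polarity of
FRN and ERN/CRN) inside an a priori search window: 200–350 ms
post-feedback for the FRN, 0–100 ms post-response for the ERN/CRN.
Single-trial scores are then the mean amplitude in the peak ± 30 ms
window, per trial and electrode. Ties in the minimum resolve to the
earliest latency; endpoint minima are permitted by default, with a
strict-local-minimum mode available. The procedure runs separately per
agency condition — observer components are typically slightly delayed —
but never separately per group or feedback valence, which would bias
the windows toward the comparison of interest.

## Trial-level statistics

All categorical predictors are deviation coded (−0.5/+0.5), continuous
predictors are centered (block around the block midpoint 2.5; reward
contingency coded −1/0/1 from the 80% to the 60% pair; SPE around its
mean), so the intercept is the grand mean. The three-level group factor
is coded with OCD-referenced deviation contrasts
(`ref_deviation_contrasts()`): the two columns' coefficients equal the
HC−OCD and SAD−OCD mean differences while the intercept stays at the
unweighted grand mean, so the planned contrasts of interest *are* the
model's coefficients and `planned_contrasts()` simply reports them with
confidence intervals and Benjamini–Hochberg adjustment within the
requested family. FDR family boundaries are an argument, not a guess:
adjustment applies within whatever set of contrasts is passed together.

`fit_mixed()` attempts the maximal random-effects structure first and,
on non-convergence or singular fit, simplifies deterministically:
random-slope correlations are removed first (the `||` form), then
interaction slopes from the highest order down, then remaining slopes —
never the by-participant intercept, and secondary intercept-only terms
(e.g. by electrode for ERP models) are retained throughout. The full
attempt log is returned. This fixed order approximates automated
maximal-model search tools without reproducing their exact term-order
heuristics. Gaussian models use lmerTest (Satterthwaite degrees of
freedom); binomial models use glmer with Wald statistics. Calibration
is tested: under 500 null simulations the planned contrast's type-I
error stays within binomial tolerance of the nominal 5%.

## Problem sizes and numerical conventions

The test suite exercises the pipeline at sizes chosen to balance
statistical resolution against a laptop-scale run: feedback-frequency
checks at $10^5$ draws (binomial 3σ ≈ 0.4 percentage points);
likelihood-oracle agreement on 50 random sessions at $10^{-10}$;
parameter recovery at 100 participants × 160 likelihood trials with 20
multistarts; model recovery over 100 cohorts of 5 participants with 6
multistarts; prediction-error slope recovery at ~5,200 trials; type-I
calibration over 500 replicates. Seeds are fixed throughout;
simulation, generation and fitting are fully reproducible from a master
seed. Floating-point conventions worth knowing: window edges are
inclusive; the ±30 ms extraction window is converted to samples on the
epoch grid; baseline correction uses samples strictly before 0 ms; the
softmax log-likelihood uses the numerically stable log1p form.

## Known limitations

Estimation is maximum-likelihood per participant-session; there is no
hierarchical pooling, which the identifiability analysis above suggests
would help the learning rates. The CIPC functional form is a documented
stand-in for a quantity the field has not standardized. The EEG
generator is statistical, not biophysical. Transfer-phase behavioral
analyses, P3 components, and dimensional symptom analyses are outside
the package's scope, as is any preprocessing of real recordings
(filtering, re-referencing, ICA, interpolation).
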