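---
title: "Methods: reinforcement-learning signals in field potential power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reinforcement-learning signals in field potential power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rlpower asks a question that recurs across intracranial studies of learning:
when a person learns by trial and error which of two cues is worth choosing,
which latent variables of that learning process are reflected in the
oscillatory power of deep-brain field potentials, in which frequency bands,
and when relative to task events? The package implements the full analysis
chain for a probabilistic reward/punishment learning task recorded with
bipolar depth electrodes, together with a synthetic-data generator that
produces task behavior and epoched signals with *known* ground-truth
coupling, so that every stage — model fitting, spectral estimation,
encoding regressions, permutation statistics, band-wise model selection —
can be validated end to end.

## The task and the behavioral model

Each session presents four new pairs of abstract cues, 24 presentations per
pair (96 trials), with two pairs assigned to a reward condition (win +1
unit or nothing) and two to a punishment condition (lose 1 unit or
nothing). Within a pair the better cue pays with probability 0.75 and the
worse with 0.25 (reciprocal contingencies); screen sides are
counterbalanced; conditions are intermingled.

Choices are modeled by a two-parameter Q-learning agent. Every cue starts
at an expected value of 0 (the mean of the possible outcomes); after each
trial the chosen option's value is updated by a fraction $\alpha$ of the
prediction error, the difference between the obtained and expected outcome:

$$\delta_t = R_t - Q_{c,t}, \qquad Q_{c,t+1} = Q_{c,t} + \alpha\,\delta_t,$$

and choice probabilities follow a softmax with temperature $\beta$:

$$P(a_t = A) = \frac{e^{Q_{A,t}/\beta}}{e^{Q_{A,t}/\beta} + e^{Q_{B,t}/\beta}}.$$

One $(\alpha, \beta)$ pair is fitted per patient by maximizing the summed
log-likelihood of the observed choices over all sessions, with values
reset at each session start and for each new cue pair. The optimizer is a
deterministic multistart: an $11 \times 11$ grid over $\alpha \in [0,1]$
and log-spaced $\beta \in [0.01, 10]$, refined by bounded L-BFGS from the
best grid point. Because the value trajectory depends on $\alpha$ only,
each $\alpha$ requires a single forward pass reused across all $\beta$.
Goodness of fit is compared against uniform random responding with
AIC $= 2k + 2\,\mathrm{nll}$ ($k = 2$ for the learning model, $0$ for
random, whose AIC is exactly $2n\log 2$). We use this standard
lower-is-better convention and test only the *ordering* of the two models
on simulated learners and random responders.

Two modeling choices deserve a note. First, the prediction error is
implemented as obtained *minus* expected value; this is the only form
under which the error vanishes at the learned fixed point. Second, latent
regressors (chosen-option value $Q$, outcome $R$, prediction error) are
z-scored across each patient's valid trials *within condition* by default,
because the encoding models are fitted per condition; a cohort-wide
z-scoring scope is available via `scope = "all"` in
`compute_regressors()`.

## The synthetic cohort generator

`simulate_cohort()` draws complete sessions: randomized pair order, exact
side counterbalancing (each cue left in half its presentations),
softmax choices of an agent learning online, outcomes from the reciprocal
contingencies, and log-normal reaction times with a +0.4 s additive median
shift in the punishment condition — the direction and rough magnitude of
the slowing observed when people avoid punishments rather than seek
rewards. Each patient's baseline speed and punishment slowing are jittered
on their own random substream (log-scale SDs 0.15 and 0.5), so group
reaction-time contrasts carry realistic inter-individual spread (paired
t-values of order 3–6 rather than the implausibly large values a shared
deterministic shift would give). Choice-performance heterogeneity is *not*
modeled: all simulated patients share one $(\alpha, \beta)$, which is the
parameter-recovery design, so accuracy-versus-chance t-values run larger
than in real cohorts. Event times (cue at 0, choice at the reaction time, outcome
1.25 s later, matching the task's 0.25 s choice highlight plus 1 s delay)
are emitted per trial so any lock event can be analyzed. A single cohort
seed deterministically spawns per-session and per-site substreams;
regeneration is bit-identical.

`synthesize_epochs()` builds one 10 s epoch per trial and site
($[-5, 5)$ s around the lock event at 512 Hz): independent $1/f$
background noise per site (unit SD, spectral exponent 1) plus an 8 Hz
carrier whose amplitude envelope inside the 0–2 s coupling window is

$$a(t) = a_0\, w(t)\, \max\!\big(0,\; 1 + c\,(g_Q z_Q(t) + g_R z_R(t))\big),
\qquad a_0 = \mathrm{snr}\,\sigma_{\text{noise}},$$

with a random carrier phase per trial and $w(t)$ a 0.3 s cosine on/off
ramp inside the window edges. The ramp matters: gating a carrier with a
hard rectangle spreads its energy across the whole spectrum
(onset/offset splatter), which would make delta- and beta-band power
spuriously track the regressors; with the ramp, cross-band contamination
is reduced to the taper-sidelobe floor. The default snr of 0.4 (carrier
amplitude relative to the broadband noise SD) keeps that residual
sidelobe leakage into the neighboring beta band statistically negligible
at cohort size while the 4–12 Hz band-level SNR stays high (across-site
group t-values of order 40 at the default gains).

Gains are specified in *recovered-power units*: one unit of gain is
intended to appear as one unit of z-scored log-power per z-scored
regressor after the standard spectral chain. The fixed calibration
constant $c = 2.6$ maps power gains to envelope depth; it was measured
by simulating cohorts at the default configuration with known envelope
gains and regressing normalized band power on the regressors. The
attenuation it compensates is the product of band dilution across the
nine 4–12 Hz bins, edge and ramp attenuation of the constant-cycle
analysis windows, log compression at moderate band SNR, the variance the
coupling itself adds to the per-trial z-score denominator, and clipping
of negative envelopes. With $c$ frozen, the default design
($g_Q = +0.3$, $g_R = -0.2$) is recovered as
$\hat\beta_Q = 0.300 \pm 0.008$ and $\hat\beta_R = -0.185 \pm 0.006$
(mean ± SD over cohorts) — a small residual shrinkage of the outcome
coefficient remains because a single constant cannot remove the
nonlinearity for both a continuous and a binary regressor
simultaneously. Away from the default carrier, band,
snr or noise exponent the mapping is only approximate, which is the
documented price of keeping the envelope linear in the regressors.
Envelopes that would go negative are clipped at zero (about a tenth of
trials at the default gains — those trials simply carry no oscillation);
a warning reports the clip count when it exceeds `clip_tol` (20 %) of
trials.

`inject_artifacts()` adds brief (20–100 ms) raised-cosine transients of
configurable amplitude (default 20 × signal SD) to randomly selected
trials and returns the ground-truth mask, emulating interictal discharges
for detector validation.

What the generator does *not* emulate: volume conduction and cross-site
coherence (sites are independent given the shared regressors),
non-stationary background spectra, line noise, true biophysics of
thalamic circuits, and any reaction-time dependence of neural coupling.
Passing tests therefore demonstrate that the pipeline recovers what it
assumes — linear band-power coupling — not that real recordings satisfy
those assumptions.

## Spectral estimation

`multitaper_tfr()` estimates power with Slepian tapers. Below 32 Hz each
frequency uses a 6-cycle window with 3 tapers, so temporal resolution
improves and spectral resolution degrades with frequency. The
time–half-bandwidth product of these tapers is 2.2 rather than the
minimal 2.0: at 2.0 the third Slepian keeps only 96 % of its energy in
band, and its −23 dB sidelobes let a strong low-frequency oscillation
contaminate neighboring-band estimates, while at 2.2 it is 98.4 %
concentrated and the 13 Hz main lobe still clears the 4–12 Hz range; at and above 32 Hz a fixed 0.2 s window is used with the taper
count interpolated linearly from 4 (32 Hz) to 31 (200 Hz), trading
spectral smoothing for estimator variance at high frequencies. The
default grid is 1 Hz steps from 1–32 Hz and 4 Hz steps from 36–200 Hz.
Estimates are scaled to spectral density (per-Hz) so that all internal
analysis rates share one unit.

Two numerical choices matter here. For the low range the signal is first
resampled by band-limited spectral truncation to the smallest rate (a
multiple of 20 Hz compatible with the output stride) that accommodates
the frequency plus its taper bandwidth; this makes the cost independent
of the acquisition rate and is verified against the full-rate path in the
tests (agreement within window-length rounding). Output times are a
regular grid (default 50 ms stride; the large simulations in the tests
use 100–250 ms, see below) and window centers snap to the nearest sample;
grid points whose analysis window does not fit inside the epoch are
returned as missing rather than zero-padded.

`normalize_power()` applies a decimal-log transform and then a z-score.
The default scope is trial-wise: each trial's log power is centered and
scaled by its own mean and SD over the full 10 s epoch, per site and
frequency. This follows the convention of baselining against a wide
window centered on the event of interest, and has a consequence worth
knowing: because each trial integrates to zero, power added inside the
coupling window is compensated by a *negative* shift of the trial's
baseline, so encoding effects appear with inverted sign outside the
window. The package treats this as a property of the normalization, not a
bug; the pooled alternative (`method = "pooled"`, statistics across all
trials per frequency) avoids it at the price of sensitivity to slow
drifts. Trials with degenerate variance at a frequency are flagged
invalid.

`reject_artifact_trials()` slides a 50 ms window (50 % overlap) across
each epoch and excludes any trial whose windowed RMS amplitude exceeds
5 × the standard deviation of the site's signal pooled over trials. The
threshold is deliberately expressed in units of the ongoing signal's SD:
a sustained 5-sigma excursion within 50 ms is essentially impossible for
stationary $1/f$ background (measured false-positive rate ≈ 0) but is
reached by discharge-like transients of ≥ 10–20 sigma. An alternative
rule — thresholding at mean + 5 SD of the window powers themselves — is
available via `threshold = "window_stats"`, but under heavy-tailed $1/f$
window-power distributions it excludes half of clean trials and is not
the default.

Band definitions are delta 1–4 Hz (upper edge exclusive), LFO 4–12 Hz
(the 4 Hz bin belongs to LFO), beta 13–33 Hz, gamma 50–150 Hz.
`band_average()` is an unweighted mean over band bins, optionally also
over a time window.

## Encoding models and group statistics

`encode_band()` fits, per site and time point, ordinary least squares of
normalized band power on z-scored regressors with an intercept —
outcome-locked designs use expected value and outcome jointly
($Y = \alpha + \beta_R R + \beta_Q Q$); cue- or choice-locked designs use
the expected value alone. Models are fitted per condition (reward trials
with $Q_r$ and $R$; punishment trials with $Q_p$ and $P$), matching how
condition-specific effects are reported. Artifact trials are excluded
listwise; sites with fewer than 20 usable trials (configurable) are
dropped from the map. `group_ttest()` then tests the estimates against
zero across sites (one-sample, two-tailed, df = sites − 1) or between
conditions (paired); points with zero across-site variance are flagged
degenerate instead of producing infinities.

## Two-level cluster permutation

Significance of the encoding time courses is controlled family-wise by a
two-level permutation scheme (`cluster_correct()`). Level one shuffles
each site's trial-to-regressor pairing (default 100 shuffles; the design
Gram matrix is permutation-invariant, so all refits collapse into one
matrix product per site). Level two draws random cross-site combinations
(default 2,000; 300 × 60,000 is the full-budget configuration available
for real-data reproduction), each picking one shuffle per site,
recomputes the across-site t-map, and records the maximal suprathreshold
cluster statistic — the sum of t-values over contiguous points exceeding
the two-tailed critical value at $\alpha = 0.05$. Observed clusters are
scored against the pooled absolute null with an add-one correction,
$p_c = (1 + \#\{\text{null} \ge |s|\})/(1 + n)$, which cannot return an
exact zero. Clustering is two-sided with signed clusters and a pooled
|statistic| null; 1-D series use adjacency, 2-D time-frequency maps use
4-connectivity. Type-I calibration on null cohorts and power on coupled
cohorts are part of the acceptance tests.

## Band-wise model selection

To ask which bands carry prediction-error information,
`band_pe_regression()` regresses the z-scored prediction error on band
power averaged over 0–2 s post-outcome (per condition: reward trials give
the reward-prediction-error regression, punishment trials the punishment
one), testing slopes across sites. The direction — error regressed on
power — follows the band-analysis convention; it is the same correlation
as the encoding direction up to variance scaling.

`log_model_evidence()` scores the eight-model space (every model contains
the LFO predictor; the others add each subset of delta, beta, gamma) with
the exact closed-form marginal likelihood of a conjugate Bayesian linear
model: standardized response and predictors, no intercept, a zero-mean
g-prior with unit-information scaling ($g = n$), and an
inverse-gamma(0.01, 0.01) noise prior. Absolute evidences therefore
differ from variational toolbox values, but model *rankings* are
comparable, which is what the group stage consumes; a −BIC/2
approximation is available and agrees in ordering. `rfx_bms()` treats the
winning model as a random effect across sites: a variational Dirichlet
scheme (prior concentration 1 per model) alternates posterior model
assignments and concentration updates to convergence ($10^{-6}$),
yielding expected frequencies $Ef = \alpha/\sum\alpha$; exceedance
probabilities come from $10^5$ seeded Dirichlet draws (Monte Carlo SD
≤ 0.005). Under unanimous hard assignment with 48 sites and 8 models the
closed form gives $\alpha_{\text{win}} = 49$ and $Ef = 49/56 = 0.875$ —
the algebraic ceiling of $Ef$ at this cohort size, which is why
identification checks target the winning model's identity rather than any
particular printed $Ef$ value. Family-level selection, Bayesian omnibus
risk and protected exceedance probabilities are out of scope.

## Orchestration and reproducibility

`run_pipeline()` chains simulate → fit-behavior → synthesize/screen →
spectral → encode/cluster → band model selection, writing TSV/JSON
outputs and a manifest with stage timings, exclusion fractions and file
digests; a run is bit-reproducible from (config, seed). Configurations
round-trip through YAML. `import_accession()` adapts a locally downloaded
deposit (trial TSV plus per-site Feather epoch files with JSON metadata)
into the internal containers, validating trial invariants with the
offending row named; `export_accession()` writes the same layout.

## Problem sizes used by the test suite

The validation suite runs the stated criteria at full run counts but
chooses desk-scale problem sizes, stated here as the package's own
choices: behavioral recovery uses 50 cohorts of 8 patients × 6 sessions;
encoding recovery uses 100 cohorts of 48 sites × 96 trials (one session)
at a 0.1 s stride with the reduced permutation budget (100 × 2,000);
type-I calibration uses 200 null cohorts synthesized at 128 Hz — the
cluster statistic operates on the 4–12 Hz band time course, whose null
behavior does not depend on the acquisition rate — at a 0.125 s stride;
band model selection uses 100 cohorts of 12 sites with the prediction
error coupled to the LFO band only (gain −0.15, at which the uncoupled
bands' residual taper-sidelobe leakage stays within the null band while
the coupled band's group t remains of order −30); detector validation uses 100 runs of
2 sites with 6 % injected transients at 20 × SD. `scripts/acceptance.R`
recomputes the same quantities at smaller replicate counts and reports
them as JSON.

## Known limitations

Fitting assumes a single learning rate and temperature per patient;
alternative learning models (dual rates, actor–critic, Pavlovian biases)
and drift-diffusion reaction-time models are out of scope. The evidence
model assumes Gaussian residuals of standardized prediction errors. The
generator's calibration constant is exact only at the default encoding
configuration. Bipolar re-referencing of raw multi-contact recordings is
provided only as part of the accession adapter's expectations, not as a
signal-processing module, and no line-noise or connectivity analyses are
included.
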