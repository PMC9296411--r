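---
title: "Models and methods behind prosodim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prosodim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosodim)
```

prosodim simulates and scores a family of psychoacoustic experiments on
statement–question intonation: an adaptive pitch-direction threshold task,
same–different discrimination of spoken sentences and of their musical
analogues, single-sentence identification, and imitation scored
acoustically from the final-word pitch glide. Everything runs on synthetic
cohorts and synthetic audio, so the full analysis chain — stimulus
construction, adaptive tracking, signal-detection scoring, F0 measurement,
correlation and power analysis — can be exercised and validated end to end
without human data. This vignette explains the models, the defaults, and
the design decisions; it states no empirical result beyond what the
package's tests and acceptance script themselves compute.

## The adaptive threshold procedure

Pitch-direction thresholds are measured with a 2-down-1-up transformed
up-down staircase on a three-alternative odd-one-out task: three gliding
tones, two moving in one direction and one in the other, and the listener
picks the odd one. The excursion (end-to-end pitch span of each glide, in
semitones) decreases by the current step after two consecutive correct
responses and increases after every error; the consecutive-correct counter
resets on each decrease and on each error. The defaults follow the
standard schedule for this task: start at 6 st, step 1 st, then 0.1 st
after 4 reversals and 0.02 st after 8, terminating at 14 reversals, with
the threshold taken as the mean excursion of the last 6 reversals. This
rule converges on the 70.71 % point of the psychometric function
($p = 2^{-1/2}$, the probability whose square is 1/2).

Simulated listeners are Weibull 3AFC observers,

$$p(x) = \tfrac13 + \left(\tfrac23 - \lambda\right)
          \left(1 - e^{-(x/\alpha)^\beta}\right),$$

with scale $\alpha$ (st), slope $\beta$ (default 3, a typical
psychometric slope for pitch), and lapse rate $\lambda$. `convergence_point()`
inverts $p(x) = 2^{-1/2}$ in closed form and serves as the analytic oracle
for the staircase: over many seeded runs the mean reversal-based estimate
must sit near that point, which the test suite checks for
$\alpha \in \{0.2, 0.5, 1, 2\}$ st.

Decisions the procedure itself leaves open, resolved as follows:

* **Reversal definition.** A trial whose excursion change runs opposite to
  the previous change — the standard transformed up-down convention.
* **Step-transition timing.** A new step applies to the first change
  *after* the scheduled reversal completes, so the change that causes the
  4th (8th) reversal still uses the old step.
* **Counter reset.** The 2-down counter resets on every error and every
  decrease; an error interrupting a correct pair therefore restarts the
  pair.
* **Floor.** Excursions are clipped at 0.02 st (the smallest step);
  thresholds this small are outside the regime the task measures.
* **Log transform.** Thresholds enter parametric analyses as `log10`;
  every inference in the package is invariant to the base up to scale.

Non-compliance screening replaces by-eye inspection of tracks with two
explicit rules on the late part of a run: coefficient of variation of the
last-6 reversal excursions above 0.5, or any of those excursions above
50 % of the starting excursion. Both cutoffs are configuration knobs; the
defaults flag lapse-prone simulated observers far more often than clean
ones (checked by simulation) but are a surrogate heuristic, not a claim
about how human runs were screened.

## Stimuli

`make_glide_contour()` builds the threshold-task tones: log-linear glides
geometrically centred on 500 Hz, i.e. running from
$500 \cdot 2^{-e/24}$ to $500 \cdot 2^{+e/24}$ Hz for an excursion of $e$
semitones. Geometric centring keeps upward and downward glides symmetric
in log frequency; "centring" is otherwise ambiguous and this is the
convention under which up/down stimuli are mirror images.

`make_utterance_contour()` builds pseudo-utterances: a stem of syllables
following a linear declination (default −10 Hz/s from ~220 Hz, an
ordinary declarative downtrend) and a final word carrying a signed linear
glide in Hz — negative for statements (terminal fall), positive for
questions (terminal rise). Statement and question members of a pair share
stem parameters, so their contours — and rendered waveforms — are
identical up to the final word, emulating cross-spliced natural pairs.
Whether natural final glides are linear in Hz or in log frequency is not
observable from the published materials; the utterance glide is linear in
Hz (which makes the signed Hz glide measurement exact), while the
threshold tones are log-linear.

Two renderers share an additive-synthesis core with per-syllable
raised-cosine onset/offset ramps and phase-continuous frequency
modulation:

* **Speech proxy** — harmonics 1..15 at amplitudes $1/n$. This timbre is
  invented plumbing: only its F0 trajectory carries meaning, and the
  analyses never consult anything but pitch.
* **Musical analogue** — one discrete gliding tone per syllable, built
  from the fundamental and its seven odd harmonics
  ($F_0 \times \{1,3,5,7,9,11,13,15\}$, exactly 8 components). The test
  suite verifies by FFT that exactly 7 overtone peaks sit above the
  fundamental and that even harmonics are at least 40 dB down.

Peak amplitudes of analogues are matched to their parent sentences with
`normalize_peak()`. The default sample rate is 22 050 Hz and every
component is validated against Nyquist. The original sentence texts are
not reproduced; pair identity is abstract (`pair01` …).

Trial lists mirror the task structure: discrimination blocks present each
of the 18 pairs twice — once "different" (statement vs question), once
"same" (one member repeated) — for 36 trials, with 750 ms ISI and 2 s ITI.
Which member repeats is balanced 9/9 across pairs so response type is not
confounded with sentence type. Identification presents all 36 sentences
singly. With an odd pair count the same-trial split is floor/ceiling
unless `strict_balance = TRUE`, which errors instead.

## Signal-detection scoring

"Different" responses on different trials (discrimination) and "question"
responses on question trials (identification, imitation) are hits.
Sensitivity uses the log-linear correction: 0.5 added to each count and 1
to each total before the inverse-normal transform,

$$d' = z\!\left(\frac{h + 0.5}{n_s + 1}\right)
     - z\!\left(\frac{f + 0.5}{n_n + 1}\right), \qquad
  c = -\tfrac12\left[z(H) + z(F)\right],$$

so $d'$ stays finite for perfect or empty cells. The criterion $c$ is
reported alongside even though bias is analysed via per-type proportions;
the per-type table (`proportions_by_response_type()`) is exactly what a
bias ANOVA would consume, and the ANOVA itself is out of scope.

Individual chance screening uses the exact binomial upper tail
$P(X \ge n_\text{correct})$ at $p = 0.5$: tails above 0.05 are classified
as consistent with guessing. The tail is one-sided by default — the
question is whether accuracy *exceeds* guessing — with a two-sided option,
since published descriptions of this screen rarely state sidedness.
$p = 0.5$ reflects the binary response sets of both tasks.

## Acoustic measurement

`extract_f0()` is a frame-wise autocorrelation tracker (40 ms frames,
10 ms hop, 75–600 Hz search band): the normalized, biased autocorrelation
is searched for its highest peak in the candidate lag band, refined by
parabolic interpolation; frames are unvoiced when the peak falls below
0.5 or the frame RMS is negligible. The biased estimator's lag taper
breaks the period-doubling tie in favour of the true fundamental.

The signed final-word glide is the OLS slope of F0 on time over voiced
frames inside the annotated final-word interval, times the interval
duration. Regression is robust to single mistracked frames, and for a
linear glide equals end-minus-start F0. Frames within 30 ms of an
interval edge are dropped: the default covers half an analysis frame plus
a guard band, so no retained window straddles a boundary or an amplitude
ramp, both of which bias the autocorrelation peak. Classification is the
sign rule with a ±1 Hz dead zone ("ambiguous" in between; the published
procedure never defines a zero-glide case). Imitations score correct only
when their glide sign matches the model's — magnitude is deliberately
irrelevant, and ambiguous measurements score incorrect and are flagged.

The tests require the full audio → F0 → glide → label chain to classify
200 synthetic utterances with |glide| ≥ 10 Hz perfectly and to recover
glide sizes within ±2 Hz; measured glides must also scale linearly with
synthesized glides ($R^2 > 0.99$) over 10–100 Hz. Final-word intervals
come from the stimulus specification for synthetic audio and from a
user-supplied annotation CSV for external WAV files; there is no
automatic segmentation.

## The synthetic cohort

`generate_cohort()` draws `n_per_cell` participants in each of six cells
(ASD/control × child/adolescent/adult; the default 14 per cell gives 84,
the design's intended sample). Each participant carries:

* **latent log2 threshold** — cell mean plus Gaussian noise
  (`threshold_sd`, default 0.8). Default cell means (log2 st) encode the
  effect directions the design targets: children worse than adolescents
  and adults, ASD children worse than control children
  (≈1.2 st vs ≈0.5 st), and only a small adult-group difference.
* **latent intonation sensitivity** — a d′-scale latent (mean 2.0,
  SD 0.6) shared by discrimination, identification and imitation.
* **condition offsets** — speech 0, music `music_advantage`
  (default 0.3 d′), encoding the music-over-speech advantage.
* **lapse** — uniform on \[0, 0.04\]: small enough that clean runs
  dominate, large enough that the compliance screen has true positives
  when raised.

Threshold and sensitivity are coupled by a Gaussian copula: the copula
correlation is $r = \sin(\pi\tau/2)$, the exact inverse of the Gaussian
rank-correlation relation $\tau = \frac{2}{\pi}\arcsin r$, applied to the
normal score of the threshold under its population marginal (a
six-component normal mixture). Because Kendall's τ is invariant to
monotone marginal transforms, the cohort-wide τ between log threshold and
sensitivity equals `tau_target` (default −0.4, the magnitude range of the
published threshold–performance correlations) exactly in population —
mixing cells without the normal-score step would attenuate it. Large-
sample tests verify the calibration within ±0.03 across targets.

Responses are generated by an equal-variance signal-detection decider
with criterion 0 (the default mirrors the absence of response bias in the
data the design models; a `criterion` knob generates biased responders for
testing the bias analysis), mixed with lapse-rate guessing. Imitation
productions match the model's glide sign with probability
$\lambda/2 + (1-\lambda)\,\Phi(d/\sqrt2)$ — the two-alternative percent
correct of that same decider — with log-normal magnitude around the model
glide (log-scale SD 0.3). These response models are stand-ins with the
right statistical shape, not claims about human decision processes: real
data add serial dependencies, fatigue, attention drift and acoustic
variability that the generator does not emulate, so passing recovery
tests validates the *pipeline*, not any psychological model.

## Power analysis

`anova_interaction_power()` computes noncentral-F power. Two
formulations are exposed. The repeated-measures within-between
interaction uses
$\lambda = f^2 N m / (1 + (m-1)\rho)$ with
$df_1 = (k-1)(m-1)\varepsilon$, $df_2 = (N-k)(m-1)\varepsilon$. Note that
this noncentrality *decreases* as the repeated-measures correlation ρ
grows — between-subject effect variance is inflated by pooled
within-subject correlation — so power falls with ρ under this
formulation.

The default design, however, is the fixed-effects "special" cell with
$\lambda = f^2 N$, numerator $df = 2$ and 12 cells: the
Group × Condition × Age three-way interaction of a 2 × 2 × 3 design has
$(2-1)(2-1)(3-1) = 2$ numerator degrees of freedom, and standard power
software computes three-factor interactions through exactly this cell
(its repeated-measures module handles only two factors). This is the
design under which the package's calibration targets hold: the smallest N
(in steps of 2, keeping groups equal) reaching power 0.80 at $f = 0.40$,
$\alpha = 0.05$ is 64, and the same design evaluated at N = 84 gives
power 0.9055 ≈ 0.91. The within-between cell with $k = 6$, $m = 2$,
$\rho = 0.5$ yields 66 and 0.90 instead, and no parameterisation of that
cell reproduces both published figures — which is how the fixed-effects
cell was identified as the one actually used. Both numbers are recomputed
from scratch by `scripts/acceptance.R`.

`kendall_tau()` is the tie-corrected τ-b (simulated d′ values tie
often); it wraps the base implementation and is validated against an
O(n²) concordance count in the tests.

## The pipeline and parameter recovery

`run_experiment()` chains everything: cohort → staircase per participant
(the simulated observer's convergence point is placed exactly at the
participant's latent threshold, so the staircase estimates the latent) →
discrimination (speech, music), identification, imitation → scoring →
summaries → recovery report, writing CSV/JSON outputs when asked. Task
order per participant is a seeded permutation, recorded for realism but
behaviourally inert. One seed makes the whole run byte-reproducible;
non-compliant tracks are excluded from threshold summaries and counted in
the report.

`recovery_report()` compares estimates against generating values:
per-cell mean log2 thresholds; the Kendall τ between estimated log10
threshold and each participant's d′ pooled over all four task blocks
(all blocks share one latent, so pooling is the least attenuated
estimate — with 36-trial blocks, single-block d′ noise attenuates the
recovered τ noticeably); the mean music − speech d′ difference; and the
identification–imitation correlation, which must be positive by
construction. Finite trial counts still attenuate the recovered τ
slightly below its generating value; the ±0.15 recovery tolerance
absorbs attenuation plus sampling error at n = 84.

## Problem sizes and numerical choices

Test and validation runs use sizes chosen to make Monte-Carlo error
comfortably smaller than the tolerances they check: copula calibration on
~10 000 participants (τ within ±0.03), staircase convergence on 500 runs
per observer (mean within 25 % of the analytic point), d′ round-trips on
pooled counts from 500 replicate blocks, the acoustic suite on 200
utterances, and recovery on the default 84-participant cohort. WAV I/O is
16-bit PCM (round-trip within one quantisation step) or float32.
Degenerate inputs fail loudly: zero-glide models, constant sequences in
τ, silent normalization references, Nyquist violations, and staircases
with fewer reversals than the estimator needs all raise errors rather
than guessing.

## Known limitations

* The response generators are statistical stand-ins; no claim is made
  that participants implement equal-variance SDT with uniform lapses.
* The speech proxy is not speech: no formants, no segmental content, no
  microprosody. Conclusions about real recordings require the annotation
  CSV route and will inherit pitch-tracker limitations on creaky or
  breathy voice that the clean synthetic suite cannot reveal.
* The compliance screen is a heuristic surrogate for expert inspection.
* Bayesian model comparison (Bayes factors, posterior summaries) used in
  the analyses this package surrounds is deliberately out of scope.
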