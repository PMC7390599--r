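---
title: "Stable and dynamic value codes: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable and dynamic value codes: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuedyn)
```

## The scientific problem

When a reward-predicting cue and its outcome are separated by a delay, the
expected value of the cue must be held in working memory. Competing theories
predict different neural signatures: *stable* codes (a fixed linear readout
decodes the value at any time in the delay), *dynamic* codes (the readout is
only valid near the time it was estimated), and *sequential* codes (transiently
active units tile the delay). `valuedyn` implements the analysis battery used
to adjudicate between these pictures in prefrontal population recordings — and
a spike-train simulator with planted coding regimes, so that every stage of the
battery can be validated on data whose ground truth is known.

The task structure assumed throughout (`task_config()`): a value cue (4 levels
x 2 reward types) shown from 0 to 0.6 s, a response-instruction cue at 2.1 s,
and reward at 3 s. The *delay* is cue offset to reward (2.4 s); most
unit-level measures are computed there, while decoding windows run from cue
onset to reward.

## The synthetic-data generator

Spike trains are drawn as inhomogeneous Poisson processes (thinning against an
analytic rate bound), from deterministic rate functions per coding class:

* `stable_linear` — rate offset `gain * (value - 2.5)` from cue onset to
  reward: a time-invariant monotonic value code.
* `stable_nonmonotonic` — a per-value offset vector (e.g. responding only to
  value 3): value information without linear order.
* `sequential` — a Gaussian bump at a unit-specific time with amplitude
  `gain * value`: transient, temporally local value coding. Bump centres tile
  cue onset to reward when drawn with `sample_population()`.
* `reversing` — the sign of the value slope flips mid-delay (drives the
  stability measure toward 0).
* `type_coder`, `time_ramp`, `untuned` — reward-type coding, pure elapsed-time
  coding and unstructured baseline activity.

Defaults were chosen once to emulate the regime the method was designed for:
baselines U(3, 8) Hz and a *modest* stable code — real prefrontal value
signals are weak at the single-unit level, with sensitivity indices around
0.2–0.3 when averaged over whole populations. Stable gains U(0.35, 0.6) Hz
per value step were calibrated against that anchor using the simulator's own
d' measurement (strongly tuned units land near d' 0.6, the population mean
near 0.3); transient sequential responses are relatively larger (amplitude
`gain * value` with gain U(1, 2) Hz, bump SDs U(0.10, 0.25) s), reward-type
effects weaker than value (U(0.5, 1) Hz), and each condition contributes 40
trials (320 trials per session). Event times are identical across trials (no
jitter), keeping alignment exact for tests.

What the generator does **not** emulate: correlated noise across units (trial
alignment is randomised per unit when pseudo-populations are built), slow
drifts in excitability, non-Poisson spiking statistics, and behavioural
covariates. Passing tests on this generator therefore validate the *analysis
machinery* (calibration, leakage-freedom, recovery of planted structure), not
claims about any particular real dataset.

## Rate estimation and binning

Rates are estimated by convolving each trial's spike train with a unit-area
Gaussian kernel (SD 100 ms; 50 ms for trajectory speed and time regression)
and averaging the smoothed rate within 100 ms bins stepped every 25 ms
(encoding) or 50 ms (decoding); the coarse search grid uses non-overlapping
200 ms bins. An interval of length `L` holds `floor(L / step)` bins — 40 bins
per second at 25 ms steps — with the last bins overhanging the epoch edge,
which is well defined because smoothing runs over the whole recording before
epoching. The same property means bins just before an event can carry
post-event information; this is documented behaviour, not corrected.

Epoch windows are not dictated by the analysis and are configuration: cue
`[-0.5, 1.3]` s around cue onset, response `[-0.8, 0.45]` s around the
response cue, reward `[-0.45, 0.5]` s around reward, chosen to abut for the
default task timing. Units averaging below 1 Hz across the session are
excluded (`filter_low_rate()`; a unit at exactly 1 Hz is retained).

Pseudo-populations draw, per unit and condition, a fixed number of trials
without replacement and stack them as pseudo-trials; the draw is repeated five
times and every population-level result is reported as the mean over the five
datasets. Drawing per unit (rather than per session) randomises trial
alignment, which removes noise correlations — the standard trade-off of
pseudo-population analyses — and makes the five datasets differ even when all
units come from one synthetic session.

## Unit encoding statistics

Per bin, activity is modelled as `activity ~ C(value) + type +
C(value):type` (value categorical; a parallel fit with numeric value is used
to identify non-linear value coders) and each term tested with an F test. The
sweep is computed for all units and bins in one multi-response QR
least-squares pass; on the balanced designs used here sequential sums of
squares equal Type II/III, and the tests agree with `anova(lm(...))` to
machine precision (asserted in the test suite).

A bin *encodes* a variable if it sits in a run of at least 7 consecutive bins
with p < 0.01 (~175 ms at 25 ms steps); latency is the first bin of the first
qualifying run (the run rule trades per-bin false positives for a far lower
unit-level false-positive rate, verified by null calibration in the tests).

Three delay-window measures summarise a unit's value code:

* encoding strength `es = mean(-log10 p(t))` — base 10, so the plotted range
  2..5 corresponds to p-values 0.01..1e-5;
* the stability measure `S`: for each value pair, `tanh(10 * (xbar_v(t) -
  xbar_w(t)) / sp_vw(t))` averaged over delay bins and taken in absolute
  value, then averaged over the 6 pairs, with `sp` the pooled SD
  `sqrt((s_v^2 + s_w^2)/2)` computed per bin. A constant separation saturates
  S toward 1; a sign reversal cancels the sum toward 0. The per-bin (rather
  than time-pooled) variance normalisation was chosen so each time point is
  standardised at its own noise level;
* d', the mean over value pairs of |mean difference| / pooled SD of per-trial
  rates averaged over the cue-to-reward window. The averaging window is a
  package choice (the measure's definition does not fix one); cue onset to
  reward matches the window of the decoding analyses.

Split-half analyses (`split_half_sequence_analysis()`) re-run the per-bin
ANOVA independently on random trial halves, keep units significant in both,
and compare peak-encoding bins and encoding durations across halves with
Spearman correlations — the consistency check behind peak-sorted "tiling"
displays.

## Decoding

Population decoding uses a ridge regression classifier, one-versus-one over
the 4 values (6 binary fits, targets ±1), majority vote with ties broken by
summed signed margins and then lowest class index. Features are z-scored per
(unit, bin) with training-fold statistics — the method as usually described
leaves scaling unspecified, but unscaled heterogeneous firing rates would let
high-rate units dominate the L2 penalty; the same bin's training statistics
are applied at test time so the readout itself stays fixed. The penalty grid
is `10^seq(-2, 5, 0.5)` (15 candidates); a single penalty per (population,
dataset) is chosen by 4-fold inner cross-validation on the first outer fold's
training trials to maximise mean same-bin accuracy over the cue-to-reward
window, with grid ties going to the smallest penalty. The closed-form primal,
SVD-path and dual (kernel) solvers agree to machine precision (tested); the
dual form makes label permutations cheap because the Gram matrices do not
depend on labels.

Cross-temporal decoding (CTD) trains at every bin and tests at every bin on
held-out trials of a stratified 5-fold cross-validation; the diagonal *is* the
standard decoding time course (exact equality under shared folds is asserted).
Significance: labels shuffled `n_perm` times, p = (number of permutations with
strictly higher accuracy)/n_perm — an observed accuracy above every
permutation is stored as 0 (i.e. < 1/n_perm) and flagged — and the five
datasets' p-values are combined as `p_agg = min(1, 2 * mean(p))`, an
aggregation valid under dependence, thresholded at 0.01.

## Value subspace and ensembles

The *value subspace* is the PCA of the 4 x n matrix of per-value class means
(activity averaged cue onset to reward, then across same-value trials): at
most 3 components for 4 values. Decoding inside the subspace uses a split/swap
protocol within each outer fold — one half of the training trials defines the
subspace, the other trains the decoder, then the halves swap and the two
accuracy matrices are averaged — so the subspace never sees decoder-test
trials. The package also ships a deliberate-leak mode (`leak_subspace = TRUE`)
which demonstrates, on noise, the optimistic bias this protocol removes.
Subspace permutations shuffle *training* labels only, preserving the
subspace's tendency to inflate same-data accuracy under the null.

Greedy backward ensemble selection starts from the full population and
removes, at each step, the unit whose removal maximises the objective,
continuing to a single unit; the selected ensemble is the argmax over the
trace (the full population is a candidate, so the selected score never falls
below the full score; ties keep the larger ensemble). Objectives:

* **stability score** — mean CTD accuracy over all train/test bin pairs from
  cue onset to reward (evaluated through the value subspace in the combined
  pipeline). The search window follows the ensemble-method description (cue
  onset to reward) rather than the figure-level "restricted to the delay";
  both are configurable via `decoder_config(window = ...)`.
* **locality measure** — per training bin, a Gaussian `a * exp(-(t2 - t1)^2 /
  (2 sigma^2)) + 0.25` is fitted to accuracy versus testing time (offset fixed
  at chance, mean fixed at the training time; only `a` and `sigma` free), and
  the measure is the mean of `(fitted peak - 0.25) / sigma`. The fit profiles
  `a` out in closed form and minimises over `sigma` with bounded Brent search
  (bounds: half a bin step to the testing-window span; failures contribute 0
  and are flagged). The dynamic search trains on one in five bins while
  testing on every bin, and operates on raw (not subspace-projected) activity
  — the subspace is paired only with the stable objective.

Search cost is kept honest and tractable by three documented choices: the
search runs on the coarse 200 ms grid (as the original method does); the
candidate objective uses a single stratified split of the outer-fold training
data (fit on one half, scored on the other — the swap is applied only in the
final evaluation); and the penalty tuned on the full population is reused
during the search, with the final selected-ensemble CTD free to re-tune.
Per-step Gram-matrix precomputation makes each candidate a rank-one
column-drop; results are identical to naive re-fitting (same closed form).

Each searched fold contributes one selected ensemble, evaluated on that fold's
held-out trials; `extract_stable_code()` / `extract_dynamic_code()` pool folds
and datasets. Ensemble overlap between stable and dynamic ensembles is tested
per instance with a 2x2 chi-squared test of membership independence,
Benjamini-Hochberg-corrected across instances. Ground-truth recovery on
synthetic populations is quantified with upper-tail hypergeometric enrichment.

Unit contributions to an ensemble are the greedy-trace step deltas (score
before removal minus after), with the final removal discarded (NA) and the
never-removed unit NA; the explicit leave-one-out form is available as
`accuracy_contribution()`. For display and correlation the signed square-root
transform `ac = sign(x) * sqrt(|x|)` is applied — monotone, hence invisible to
the Spearman correlations in `correlation_battery()`. Subspace participation
of a unit is summarised as the L2 norm of its component loadings (a 3-vector
per unit; the norm captures total participation irrespective of sign),
averaged over datasets.

## Population dynamics

Trajectory speed is the Euclidean distance between consecutive bins of the
across-trial mean population trajectory (50 ms kernel for temporal precision);
constant-rate units contribute nothing, and the scale grows with unit count.
Time regression predicts the integer bin index from the per-trial population
vector with OLS from 0.5 s before cue onset to 0.5 s after reward, assessed by
leave-one-trial-out cross-validation (a tiny ridge penalty is added and
flagged if the design is singular); a seconds-scale target is a trivial
rescaling of the index and not separately implemented.

## Numerical choices and degenerate inputs

* Zero-variance bins in the ANOVA: p = 1, flagged.
* p = 0 after clamping in `es`: clamped to the double floor, flagged.
* Zero pooled SD in S and d': the tanh term becomes sign(difference) (0 if the
  difference is 0) and the pair is excluded from d'; both flagged.
* Degenerate class means (rank < 3): fewer subspace components, flagged.
* OVO vote ties: summed signed margins, then lowest class index —
  deterministic.
* All randomness flows from one integer seed through a fixed sub-seed scheme;
  identical seeds give byte-identical sessions, draws, folds and searches.

## Analysis sizes used by the packaged studies

The packaged validation studies (test suite and acceptance script) run the
full battery on a 120-unit population (30 stable, 40 sequential, 50 untuned;
40 trials/condition generated, 32 drawn per condition per dataset), five
pseudo-population datasets, the coarse 200 ms grid for all cross-temporal
analyses, 100 label permutations per dataset, three greedy search folds per
dataset for the stable pipeline (their held-out evaluations pooled) and one
for the dynamic pipeline, with the search objective sampled on every second
grid bin (`search_stride = 2`; the reported CTDs always use the full grid).
These sizes are the package's choices for a single-workstation run of the
complete pipeline; all of them scale up by configuration (`n_perm = 1000` and
five search folds per dataset reproduce the original protocol).

One outcome of these studies is worth stating plainly: with amplitudes
calibrated to realistic per-unit sensitivities, a 40-unit sequential pool at
120-unit scale supports only a modest diagonal advantage in the
cross-temporal accuracy (the acceptance script reports the
diagonal-versus-far-off-diagonal gap it measures), and the greedy locality
search — whose per-step signal is then comparable to split noise — recovers
the planted pool only in a subset of datasets. Strongly diagonal dynamic
extractions of the kind seen in recordings of many hundreds of units require
either more units or per-unit transients that compensate for unit count.

## Known limitations

* Pseudo-trials destroy noise correlations; conclusions about correlated
  variability are out of reach by construction.
* The greedy search is not guaranteed globally optimal (it is compared with
  exhaustive enumeration on small populations in the tests).
* Per-trial event jitter is not supported by the shared bin grid (the
  generator's jitter stays off by default).
* The aggregation `2 * mean(p)` is conservative; with five datasets the
  smallest attainable aggregated p is 2/5 of the per-dataset floor.
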