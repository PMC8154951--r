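---
title: "Methods: stimulus design, gaze simulation and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus design, gaze simulation and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexigaze)
```

# The paradigm

`lexigaze` implements the analysis chain of an infant preferential-looking
study in which trisyllabic nonsense words are learned from a continuous
audiovisual stream. Four CVCVCV words are each paired with a visual token:
two *object-words* with the face pictures of two women, and two
*action-words* with head-gesture videos (up-and-down or left-to-right,
performed by both women). Two of the four words carry a phonological cue —
*vowel harmony* (the same vowel in all three syllables) or *consonant
harmony* (the same consonant) — and only those cued words are tested.

After familiarization, learning is probed in 16 two-alternative test trials:
the infant hears a cued word while two lateralized images appear; longer
looking at the image that co-occurred with the word during familiarization
indicates learning.

# Stimulus construction

## Words

`make_words()` assembles the four words from a consonant-vowel inventory
under three constraints: each word is CVCVCV; the two cued words repeat one
vowel (or consonant) across their three syllables; and the 12 syllables are
pairwise distinct. The last constraint is what makes the within-word
syllable transitional probability (TP) exactly 1 in the stream: each
syllable has a unique successor. Published word lists can be passed in
verbatim and are validated against the same invariants.

## The TP-balanced stream

The familiarization stream presents each word 24 times (96 events). Design
properties:

* pictures and videos strictly alternate, so object- and action-word events
  alternate too;
* each video is performed by the woman of the immediately preceding picture
  ("the same woman" pairing);
* every between-word TP is 0.5, every between-image TP is 0.5.

Exact balance on a *linear* sequence is impossible — 96 events have only 95
interior transitions, which cannot split the eight allowed word-to-word
transitions into equal counts of 12. The generator therefore builds the
stream as a **closed Eulerian circuit** and cuts it at a random rotation:
the sequence of women over the 48 picture/video blocks is a random Eulerian
circuit on the two-node multigraph with 12 parallel edges per ordered pair,
and gestures are then allocated within each woman's blocks, balanced across
successor-woman classes (with complementary rounding across the two women
when the repetition count is not divisible by 4). On the circular closure,
every word-level transition occurs exactly `n/2` times and every video token
is followed by each woman's picture exactly `n/4` times.
`compute_transition_table()` accordingly counts transitions circularly by
default (`circular = FALSE` gives plain linear counting, which differs by a
single transition).

```{r stream}
cfg <- design_config(words = make_words("vowel", "action", seed = 7))
stream_seq <- build_familiarization_sequence(cfg, seed = 3)
tt <- compute_transition_table(stream_seq, words = cfg$words)
range(tt$within_word_syllable)   # 1: deterministic within words
range(tt$word[tt$word > 0])      # 0.5 between words
```

With the default phoneme durations (170 ms consonants, 286 ms vowels) each
word lasts 1368 ms and the 96-event stream lasts 131,328 ms (2.19 min);
`schedule_stream()` reports the exact duration rather than forcing a round
figure. An odd repetition count is rejected (balance is impossible); counts
that are even but not divisible by 4 keep word-level balance exact and make
image-level balance as even as integer counts allow.

## Test trials

`build_test_trials()` produces 16 trials = 8 unique displays, each presented
twice, 8 trials per tested word, with the correct image left and right
equally often per word. For action-word tests the two lateral images are the
two gestures performed by the *same* woman, and the woman is the third
counterbalancing factor. For object-word tests the two images are always the
two women's pictures, so the display is fully determined by word and side;
the third factor is a nominal presentation block. Order is a uniform shuffle
rejected until no more than two consecutive trials share a word or a correct
side — the usual infant-paradigm constraint, with the run length
configurable.

The trial timeline is fixed relative to the lateral-image onset at t = 0:
attractor (1500 ms default), first word presentation over empty placeholder
squares, 1000 ms silence, second presentation synchronized with image onset,
1000 ms silence, third presentation, trial end at 4700 ms. The images remain
on screen from t = 0 until trial end, so looking is measurable throughout
the analysis window, including the silences. Attractor and inter-trial
interval are excluded from every analysis window. Three counterbalanced
stream versions (`counterbalance_versions()`) differ only in the word-image
pairing and jointly cover every word with both members of its image class.

# Areas of interest

All gaze classification uses half-open pixel rectangles on the 1024 x 768
screen. The default test-phase geometry tiles the width exactly: left image
[0, 380), centre strip [380, 644), right image [644, 1024), with the
380 x 350 image squares vertically centred. (Centring the squares within
each screen half would overlap a 264-px centre strip, violating
disjointness; the flush tiling — note 380 + 264 + 380 = 1024 — keeps the
printed square size and strip width compatible.) The centre strip spans the
full height so that pre-onset centring is detected leniently. Familiarization
uses the 550 x 580 central stimulus rectangle with eyes and mouth
sub-regions. Every rectangle is configurable through `aoi_config()`, which
rejects overlapping primary regions at load time.

# Fixation detection

`idt_fixations()` implements the standard dispersion-threshold (I-DT)
algorithm: a window of consecutive valid samples is a fixation iff it lasts
at least 100 ms and its dispersion `(max x - min x) + (max y - min y)` stays
within 30 px; windows are extended greedily until the next sample would
break the bound, so fixations are maximal, non-overlapping and time-ordered.
A fixation's duration is `n_samples x 20 ms`, so the 100 ms minimum is 5
samples. Isolated one-sample dropouts are bridged by linear interpolation
before parsing (configurable off); longer invalid runs and timestamp gaps
always split windows. The test suite checks the implementation against an
independent exhaustive-window oracle on hundreds of random traces, plus
translation invariance and maximality.

# Trial validity and inclusion

A test trial is *valid* when at least 50% of the valid samples in the 100 ms
before image onset fall in the centre AOI ("centred just before onset"; the
window and threshold are configurable — 100 ms is one fixation-length of
evidence). Infants enter the analysis with at least 5 valid trials of 16.
Fussiness exclusion is an input flag (from the simulator's ground truth or
session metadata), never inferred from gaze. Familiarization engagement
(TLT-pct) uses the full stream duration as denominator by default, with
tracked-time available as an option.

# The data-driven analysis window

For each valid trial, the gaze is binarized every 20 ms from -500 to
4700 ms: 1 when the sample falls on either lateral image, 0 otherwise
(invalid samples count 0; the same isolated-dropout bridging used before
fixation parsing is applied first, since an isolated lost sample otherwise
vetoes the time point). The binary courses are averaged within infants, and
each time point is submitted to a right-tailed one-sample t-test of the
infant means against 0.98 at alpha = 0.01. Zero-variance columns have no t
statistic; they are significant iff their common mean exceeds 0.98 —
ceiling behaviour is exactly the phenomenon the procedure detects. The
analysis window runs from the earliest time t >= 0 with sustained
significance through 4700 ms (a transient-tolerance parameter, default 0,
can bridge isolated dips). Pre-onset points are tested but the window start
is restricted to t >= 0, and a sustained stretch narrower than one fixation
(100 ms) is reported as no-window — the fixation-based metrics cannot be
computed inside it.

The 0.98 criterion is deliberately implemented exactly as specified even
though it is strict for proportions: a time point only passes when
essentially *every* valid trial of *every* infant is lateralized there. One
non-lateral sample in one trial of an infant contributing few trials can
veto a time point. Consequently a sustained window exists only in the
ceiling regime — gaze glued to the images after lateralizing, negligible
track loss. When no sustained window exists, `analyze_experiment()` falls
back (flagged) to the full 0-4700 ms interval so the metrics remain
defined; `mu0` is configurable for sensitivity analyses.

Whether the original timecourse was computed from raw samples or from
parsed fixations is ambiguous; the package uses raw samples by default and
exposes `timecourse_source = "fixations"`, in which time points are covered
by lateral fixations (including gaps between two lateral fixations, i.e.
gaze in transit between the images). Metrics always use fixations.

# Looking-time metrics and inference

Within the analysis window, each valid trial yields: **TLT** (summed
fixation time per lateral image, clipped to the window), **LF** (longest
single clipped fixation per image), and **FG** (whether the first lateral
fixation beginning at or after the window start is on the correct image).
The proportions `TLT-p = TLT_correct / (TLT_correct + TLT_incorrect)` and
`LF-p` are undefined (NA) when their denominator is zero; the accuracies
binarize the proportions per trial (ties NA). Metrics are computed per trial
and averaged per infant; group tests run on infant means (trial-level
pooling would inflate the degrees of freedom, and the reported group dfs of
n - 1 force this aggregation order). Per-infant binarization of accuracy is
available as an alternative through the trial metrics table.

Group inference per experiment: paired t (TLT correct vs incorrect) and
two-sided one-sample t-tests against 0.5 for TLT-p, TLT-acc, LF-p, LF-acc
and FG, each with Cohen's d. The one-sample d is `(mean - 0.5)/sd = t/sqrt(n)`
(this identity reproduces printed (t, d) pairs such as t = 2.389, n = 23 ->
d = 0.50). For the paired d, the mean difference over the SD of differences
is the default, with the averaged-SD variant available — published paired
effect sizes in this paradigm do not always correspond to a unique
convention, so both are provided and neither is asserted. Cross-experiment:
two-way between-subjects ANOVA (phonemic cue x word type) with Type-II sums
of squares (the appropriate convention for unbalanced cohorts; Type-III via
`ss_type = 3`) and partial eta squared `SS_effect / (SS_effect + SS_error)`;
ANCOVA with age; Pearson correlations of metrics with age, engagement and
valid-trial counts; Holm correction by default for families of tests;
Shapiro-Wilk recorded as a diagnostic only. All p values are two-sided
except the pointwise window test, which the procedure defines as
right-tailed.

Degenerate inputs are explicit errors rather than silent conventions: zero
variance stops the t-tests, an empty design cell stops the ANOVA, a constant
covariate drops the ANCOVA to the ANOVA with a warning, and an all-identical
response reports F = 0 throughout.

# The gaze simulator

Because raw infant gaze recordings in this paradigm are generally not
deposited, the package ships a generative stand-in that makes every
downstream stage testable against known ground truth. It emulates a 50 Hz
remote tracker on a 1024 x 768 screen: binocular-averaged samples every
20 ms, invalid samples emitted (not dropped), coordinates clamped to the
screen.

**Preference acts on look episodes, not samples.** A simulated valid trial
starts centred, departs after a lognormal latency, and then produces
lateral look episodes with lognormal durations; each episode targets the
correct image with probability `preference_theta` (0.5 = null). Episode
boundaries re-orient with probability `refixation_rate` (drawing a fresh
side), return briefly to the centre with probability `p_center_return`, and
otherwise re-fixate the same image. Sample-level Bernoulli noise would
average out within trials and inflate apparent power; episode-level
preference reproduces the autocorrelated structure of real gaze. Because
episode sides are drawn independently of episode durations, the expected
TLT-p of a trial equals theta exactly, which is what the parameter-recovery
tests check.

Defaults are chosen once to emulate the descriptive statistics of
8-month-old cohorts in this paradigm: `p_invalid_trial = 0.45` (about
9 +/- 3 valid trials of 16), `engagement_familiarization = 0.70` and
`p_eyes_region = 0.90` (engagement near 65-78% with gaze concentrated on
the eyes), latency median 700 ms (`sdlog` 0.25, placing the cohort's
slowest lateralization in the 1.1-1.5 s range where data-driven windows
start), look episodes with median 1.8 s, 2% isolated sample loss, 40 ms
saccade transits, episode centroids jittered 15 px around the AOI centre
with 3 px within-episode noise, and 17% mid-session fussiness attrition
(truncated recordings flagged for exclusion). `p_center_return` defaults to
0: within valid trials of this paradigm, post-lateralization gaze must be
essentially glued to the images for the strict 0.98 window criterion ever
to pass, and that is the regime the defaults reproduce. All parameters are
exposed per infant through `infant_profile()`.

Familiarization gaze alternates on-stimulus episodes (eyes or mouth) with
off-stimulus episodes whose durations are scaled by `(1 - e)/e` around the
engagement target `e`, so realized engagement tracks the target tightly
rather than drifting with episode-level variance; off-stimulus episodes are
background looks or tracking loss with equal probability.

**What the simulator does not model:** pupilometry, binocular disparity,
smooth pursuit of the moving video stimuli, head-movement-driven track-loss
dynamics (loss is i.i.d. per sample), drift or calibration error, and any
real latency/duration distributions of a specific cohort — the lognormal
defaults are literature-typical assumptions. Passing calibration tests on
simulated cohorts therefore validates the pipeline's statistical behaviour
under the generative model, not claims about any real dataset.

# Numerical and design choices

* **Half-open AOI rectangles** make boundary assignment unambiguous.
* **Fixation duration** is `n_samples x 20 ms` (each sample stands for one
  frame), so onset/offset grids align with the sample grid.
* **Eulerian-circuit stream construction with circular TP counting** makes
  the designed probabilities exact for every seed (see above).
* **Trial sample times** are stored as absolute time within the phase
  (trial k spans `[(k-1) x 5220, k x 5220)` ms), keeping recordings
  strictly time-ordered; an onset-relative `rel_ms` column is carried for
  analysis and reconstructed by `read_gaze_csv()`.
* **Windowing at the ceiling**: zero-variance columns decide by mean side;
  the sustained-significance rule takes the latest blocking run and starts
  after it; a window must reach 4700 ms.
* **Type-II sums of squares** for the unbalanced cross-experiment ANOVA;
  degenerate (zero-residual) fits fall back to sequential sums of squares
  with F coded 0 for zero-SS terms.
* **Problem sizes in the shipped tests**: calibration loops use 200
  replicate experiments of 23 infants and 16 trials each; the I-DT oracle
  comparison uses 100 random 600-sample traces; stream invariants are
  checked over 50 seeds.

# Known limitations

* The strict 0.98 pointwise criterion makes the data-driven window
  unavailable outside the ceiling-lateralization regime; the pipeline then
  analyses the full trial window and says so. This mirrors the procedure it
  implements rather than a preference of ours.
* Image-level TP balance is exact only when the repetition count is
  divisible by 4 (the default 24 is).
* The simulator's attrition model truncates at a uniformly random trial;
  real fussiness is likelier late in a session.
* No cluster-based correction across time points is applied in the window
  search (the procedure uses none), and no mixed-effects modelling of gaze
  is provided.
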