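---
title: "Hybrid-feature EEG stress detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-feature EEG stress detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstress)
```

## The problem and the pipeline

Self-assessed affect ratings let an EEG experiment label its own trials:
a trial watched in a calm state sits in a mid-valence, low-arousal region
of the rating plane, a stressed trial in a low-valence, high-arousal
region. The package implements a complete detection pipeline for such
data: strict-threshold annotation (calm: 4 < valence < 6 and arousal < 4;
stress: valence < 3 and arousal > 5, everything else dropped), per-channel
extraction of a 19-dimensional hybrid feature pool, all-relevant feature
ranking with shadow features, SMOTE class balancing, and k-NN
classification with cross-validated neighbourhood size.

The sampling unit is the **(trial, channel) pair**: a 32-channel trial
contributes 32 labeled 19-vectors, all carrying the trial's state. This
is the only reading under which a 60/40 split and 10-fold
cross-validation are meaningful for participants with as few as two
trials in a class, and it mirrors how per-channel features are used in
practice; its cost is that rows from the same trial are statistically
dependent, so split accuracies should be read as within-protocol scores,
not as estimates of generalization to new recording sessions.

Ratings are treated as continuous reals, the threshold inequalities as
strict exactly as written above; experiment ids are 1-based. Trials
whose participant shows only one state are excluded with the whole
participant, because a one-class dataset cannot be split or scored.

## The feature pool

**Time domain (F1–F11).** For a signal $x$ of length $N$ with population
moments ($\sigma^2 = \frac1N\sum(x_i-\bar x)^2$):

| | definition | | definition |
|---|---|---|---|
| F1 RMS | $\sqrt{\frac1N\sum x_i^2}$ | F6 kurtosis factor | $F4 / F1^4$ |
| F2 square mean root | $(\frac1N\sum\sqrt{|x_i|})^2$ | F7 shape factor | $F1 / \frac1N\sum|x_i|$ |
| F3 peak-to-peak | $\max|x| - \min|x|$ | F8 crest factor | $\max|x| / F1$ |
| F4 kurtosis | $\frac1N\sum(\frac{x_i-\bar x}{\sigma})^4$ | F9 impulse factor | $\max|x| / \frac1N\sum|x_i|$ |
| F5 skewness | $\frac1N\sum(\frac{x_i-\bar x}{\sigma})^3$ | | |

F10 is Hjorth mobility $\sqrt{\mathrm{var}(x')/\mathrm{var}(x)}$ and F11
Hjorth complexity $\mathrm{mobility}(x')/\mathrm{mobility}(x)$, with $x'$
the plain first difference. Three conventions deserve a note because
published tables of these descriptors are frequently garbled and the
choices matter numerically:

- *Population (1/N) normalization* everywhere, matching the
  $\frac1N\sum$ form of the defining sums.
- *Mobility carries the square root*, the standard Hjorth definition;
  the variance ratio without the radical appears in some secondary
  sources but breaks the interpretation of mobility as a mean
  frequency. For a pure sinusoid of angular frequency $\omega$
  rad/sample, first-difference mobility is $2\sin(\omega/2)$, which the
  tests verify.
- *No sampling-rate scaling of the derivative*: F10 is in radians per
  sample and F11 is dimensionless, so $f_s$ cancels everywhere it could
  matter.

Note that F6 is **not** scale-invariant (it scales as $c^{-4}$ under
$x \to cx$) — this follows directly from its definition as
kurtosis/RMS⁴, and the property tests assert exactly that behaviour.

**Wavelet packets (F12–F19).** A level-5 discrete wavelet packet
transform with the Daubechies filter with 4 vanishing moments (db4,
8 taps) splits both branches recursively, giving bands of width
$(f_s/2)/2^L$ at level $L$. Nodes are indexed in *frequency order*: the
natural (Paley) index of frequency position $i$ is its binary-reflected
Gray code, the bookkeeping that undoes the band-order flips introduced
in every highpass branch. The five packets used are θ 4–8 and α 8–12 Hz
(level 4), low β 14–16 Hz (level 5), high β 16–32 Hz (level 2) and
γ 32–40 Hz (level 3) — a mixed-level selection, since no single level
produces those widths. Delta (0–4 Hz) is excluded: 4–45 Hz bandpassed
input carries none.

Circular (periodized) convolution keeps the transform orthogonal at any
length divisible by $2^5$, which the Parseval test exploits: coefficient
energy equals signal energy to $10^{-8}$ relative error at every level.

From the five packets: F12 is the total coefficient energy and F13 the
population standard deviation of the concatenated coefficient vector;
F14 sums per-packet Shannon entropies (natural log) of the normalized
squared-coefficient distributions — zero for a one-hot packet,
$\ln n_i$ summed for flat ones; F15–F19 are per-band powers. Band power
is computed by reconstructing each packet alone back to signal length
(coefficients live at a decimated rate, so "power per Hz" is only
well-defined on a reconstruction), taking a Welch PSD — Hann window,
256-sample (2 s) segments, 50% overlap, mean averaging — and integrating
it over the packet's nominal band by the trapezoid rule. The Welch
parameters are fixed in `default_config()` because absolute PSD values
depend on them.

**A calibration worth knowing:** db4 packets are not brick-wall filters.
A sinusoid in the middle of a band keeps only ≈70% of its power inside
the nominal band after single-node reconstruction, and adjacent packets
exchange a few percent. The feature remains monotone in true band power
(which is all classification needs), but F15–F19 should not be read as
absolute physical band powers. For the same reason the per-band features
are *not* invariant under time reversal (the db4 filters are
asymmetric); only the total-pool energy and spread are approximately so,
and the tests assert exactly that.

## Feature ranking

The ranking wrapper extends the matrix with one row-shuffled *shadow*
copy of every feature, scores all columns with random-forest permutation
importance (per-tree out-of-bag accuracy loss under within-tree
permutation; $Z$ = mean loss / SD of losses across trees, 0 when the SD
is 0), and grants a feature a hit when its $Z$ beats the best shadow
$Z$. Shadows are re-shuffled fresh in each of the 20 iterations. A
single importance scale is used for originals and shadows — descriptions
that mix impurity importance for shadows with permutation $Z$ for
originals make the comparison incoherent, so the canonical
permutation-$Z$-for-everything form is implemented, with an impurity
(MDI) engine available behind the same interface for comparison
experiments. After the loop, hit counts face one-sided binomial tests
against Binomial(20, ½) at α = 0.05: significantly above half confirms,
significantly below rejects, the rest stay tentative. Tentative features
are reported but **excluded** from the selected set; with 20 iterations
the confirmation threshold is ≥ 15 hits. The forest uses 100 trees and
√p variables per split.

These are *all-relevant* semantics: a duplicated informative feature
does not doom its twin, unlike minimal-optimal selectors — one property
test checks precisely this.

## Balancing, classification, evaluation

SMOTE interpolates synthetic minority rows $x_i + u(x_{nn} - x_i)$,
$u \sim U(0,1)$, between a minority row and one of its $k = 5$ nearest
minority neighbours (the neighbour count of the original SMOTE
formulation), until the classes balance. Synthetic rows therefore lie on
minority-pair segments inside the minority convex hull; majority rows
are never touched. By default balancing happens **after** the split, on
training rows only — balancing before the split leaks synthetic copies
of test information into training; `smote$before_split = TRUE`
reproduces the literal protocol of balancing the whole dataset first.

k-NN uses plain Euclidean distance on z-scored features
(standardization uses training-split statistics; without it the
wavelet-energy scales dwarf the dimensionless shape factors in the
distance). Both tie-breaks are fixed deterministically: a distance tie
at the k-th position keeps the lower row index, a vote tie takes the
class of the single nearest neighbour. k is chosen from the odd
candidates {1, 3, …, 19} by stratified 10-fold cross-validation,
minimizing mean misclassification error with ties to the smallest k.
Tuning runs on the training split by default; `knn$tune_on_test =
TRUE` tunes on the test split instead, reproducing the published wording
(which tunes on test data — kept available for fidelity, not as a
default). Reported metrics are the class-wise accuracy TP/(TP+FP) with
each class in turn as positive — formally a precision; the standard
recall is emitted alongside since the published formula is ambiguous
about intent — and the average accuracy (TP+TN)/total, both as
percentages. `one_way_anova()` wraps the classical fixed-effects F test
for the cross-method comparison.

## The synthetic generator

`synthetic_spec()` emulates the DEAP recording shape — 32 channels,
128 Hz, 63 s per trial including a 3-s baseline generated identically to
the body (the pipeline discards it anyway) — with one random-frequency,
random-phase oscillator per band (θ, α, low β, high β, γ) per channel
plus white Gaussian noise. Class structure enters through the band-power
profiles: calm trials default to alpha-dominant
(θ 1, α 2, β 0.4/0.4, γ 0.2), stress trials to beta/gamma-dominant
(θ 0.5, α 0.5, β 1.2/1.2, γ 0.8) — the classic relaxed-versus-aroused
spectral signature. Oscillator amplitude is $\sqrt{2p}$ so a relative
power $p$ is the oscillator's mean square. The default noise SD of 3
puts every oscillator well below the broadband floor (per-band SNR
0.02–0.2), chosen because noiseless defaults drive every classifier to
100% and make method comparisons degenerate — no real EEG study
saturates like that. Ratings are drawn uniformly inside the open
threshold region of the generating state, so relabeling recovers the
states exactly; stress counts are `round(balance × n_trials)` clamped to
keep both classes present.

What the generator deliberately does **not** emulate: 1/f background
spectra, event-related potentials, artifacts, inter-channel correlation
and volume conduction, non-stationarity. Passing tests therefore show
that the pipeline recovers *band-power class structure under heavy
stationary noise* — the mechanism the method is built on — not that it
attains any particular accuracy on real recordings.

## Problem sizes and numerical choices

The test and reproduction runs use scaled-down studies (4–8 channels,
5–9 s trials, 12–20 trials) so a full suite finishes in about a minute;
signal lengths are kept divisible by $2^5$ as the periodized tree
requires. Degenerate inputs are defined and handled explicitly: constant
signals (or constant first differences) raise degenerate-signal errors
and are skipped per channel during extraction with a counted warning; a
class losing all rows is a dataset error; zero importance-SD gives
Z = 0; an all-zero packet contributes zero entropy; a never-predicted
class yields an NA class-wise accuracy rather than an exception; a zero
within-group ANOVA variance reports an infinite F.

Known limitations: per-(trial, channel) sampling inflates split scores
relative to trial-level splits (rows of one trial are near-duplicates
across the split boundary); the db4 band powers are relative, not
absolute; ranking before a small test split can be optimistic when run
with `before_split` fidelity options; and k-NN is O(n²), entirely
adequate at these dataset sizes but not for merged studies orders of
magnitude larger.
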