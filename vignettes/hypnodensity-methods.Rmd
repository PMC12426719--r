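---
title: "Hypnodensity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypnodensity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnodense)
```

## The problem

Automated sleep-stage classifiers emit, per 30-s epoch, a probability
distribution over the sleep stages (the *hypnodensity*); the familiar
hypnogram is its argmax trace. Two summaries of that distribution carry
information the hypnogram cannot: how spread out the distribution is
(scoring *ambiguity*), and how much it moves across a stage transition
(*transition continuity*). This package computes those summaries
together with the conventional hypnogram measures (bouts, agreement
with a reference scorer) and a group-comparison layer, and ships a
synthetic cohort generator so that the full pipeline is testable
without access-restricted polysomnography.

## The measures and their conventions

**Ambiguity.** $A(p) = -\frac{1}{\log K}\sum_i p_i \log p_i$ with
$0\log 0 = 0$. Conventions:

* Natural logarithms in both the sum and the normaliser. The value is
  base-invariant as long as the two match; fixing one base prevents
  mixed-base bugs, and a property test checks invariance explicitly.
* $K$ is the size of the declared stage set (4 after merging N1 and
  N2); the function accepts any $K \ge 2$.
* Useful anchors at $K = 4$: the maximum over vectors with at most two
  non-zero entries is exactly $0.5$ (two-point uniform), and over three
  non-zero entries $\log 3 / \log 4 \approx 0.79$. Observed values
  above those thresholds therefore certify that probability was spread
  over at least three, respectively four, stages.

**Transition continuity.** $C = 1 - \frac{1}{2}\sum_i |p_i^{t} -
p_i^{t+1}|$, i.e. one minus the total-variation distance between the
two epochs flanking the transition boundary. The flanking epochs are
$t$ and $t+1$ — the epochs immediately before and after the boundary,
matching the formula's superscripts — not $t-1$ and $t+1$. Continuity
is only evaluated at transitions of the *same* classifier's hypnogram,
never at the reference scorer's transitions.

**Stage attribution.** Stage-specific ambiguity summaries group epochs
by the stage the same classifier assigned (its own hypnogram, by
default the argmax trace), never by the manual staging. This keeps the
conditioning variable and the probability vector from the same model.

**Bouts.** Run-length encoding of the hypnogram; durations in minutes.
The censored runs at recording start and end are kept by default (total
bout time then equals recording time, a tested conservation law); a
`drop_edges` flag removes them.

**Argmax tie-breaking.** Exact ties go to the earlier stage in the
declared stage-set order (W over N1+N2 over N3 over R). Classifiers
that resolve epochs through an undisclosed internal hierarchy can
supply their own hypnogram next to the hypnodensity; every analysis
function accepts an explicit staging, so both conventions can be
analysed. Collapsing 5-stage to 4-stage commutes with the argmax
*except* when the merged N1+N2 column overtakes the 5-stage winner; a
property test checks that exception condition exactly.

**Agreement.** Cohen's kappa is computed per subject and summarised as
mean ± SD across subjects (pooled-epoch kappa is a one-liner on the
stored confusion matrices if wanted). Per-class scores follow explicit
boundary conventions: a stage absent from both scorers is undefined
(`NA`), not 0; a stage present in the reference but never predicted has
sensitivity 0, undefined PPV, and F1 = 0. Short synthetic records would
otherwise fabricate performance for stages they never contain.

## The statistical layer

* **Mann-Whitney U**, two-sided. Exact permutation distribution when
  $n_1 + n_2 \le 12$ and the data are tie-free, otherwise the normal
  approximation with continuity and tie corrections. The reported
  statistic is $U = \#\{x > y\} + \frac12\#\{x = y\}$; the effect size
  is the rank-biserial correlation $|1 - 2U/(n_1 n_2)|$ (the signed
  value is kept alongside). If every observation in both samples is
  identical the test is declared uninformative ($p = 1$, $r = 0$)
  rather than NaN.
* **t-tests** for kappa: Welch's unequal-variance form by default —
  only "t-test" is conventionally specified in this literature and
  Welch is the safer default — with Student's form behind a flag.
* **Friedman test** across $k \ge 3$ scoring methods on matched blocks.
  Blocks are subjects, the blocked value is the subject's median bout
  duration under each method: bouts themselves are not matched across
  methods (methods disagree about how many bouts exist), so a literal
  Friedman on pooled bouts is ill-defined. Post-hoc method pairs use U
  tests on the pooled aggregated durations, which is how published
  analyses report them. The effect size is the Kendall's-W style
  $\eta^2 = H/(n(k-1))$ (1 under perfect concordance); conventions for
  a Friedman effect size differ across the literature, so the choice is
  documented rather than assumed. Fully tied blocks yield $H = 0$,
  $p = 1$.
* **Benjamini-Hochberg.** One joint family across all stages of a run:
  sort ascending, $\tilde p_{(i)} = p_{(i)} m / i$, running minimum
  from the largest rank down, cap at 1, significant at adjusted
  $p \le$ FDR (default 10%). A per-stage family is a matter of slicing
  the returned table.

### Units of analysis and calibration

Epoch-level quantities are autocorrelated within a subject (stages
persist for whole bouts), so rank tests on pooled epochs overstate
their effective sample size. The config therefore has a `pooling`
switch:

* `per_subject` (default): each subject is reduced to a median before
  the rank test, so the test compares independent units. Under a null
  cohort (both groups simulated from one profile) the group-contrast
  tests are then calibrated — the acceptance suite checks a raw type-I
  rate near 0.05 and a BH-significant fraction within its FDR bound
  over 50 seeds.
* `pooled_epochs`: every epoch/bout/transition enters the test,
  reproducing the pooled design of published hypnodensity analyses. In
  a pilot under the null this inflated the BH-significant fraction of
  group contrasts to roughly 27%, which is exactly the pseudo-
  replication caveat one should keep in mind when reading pooled
  designs.

Summary tables (medians, IQRs, tail fractions) always pool across
subjects, as published tables do; the switch affects only what the
tests consume. Note that in a "null cohort" only the *group* contrasts
are null: contrasts between scoring methods differ by construction and
are expected to be significant.

## The synthetic cohort generator

The generator's purpose is directional and property testing, not
physiological realism; it makes no attempt to fit any clinical
distribution.

* **Stage dynamics**: first-order Markov chain over (W, N1+N2, N3, R),
  started in W. Bout lengths are geometric with mean
  $1/(1-\text{diagonal})$ epochs — the simplest process with
  controllable run lengths. Real sleep has time-of-night structure
  (sleep cycles, REM periodicity) that this deliberately lacks.
* **Hypnodensity rows**: Dirichlet draws with
  $\alpha = c \cdot \text{onehot(true stage)} + 1$, where $c$ is the
  profile's `concentration`. The unit pseudo-count floor keeps every
  stage's expected probability positive and lets genuinely ambiguous
  epochs occur at low $c$. Under this parameterisation the expected
  ambiguity is *strictly decreasing* in $c$ (closed form:
  $E[H] = \psi(\alpha_0+1) - \sum_i \frac{\alpha_i}{\alpha_0}
  \psi(\alpha_i+1)$, normalised $\approx$ 0.78, 0.70, 0.48, 0.25, 0.07
  at $c$ = 1, 3, 10, 30, 100), which the tests verify by simulation.
  The superficially natural alternative — scaling a fixed mean vector,
  $\alpha = c \cdot m$ — behaves the other way around (higher $c$ pulls
  draws toward the fixed, non-degenerate mean and *raises* expected
  entropy toward $H(m)$, while small $c$ concentrates draws on simplex
  vertices), so it cannot serve as an "uncertainty" knob.
* **REM leakage** (`rem_leak`, default 0.35 for the RBD-like preset,
  0.05 for the OSA-like one): on true-REM epochs, that fraction of the
  drawn REM probability moves to N1+N2 and W in a 2:1 split — the
  dominant REM-to-light-sleep confusion direction reported for RBD,
  with a secondary wake component. This raises REM-epoch ambiguity,
  lowers REM sensitivity and kappa, and sends the lost epochs
  predominantly to N1+N2; all three consequences are tested.
* **Crossfade** (`crossfade_epochs`, RBD-like 2, OSA-like 1): within
  that many epochs of a stage boundary the row is replaced by the
  linear blend of the two flanking stages' target distributions (each
  epoch claimed by its nearest boundary), so probability mass drifts
  across the transition. Boundary continuity is then
  $1 - \mathrm{TV}(m_{\text{from}}, m_{\text{to}})/(2w+1)$, increasing
  in $w$. Because blended epochs are deterministic, continuity at true
  boundaries is nearly point-massed per stage pair — visible as tiny
  IQRs — which real classifiers would smear out. Spurious
  (noise-driven) argmax transitions away from true boundaries provide
  the low-continuity tail.
* **Manual scorer** (`manual_noise`, 0.08 in both presets): per epoch,
  that probability of replacing the true stage by a draw from a
  confusion kernel (default uniform over the other stages). Both
  presets share it so agreement contrasts are driven by the
  hypnodensity structure, not by scorer quality.
* **Methods**: the cohort simulator derives an `exg`-like method (full
  concentration and crossfade) and an `hrvm`-like one (40% of the
  concentration, one epoch less crossfade) from each group profile —
  surrogate cardiorespiratory signals carry less stage information, so
  their classifier is noisier across the board. Concentration is a
  *method* attribute; both group presets share concentration 8, and the
  group contrasts ride exclusively on `rem_leak`, `crossfade_epochs`
  and the fragmentation of the transition matrix. (An early draft gave
  the groups different concentrations; the extra spurious transitions
  in the low-concentration group then worked against the crossfade
  contrast, an instructive confound.)
* **Reproducibility**: one global seed is expanded into per-subject,
  per-component 32-bit substreams (component codes: 1 truth chain, 2
  manual scorer, 3 metadata, 10+j method hypnodensities), so cohorts
  are identical across runs and platforms and individual records can be
  regenerated in isolation. The simulators save and restore the
  caller's RNG state.

What a green directional test establishes: that the analysis pipeline
recovers the directions built into the generator (lower kappa, lower
REM F1, higher REM ambiguity, higher continuity in the RBD-like group).
It does *not* establish anything about effect magnitudes in clinical
data, which come from an access-restricted population this package does
not model.

## Numerical and I/O choices

* Probability rows must sum to 1: deviations $\le 10^{-6}$ are
  renormalised silently (CSV rounding), deviations in
  $(10^{-6}, 10^{-3}]$ renormalised with a warning, larger ones
  rejected as corrupt. Validation tolerance inside the metric functions
  is $10^{-6}$.
* Stagings of unequal length within a subject are truncated to the
  common minimum with a message (concurrent recordings can differ by
  trailing epochs); hypnogram/hypnodensity length mismatches within one
  method are errors.
* Epoch duration defaults to 30 s and is configurable; bout durations
  are reported in minutes.
* Tail fractions use strict inequalities (continuity $< 0.05$,
  $> 0.95$) and are an error, not 0, on an empty transition list.
* Degenerate inputs: kappa is `NA` when the margins force agreement
  ($p_e = 1$); constant hypnograms produce one bout, no transitions,
  and a logged skip of the continuity analysis.
* Report tables are written with deterministic column and row order so
  reruns are diffable; cohort manifests are JSON (no YAML parser in the
  supported dependency set).

## Known limitations

* The Markov/Dirichlet generator has no subject-level random effects,
  no sleep-cycle structure, and point-massed boundary continuity; it is
  an operational stand-in for testing, not a model of sleep.
* Pooled-epoch mode is provided for comparability but is known to be
  anti-conservative; see the calibration discussion above.
* The Friedman effect-size convention and the exact composition of the
  BH family are documented choices; other packages may slice either
  differently.
* Only two-group designs get automatic group contrasts; multi-group
  cohorts still produce all tables but no pairwise test inventory.
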