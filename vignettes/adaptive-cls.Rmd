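---
title: "Adaptive categorical loudness scaling by maximum expected information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive categorical loudness scaling by maximum expected information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsmei)
```

## The measurement and the model

Categorical loudness scaling (CLS) asks a listener to judge tones on an
ordered 11-category scale, coded 0–50 CU in steps of 5, across levels
from 0 to 110 dB SPL. `clsmei` models a listener as a multi-category
psychometric function (MCPF): ten logistic boundary functions
$\Psi_k(L) = [1 + \exp(-(L - L_k)/w_k)]^{-1}$, where $\Psi_k$ is the
probability of responding at least CU $5k$, $L_k$ the 50% point and
$w_k$ the width. Category probabilities are the differences
$P(\mathrm{CU}=5j\mid L) = \Psi_j(L) - \Psi_{j+1}(L)$ (with
$\Psi_0 \equiv 1$, $\Psi_{11} \equiv 0$), so they sum to one exactly and
are non-negative whenever the boundaries do not cross.

The key assumptions are: (1) responses at different levels are
conditionally independent given the MCPF — listeners are memoryless;
(2) the boundary kernels are logistic, which makes the 50% point of each
boundary the natural level estimate for the corresponding CU, so the
CLS function of a fitted entry is exactly its boundary-level vector; and
(3) the listener is adequately described by *some* entry of a finite
catalog, the hypothesis space for all Bayesian computations. Assumption
(3) is the interesting one: the package's simulation machinery exists
largely to probe what happens when it holds (`from_catalog` listeners)
and when it does not (`perturbed` listeners).

Only the logistic kernel is implemented; the validation and probability
machinery would accept other sigmoid kernels, but none is in scope.

## Bayesian tracking and MEI selection

Before the first trial every catalog entry is equally likely, so the
posterior entropy is $\log_2 N$ bits. Each trial multiplies the
posterior by the entry-wise likelihood of the observed category at the
presented level and renormalises. The maximum-expected-information (MEI)
rule scores every admissible candidate level by the expected entropy of
the updated posterior, enumerating all 11 possible responses exactly
(no sampling — at 11 categories by at most 23 grid levels the exact sum
is trivially cheap), and presents the minimiser.

Numerical choices:

* **Likelihood floor** $\varepsilon = 10^{-6}$: a single lapse response
  would otherwise zero an entry permanently and make maximum-likelihood
  fitting brittle. The floor is applied consistently in posterior
  updates, predictive distributions, expected-entropy scoring and ML
  fitting, which preserves the "information never hurts" inequality
  $E[H \mid \ell] \le H$ exactly (both sides live on the same floored
  channel).
* **Tie-break at the lowest level.** With a point-mass posterior every
  candidate ties at zero expected entropy; the lowest level is chosen,
  favouring listener comfort. Ties are detected with a $10^{-12}$-bit
  tolerance.
* **Candidate set**: the 5-dB grid inside the *current run's* limits,
  not the full instrument range — consistent with the procedures'
  avoidance of uncomfortably loud presentations. Transitions are capped
  at 45 dB and immediate repeats are forbidden; both rules are exposed
  as `selection_constraints()` fields, and the repeat rule defaults on
  for MEI even though the source procedures state it only for the
  fixed-level order.
* The posterior is carried **across** the five runs of a session, not
  reset per run: a session is one track.
* Each run consists of nine *trials*; distinctness of the nine levels is
  not enforced (the MEI criterion may legitimately revisit a level after
  an informative response elsewhere).

## Session structure

All procedures begin with a dynamic-range pre-phase: interleaved
ascending/descending sequences (ascending first), both starting at 60 dB
SPL in 10-dB steps — values chosen for symmetry and speed and exposed as
arguments. The upper end is the last ascending level not judged "Too
Loud" (capped at 110), the lower end the last audible descending level
(floored at 0, with a fallback to the first audible ascending level when
the start is inaudible). The adaptive trackers then run 5 runs × 9
trials: slope-adaptive presents nine evenly spaced levels per run in
seeded random order (the source procedures do not state an order;
randomisation avoids systematic sweep bias), MEI selects each level as
above starting from the grid midpoint of the dynamic range, and the
uniform-random (URD) comparison tracker draws each level uniformly from
the in-limit grid. After any run containing a "Too Loud" response the
upper limit drops 5 dB (guarded to stay above the lower limit); after a
run with none it rises 5 dB, never beyond 110 dB SPL. The fixed-level
reference presents every 5-dB grid level in the dynamic range ten times
in a randomised order with no immediate repeats and jumps of at most
45 dB; the order is built by sequential random choice with restarts,
which comfortably succeeds for every feasible range.

## Estimating the CLS function

Two estimators operate on a session log. `median_cls()` takes the median
presented level per CU (midpoint convention for even counts — the
sources are silent, and the midpoint is the standard sample median),
removes no outliers, leaves unused categories missing, and flags CU 0
and 50 as excluded: their level sets are unbounded (any level above a
"Too Loud" judgement would also be "Too Loud"). `ml_cls()` picks the
catalog entry with the highest summed log-likelihood (ties to the lowest
index) and reads the CLS function off its boundary levels, which smooths
estimates across categories the listener never used; the CU 50 boundary
is retained structurally but flagged out of analyses like the median
method's extremes. Threshold is the level at 2.5 CU — midway between
"Can't Hear" and "Very Soft", i.e. audible half the time — from ordinary
least squares on the CU ≤ 20 points, falling back to the lowest
estimated level when fewer than two such points exist. CU-to-phon
conversion is a pluggable monotone anchor table with linear
interpolation; the packaged default (`phon = 2.2 CU`, id
`synthetic-linear-2.2`) is an explicitly synthetic placeholder — swap in
a published conversion for real analyses; every converted function
carries its map id.

## The synthetic catalog generator

No empirical MCPF catalog is distributed, so `generate_catalog()`
synthesises one: per entry it samples the CU-5 boundary $L_1$ (default
0–60 dB SPL, normal hearing through moderate loss), the CU-50 boundary
$L_{10}$ (85–110 dB SPL) subject to a minimum dynamic range (30 dB), and
places the interior boundaries on a two-segment bent line whose bend
grows with threshold elevation: severity is $(L_1 - 20)/60$ clamped to
$[0,1]$ — an absolute audiological scale, so a population generated with
normal-hearing thresholds is straight regardless of the configured
range. Higher severity compresses the below-knee segment, giving
recruitment-like steep growth just above threshold and the reduced
dynamic range characteristic of sensorineural loss. Each entry uses a
common boundary width (3–10 dB, capped at a third of the tightest
boundary gap): ordered logistics with a shared width can never cross, so
category probabilities are exactly non-negative; per-boundary widths
remain supported by the `mcpf` class and are validated on a 1-dB grid at
construction. The default size, 1460 entries, matches the scale of the
empirical catalog this generator stands in for.

What the generator does *not* emulate: sequence effects (assimilation
toward the previous level after large transitions), lapses and
finger-errors beyond what the logistic tails produce, frequency
dependence beyond a label, and any empirical joint distribution of
threshold, width and shape. Tests passing on this population therefore
certify the algorithms — posterior arithmetic, entropy accounting,
selection logic, estimator behaviour — not the clinical performance of
MEI on human listeners.

## The simulation study

`run_simulation_study()` draws stochastic listeners (each with a private
seeded response stream), runs each through the MEI and URD trackers
(fresh response stream per track, so the trackers see independent
sessions of the same listener), and records after every trial the
posterior entropy and the rmse between the running ML-CLS estimate and
the listener's true boundary levels over CU 5–45, in dB — the rmse
domain is a package decision recorded in the result's metadata. The
pre-phase uses the stochastic listener itself; in the rare degenerate
case (a near-threshold listener answering "Can't Hear" at every probe)
the true boundary span widened by 5 dB is used instead.

Scales used by the shipped tests: the tracker-comparison test runs 200
from-catalog listeners on the full 1460-entry default catalog (about
90 s); module tests use catalogs of 2–50 entries where the brute-force
MEI oracle (explicit triple loop over levels, responses and entries)
stays exact and instant. The directional claim asserted is that MEI's
mean final entropy is below URD's; no direction is asserted for rmse —
separating those two outcomes is precisely what the study design is for,
since an entropy-optimal probe sequence need not minimise the error of
the fitted loudness function when the catalog's entries are themselves
close in function space.

## Known limitations

* Simulated listeners are memoryless; context and bias effects of large
  level transitions are acknowledged but not modelled, so the 45-dB
  transition cap is a constraint on the selector, not a behavioural
  model.
* The catalog generator is synthetic; fitting a catalog from human
  trial data is out of scope.
* The phon conversion default is a labelled synthetic placeholder.
* Boundary kernels are logistic only.
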