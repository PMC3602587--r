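---
title: "Companion-effector combination screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Companion-effector combination screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectorscreen)
```

## The screening design

A companion-effector screen tests a compound library twice under otherwise
identical conditions: once with and once without a co-applied bait compound
(the *effector*) — here a resveratrol-like nutraceutical dosed at a working
concentration that alone reduces viability by roughly half. Compounds whose
potency the effector *increases* are agonist candidates (potential
combination-therapy partners); compounds it *decreases* are antagonists
(potential drug–supplement interactions). Both directions are scientifically
interesting, and the pipeline treats them symmetrically.

The package implements the full analysis chain: assay-development QC,
primary-screen normalization and dual-condition selection, censored
four-parameter logistic (4PL) dose–response confirmation, and cell-line
panel profiling, with a synthetic-data layer that plants known truth under
every stage.

## Normalization and its assumptions

Percent inhibition anchors each read to the plate set's own controls,

$$\%I = \frac{\mu_{high} - read}{\mu_{high} - \mu_{low}} \times 100,$$

where the high control is vehicle-only and the low control a full-kill
treatment. Two consequences matter. First, %I is invariant under any affine
rescaling of the raw signal, so gain settings and plate-to-plate offsets
cancel (`percent_inhibition()` and `zprime()` both carry property tests for
this). Second, controls must come from the condition being normalized: the
effector itself depresses the vehicle signal (S/N drops from about 10:1 to
about 3:1 in the co-treated condition), so normalizing effector-treated
wells against effector-free controls would misstate inhibition by tens of
points. Cross-condition normalization is available only as an explicit
diagnostic. %I is never clipped; values below 0 (growth stimulation) and
above 100 are retained.

## QC statistics and gates

- **Z′-factor** `1 − 3(σ_h + σ_l)/|μ_h − μ_l|`, computed from pooled
  control wells with sample (n−1) SDs. The robustness gate is *strict*
  (`Z′ > 0.5`); narrative bands follow common HTS practice (> 0.7 excellent,
  0.5–0.7 good, otherwise poor). A failing condition is flagged, not fatal:
  a real campaign proceeded with a weak co-treated condition by shifting the
  primary selection onto the cleaner cell line, and `run_analyze()`
  preserves that behaviour (warning + flagged outputs, analysis continues).
- **Growth linearity.** Per seeding density, a least-squares line of signal
  against time; linear means R² ≥ 0.95 (the design constraint is "linear
  conversion over the incubation window", stated without a numeric
  criterion; 0.95 over ≥3 timepoints is this package's operationalization).
  Among linear densities the one maximizing the signal window (signal gain
  between first timepoint and horizon) is selected — wider windows resolve
  inhibition better.
- **Solubility limit.** Threshold = buffer baseline mean + 3 SD (with the
  canonical baseline of 4 NTU and a 20 NTU threshold this implies a
  baseline SD of 16/3 NTU, which the turbidity generator reproduces
  exactly). The limit is the lowest tested concentration exceeding the
  threshold *with every higher concentration also exceeding it* — the
  sustained-crossing clause guards against single-well spikes, which the
  bare exceedance wording would not.
- **S/N** is the plain ratio of control means; reports round it to an
  integer "n:1" (9.73 prints as 10:1) but computation never rounds.

## Hit selection

With threshold *t* (default 50%I) and mean duplicate %I with (`p⁺`) and
without (`p⁻`) effector:

| class | rule |
|---|---|
| agonist candidate | `p⁺ ≥ t`, `p⁻ ≤ t`, `p⁺ > p⁻` |
| antagonist candidate | `p⁻ ≥ t`, `p⁺ ≤ t`, `p⁻ > p⁺` |
| active both | `p⁺ > t` and `p⁻ > t` |
| inactive | `p⁺ < t` and `p⁻ < t` |
| ambiguous | `p⁺ = p⁻ = t` |

The published selection wording ("≥ 50 with, ≤ 50 without") overlaps at
exactly 50; the strict ordering between conditions plus the `ambiguous` tie
class makes the five classes a partition, so no compound is simultaneously
agonist and antagonist. Duplicates are averaged before classification (an
optional strict mode requires each replicate to satisfy the rule alone).
Candidates survive cross-line refinement only with the same class in both
screening lines, then collapse to unique compounds by canonical name
(case-folded, whitespace-normalized — the deduplication is by identity
across suppliers, not by structure).

## Censored dose–response analysis

**Model.** `y(c) = bottom + (top − bottom)/(1 + (IC50/c)^hill)`, fitted to
replicate-averaged %I against log₁₀ concentration by bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`). Bounds: bottom ∈ [−20, 30],
top ∈ [30, 120], IC50 ∈ [lowest dose/4, 4 × top dose], hill ∈ (0, 10].
Initialization: bottom = min %I, top = max %I (clamped into bounds), IC50 at
the concentration nearest half-maximal response. Because a single LM start
can pin against a bound or meet a singular initial Jacobian, the fitter runs
a small start grid (hill ∈ {0.5, 1, 2, 4} × two asymptote initializations)
and keeps the lowest-SSE solution; on noise-free curves whose IC50 the
dilution series brackets this recovers IC50 to well under 1%.

**Partial curves.** A fit is partial if max observed %I < 65, or the
observed %I at the top dose differs from the fitted top by more than 5
percentage points (the plateau tolerance; the source protocol says "failed
to reach an asymptote" without a number). Partial fits keep their IC50 but
carry the flag — the asterisk of the published tables.

**Censoring.** If max observed %I < 50 (strictly) even at the top dose, no
meaningful IC50 exists and the result is `(">", limit)` with the limit
defaulting to the top tested concentration (100 µM in confirmation studies;
a 400 µM effector series uses its own top dose). Censored values are a
first-class type: they never enter averages, ratios with one censored
operand propagate a ">" qualifier, and double-censored ratios are
*indeterminate*, never silently 1.

**Fold shifts.** For reference (no effector) and treated values:
both exact gives magnitude `max(r, 1/r)`, `r = ref/treat`; a censored
treated value gives a `loss` lower bound `limit/ref`; a censored reference
gives a `gain` lower bound `limit/treat`; both censored is indeterminate.
When the exact operand already exceeds the censor limit the bound is vacuous
(< 1) and the shift is reported indeterminate with magnitude 1 rather than
a fabricated direction. Bounds are true lower bounds — substituting any
exact value beyond the limit can only increase the magnitude, a property
the tests verify by brute force. Magnitudes are reported unrounded; display
rounds to "n-fold" (24/8.6 = 2.79 prints as three-fold).

**Confirmation and panel rules.** A compound confirms as agonist
(antagonist) when any cell line shows a gain (loss) of ≥ 2-fold at the
80 µM working concentration, censored bounds counting when the bound itself
reaches the threshold. When different lines confirm opposite directions the
call follows the larger magnitude and the conflict is flagged — applied to
the bundled published viability table this flips one borderline compound
(an aurora-kinase inhibitor whose Y79 gain of 6.10 marginally exceeds its
RB355 loss of 6.0) relative to the original report, and the stated ≥2-fold
rule also admits one compound (a 2.46-fold loss) the original narrative did
not count; both are consequences of applying the stated rules to rounded
printed values, and the package reports the rule's output rather than
special-casing compounds. One published agonist call (budesonide) rests
entirely on censored entries and is not recoverable from any printed value;
under the package's algebra it is neutral. Panel confirmation requires ≥ 3
qualifying *non-retinoblastoma* lines at 30 or 80 µM — evidence that the
combination effect generalizes beyond the screening disease model.

## The synthetic-data layer

Generators produce every input with planted truth, under one global seed
fanned out to per-stage sub-seeds (`seed + stage ordinal`) so stages are
independently reproducible.

- **Noise model:** well-level multiplicative log-normal noise with stated
  CV (mean-preserving) plus an optional additive per-plate offset —
  fluorescence HTS noise scales with signal. Default CV 5%, a typical
  plate-reader figure; the calibrated robustness checks use 10%.
- **Screen:** 6,912 compounds in duplicate, two cell lines, effector at
  0/80 µM, 384-well plates with samples in columns 1–22 and 16 high/16 low
  controls in columns 23/24 (the real control layout is unpublished; this
  is a configurable assumption). Condition control means follow the
  published control run (e.g. 14,426/1,483 without effector, 8,065/2,557
  with, for the primary line), so the co-treated condition's narrower
  window is reproduced. Planted classes sit ≥ 15 percentage points from the
  50% threshold (88 agonists, 67 antagonists by default, matching the
  original campaign's initial-positive counts as generator parameters, not
  as recoverable results); zero-noise output is exactly classifiable by
  construction, which the end-to-end identity suite exploits.
- **Dose–response:** 4PL truths with base IC50 log-uniform in 2–40 µM and
  planted effector shifts (agonists gain 4-fold at 80 µM, antagonists lose
  8-fold), sampled over 12 doubling dilutions with Gaussian %I noise.
- **Turbidity / growth / images:** baseline readings constructed to
  reproduce the requested mean/SD pair exactly; linear-then-saturating
  growth with density-proportional slopes; Gaussian-profile nuclei with a
  controllable overlapping fraction (clumped pairs at 1.2 radii).

What the generators do *not* emulate: spatial plate artifacts (edge
effects, dispenser striping), compound autofluorescence and quenching,
carry-over, cytostatic-versus-cytotoxic response shapes, biphasic curves,
or microscope illumination gradients. Passing tests therefore demonstrate
the *analytics* are correct under the stated noise model, not that the
pipeline is robust to every real-plate pathology.

## Numerical choices and degenerate inputs

- Blank signal fields parse to missing, never 0 — 0 is a legal signal.
- Constant responses, all-censored evidence, flat growth curves and blank
  images return flagged results (`no_fit`, `indeterminate`, NA selections,
  count 0), not exceptions; genuinely contradictory inputs (equal control
  means, one-well control sets, oversubscribed planting) fail loudly.
- Segmentation uses Otsu on the max-normalized image (making counts
  invariant to exposure scaling), 8-connected components, minimum object
  area 4 px, and a distance-map watershed with seed separation 2 px and
  depth tolerance 0.5 px — touching round nuclei meet in a shallow saddle,
  so a deliberately small tolerance is needed to split pairs at 1.2 radii.
  The vendor software behind the original counts is proprietary; this
  pipeline is a transparent stand-in whose parameters are all exposed, and
  agreement is assessed against synthetic truth, not against the
  instrument.
- The turbidity generator snaps its planted limit to the lowest tested
  concentration at or above it: a dilution series can only localize a
  solubility limit to a tested dose, and the default design's top dose is
  chosen so the canonical 400 µM limit is itself a tested dilution.

## Problem sizes

The test suite and acceptance script run the screen at its full size
(6,912 compounds × 2 lines × 2 conditions × duplicate ≈ 55,000 sample
wells, simulated and analyzed in under a minute), 4PL recovery at 25
noise-free curves plus 500 Monte-Carlo fits at %I noise SD 5, selection
sensitivity on a 2,000-compound screen at 10% CV, and nuclei counting over
20 seeded images; these sizes give stable statistics while keeping a full
run in the low minutes on a single core.

## Known limitations

- Identity of compounds is name-based; structurally identical compounds
  registered under different names will not merge.
- The 4PL is the only response model; bell-shaped or biphasic responses
  will fit poorly and typically flag partial. Synergy reference models
  (Bliss, Loewe, Chou–Talalay) are out of scope by design — the
  classification here is threshold-based fold shift.
- Censored bounds below the threshold are conservative: a true ≥2-fold
  antagonist whose reference IC50 exceeds half the censor limit can never
  be confirmed from censored data.
- Confirmed calls depend on the censor limit: raising the top tested dose
  can convert censored bounds into exact values and change magnitudes.
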