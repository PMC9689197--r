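---
title: "The sitting-height multiplier method: model, derivation machinery, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sitting-height multiplier method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemult)
```

## The model

For a growing dimension measured at age $t$, the multiplier is

$$M(t, \text{sex}) = \frac{L_m}{L(t)},$$

the dimension at skeletal maturity divided by the dimension now. Predicted
mature value $= L(t) \times M$. The method's power comes from an empirical
regularity: within a sex, $M$ is almost independent of *where* in the height
distribution a child sits. A child tracking the 3rd percentile and one
tracking the 97th have nearly the same ratio of mature to current sitting
height, so one monthly table per sex covers all children, and predicting
growth needs one measurement and one multiplication — no percentile
assignment, no chart.

The packaged tables cover sitting height from 0y3m (no published values exist
at 0y1m and 0y2m; we treat those ages as below the domain rather than
extrapolating a multiplier above 2.3 into clinically consequential
territory). Maturity — $M = 1$ exactly — is 216 months for boys and 192 for
girls. Values are stored exactly as printed, to three decimals; lookups are
exact on the monthly grid and never interpolate, because the table is the
authority and the grid is complete. Decimal ages snap to the nearest month,
with an exact half-month tie going to the *younger* month: sub-month
precision in a clinical age is spurious, and when it matters at all the
younger month gives the more conservative (larger) growth-remaining figure.

Post-maturity ages are a policy question rather than a lookup question. The
library raises an error by default, so programmatic misuse cannot silently
return a number; the CLI clamps to $M = 1$ by default (with a `post_maturity`
flag in the record), because "no growth remains" is the clinically correct
answer to the common query. Both surfaces expose the other behaviour.

## The clinical formulas

All of the package's clinical operations are small algebra on $M$:

* mature sitting height $= S \times M$;
* growth remaining $G = L(M - 1)$, i.e. mature length minus current length;
* single-vertebra mature height $= L M / 5$ (lumbar) or $L M / 12$
  (thoracic), assuming each vertebra contributes an equal share of its
  segment's growth — exactly $1/5$ and $1/12$, with no per-level weighting;
* arthrodesis growth loss $= L(M-1)/\text{count} \times V_f$ for $V_f$ fused
  vertebrae, so fusing the whole segment forfeits exactly the segment's
  growth remaining.

One source formula prints growth remaining in a form, $M[L-1]$, that is
algebraically inconsistent with its own verbal definition and with the
per-vertebra expressions $L(M-1)/5$; we implement $G = L(M-1)$, which all
three agree on, and treat the printed form as a typographical slip. Likewise
the thoracic per-vertebra formula as printed names the lumbar length; the
operation takes the length of the segment it is asked about.

The thoracic and lumbar predictions use the sitting-height table: thoracic
and lumbar multipliers track sitting-height multipliers almost exactly.
Cervical multipliers do not (they are substantially higher, tracking
upper-extremity growth), so no cervical prediction is offered against the
packaged table; a user-supplied cervical multiplier table can be passed to
the same operations via `table =`.

Limb-lengthening planning in achondroplasia uses the adult Vitruvian
proportion — sitting height 53% of standing height, lower extremity 47% —
giving a target limb length of $47/53 \approx 88.6\%$ of predicted mature
sitting height. The constants are applied as exact rationals ($47/53$,
$100/53$); "88.6%" is display-only (note it is the *truncation* of
88.679... to one decimal, which is how the ratio is conventionally quoted;
the package renders it that way deliberately). This makes the closure
identities exact up to floating point: `h + limb_lengthening_target(h)`
equals `estimate_mature_standing_height(h)`.

For a planned arthrodesis, the age passed in is the age at which growth in
the fused levels stops; whether that is the age at surgery or a later planned
date is a scheduling question the caller owns — the operations deliberately
take a single age and no calendar.

## Deriving multipliers from a growth reference

`derive_multipliers()` inverts the definition on a percentile-structured
reference: for every (sex, percentile, age) record, $M = L_m / L$ with $L_m$
taken from the same percentile curve at the maturity age. Two consequences
are used as tests: the derivation is scale-invariant (multiplying a whole
curve by any constant cancels), and percentile curves that are exact scalar
multiples of each other produce identical multipliers — zero cross-percentile
variability.

**Variability.** The reported headline statistics for cross-percentile
agreement come without a printed definition in the source literature, so the
package defines one and documents it: at each (sex, age), the maximum
absolute deviation of the percentile multipliers from their unweighted
cross-percentile mean; summarized per sex (and pooled) by the unweighted mean
over ages and the maximum over ages. This choice is brute-force checkable,
reproduces the qualitative findings on SD-offset data (largest at the
youngest ages, shrinking toward maturity), and the full per-age series is
carried in the report so any alternative summary can be computed from it.
Whether the literature's pooled figure averages over ages, sexes, or both is
not stated; the report exposes per-sex and pooled values rather than
guessing.

**Comparison.** Two multiplier sets are compared through their mean
multiplier curves (unweighted means across percentile labels — no weights are
given in the source methodology) on the ages they share. Ages are matched
exactly by total months; we do not interpolate between age grids, which would
invent data. A least-squares polynomial with one set's curve as response and
the other's as predictor yields $R^2$ and residual RMSE; the raw maximum
absolute difference between the curves is reported alongside, pre-fit, so a
constant offset that the regression absorbs is still visible. The default
degree is 3 — the multiplier-vs-multiplier relationship between two sane
references is smooth and gently curved, and degree 3 is the smallest odd
degree that absorbs the mild S-shape around the pubertal spurt — but the CLI
makes the degree a required flag so published comparisons never hide a
default. Percentile labels are opaque strings throughout: references mix SD
labels and percentile labels, and nothing in the method needs an ordering.

## The synthetic reference generator

Testing derivation against real references would require redistributable raw
growth data; instead the generator constructs references with *exactly known*
multipliers by inverting a seed table: $L(t) = L_m / M(t)$. This is a design
choice over an independent parametric growth model (e.g.
infancy–childhood–puberty curves): inversion gives provable ground truth and
exercises the derivation inverse directly, at the cost of realism (see
limitations).

* **proportional** mode gives each percentile its own mature height; curves
  are scalar multiples, so true multipliers are identical across percentiles.
  This is the percentile-invariance ideal.
* **sd_offset** mode adds to the median curve a signed offset $k_p$ times a
  spread $s(t)$ that shrinks linearly in total months from `spread_at_birth`
  (default 3 cm) to `spread_at_maturity` (default 1 cm). True multipliers
  then genuinely differ across percentiles, most at the youngest ages —
  mimicking the pattern reported for real SD-line references. Note this
  construction is deliberately stylized: in real references the *absolute*
  spread grows with age while the *relative* spread behaves differently; the
  narrowing additive band is the simplest construction whose exact ground
  truth reproduces the qualitative variability-vs-age pattern.

Offsets default to evenly spaced values centered at 0 with unit step
(integers for an odd number of labels); the five default labels mirror the
−2.5/−1/0/+1/+2.5 SD lines of the most comprehensive published reference.
Default mature sitting heights are 92 cm (male) and 86 cm (female) at the
center — ordinary adult values — spread by $k_p \times$ `spread_at_maturity`.
Measurement noise is multiplicative, $(1+\varepsilon)$ with
$\varepsilon \sim N(0, \texttt{noise\_sd})$, because measurement error scales
with the measured size; the default 1% matches a realistic sitting-height
measurement error of better than 1 cm. Maturity records are always emitted
noise-free, so in the ratio $L_m/L$ only the denominator is noisy and the
recovery error is cleanly bounded (about $M \times 3\sigma$ pointwise).
Generation is bit-stable given the seed and leaves the caller's RNG stream
untouched.

What passing these tests shows — and does not. Round-trip exactness, oracle
agreement, zero variability on proportional curves and sub-0.05 recovery
under 1% noise establish that the derivation machinery computes its
definitions correctly and is numerically robust at realistic noise. They do
not validate the multiplier method against real children: the generator has
no secular trends, no longitudinal (within-child) correlation, no skewness,
and its percentile structure is constructed from the very table being
recovered. Validation against real references requires the user's own data
through `read_growth_database()`.

## Numerical and interface choices

* Multipliers compare at three decimals (the printed precision); table
  serialization rounds half-even to 3 decimals, derived sets carry 6.
* Invariant checks use a $10^{-9}$ absolute tolerance: tables arrive either
  as 3-decimal printed values or as exact ratios, so anything beyond that is
  a real violation, not roundoff.
* `validate_table()` reports *every* violation with its sex and age and
  never raises; constructors and readers raise on the first violation.
  Monotonicity violations are flagged at the later of the two ages.
* Degenerate comparison inputs (fewer shared ages than degree + 1, or a
  rank-deficient fit) are domain errors, not silent NA results. A constant
  response with zero residuals reports $R^2 = 1$.
* CSV errors carry the offending line number (header = line 1); a missing
  maturity record, which has no single line, names the percentile.
* The CLI writes results to stdout and logs to stderr; exit status 0/2/3
  distinguishes success, usage errors, and data errors. Reruns with the same
  flags and files are byte-identical.

## Problem sizes

The test suite and the acceptance script run synthetic references of 3–5
percentile curves on 16–21 grid ages per sex (plus maturity), 50–200
randomized small instances (≤ 4 percentiles × ≤ 10 ages) for the brute-force
oracle, and the full 404-cell packaged table; the whole suite completes in
well under a minute on one CPU. These sizes match the structure of real
published references, which tabulate a handful of percentile curves at
monthly-to-yearly ages.

## Known limitations

* The packaged tables are sitting height only; cervical and upper-extremity
  tables exist in the literature but are not reproduced here (values not
  printed in the source tables) — load your own via the table CSV dialect.
* Figures of merit derived from the external Fredriks reference (the
  published variability magnitudes and curves) are not reproducible here
  because that database is not redistributable; the package reproduces the
  *method* and validates it on synthetic references instead.
* Growth after spinal pathology or fusion surgery need not follow the normal
  curves the multipliers encode; post-maturity disk-height changes are
  outside the model. Clinical judgment about whether a patient tracks the
  reference curves remains the physician's.
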