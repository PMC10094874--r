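---
title: "Total bioactivity accounting: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total bioactivity accounting: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbakit)
```

## The accounting model

Bioactivity-guided fractionation tracks a biological readout — here, the
running example is inhibition of NO production in LPS + IFN-γ activated
RAW 264.7 macrophages — through successive purification steps. The package
rests on two definitions and one balance:

**Potency as a dilution volume.** The half-maximal effective dilution volume
is the reciprocal of the half-maximal concentration,

$$\mathrm{EDV}_{50} = \frac{1}{\mathrm{EC}_{50}} \quad [\mathrm{L/g}],$$

the volume into which one gram of material can be diluted while still
eliciting half the maximal effect. Unlike EC₅₀/IC₅₀ it grows with potency,
which makes it the natural axis for ranking fractions and for overlaying on
a chromatogram. An IC₅₀ of 1 µg/mL (10⁻³ g/L) is an EDV₅₀ of 10³ L/g.

**Total bioactivity.** For a material of solid weight $w$ grams,

$$\mathrm{TBA} = \mathrm{EDV}_{50} \times w \quad [\mathrm{L}].$$

TBA is extensive: linear in weight, additive over materials, invariant to
the units the inputs arrived in (everything is canonicalized to g/L and g at
the boundary). Dividing by the grams of dry starting plant gives an
intensive figure, L of bioactivity per g of plant, comparable across batch
sizes. On units: some published tables print TBA as "L⁻¹", but the defining
arithmetic (L/g × g) yields liters, and liters is what this package uses;
published tables are reproduced numerically either way.

**The recovery balance.** For a parent split into children,

$$\text{mass recovery} = 100\,\frac{\sum_c w_c}{w_p}\,\%,\qquad
  \text{TBA recovery} = 100\,\frac{\sum_c \mathrm{TBA}_c}{\mathrm{TBA}_p}\,\%.$$

Their comparison is the scientific payoff. If the components of a mixture
act *additively* (dose addition), splitting the mixture conserves TBA
exactly, so bioactivity recovery should track mass recovery. Bioactivity
falling behind mass indicates degradation of an active component and/or loss
of a synergistic interaction; bioactivity ahead of mass indicates antagonism
in the original mixture and/or incomplete capture by the reference process.
The balance cannot distinguish the readings within each pair, so
`classify_interaction()` always reports both.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| equivalence band, extract comparison | `classify_interaction()` | 10% relative | per-gram yields from parallel extraction routes are fairly reproducible; a 6.8% deficit (the Grey Myrtle single-vs-sequential case) should read "equivalent" |
| equivalence band, recovery | `recovery()` | 25% relative | a chromatography step compounds many small weighing/assay errors on mg-scale fractions; the Grey Myrtle HPLC balance (2.1% TBA vs 2.61% mass, a 19.5% relative gap) is read by its authors as bioactivity retained, and we agree that at this noise level it is not evidence of lost synergy |
| `round_edv50`, `round_tba` | `compute_tba()`, `sum_tba()`, `campaign_report()` | `NULL` (never round) | printed-table mode only; see below |
| 4PL bounds | `fit_dose_response()` | slope ∈ (0.1, 10), top ∈ [50, 120], bottom ∈ [−10, 40] | inhibition plates normalized to untreated signal; slopes outside (0.1, 10) are artifacts at typical 6–10 point designs |
| Monte-Carlo draws | `potency_uncertainty_to_edv50()` | 10 000, caller-supplied seed | stable 2-digit SDs; the seed is mandatory so reported uncertainties are reproducible |

## Rounding: analytic mode vs printed-table mode

Stored values are never rounded. The printed-table mode (`round_edv50`,
`round_tba`) exists because published tables are themselves computed from
rounded intermediates, and reproducing a printed total requires reproducing
its arithmetic: the Grey Myrtle fraction table's total (5.963 L) is the sum
of seventeen 3-decimal TBAs (the unrounded sum is 5.960 L), and its parent
row (283.88 L) is the 2-decimal EDV₅₀ 70.97 L/g × 4 g (unrounded: 283.89 L).
Interestingly the same study's extract table uses *unrounded* arithmetic
(DCM: 425.83 L = 6 g / 0.01409 g/L, where 70.97 × 6 would give 425.82) — a
good illustration of why the mode is explicit and off by default.

## Censoring

When the response never crosses halfway within the tested range, the IC₅₀ is
only bounded below (EDV₅₀ bounded above): `fit_dose_response()` flags such
potencies right-censored whenever the fitted IC₅₀ exceeds the highest tested
concentration. Censored materials are excluded from TBA sums and recovery
numerators by default — their mass still counts in the denominator, which is
the conservative direction — and are listed in the report rather than
silently dropped. `allow_censored = TRUE` instead treats the bound as a
conservative EDV₅₀ estimate, for sensitivity analyses.

## Uncertainty propagation

Published potencies often come as IC₅₀ ± SD. On the EDV₅₀ scale the
delta method gives $\sigma_{\mathrm{EDV}} = \sigma_{\mathrm{IC}} /
\mathrm{IC}_{50}^2$, and TBA uncertainty scales linearly with weight. The
Monte-Carlo alternative resamples the IC₅₀ from a moment-matched lognormal
and takes the SD of the reciprocal draws; because the reciprocal is convex,
the two agree within 15% up to CV ≈ 0.2 and then diverge (at CV = 0.5 the
lognormal route exceeds the linearization by ~25%), in which case the result
carries a `divergent` flag instead of a silently blended number. How a
published SD was obtained (replicate spread vs fit standard error) is rarely
stated; the `sd_source` field records which path produced ours and no guess
is made about anyone else's.

## The dose-response fitter

The model is the four-parameter logistic on the falling-signal convention,
`response(c) = bottom + (top − bottom)/(1 + (c/IC₅₀)^h)` with h > 0 (the
"3PL" variant pins bottom = 0). The published campaign reports only IC₅₀
values, not the curve model behind them, so the fitter is deliberately a
replaceable standard choice rather than a claim. Numerics: the fit runs on
log(IC₅₀) (positivity, scale invariance) under box constraints, from a small
multi-start grid seeded at the geometric mid-concentration (plus the range
endpoints and slopes 0.5/1/2), with L-BFGS-B followed by a damped
Gauss-Newton (Levenberg-Marquardt) polish — the quasi-Newton line search
stalls about 10⁻⁵ short of exact optima on noiseless data, and the polish
restores quadratic convergence there. An interpolating fit (SSE ≈ 0) or a
vanished gradient counts as converged even when the optimizer's exit code
says otherwise; anything else returns `converged = FALSE` plus a warning,
never a silent number. Standard errors come from the Gauss-Newton
covariance at the optimum.

## What the simulator emulates — and what it does not

`simulate_fractionation()` makes "additive vs synergistic" operational. Its
mixture rule is mass-fraction-weighted EDV₅₀ (Loewe-style dose addition),

$$\mathrm{EDV}_{50}(\text{mix}) = (1+s)\sum_i w_i\,\mathrm{EDV}_{50}(i),$$

chosen because it is the unique rule under which TBA bookkeeping balances
exactly for $s = 0$ — a modeling choice that makes the ledger testable, not
an empirical claim. Synergy is a single multiplicative factor $s$ on the
intact parent mixture only (fractions are internally additive), the minimal
mechanism producing the "synergy lost on separation" signature; material
loss is a single per-split fraction. The closed-form recovery law under the
default one-compound-one-fraction assignment,

$$\text{TBA recovery} = 100\,\frac{1-\text{loss}}{1+s}\,\%,$$

is verified over a seeded grid in the tests. `simulate_plate()` draws 4PL
responses with i.i.d. Gaussian noise clipped to [−10, 110]%.

Real data the simulator does *not* emulate: co-elution and peak-shape
effects (a compound split across fractions), concentration-dependent or
pairwise synergy, heteroscedastic assay noise, plate-position effects, and
weighing error on fraction masses (weights are point values throughout —
the published tables give none). A green simulator-backed test therefore
establishes that the *accounting* is correct under stated assumptions, not
that any particular biological mixture is additive.

## Degenerate inputs and tie-breaks

Zero weight is a zero TBA, not an error; a missing potency or weight is an
explicit `not computable` row with a reason; a parent with zero weight or
zero TBA makes recovery undefined and errors. Sums over empty lists are 0.
Classification at exactly the tolerance boundary is `equivalent` (closed
band). Report node order is depth-first with siblings in input order, so
rendered output is byte-deterministic.

## Known limitations

- TBA compares materials only within one assay and readout; there is no
  cross-assay normalization.
- No statistical test accompanies the recovery classification; the bands are
  practitioner defaults, not significance thresholds.
- Censored potencies contribute zero rather than an interval; interval
  arithmetic for TBA is out of scope.
- The fitter is least-squares only (no robust or Bayesian variants) and
  assumes the falling-signal 4PL; assays with a rising raw signal must be
  normalized to percent-of-control first.
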