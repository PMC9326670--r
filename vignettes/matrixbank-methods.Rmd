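---
title: "Methods: rule-based figural matrix item banking"
author: "matrixbank developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based figural matrix item banking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package models

Figural matrix tasks present a 3×3 grid of geometric patterns whose ninth
cell is missing; the respondent must induce the rules that govern the rows
and produce the missing cell. `matrixbank` implements the full life cycle of
a *construction-based* matrix item bank: instead of picking among
distractors, the respondent assembles the answer by selecting from a fixed
palette of 20 construction elements, and an answer is scored correct only if
the selected set equals the solution exactly.

The toolkit covers five stages:

1. **Item generation** (`compose_item()`, `solve_stem()`): rule-based items
   with a machine-verified unique solution.
2. **Bank assembly** (`build_bank()`, `split_and_anchor()`,
   `render_svg()`): a 220-item bank split into 10 test sets of 22 items,
   each set augmented with the same 6 anchor items and 2 unscored practice
   items (28 scored tasks per form), exported as SVG.
3. **Response simulation** (`sample_abilities()`, `simulate_responses()`,
   `inject_misfit()`): dichotomous responses under the two-parameter
   logistic (2PL) model with planned missingness by form.
4. **Calibration and diagnostics** (`fit_2pl()`, `estimate_abilities()`,
   `fit_statistics()`): marginal maximum likelihood (EM over fixed
   quadrature), EAP scoring, infit/outfit misfit flags.
5. **Equating and reporting** (`link_forms()`, `equate_forms()`,
   `ctt_stats()`, `oneway_anova()`, `correlate_with_trim()`,
   `rule_regression()`, `psychometric_report()`).

## The element taxonomy

The construction palette is 5 element families × 4 rotation-orbit positions
= 20 elements (corner squares, edge bars, diagonal strokes, quarter arcs,
inner dots). Each family is closed under 90° rotation about the cell centre:
orbit *k* rotated one quarter turn clockwise gives orbit *k*+1 (mod 4). This
closure is not cosmetic — it is what makes the rotation rule a well-defined
permutation of element ids, and it matches the classic worked example in
which the four corner elements of a family are combined across a row. The
published element artwork is not described geometrically in any text source,
so the shapes here are a canonical stand-in with the same combinatorial
structure; rendered items are structurally, not pixel-wise, equivalent to
the published bank.

## Construction rules and uniqueness

Six rules map the first two cells of a row to the third, each acting on one
family (its *scope*): addition (union), subtraction (set difference),
disjunctive union (symmetric difference), intersection, rotation (one orbit
step per cell, clockwise or counter-clockwise), and completeness (a fixed
required set must be covered by the row; the third cell supplies what the
first two miss). An item uses 1–5 rules on pairwise **disjoint** families;
families under no rule stay empty. Disjoint scopes prevent rule
interference and keep the uniqueness check tractable.

Rules hold along rows only; columns are unconstrained. The generator draws
random scoped cell contents per row, then hands the eight visible cells to
an **independent solver** that enumerates every rule hypothesis per family
(six kinds × both rotation directions × all 15 candidate required sets) and
keeps those consistent with the two complete rows. The stem is accepted
only if every populated family has at least one consistent hypothesis and
all consistent hypotheses agree on the predicted ninth cell — uniqueness is
defined over *predictions*, not rule labels, so two rules that mimic each
other on a particular stem (e.g. addition and disjunctive union on disjoint
cells) do not spoil an item as long as they imply the same solution. Up to
50 redraws are attempted per item (fresh sub-seed each) before a
generation-failure error; in practice the full 220-item bank generates in a
few seconds. Items whose correct response would be the empty selection are
rejected as non-administrable.

For the completeness rule the generator guarantees that the union of the
first two cells is a strict subset of the required set (nonempty third
cell, containment never violated); the solver treats any row violating
containment as inconsistent with that completeness hypothesis.

Scoring is dichotomous exact match (`score_response()`): of the 2^20
possible selections exactly one scores 1. The source analyses are all
dichotomous 2PL, so no partial credit is defined.

## Bank design

The default `bank_config()` reproduces the published design: 20/50/80/50/20
items with 1–5 rules (220 total), 10 sets × 22 items (2/5/8/5/2 per rule
count), 6 anchors (rule counts 1, 2, 3, 3, 4, 5) identical across sets, and
2 one-rule practice items (addition, rotation) excluded from scoring. The
published table of per-rule-count kind usage is reproduced **exactly** by
quota sampling: each item takes the kinds with the largest remaining quota
(seeded random tie-breaks), which provably exhausts a feasible quota vector.
The published appendix's exact kind *combinations* per item are not in any
text source; combinations are therefore random under the fixed marginals.

Anchor placement within the 28-task presentation order is not documented;
anchors are interleaved at fixed ordinal positions 5, 9, 13, 17, 21, 25 to
spread them across the session and limit position confounds (scaled-down
configurations fall back to evenly spaced slots).

Rendering uses a 600×600 canvas with 200-px cells and 4-px borders, black
glyphs, and byte-deterministic output; the response panel draws the 20
elements as separate `<g>` groups. Selection highlighting is an interaction
concern of the delivery platform and is not part of the static export.

## The response model and the synthetic world

Responses follow the 2PL: `P(x = 1 | θ) = logis(a(θ − b))` with
discrimination `a > 0` and threshold `b` on the logit scale. Abilities are
standard normal by default (the usual identification convention); a mean/sd
override supports emulating range-restricted applicant populations. Persons
are assigned to forms round-robin (per-form sample sizes were not reported;
even allocation is the neutral choice).

The demo pipeline's "true" item parameters (`simulate_item_params()`) are
the stated world of the source design, not tuning knobs:

* thresholds follow the reported rule-difficulty model — intercept −1.56,
  weights 0.41 (addition), 0.51 (subtraction), 0.77 (disjunctive union),
  0.68 (intersection), 0.34 (rotation), 0.12 (completeness) — plus
  Normal(0, 0.8) item noise. The residual SD is chosen once so the rule
  indicators explain roughly a third of threshold variance, matching the
  reported R² ≈ .34; under the default design the implied mean threshold is
  ≈ −0.14, close to the reported −0.17.
* discriminations follow the reported rule-count gradient (means 1.45,
  1.52, 2.01, 2.64, 3.10 for 1–5 rules — weighted mean exactly 2.09 under
  the default rule-count distribution) with lognormal noise (σ = 0.25),
  truncated to [0.3, 5.5].

What the generator deliberately does **not** emulate: real respondents'
position/fatigue effects, response times, partial rule knowledge, cheating
in unproctored settings, and the gender/selection structure of an applicant
sample. A green simulation test therefore establishes the correctness of
the *machinery* (estimation, linking, reporting) under the model, not the
empirical claims about any human sample.

## Calibration

`fit_2pl()` implements MML-EM with a Normal(0, 1) latent prior on 61
equally spaced quadrature nodes over [−6, 6] with normal-density weights
(fixed, reproducible; verified against a 10× finer grid to ~2e-6 for EAP
scoring). The E-step groups persons by observed-item pattern — one group
per form under planned missingness — so the posterior is dense matrix
algebra. The M-step is per-item Newton–Raphson on the expected
complete-data logistic likelihood in the intercept/slope parameterisation,
at most 10 inner iterations with step-halving (which also guarantees EM
monotonicity of the marginal log-likelihood, asserted per cycle in the
tests). Numerical choices:

* slope floored at 0.001 (prevents sign flips) and capped at 10 — without a
  cap, locally dependent (duplicate) or Guttman-like items drive the slope
  to infinity;
* probabilities clamped to [1e−12, 1 − 1e−12] before logs, since the
  logistic saturates to exactly 0/1 in double precision around |logit| ≈ 37
  and `0 × log 0` would poison the E-step;
* convergence at max |parameter change| < 1e−5 or 500 cycles, with the
  status carried in the result (never silent);
* all-correct/all-wrong items have no finite MLE and are excluded with a
  report;
* standard errors are the expected complete-data information at the final
  E-step with a delta-method transform to (a, b) — the usual EM
  approximation; the Louis correction for the exact observed information is
  out of scope.

Start values are `a = 1` and `b = −logit(p̄)`.

## Misfit diagnostics

For each item, infit is the information-weighted mean square
`Σ(x−P)² / ΣP(1−P)` and outfit the unweighted mean of squared standardised
residuals; both are standardised by the Wilson–Hilferty cube-root transform
with the model variance of the mean square. The exclusion rule is: flag an
item when infit or outfit leaves [0.75, 1.33] **and** the corresponding
|ZSTD| ≥ 1.96 — both an aberrant magnitude and statistical significance are
required, so a trivially "significant" deviation at huge n with msq 1.05 is
not flagged, and a wild msq with no significance is not flagged either.

**Conditioning (a deliberate design deviation).** The classical choice
evaluates residuals at EAP point abilities. That works when the parameters
were just calibrated on the same data (estimation absorbs the EAP
shrinkage), but this package's misfit pathway targets the *item-bank* use
case: banked reference parameters are fixed, and incoming response data are
checked for conformity. With fixed parameters, point-EAP conditioning
mismatches the response curves through shrinkage and (measured, n = 2000,
20 replicates) false-flags ~19.5% of model-true items. The default here
therefore integrates every residual moment over each person's ability
*posterior* on the quadrature grid, which keeps mean squares calibrated
near 1 for model-consistent data (measured false-flag rate 0.75%) while an
injected random responder is flagged in 20/20 replicates. The point-ability
version remains available as `conditioning = "eap"`.

Two facts about detectability worth knowing: (1) a random-responder column
is *representable inside* the 2PL family (slope → 0), so after joint
recalibration its own fitted curve shows msq ≈ 1 — random responding is
only detectable against reference parameters, which is how the acceptance
pipeline runs; (2) outfit has a heavy-tailed sampling distribution for
steep/extreme items (one lucky response at P ≈ 0 dominates the unweighted
mean), so on model-true data single outfit values outside [0.8, 1.2] are
expected — this is why the flag requires the significance condition too.

## Equating

Forms are calibrated separately (each with its own Normal(0, 1)
identification), then placed on a common scale through the anchor block.
Since all forms share one anchor set, each form links *directly* to a
designated reference form (form 1; characteristic-curve and simultaneous
multi-form methods are out of scope). Mean-sigma (default):
`A = sd(b_ref)/sd(b_g)`, `B = mean(b_ref) − A·mean(b_g)` over anchors;
mean-mean uses the discrimination ratio instead. Parameters transform as
`b* = A·b + B`, `a* = a/A` (anchors like any item; the map is invertible,
and standard errors are rescaled accordingly). `equating_check()` runs
one-way ANOVAs of equated unique-item parameters across forms with ω² —
successful equating of forms drawn from a common item population should
leave no significant differences. An option recentres the final scale to
mean-b 0.

A practical note from the simulations: with only 6 anchors, the mean-sigma
slope `A` is estimated from a 6-point SD ratio and is noisy at modest
per-form n; at n ≈ 256/form this inflates between-form variance of the
equated discriminations (the `a` ANOVA can reject even under a true null)
while threshold equating remains well behaved. At n = 2000/form both checks
are calibrated.

## Reporting layer

Classical statistics are computed per form over the persons administered
it: difficulty `p`, corrected item-total ("part–whole") correlation (the
item is excluded from the total — the standard reading in this literature),
and Cronbach's α on complete administered columns. Zero-variance items
report an undefined marker rather than being dropped. One-way ANOVA reports
ω² = (SS_b − df_b·MS_w)/(SS_t + MS_w), truncated at 0. The outlier-trimmed
correlation removes pairs where either coordinate deviates more than 3 SD
from its own mean — single pass, SDs computed once on the raw vectors (the
source does not say whether trimming was iterative or bivariate; one-pass
marginal trimming is the simplest defensible reading). The difficulty
regression is OLS of equated `b` on the six 0/1 rule indicators, with
standardised weights `β = B·sd(x)/sd(y)` and an incremental F against the
nested rule-count-only baseline (the rule count is the indicator sum, so
the models are genuinely nested).

All of these agree with independent brute-force recomputations (explicit
loops and normal equations in the test suite) to 1e−10, and the noiseless
regression fixture recovers its generating coefficients exactly.

## Degenerate inputs and tie-breaks

* Items with overlapping rule scopes, rule count 0 or > 5: configuration
  error before generation.
* Rotation rows whose second cell is not one orbit step from the first, and
  completeness rows violating containment: rule-violation errors.
* Unsolvable stems return a report (`solvable = FALSE`), not an exception.
* Persons with no observed responses are excluded at load/scoring time with
  a report, mirroring the source's exclusion of non-responders.
* Anchor order never affects linking (means and SDs are symmetric).
* Quota ties in kind sampling are broken by the seeded RNG.

## Known limitations

* The element artwork is a canonical stand-in (see above).
* Equating is direct-to-reference mean-sigma/mean-mean; no
  Haebara/Stocking–Lord, no concurrent calibration.
* The demo's simulated world is idealised 2PL: it cannot reproduce
  sample-specific published statistics (those depend on a real applicant
  sample whose raw data are not available), only the structural targets and
  the behaviour of the machinery at matched design sizes.
* Measurement-invariance (MGCFA) analyses are deliberately out of scope.
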