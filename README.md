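# matrixbank

Rule-based figural matrix item banking with 2PL calibration and anchor
equating.

## What problem this solves, and for whom

Figural matrix tasks (3×3 grids whose ninth cell must be inferred from
rules governing the rows) are a workhorse of fluid-reasoning assessment,
but open, royalty-free item banks are rare, and building one requires a
whole pipeline: generating items whose solution is *provably unique*,
splitting a large pool across test forms no single person could finish,
and putting separately administered forms back on one measurement scale.
`matrixbank` is that pipeline for researchers and psychometricians. It
uses a **construction-based** response format: the respondent builds the
answer by selecting from a palette of 20 construction elements (5 families
× 4 rotation positions), and is scored correct only on an exact match.

## The model at the core

Items are generated from six construction rules acting row-wise on
disjoint element families — for cells *C₁, C₂, C₃* of a row and scope
set *S*:

| rule | relation |
|---|---|
| addition | C₃ = C₁ ∪ C₂ |
| subtraction | C₃ = C₁ \ C₂ |
| disjunctive union | C₃ = C₁ Δ C₂ |
| intersection | C₃ = C₁ ∩ C₂ |
| rotation | C₂ = ρ(C₁), C₃ = ρ(C₂) (ρ = one 90° orbit step) |
| completeness | C₃ = R \ (C₁ ∪ C₂) for a fixed required set R |

An independent solver enumerates every rule hypothesis consistent with the
two complete rows and certifies that all of them predict the same ninth
cell (uniqueness over *predictions*, not rule labels).

Responses follow the two-parameter logistic IRT model,
P(correct | θ) = 1 / (1 + exp(−a(θ − b))), calibrated by marginal maximum
likelihood (EM over 61 fixed quadrature nodes, Normal(0,1) prior). Items
are screened with infit/outfit mean squares (flag: msq outside
[0.75, 1.33] **and** |ZSTD| ≥ 1.96), forms are linked through their six
common anchors by mean-sigma equating (b* = A·b + B, a* = a/A), and the
report layer produces CTT difficulty/part–whole/α, ANOVAs with ω²,
±3SD-trimmed correlations, and the OLS regression of difficulty on the six
rule indicators.

## Worked example

```r
library(matrixbank)

# one item: corner squares added within the rows
item <- compose_item(list(rule_instance("ADD", 0)), seed = 7)
item
#> <matrix_item item_7: 1 rule(s) [ADD]>
validate_item(item)
#> <validation: rules_hold=TRUE solvable=TRUE unique=TRUE competing=0>
score_response(item, item$cells[[9]])   # exact match -> 1
#> [1] 1

# the full published design, end to end, at n = 2560 simulated applicants
man <- run_demo(seed = 7, out_dir = "demo_out", n_persons = 2560)
read.csv("demo_out/summary.csv")
#>             statistic         value
#> 1              mean_p  5.125558e-01
#> 2                sd_p  2.193344e-01
#> 3          mean_alpha  9.268683e-01
#> 4              mean_a  2.530613e+00
#> 5              mean_b -1.068241e-01
#> 6  anova_difficulty_F  6.727951e-01
#> 7  anova_difficulty_p  7.333475e-01
#> 8        equating_a_F  6.373376e+00
#> 9        equating_a_p  5.887338e-08
#> 10       equating_b_F  8.273488e-01
#> 11       equating_b_p  5.916147e-01
#> 12           r_p_vs_b -9.640945e-01
#> 13   r_p_vs_b_trimmed -9.640945e-01
#> 14      regression_r2  2.748525e-01
```

Reading this: the simulated bank is of medium difficulty (mean proportion
correct .51, SD .22) with high internal consistency per form (mean α =
.93). After mean-sigma equating, form thresholds show no residual
differences (F = 0.83, p = .59); the discrimination ANOVA rejects because
the 6-anchor SD-ratio slope is noisy at 256 persons/form (see the methods
vignette). CTT difficulty and the equated 2PL threshold correlate strongly
negatively (r = −.96 in this idealised world), and the six rule indicators
explain 27% of threshold variance in this replicate.

The demo writes `bank.json` (the validated bank with forms), one CSV per
stage (`responses.csv`, `form_fits.csv`, `equated_params.csv`, CTT and
regression tables), and a `manifest.json` with per-file MD5 digests —
rerunning with the same seed reproduces the digests byte-for-byte.

A command-line front-end ships at `inst/cli/matrixbank`
(`generate | render | simulate | fit | equate | report | demo`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "matrixbank", package = "matrixbank"))')" \
  demo --seed 7 --out demo_out --n 2560
```

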