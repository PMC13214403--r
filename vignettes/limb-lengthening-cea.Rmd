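---
title: "Modelling the cost-effectiveness of limb lengthening in achondroplasia"
author: "achecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of limb lengthening in achondroplasia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achecon)
```

## The decision problem

Achondroplasia, the most common skeletal dysplasia, produces
disproportionate short stature with substantial consequences for autonomy
and health-related quality of life, and is associated with a life
expectancy roughly ten years below that of the general population.
Two-stage surgical limb lengthening (simultaneous femoral and tibial
lengthening by distraction osteogenesis, optionally followed by bilateral
humeral lengthening) can increase stature enough to change functional
outcomes, at a non-trivial cost and with a high reoperation rate. `achecon`
implements a decision-analytic comparison of two strategies for a
pre-adolescent cohort — *no treatment* versus *surgical limb lengthening* —
from a public payer's perspective, over the remaining lifetime.

## The Markov cohort model

Both strategies are discrete-time Markov cohort models with annual cycles
(90 by default, from a configurable start age of 12). The no-treatment
chain has two states, normal life and death. The surgery chain enters at
lower-limb lengthening (LLL) and moves through an optional lower-limb
complication year (LLComp), upper-limb lengthening (ULL), an optional
upper-limb complication year (ULComp), and then lifelong normal life;
death is absorbing and reachable from every state.

Transitions out of the surgical states combine four probabilities: the
complication probabilities `p_ll_comp` (0.8) and `p_ul_comp` (0.1), the
withdrawal probability `p_withdraw` (0.1) with which a patient leaves the
programme after the lower-limb stage, the age-dependent background death
probability `dp`, and the per-surgical-cycle mortality `surg_dp`
(0.013%). In a surgical state the death outflow is `dp + surg_dp`; the
survivors split between the complication branch and progression or
withdrawal exactly as the transition table of the source analysis
prescribes.

Two modelling choices deserve comment.

**Split normal-life state.** Lifelong utility differs between patients who
withdrew after lower-limb lengthening (utility 0.888) and those who
completed both stages (0.944), but a memoryless chain cannot look back at
the path taken. Normal life is therefore carried as two bookkeeping states,
`NormalLife_LLLOnly` and `NormalLife_Full`, with identical transition
behaviour; their occupancies sum to the single printed normal-life column.
This also makes the surgical strategy a seven-state chain.

**Infeasible rows at extreme ages.** The printed row formulas produce a
negative entry whenever `p_ll_comp + dp + surg_dp > 1`, which happens with
the base-case complication probability of 0.8 once the (age-shifted)
background mortality exceeds about 0.2 — ages the cohort only reaches some
seventy cycles after surgery. Because the cohort starts wholly in LLL, the
four surgical states are structurally empty from cycle 4 onward, so those
late rows can never be exercised. `transition_matrices()` therefore builds
every row by the printed formula where feasible and redirects an
infeasible row to the absorbing death state only when the row is
unreachable (beyond the `strict_cycles = 4` window); within the window an
infeasible row is an error, which the PSA treats as an invalid draw to be
rejected and redrawn. Every matrix in the sequence is row-stochastic at
machine precision, at every age, without altering the cohort trace.

## Mortality

The background mortality of the general population enters through an
annual life table (`age`, `qx`). The ten-year life-expectancy reduction of
achondroplasia is implemented as an **age shift in the lookup**: the death
probability applied at age $a$ is the general-population $q_{a+10}$. This
is the simplest operationalisation consistent with describing the cycle
probability as that of the general population "reduced by 10 years", and
it is isolated in `dp_at()` so an alternative transformation (e.g. a hazard
multiplier) could be substituted without touching the engine.

National tables are not bundled; `gompertz_makeham_table()` generates a
synthetic stand-in from the hazard $h(x) = a + bc^x$, integrated exactly
over each year of age. The defaults ($a = 5\times10^{-4}$,
$b = 3.5\times10^{-5}$, $c = 1.095$) give a life expectancy at birth of
78.2 years, deliberately close to contemporary Spain. The generator mimics
the overall level and old-age acceleration of an all-cause schedule; it
does not reproduce infant mortality, the young-adult accident hump, sex
differences, or cohort effects, so quantitative outputs on the synthetic
table characterise the method rather than the Spanish population. A real
table supplied via `read_life_table()` replaces it seamlessly (tables are
unisex at one-year resolution, contiguous from age 0 and closed with
$q = 1$ at the maximum age, 120 by default).

## Valuation

Occupancy at cycle $t$ earns cycle-$t$ rewards, and transitions happen at
cycle end; no half-cycle correction is applied (the source analysis does
not use one, and the choice is confined to `accumulate_trace()`).
Discounted QALYs are $\sum_t (1+r_h)^{-t} \sum_s occ(t,s)\,u(s)$ with
$r_h = 3\%$, and costs the analogue at $r_c = 3\%$.

Utilities: lifelong normal life carries 0.711 (untreated), 0.888
(lower-limb only) or 0.944 (fully lengthened). Each surgical or
complication year is the stage's multiplier (0.7, 0.8, 0.8, 0.75) times a
base utility. The source material does not say which utility the
multipliers scale; the default applies them to the post-stage utility of
the pathway under the knife (`u_lll` for lower-limb states, `u_full` for
upper-limb states), keeping each pathway internally consistent. The
alternative reading — multipliers on the untreated 0.711 — is available as
`multiplier_base = "baseline"` and covered by tests; it lowers surgical-year
utilities and slightly raises the incremental QALY gain.

Costs accrue on occupancy of the procedure states (EUR 28,539 for LLL,
10,834 for ULL, 6,275 for either complication) in the cycle of the
procedure, with no spreading. Normal life carries no incremental cost:
costs shared by both strategies cancel in the comparison, which also fixes
the no-treatment arm's cost at zero. Composing these printed unit costs
under this simplest accrual convention yields a discounted per-patient
incremental cost of about EUR 43.2k on the synthetic table — the published
analysis reports 49,480, and the gap is not closable from the printed
inputs alone (the authors' exact accrual convention and any follow-up cost
components are not recoverable); the convention here is deliberately the
plainest one and is documented rather than tuned.

## Probabilistic sensitivity analysis

`run_psa()` (or `simulate()` on a fitted model) redraws, per iteration and
in a fixed documented order: the three utilities from beta distributions
moment-matched to their reported mean and sd; the four multipliers and
three transition probabilities from beta distributions with a fixed
effective sample size of 50 (the multipliers have no reported dispersion,
so the probability rule is applied to them as well — a judgement call
recorded here); and the three costs from gamma distributions with a 30%
coefficient of variation. Mortality, discount rates and the threshold stay
fixed. One thousand iterations are the default.

The unoperated utility's reported moments (0.711 ± 0.266) sit close to the
beta feasibility edge and imply shapes (1.35, 0.55) — a U-adjacent
distribution with substantial mass near 1. It is used exactly as reported,
with a loud note rather than truncation; this right-skew is why the CEAC's
50% crossover sits well above the ICER of means. Structurally invalid
draws (a reachable row's outflow exceeding 1) are rejected and redrawn
rather than clamped, and the rejection count is reported; at the base-case
distributions rejections are essentially absent.

The PSA summary reports the ICER as the ratio of mean increments, which is
stable when individual iterations have incremental effects near zero
(the mean of per-iteration ratios is not).

## Decision uncertainty

`voi_curves()` computes, over a willingness-to-pay grid (0–50,000 in steps
of 500 by default, spanning the EUR 25,000 decision threshold and the
60,000 upper bound discussed for Spain): the CEAC (per-$\lambda$ fraction
of iterations in which each strategy has the highest net monetary benefit,
with ties awarded to no treatment — deterministic and conservative toward
the intervention), the CEAF (the acceptability of the strategy with the
highest *expected* NMB, which switches exactly at the ICER of means), and
the per-patient EVPI $E[\max_s NMB_s] - \max_s E[NMB_s]$, computed on
incremental net benefit so it is invariant to costs common to both
strategies.

## Budget impact

`cost_stream()` extracts the per-patient expected incremental cost by year
since programme entry (zero from year 4, since only the transient surgical
states carry costs); `run_budget()` stacks one entering cohort per year
(15 at full uptake, 7 in the 50% scenario) over a 15-year horizon,
discounts each calendar year's spend to programme start at the cost rate,
and truncates costs falling beyond the horizon. The published cumulative
figure's exact discounting convention is not stated, so the convention is
a flag (`discounting = "program_start"` or `"none"`); what holds under any
convention, and is asserted exactly in tests, is linearity in the number
of treated patients — the published full- and half-uptake figures are in
the exact ratio 15:7.

## Numerical conventions and degenerate inputs

Row sums are validated at $10^{-12}$ and trace mass conservation at
$10^{-10}$; death occupancy is checked monotone. A life table must close
with $q = 1$ so the chain is eventually absorbed when the horizon permits.
`cea_compare()` reports the ICER only when QALYs are gained; otherwise it
is `NA` with a dominance label, avoiding the sign ambiguity of negative
ratios. Beta moment-matching rejects infeasible (mean, sd) pairs outright.
Degenerate PSAs (all parameters fixed) reproduce the deterministic base
case bit-for-bit and give identically zero EVPI.

## Problem sizes and what the tests show

The shipped analyses use the full 90-cycle horizon with 1,000 PSA
iterations (a few seconds end to end). The test suite exercises the same
horizon, checks the cohort engine against an independent 100,000-individual
microsimulation at cycles 1, 2, 5 and 50, the distribution builders
against $10^6$-draw moment recovery, and the VOI curves against an
explicit per-iteration argmax oracle. Passing on the synthetic table
demonstrates correctness of the machinery and the qualitative decision
picture (surgery's expected NMB dominates at EUR 25,000/QALY; the CEAC
crossover lands in the 10,000–16,000 band; the EVPI kink localises at the
ICER of means). It does not certify the published absolute numbers, which
depend on the national life table used and on accrual conventions the
printed inputs do not determine.

## Known limitations

Quality-of-life gains are assumed lifelong, as in the source analysis; the
model has no pharmacological comparator arm; complications are one-cycle
states without severity grades; the budget model has no prevalence pool or
price dynamics; and the synthetic mortality schedule is a stand-in, not a
national table.
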