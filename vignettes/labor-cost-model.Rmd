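---
title: "A labor-cost decision model for central venous catheter confirmation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A labor-cost decision model for central venous catheter confirmation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvccost)
```

## The problem and the model

After a central venous catheter (CVC) is placed, its tip position must be
confirmed and an iatrogenic pneumothorax excluded before the line is used.
Two workflows accomplish this:

* **Protocol A (radiograph)** — a radiology technician acquires a portable
  chest radiograph, the bedside physician reviews it, and a radiologist
  interprets it.
* **Protocol B (ultrasound)** — the physician who placed the line performs a
  three-step bedside ultrasound confirmation (venous placement via the
  right-atrial swirl sign, malposition exclusion at the contralateral neck
  vessels, pneumothorax exclusion via lung slide), assisted by a nurse.

`cvccost` models the *labor* cost of each workflow by micro-costing: each
labor segment is `minutes × wage`, with wages in dollars per minute. With
task times $t$ and wages $w$,

$$C_A = t_{\text{tech}} w_{\text{tech}} + t_{\text{mdA}} w_{\text{md}} +
  t_{\text{read}} w_{\text{rad}},$$

and the ultrasound arm adds the expected cost of *diversion*: when the
bedside ultrasound raises suspicion of a malposition (probability
$p_{\text{mal}}$) or a pneumothorax ($p_{\text{ptx}}$), the patient goes on
to the full radiograph pathway, incurring $C_A$ *in addition to* the
ultrasound time already spent (no credit is given for overlapping review
effort):

$$C_B = t_{\text{mdB}} w_{\text{md}} + t_{\text{rn}} w_{\text{rn}} +
  p_{\text{div}}\, C_A .$$

The same structure is represented explicitly as a two-strategy decision tree
(`build_decision_tree()`) whose protocol-B arm has three chance paths — no
complication, suspected malposition, suspected pneumothorax — and evaluated
by expected-value rollback. The test suite holds the tree and the closed
form to within $10^{-9}$ of each other across randomized parameter sets;
the two routes are maintained separately precisely so each checks the other.

### Diversion conventions

The two complication probabilities can combine in two ways, and the package
exposes both because both figures circulate for this comparison:

* **sequential** (default): pneumothorax is only assessed when no
  malposition was suspected, so
  $p_{\text{div}} = p_{\text{mal}} + (1 - p_{\text{mal}})\,p_{\text{ptx}}$
  — with the default inputs, 7.83%. This matches the itemized diversion
  formula `(1 − 0.068) × 0.011 × $18.48` for the pneumothorax term.
* **additive**: $p_{\text{div}} = p_{\text{mal}} + p_{\text{ptx}}$ = 7.9%
  with the default inputs, the figure usually quoted in prose.

The sequential diversion cost is never larger than the additive one, with
equality exactly when one probability is zero; a property test enforces
this. The additive convention additionally requires
$p_{\text{mal}} + p_{\text{ptx}} \le 1$, which is checked at evaluation
time rather than at parameter construction so that sequential-only
degenerate analyses (e.g. $p_{\text{mal}} = 1$) remain expressible.

## Parameters, units, defaults

`default_parameters()` carries the model's single source of truth
(also packaged as `inst/extdata/default_parameters.json`):

```{r}
default_parameters()
```

* **Wages** ($/minute): bedside physician 1.72 (1.41–1.99), radiologist
  1.89 (1.66–2.06), registered nurse 0.64 (0.52–0.79), radiology
  technician 0.51 (0.42–0.63). Ranges are 25th–75th percentiles of national
  salary sources; the salary-to-$/minute conversion happened upstream and
  the $/minute figures are direct inputs here.
* **Task times** (minutes): radiograph acquisition 15 (10–20), bedside
  review 3 (2–4), radiologist read 3 (2–4), ultrasound confirmation 5.6
  (3.1–8.1) for both physician and nurse.
* **Probabilities**: malposition 0.068, pneumothorax 0.011 (a 2018
  meta-analysis; the default central source). The sensitivity ranges span
  the three published sources packaged as scenarios — malposition
  0.026–0.176, pneumothorax 0.011–0.032.
* **Population**: 2,045 radiograph-confirmed CVCs per hospital-year (of
  3,069 total), and 3.3M supradiaphragmatic CVCs nationally (66% of 5M).

Each scenario (`load_scenario()`) also carries that source's published
*elapsed* confirmation-time intervals (order-to-completion). These are
annotation only: the cost equations use hands-on labor minutes, which are a
different quantity, and the package deliberately never substitutes one for
the other.

## Numerical conventions

**All arithmetic is carried at full floating precision; rounding happens
only in the reporting layer** (cents per patient, whole dollars per
hospital-year, $0.1M at national scale, whole percent for relative
savings). This is not cosmetic: the hospital-year total $29{,}984$ and the
national $48.4$M only reconcile when the *unrounded* per-patient cost
$14.66209696$ is scaled, and the per-patient total $14.66$ only reconciles
when exact line products ($5.6 \times 1.72 = 9.632$, not a cent-level
display figure like $9.65$) are summed before rounding. A regression test
guards both directions.

Other numerical choices:

* `break_even()` exploits that the cost difference is linear in every
  individual parameter: the root is solved in closed form from two
  evaluations and cross-verified with `stats::uniroot()` whenever a sign
  change brackets it (the test suite re-verifies against an independent
  bisection to $10^{-6}$). The search window is the declared range extended
  tenfold about the central value, clamped to valid supports; a flat,
  nonzero difference yields `NA`, a flat zero difference returns the
  central value.
* Task times admit zero as a degenerate limit (a zero-duration task is
  meaningful and `line_cost(0, w)` is 0); wages must stay strictly
  positive; probabilities live in $[0,1]$.
* Tornado ties break lexicographically by parameter label, so the ordering
  is bit-reproducible.

## Sensitivity analysis design

One-way analysis re-evaluates the *full* model at one parameter's bounds.
Consequences of full-model consistency worth knowing: varying a
protocol-A quantity (say technician time) also moves protocol B's diversion
term, because diverted patients incur the perturbed radiograph cost. The
default tornado varies the five task times and the two probabilities.
Wage sensitivity is computed on request (`include_wages = TRUE`) but kept
out of the default view: wages scale both protocols proportionally, so
their one-way excursions never change the sign of the savings and mostly
restate the linearity of the model. With the default inputs exactly one
extreme flips the comparison — the bedside physician's ultrasound time at
8.1 minutes makes protocol B about 3% more costly — and the break-even
for that time falls at 7.82 minutes, inside its declared range.

The tornado metric is the dollar swing of the savings $C_A - C_B$;
`metric = "percent"` rescales by the base-case $C_A$ for comparability with
percent-change presentations. Two-way analysis evaluates an evenly spaced
grid (default 11 × 11) over two ranges.

## The Monte-Carlo layer and what it does (not) show

The deterministic inputs carry ranges, not distributions, so the
probabilistic layer must choose sampling families. Defaults
(`default_psa_specs()`): **triangular(low, central, high)** for task times
and probabilities — it honors the central estimate as the mode on a bounded
support without claiming more than the ranges justify — and **uniform(low,
high)** for wages, whose range endpoints are salary percentiles carrying no
mode information. Both are overridable per parameter (`dist_spec()`),
including a point-mass `"fixed"` family whose draws recover the
deterministic base case exactly. Draws are independent across parameters
(no correlation data exist), truncated to $[0,1]$ for probabilities, and
reproducible: parameters are sampled one at a time as blocks of `n`, so a
`(specs, n, seed)` triple fixes the entire draw matrix. Defaults are
`n = 10000`, `seed = 20220915`.

```{r}
psa <- run_psa(sample_parameters(n = 2000, seed = 20220915))
psa
```

What this emulates is *parameter* uncertainty over the stated ranges of a
desk-scale model whose inputs were measured at one academic center. It does
not emulate sampling variation in real task times, correlation between a
clinician's speed on the two protocols, between-site wage structure, or any
effectiveness difference — the model is deliberately labor-cost-only, with
no QALYs, equipment, training, or facility costs. Passing tests therefore
show internal consistency and faithful propagation of the declared
uncertainty, not external validity. Note also that the triangular
distribution for the malposition probability is right-skewed (mode 0.068,
support up to 0.176), so the Monte-Carlo mean savings (~$3.39) sits
slightly below the deterministic base case ($3.82); that is a property of
the declared uncertainty, not an inconsistency.

## Problem sizes

The packaged analyses use the sizes their statistical purpose requires:
1,000 random parameter sets for the tree/closed-form equivalence property,
10,000 Monte-Carlo draws for the headline PSA (Monte-Carlo error on the
mean savings ≈ $0.03), and 11-point axes for two-way grids. Everything is
desk-scale; the full analysis suite runs in well under a minute.

## Known limitations

* Single-center inputs; wage and time structures will differ elsewhere.
* The diverted-patient cost adds the full radiograph-pathway cost on top of
  the spent ultrasound time; if a real workflow truncates the radiograph
  review after an ultrasound flag, the model slightly overstates diversion
  cost.
* No modeling of downstream consequences (delayed catheter use, radiation,
  infection control) — those favor the ultrasound arm clinically but are
  outside a labor-cost frame.
* The commonly quoted "7.9% diverted" figure and the itemized sequential
  diversion formula imply different conventions (7.9% vs 7.83%); the
  package computes both and documents the divergence rather than
  reconciling it silently.
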