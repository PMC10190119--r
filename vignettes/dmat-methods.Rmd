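---
title: "Scoring observational dampness and mold assessments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring observational dampness and mold assessments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmat)
```

## The instrument and its data model

An observational assessment grades dampness/mold-related damage in a room
without environmental sampling. Four factors are scored: **mold odor**
(judged once per room, first, before the observer acclimates), and three
component-level factors — **water damage/stains**, **visible mold**, and
**wet/damp materials** — judged on each of eight room components:
ceiling, walls, floor (the basic components, expected in every enclosed
room), windows, furnishings, HVAC, supplies/materials, and pipes.
Components that do not exist in a room are excluded from scoring entirely;
recording which components exist matters because averages divide by the
number of existing components.

Component-level scores are ordinal 0–3, sized by the *combined* area of
all damage patches on the component against two everyday references: up
to a standard paper sheet (8.5 × 11 in = 93.5 in²) scores 1, up to a
standard interior door (32 × 80 in = 2560 in²) scores 2, and anything
larger scores 3. The instrument's published wording assigns "less than" a
sheet to 1 and "greater than" a sheet to 2, leaving exact equality
unassigned; `size_to_score()` resolves this by closing intervals on the
left, so an area exactly at a threshold takes the lower score. In practice
observers judge the category directly; the area mapping exists for
training and for synthetic data.

Mold odor intensity is recorded as none/mild/moderate/strong. The
instrument names intensities rather than printing numerals, but its data
entry sheet carries a numeric odor score column with 0 for no odor; we fix
the mapping none = 0, mild = 1, moderate = 2, strong = 3, symmetric with
the size scale. A `source_unknown` flag on an observed odor marks
potential hidden mold. Two per-component flags complete the record:
`nothing_found` (shorthand for all three factors scoring zero) and
`near_exterior_wall` (damage within three feet of an exterior wall,
suggesting external leakage). The form carries one near-exterior checkbox
per component row, so the flag is stored per component, not per factor.

`validate_assessment()` returns violations as data rather than exceptions,
with a severity column: structural contradictions (a non-zero score under
`nothing_found`, duplicate components, scores outside 0–3) are errors;
unusual but acceptable records (a missing basic component, an unlisted
school room type) only warn.

## Summary scores

For a room with $n$ existing components, scores $s_{cf}$ and odor $o$:
component total $T_c = \sum_f s_{cf}$; room total $T = \sum_c T_c + o$;
factor average $\bar s_f = \frac{1}{n} \sum_c s_{cf}$; room average
$\bar T = \sum_f \bar s_f + o$. The odor score is added undivided to both
the total and the average: it is a single room-level observation, and the
published formulas never divide it by the component count. These
identities are enforced by property tests
($\bar T - o = (T - o)/n$ to $10^{-9}$) against an independent naive
recomputation. Averages are carried at full floating precision; files
round to 6 decimals only on output.

Room totals classify onto floor maps as green (1–2), yellow (3–6) and red
(≥ 7). A total of 0 falls below the published green band; rather than
stretching green we emit an explicit `none` band, which keeps "no damage"
distinguishable from "minor damage" on maps.

## Aggregation

Building/school summaries follow the field's constructions: the
**school average score** is the mean room total over assessed rooms; the
**component-specific school average** sums one component's totals over all
rooms and divides by the number of rooms assessed (rooms lacking the
component count in the denominator — it is a per-room rate, not a
per-component mean); **score frequencies** count rooms per non-zero score
and component; **prevalence** is room-level (a room is affected by a
factor if any component scores non-zero). Schools dichotomize at the
median of school average scores; the published construction says only
"above or below the median", so ties go to the lower (`at_or_below`)
group — with an even number of schools the median is the midpoint of the
two central order statistics and exact ties are possible. When a room has
repeat assessments, aggregation uses the latest date; earlier ones remain
available to the longitudinal comparison.

## Exposure indices

The **time-weighted average** index is
$\sum_i w_i x_i / \sum_i w_i$ over the rooms a person occupies, with
arbitrary nonnegative weights (hours, semester shares); no normalisation
convention is imposed on input.

The **mixed microbial exposure index** (MMEI) summarises eight agents
measured in dust (total culturable fungi and bacteria, Gram-positive and
Gram-negative bacteria, endotoxin, ergosterol, (1→3)-β-D-glucan, muramic
acid): each agent's concentrations are decile-ranked across the sample
set and a sample's MMEI is the sum of its eight decile ranks, range
8–80. The original decile convention (1–10 vs 0–9) is not printed; we use
1–10, giving the [8, 80] range, with deciles computed as
$\lceil 10\,r/n \rceil$ from stable ordinal ranks (ties broken by input
order). Any quantile convention changes the index for tied data, so the
rule is fixed and documented; the index is consequently invariant to
monotone rescaling of any single agent.

**Concordance** between observers is percent agreement on room-level
presence/absence of a factor, reported to the whole percent as the field
does. Presence/absence (not exact score equality) is the published
crosscheck construction, and whether it was computed per room or per
room-component is not stated — we chose room level; an exact-score mode
is available separately. Agreement by chance is not corrected for (percent
agreement, not kappa, is the published statistic).

## Longitudinal comparison

Repeat assessments of the same rooms diff per (room, component, factor):
0→positive is `new`, increases are `worsened`, equal `unchanged`,
decreases `improved`, positive→0 `resolved`; swapping campaigns maps
new↔resolved and worsened↔improved. Components present in only one
campaign (furnishings removed, pipes boxed in) are reported as structural
changes and excluded from score deltas — the source material is silent on
this case. `flag_for_action()` ranks rooms: any current wet/damp material,
visible mold, or mold odor puts a room in the immediate tier (these signal
ongoing or recent incursion, unlike dried stains); the tier is not
sub-ranked by which of the three factors triggered it, since no such
ordering is published; within tiers rooms sort by new/worsened count, then
current total, then room key, giving a reproducible total order. Band
transitions (e.g. green→yellow) are reported but do not by themselves
trigger the immediate tier.

## Tabular I/O

The CSV dialect flattens the spreadsheet's two-level merged headers into
snake_case columns (metadata, odor block, eight columns per component, a
schema version column). Reading honours the sheet's entry conventions: an
empty factor cell on a present component decodes to 0; an empty
`<component>_present` cell means the component does not exist; the odor
score cell must always be filled (no odor is entered as 0). Writing is
stricter than the conventions require: zeros are emitted explicitly so
"assessed as 0" never collapses into "not assessed", rows sort by
building/room/date/observer, and output is byte-deterministic — golden
files are compared byte for byte in the tests. Dates are ISO-8601. A
non-zero score on a non-present component is reported as a violation and
dropped. Both note fields (component materials, assessment remarks) are
carried as free text.

## Synthetic campaigns

The generators make every module testable without field data.
`campaign_spec()` defaults emulate a school-district campaign: 16
buildings × 142 rooms (≈ 2300 rooms, the scale of a district-wide
inspection), room-level factor prevalences of 52% water damage/stains, 2%
visible mold, 2% wet/damp and 17% mold odor (the pattern observed in a
three-school field study, with water damage and stains merged as the
instrument merges them), severity probabilities (0.7, 0.2, 0.1) over
scores 1–3 (most field damage is small), component presence probabilities
of 1 for the basic components and plausible rates for the rest (e.g.
windows 0.9, pipes 0.3), and a 0.3 near-exterior probability.

A room is affected by a factor with the spec prevalence; within an
affected room the damage lands on one guaranteed component plus each other
present component with probability `component_spread` = 0.3, so the
room-level prevalence is exactly Bernoulli and recoverable within binomial
error (verified at n = 1000 within 3 SE). `generate_observer_pair()`
reproduces each room-level presence/absence call with probability
`agreement_prob`, independently per room and factor, so expected
concordance is exactly `100 × agreement_prob`. `generate_microbial()`
draws the eight agents log-normal — the standard model for environmental
counts; only associations, not distributions, are published — with
log-location shifted by `score_effect` (default 0.15 per unit room total),
reproducing the observation that rooms above the median dampness score
carry higher microbial loads and MMEI.

What the generators do *not* emulate: spatial correlation of damage along
leak paths (an optional room-level coupling exists only through
`component_spread`), seasonal dynamics, observer drift, building physics,
and the long right tail of real severity distributions. Passing recovery
tests therefore show the pipeline's arithmetic and the generators'
self-consistency, not field validity of the instrument.

All generators run under a locally seeded RNG (Mersenne-Twister via
`set.seed`) that is restored afterwards, so identical seeds give identical
campaigns and library calls never disturb the caller's RNG stream.

## Problem sizes and numerical choices

Property suites run on 300–1000 random rooms per block and brute-force
oracles on campaigns of ≤ 500 rooms; stochastic recovery checks use
n = 1000 rooms (prevalence, concordance) and n = 200 rooms (score–MMEI
correlation), all under fixed seeds. Floating comparisons use 1e−9
tolerances on the score identities; everything else is integer-exact.
Degenerate inputs are explicit errors: zero existing components for
averages, zero rooms for aggregation, empty value sets for decile ranks,
all-zero time weights, fewer than two schools for dichotomization.

## Known limitations

- The assessment itself is subjective; the package models the recorded
  scores, not the observation error behind them, and offers no latent
  "true damage" inference.
- Health-outcome modelling (logistic regression of symptoms on exposure
  groups) is out of scope; the package produces the exposure metrics such
  models consume.
- The Excel mirror of the entry sheet is not written; CSV is the
  normative interchange format.
- Floor-map rendering is left to the user: `band_rooms()` emits the
  color table ready for joining to map geometry.
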