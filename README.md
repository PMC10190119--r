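# dmat

Tools for scoring and analysing **observational dampness and mold
assessments** of buildings — the standardized visual/olfactory walkthrough
method used by industrial hygienists and facility managers to evaluate
water-damage-related conditions without collecting environmental samples.

Indoor dampness and mold exposure is consistently associated with asthma
exacerbation and other respiratory outcomes, but quantifying airborne
microbial agents is expensive and noisy. Semi-quantitative observational
scoring is the practical alternative: an observer walks each room, smells
for mold odor, and grades three damage factors — water damage/stains,
visible mold, and wet/damp materials — on each of eight room components
(ceiling, walls, floor, windows, furnishings, HVAC, supplies/materials,
pipes), each on an ordinal 0–3 scale sized against everyday references
(a sheet of paper, an interior door). This package implements the full
data life cycle of such assessments: a validated record model, the scoring
formulas, building-level aggregation, exposure indices for epidemiology,
observer concordance, longitudinal change tracking, and seeded synthetic
campaign generators.

## The scoring model

For a room with $n$ existing components, component-level factor scores
$s_{cf} \in \{0,1,2,3\}$ (component $c$, factor $f$) and room-level mold
odor score $o \in \{0,1,2,3\}$:

- **component total**: $T_c = \sum_f s_{cf}$ (range 0–9);
- **room total**: $T = \sum_c T_c + o$ (range 0–75 with all eight
  components present);
- **factor average**: $\bar s_f = \tfrac{1}{n}\sum_c s_{cf}$, over
  existing components only;
- **room average**: $\bar T = \sum_f \bar s_f + o$ (odor enters
  undivided — it is a room-level observation).

Damage size maps to scores at two thresholds: up to one standard paper
sheet (8.5 × 11 in = 93.5 in²) scores 1, up to one standard interior door
(32 × 80 in = 2560 in²) scores 2, larger scores 3. Room totals classify
onto floor maps as **green** (1–2), **yellow** (3–6), **red** (≥ 7), with
an explicit **none** band for undamaged rooms.

For exposure assessment the package provides the **time-weighted average**
individual exposure index (room scores weighted by occupant time), the
**mixed microbial exposure index** (MMEI: per-sample sum of decile ranks
across eight microbial agents, range 8–80), and inter-observer
**concordance rates** (percent agreement on factor presence/absence).

## Worked example

```r
library(dmat)

path <- system.file("extdata", "two_room_example.csv", package = "dmat")
res  <- read_assessments(path)
is_clean(res$report)   # TRUE: no validation errors
score_room(res$records[[1]])
```

```
Room scores: building A, room 101 (2024-05-01)
  component totals: ceiling=3, walls=1, floor=0, windows=1
  room total 6 (band: yellow), odor 1
  factor averages: water_damage_stains=0.75, visible_mold=0.25, wet_damp=0.25
  room average 2.25 over 4 components
```

Room 101 has four existing components. The ceiling carries water
damage/stains scored 2 plus visible mold scored 1 (component total 3), the
walls a score-1 stain near an exterior wall, the windows a score-1 damp
sill. With the mild mold odor (score 1) the room total is
3 + 1 + 0 + 1 + 1 = 6, the top of the yellow band; the room average is
(0.75 + 0.25 + 0.25) + 1 = 2.25. Mild odor with `source_unknown` flags
potential hidden mold, so this room lands in the immediate-action tier of
`flag_for_action()`.

Campaign-level analysis mirrors the field workflow:

```r
camp  <- generate_campaign(campaign_spec(seed = 1))   # 16 schools, 2272 rooms
summ  <- campaign_summary(camp)                       # per-school averages, prevalences
bands <- band_rooms(camp)                             # floor-map color table
dichotomize_by_median(setNames(summ$school_average_score, summ$group))
```

A command-line wrapper (`inst/exec/dmat`) exposes the same pipeline as
`validate`, `score`, `aggregate`, `compare` and `simulate` subcommands.

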