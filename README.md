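# wetsdm

Structured decision analysis for landscape-scale wetland restoration
targeting.

Restoration planners screening a large coastal-plain landscape can face
hundreds to thousands of candidate restoration sites ("alternatives"), each
with opportunity to improve water quality and climate resilience. `wetsdm`
implements the full decision pipeline for that problem: it delineates
candidate patches and their contributing watersheds from raster landscape
data, measures seven decision criteria per alternative, ranks the
alternatives under two multi-criteria methods across weight-sensitivity
sweeps, scores them on the first principal component of the standardized
criteria, assembles priority sets, and screens candidate outreach regions
with consequence tables and dominance analysis. A synthetic-landscape
generator with planted ground truth makes every stage testable end to end.

## The model

Seven criteria measure two objectives. Water quality: total nitrogen and
total phosphorus loads entering an alternative from its contributing
watershed (TN, TP, kg/yr, from per-sector export coefficients), share of
agricultural land use in the watershed (AG, %), share of
ecohydrologically active area in the patch (EHA, %, land within 0.5 m
vertical of the nearest down-gradient surface water along the D8 flow
path), and 100-year floodplain presence (FP, yes/no). Climate resilience:
share of high-storage dual-class hydrologic soils A/D, B/D, C/D (WS, %)
and share of above-average climate flow (CF, %). Larger is preferred on
every criterion.

Each criterion measure *z<sub>ij</sub>* is scaled to [0, 1]. Linear value
scaling uses

&nbsp;&nbsp;*x<sub>ij</sub>* = (*z<sub>ij</sub>* − *z<sub>j</sub>*\*) / (*z<sub>j</sub>*\*\* − *z<sub>j</sub>*\*),

with *z\** and *z\*\** the worst and best measures of criterion *j*; the
distance orientation uses the complement. The heavy-tailed criteria TN,
TP and CF instead use a risk-averse empirical-CDF scale,
*x<sub>ij</sub>* = P(*z* ≤ *z<sub>ij</sub>*), whose largely concave shape
discounts rare very large measures.

Two aggregation methods rank the alternatives:

- additive value function (multi-attribute value theory):
  *V<sub>i</sub>* = Σ<sub>j</sub> *w<sub>j</sub> x<sub>ij</sub>*, higher
  better;
- compromise-programming distance from the ideal alternative:
  *D<sub>i</sub>* = Σ<sub>j</sub> *w<sub>j</sub><sup>p</sup>
  x<sub>ij</sub><sup>p</sup>* (default *p* = 2; the conventional
  (Σ (*w<sub>j</sub> x<sub>ij</sub>*)<sup>p</sup>)<sup>1/p</sup> norm is
  available as an option), lower better.

Weights come from a two-objective emphasis scheme: the emphasized
objective's criteria share a proportion *w* ∈ {0.60, 0.65, …, 0.90}
equally and the other objective's criteria share 1 − *w* equally (at 60%
water-quality emphasis each of the five WQ criteria gets 0.12 and each of
the two CR criteria gets 0.2). Seven emphasis levels × two objectives ×
two methods = 28 ranking runs; ranks are averaged over each objective's 14
runs and the top 100 alternatives per objective are retained. A parallel
route standardizes the criteria (mean 0, sd 1), eigendecomposes their
covariance matrix *A*, and scores each alternative on the dominant
eigenvector, *Z<sub>1i</sub>* = Σ<sub>n</sub> *v<sub>n1</sub>
x<sub>ij</sub>*; the 100 lowest *Z*₁ scores join the water-quality
priorities. Priority categories (water quality / climate resilience /
both), adjacency expansion, a two-foot elevation exclusion and region
assignment produce the final map sets, and region × criterion consequence
tables — color-coded by 20/60/20 placement and reduced by dominance —
support the final tradeoff deliberation.

## Worked example

```r
library(wetsdm)

cfg  <- synth_config(n_alternatives = 500, seed = 1)
ga   <- gen_alternatives(cfg)          # table + planted ground truth
sets <- prioritize_alternatives(ga$table)
sets
#> priority sets: 77 water quality, 30 climate resilience, 44 both,
#>   266 adjacent, 53 excluded (low elevation)
```

Of 500 synthetic alternatives, 44 rank in the top 100 under both
weighting scenarios (highest priority), 77 qualify through the
water-quality scenario or their low *Z*₁ score, and 30 through climate
resilience alone; 53 candidates fell below the two-foot elevation cutoff
and were excluded. The planted dominant alternative (id 1) lands in
`sets$both`, as it must.

```r
ct <- consequence_table(ga$table, sets, "overall")
ct
#> consequence table (overall): 4 regions
#>         TN     TP    AG   EHA   FP    WS    CF
#> R1 3559.82 188.60 74.08 58.92 0.57 48.25 38.14
#> R2 3157.06 167.86 67.32 56.18 0.62 54.43 36.03
#> R3 3646.93 135.95 75.03 57.56 0.62 53.03 32.71
#> R4 4136.11 244.94 71.28 61.22 0.55 50.51 33.00

coded <- drop_irrelevant(color_code(ct, reference = ga$table))
dominance(coded)$non_dominated
#> [1] "R1" "R2" "R3" "R4"
```

Each cell is the mean criterion measure of the priority alternatives in a
region. After 20/60/20 color coding, all four synthetic regions trade off
value on some criterion, so none is dominated — on real landscapes with
more contrasted regions, dominated regions drop out and any region
dominating all others is the standout choice.

The raster route starts one step earlier:

```r
ls  <- gen_landscape(cfg)                    # DEM + land use + masks
tab <- screen_landscape(ls)                  # patches -> criteria table
```

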