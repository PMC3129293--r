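# khscm

Step-down costing of health facilities and essential-health-package
episodes, in the tradition of the Kenya Health Sector Costing Model.

Health-system planners in low- and middle-income countries need to know
what a visit, an admission, a bed-day or a treated malaria case actually
costs — by level of care and by owner (government, faith-based/NGO,
private) — before they can budget an essential package of care or predict
how costs respond to rising coverage. Facility accounts alone cannot answer
this: most cost sits on support departments (administration, laundry,
kitchen) and has to be apportioned onto the departments that serve
patients. `khscm` implements the standard machinery for this job as a
tested, scriptable R package for health economists and costing analysts.

## The model

**Step-down allocation.** Each facility's ledger is split into *direct*
cost (attributable to a single cost unit — a visit, an operation) and
*indirect* cost attached to the cost centre where it occurs. Support
centres then close one at a time: the closing centre's accumulated cost
$c_s$ is distributed over the not-yet-closed centres $r$ in proportion to
basis weights $w_r$,

$$\text{received}_r = c_s \cdot \frac{w_r}{\sum_{r' \in \text{open}} w_{r'}},$$

until only final centres (OPD, wards) hold cost. Closed centres never
receive (one pass, no reciprocal allocation). Unit costs divide each
service group's total by its annual output; the admission/bed-day cost
ratio approximates the average length of stay.

**Annualization.** Assets depreciate straight-line over 10/8/8/30 years
(general equipment / medical equipment / vehicles / buildings); buildings
are valued as floor area × cost per m²; two ledger years are averaged with
the earlier year uplifted by 5% inflation; Ksh convert to EUR at 90.66;
staff time is valued at (base + allowances) / (220 days × 6 h × 60 min).

**Episode costing.** A treatment episode costs its direct recipe (drugs,
staff minutes, lab tests at unit prices) **plus** the *indirect* component
of the unit cost as overhead — per visit for outpatient schemes, per
bed-day × length of stay for inpatient ones — so direct inputs are never
double-counted. Normative (standard-scheme) and actual variants use the
same machinery. Mean outside-facility drug purchases from exit interviews
are folded into provider unit costs; user fees and transport are not.

**Scenarios.** With a fixed/variable split $(F, V)$ of the national cost
matrix, demand multiplied by $m$ within existing capacity costs
$F + mV$ — a factor $(F + mV)/(F + V) \le m$; beyond a capacity threshold,
discrete expansion blocks are added. Inpatient unit costs can be restated
at a standard 85% bed occupancy.

A seeded synthetic-data generator emulates a stratified national facility
sample and can be calibrated so its aggregate reproduces a target cost
matrix; the bundled fixtures are the published Kenyan FY 2006/07 national
summary and unit-cost tables.

## Worked example

```r
library(khscm)

rec <- load_facility_ledger(system.file("extdata", "toy_facility", package = "khscm"))
res <- stepdown_allocate(rec)
res
#> <allocation_result> 1 support centre(s) closed onto 2 final centre(s)
#>   order: ADMIN
#>   total cost 2,420,000 Ksh (direct 220,000, indirect 2,200,000)

unit_costs(res, rec)
#> # A tibble: 3 x 8
#>   measure          total_ksh output unit_cost_ksh direct_ksh indirect_ksh ...
#> 1 outpatient_visit   955556.   5000          191.       20           171.
#> 2 admission         1464444.    600         2441.      200          2241.
#> 3 bed_day           1464444.   3600          407.       33.3         373.
```

The 400,000 Ksh sitting on administration has been spread over OPD and the
ward in proportion to their own indirect costs; each visit at this toy
health centre costs ~191 Ksh (20 direct, 171 allocated overhead), each
admission ~2,441 Ksh, and the admission/bed-day ratio of 6.0 is the average
length of stay.

National reporting runs off the bundled summary matrix:

```r
m <- kenya_cost_matrix()
share_by_category(m)
#>   category        amount     share_of_total_pct share_of_recurrent_pct
#> 1 drugs_supplies  156223174                 22                     31
#> 2 staffing        259734287                 37                     52
#> 3 other_recurrent  87280555                 13                     17
#> 4 fixed           191709086                 28                     NA

fv <- fixed_variable_split(m, "fixed_only")
demand_multiplier_factor(fv$F, fv$V, 3)
#> [1] 2.448277
```

Staffing absorbs 37% of the 694,947,102 € total (52% of recurrent cost);
because 27.6% of cost is fixed, tripling demand raises total cost by a
factor of only ~2.45, not 3 — the economic core of the coverage scenarios
(`coverage_response()`, `autoplot()`).

An end-to-end run on a synthetic sample:

```r
s <- generate_sample(generator_config(), seed = 42)   # 154 facilities: 85/35/34 by trustee
write_sample(s, "sample")
run_pipeline("sample", "report")   # matrix.csv, unit_costs.csv, episodes.csv, curve.csv, manifest.json
```

A thin command-line wrapper with the same stages (`synth`, `ingest`,
`stepdown`, `keph`, `report`, `scenario`, `run`) is installed at
`system.file("cli", "khscm.R", package = "khscm")`.

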