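---
title: "Methods: step-down facility costing, episode costing and coverage scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step-down facility costing, episode costing and coverage scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(khscm)
```

`khscm` is a costing engine for national health-sector analysis in settings
where facility accounting is rudimentary: it turns facility ledgers, asset
registers, payrolls and service statistics into unit costs per outpatient
visit, admission and bed-day, costs essential-package treatment episodes,
aggregates to a national stratum-by-category matrix, and simulates cost
response to rising coverage. This vignette explains the model, its
assumptions and the design choices where the methodology left them open.

## The cost model

### Direct and indirect cost

Every ledger line is classified by *traceability*. Cost induced by a single
cost unit (an outpatient visit, an operation, a delivery) is **direct** and
attaches to that cost unit. Everything else is **indirect** and attaches to
the cost centre where it occurs. Cost centres are either **support**
centres (administration, laundry, kitchen) — they serve other centres, not
patients — or **final** centres (OPD, wards), whose output is a countable
service. Each item also carries one of four input categories: drugs and
supplies, staffing, other recurrent cost, fixed (annualized capital) cost.
The category label survives every later transformation, which is what makes
the fixed/variable scenario analysis possible downstream.

### Step-down allocation

`stepdown_allocate()` implements classic one-pass step-down: support
centres close one at a time, and a closing centre's accumulated cost — its
own indirect cost plus whatever it received from earlier closures — is
distributed over all not-yet-closed centres in proportion to basis weights.
Closed centres never receive anything back, so reciprocal allocation loops
are structurally impossible and the cascade always terminates with the
entire indirect cost on final centres.

Three choices here were genuinely open, and we resolved them as follows:

* **Closure order.** The method prescribes an order without naming one. The
  default is descending accumulated indirect cost (the common convention:
  the biggest support centre distorts least when it closes first), with
  ties broken by centre id so results are reproducible. Any published or
  in-house order can be forced with `ordering = "explicit_list"`.
* **Allocation bases.** Field practice uses "an appropriate measure of
  output" per support centre — bed-days for the kitchen, floor area for
  maintenance, and so on. The engine supports those bases where the centre
  chart carries the data (`bed_days`, `outpatient_visits`, `staff_count`,
  `floor_area`, explicit weights). The *default* basis is
  `direct_cost_share`: each receiver is weighted by its own indirect cost
  before allocation. It is always computable from the ledger alone and
  scale-free.
* **Frozen weights.** `direct_cost_share` weights are the receivers' costs
  *before* the cascade starts, not updated mid-cascade. Updating them with
  received amounts would make results depend on floating-point accumulation
  order; freezing them keeps the allocation exactly reproducible and
  order-sensitivity interpretable.

Order sensitivity is real — different closure orders shift cost between
final centres — but conservation is exact under every order: the sum of
final-centre totals plus direct cost equals the ledger total (tested to
1e-6 relative, observed at ~1e-16). The test suite also checks the engine
against an independent brute-force sequential allocator on thousands of
small random instances.

### Unit costs

`unit_costs()` divides each service group's total (allocated indirect cost
of its final centres plus direct cost attached to its cost units) by annual
output: visits for the outpatient group, admissions and bed-days for the
inpatient group. Each unit cost is decomposed direct/indirect and
fixed/variable. A facility with nonzero cost but zero recorded output
cannot be unit-costed; the engine raises a typed error and the pipeline
excludes the facility *and counts it* — incomplete facilities are a
reported quantity, not silent data loss. The admission/bed-day cost ratio
is reported at one decimal as an average-length-of-stay proxy, and the
bed-day/visit ratio as a workload comparison.

### Annualization

* Straight-line depreciation from full initial value: 10 years for general
  equipment, 8 for medical equipment, 8 for vehicles, 30 for buildings; no
  salvage value, no mid-year convention. Buildings may be valued as floor
  area × regional cost per m². A per-asset `condition_adjustment`
  multiplies the lifetime (how condition adjustment was applied in the
  original exercise is not documented; a multiplicative lifetime factor is
  the simplest faithful mechanism).
* Two ledger years are combined as `(year1 × 1.05 + year2) / 2`; the 5%
  uplift is exposed as a parameter. Whether the uplift should compound over
  longer series is not specified anywhere, so the engine deliberately
  models only the two-year average and rejects longer ledgers.
* Currency: a single fixed rate (90.66 Ksh/€). Conversion is exact and
  unrounded; rounding (half away from zero) happens only at reporting.
* Staff time: (base + allowances) / (220 working days × 6 direct hours ×
  60), i.e. 79,200 minutes per year by default. Missing private-sector pay
  falls back to the public scale and is flagged as imputed.

### Episode costing

An episode's **direct** cost prices its resource recipe: drug and lab
quantities at price-list prices plus staff minutes at per-minute rates.
Its **overhead** is the *indirect component only* of the relevant unit
cost — per visit for outpatient schemes, per bed-day × length of stay for
inpatient ones. Using the full unit cost would double-count the drugs and
staff time already in the direct recipe; this interpretation is flagged in
the report footnote because published episode tables rarely state it.
Schemes carry per-age-group quantities; costing takes an `age_group`
argument (default `"under5"`). Normative (expert standard) and actual
(observed use) variants run through the same functions, so an identical
scheme costs identically and a normative superset can only cost more.

Demand-side adjustment adds the unweighted mean outside-facility drug
purchase per interviewed patient (by stratum and patient type) to the
provider unit cost — stock-outs push real resource use above facility
expenditure, most strongly in the public sector. User fees and transport
are recorded but never added: fees are transfers, transport is not a
provider cost. No weighting scheme is applied to the interview means
because none is documented for the original survey.

### National aggregation and reporting

`national_totals()` sums facility category totals by stratum with optional
expansion weights. Weights default to 1 — the package reports the sample
itself, because the original expansion from a 154-facility sample to the
4,002-facility national list is undescribed. The bundled national matrix
(`kenya_cost_matrix()`, FY 2006/07, EUR) carries printed cells *and*
printed margins; they disagree by ±1 € on a few rows because the source
rounded independently, so the matrix validator allows about one currency
unit of slack per row and then treats the printed margins as authoritative.

Two published shares do not recompute from that matrix: the labelled
public rows give 52% (printed: 54%) and the administration rows 7%
(printed: "some 6%"). Similarly the unlabelled nursing-home row must be
*excluded* from the private group to reproduce the printed 23% (including
it gives 24%), and the drugs share of recurrent cost computes to 31%, not
the printed 28%. The package documents these discrepancies and asserts the
recomputed values; it does not force the printed ones.

### Scenarios

`fixed_variable_split()` offers two policies: `fixed_only` (annualized
capital is fixed, everything else variable) and `fixed_plus_staffing`
(hiring professional staff is sticky in the short run, so staffing is also
fixed). Within capacity, demand × m costs `F + mV`, a factor
`(F + mV)/(F + V) ≤ m`. On the bundled matrix the fixed-only split gives a
factor of ≈2.45 at threefold demand; the originally published 2.11 rests
on an unpublished fixed/variable classification and is treated as a
qualitative anchor (subproportionality), not a target.

`coverage_response()` adds a capacity mechanism: above a utilization
threshold (default 1.4 × baseline — a 25%→35% coverage rise fits within
existing capacity), discrete expansion blocks of `capacity_block`
utilization units (default 0.2) are added at `expansion_step_cost` each.
The block size is this package's own parameter; the source methodology
says only that extra demand eventually "calls for increased capacity".
With the default step cost of 0 the curve is the pure `F + uV` line.

`standard_occupancy_unit_costs()` restates inpatient unit costs at 85%
occupancy: fixed cost per bed-day rescales by actual/standard bed-days,
variable cost per bed-day is unchanged, and the standard admission cost
keeps the facility's actual length-of-stay proxy. At actual occupancy the
restatement is the identity; for an under-utilized private district
hospital it strictly reduces both inpatient unit costs.

## The synthetic-data generator

No facility micro-data accompany the published tables, so the package
ships a seeded generator whose defaults *are* the study conditions:

* **Stratification.** The default plan is the analysed sample: 154 units
  over levels 2–6, nursing homes and district administration, 85 public /
  35 FBO-NGO / 34 private. An extended plan adds the singleton strata the
  national matrix has but the sample table does not (community services, a
  public nursing home, the ministry, a district/provincial administration
  split of 7 + 2 — only their total of 9 is documented).
* **Cost scales.** Per-stratum, per-category log-normal draws for the
  later ledger year; the earlier year sits 2–12% below it so the
  inflation-averaging path is exercised end to end. Location parameters
  default to the bundled national matrix cell divided by the stratum's
  facility count; dispersion is trustee-specific (σ = 0.3 public, 0.6
  FBO/NGO, 0.9 private), encoding the finding that private-sector unit
  costs spread far more widely than public ones.
* **Service volumes.** Derived from the two bundled published tables: the
  stratum's mean facility cost is split half outpatient / half inpatient
  and divided by the published cost per visit and per bed-day, so
  synthetic unit costs come out at realistic magnitudes. Occupancy is
  stratum-specific (public district hospitals over-full at 107%,
  provincial at 90%, private hospitals well under capacity at ~45–50%),
  which is exactly the structure the standard-occupancy scenario needs.
  Admissions follow from bed-days via the published admission/bed-day cost
  ratio. A synthetic "facility" is therefore a national stratum slice: the
  whole-sample aggregate equals the national total at weights 1, matching
  the package's report-the-sample default.
* **Exit interviews** (default n = 1369): log-normal outside-drug
  purchases with public > FBO/NGO > private means (450/300/150 Ksh),
  encoding the stock-out gradient. **Treatment schemes**: a small invented
  collection (malaria by age group, diarrhoea, normal delivery, inpatient
  pneumonia) in actual and normative variants, with normative recipes as
  supersets; these are labelled synthetic throughout — the real 59-scheme
  collection is unpublished, which is also why absolute episode costs are
  out of reach and only orderings are tested.

`calibrate_to_matrix()` closes the stochastic gap between a generated
sample and a target matrix by one deterministic rescaling pass:
`meanlog += log(target/actual)` per stratum × category. Because a location
shift scales every log-normal draw multiplicatively without disturbing the
random stream, regeneration under the same seed hits the target margins to
floating-point precision (observed residuals ~1e-7 of a percent against
the national matrix); the 1% tolerance exists because any change to seed
or structure reintroduces sampling noise, and a zero tolerance is rejected
outright. One per-stratum caveat: the published matrix itself has
fixed-cost shares from 9% (public tertiary) to 48% (private district), so
the generator's stratum shares follow the printed rows rather than any
uniform band; only the sample-wide share (27.6%) is banded in the tests.

What passing tests on this synthetic sample do **not** show: that the
engine reproduces the published absolute unit costs (Ksh per visit,
admission, episode) — those depend on the unpublished micro-data and the
real sample's within-stratum heterogeneity, exclusions (53 of 207
facilities) and measurement error, none of which the generator emulates.
The synthetic sample validates mechanics (conservation, calibration,
direction of scenario effects, orderings), not field values.

## Numerical choices and degenerate inputs

* Report rounding is half away from zero (`round_half_away()`), matching
  how the published tables are rounded; base R's half-to-even would give
  16 where the published share is 17.
* Tie-breaks: equal-cost support centres close in centre-id order.
* Degenerate cases: a support centre with zero cost is skipped silently; a
  basis that gives zero weight to every remaining receiver is an error
  naming the centre; an all-direct ledger leaves the indirect map empty; a
  zero-support facility's final centres keep their own costs; occupancy
  above 100% is legal (observed in practice) and only above 150% draws a
  validation warning.
* Problem sizes: property tests run ~600 random step-down instances of up
  to 7 support and 4 final centres against the brute-force oracle, and the
  calibration check runs the full 157-unit extended plan twice; the whole
  suite completes in about a minute.

## Known limitations

* One-pass step-down only; reciprocal (simultaneous-equations) allocation
  and activity-based costing are out of scope.
* No variance model: national totals carry no confidence intervals, and
  sampling weights are user-supplied if expansion beyond the sample is
  wanted.
* The two-year inflation average does not generalize to longer series.
* Episode costing resolves age groups but not severity or comorbidity, and
  demand-side costs cannot be broken down by condition.
* Level-1 (community) services appear only as a single aggregate row;
  their internal costing is not modelled.
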