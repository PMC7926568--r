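# hwfplan

Needs-based health workforce planning as a deterministic, tested
simulation engine in R.

Health ministries and planners need to know how many midwives, physicians
or other cadres their population will *need* over the next decade — derived
from demography, health status and explicit service norms rather than from
current utilisation — and whether the training pipeline and labour market
will deliver that many. hwfplan implements the population needs-based
planning methodology end to end:

* **Need.** For each service and year, the evidence-based service
  requirement is `NHS_t = Σ_strata P × H_t × L`: population times the
  proportion in need times the planned service frequency, with the level of
  need `H_t = H_{t-1}(1 + R)` compounding at an annual rate of change
  estimated from two survey waves. Volumes convert to full-time-equivalent
  requirements via WISN-style standard workloads `SW = AWT / SS` (available
  working time over the service standard), work division `W` across cadres,
  and the support-activities adjustment factor `SAAF = 1 / (1 − Σ SAS)`:

  `N_{n,t} = ( Σ_y NHS_{y,t} · W_{y,n} / SW_{n,y} ) × SAAF_n`

* **Supply.** A stock-and-flow recursion per cadre:
  `T_t = T_{t-1}(1 − a) + I_t`, `S_t = T_t × P`, with attrition `a`,
  participation rate `P`, and education-pipeline inflow
  `I_t = (enrolment_{t−d}(1 − dropout) + immigration_t) × pass rate`.

* **Integration.** Absolute gap `S − N` (negative = shortage still to be
  trained), staff availability ratio `SAR = S / N` (1 = equilibrium), and
  wage bills `headcount × income` with income compounding at an inflation
  rate — plus pre-registered what-if variants (rate of change off, support
  adjustment off, tertiary activity standards) and seeded Latin-hypercube
  sensitivity sweeps.

Scenarios are validated YAML + CSV configurations (population, indicators,
services, cadres); every invariant violation is reported with the offending
parameter path. A seeded synthetic-scenario generator makes the whole
engine testable with no external data.

## Worked example

The bundled demo scenario is a *synthetic* maternal-and-newborn-care
setup (two cadres, four services, three female age cohorts, 2020–2030);
the raw national inputs of the published application are not public, so
this scenario illustrates the machinery rather than any country estimate.

```r
library(hwfplan)
scn <- load_scenario(system.file("extdata", "demo_scenario",
                                 package = "hwfplan"))
res <- run_scenario(scn)
res
#> <hwf_projection> demo-maternal-care-synthetic (2020-2030)
#>   midwife: need 7,184 -> 9,803, supply 11,930 -> 28,818, gap 4,746 -> 19,015, SAR 166.1% -> 294.0%
#>   obstetrician_gynaecologist: need 1,449 -> 2,193, supply 189 -> 515, gap -1,260 -> -1,678, SAR 13.0% -> 23.5%

subset(res$cadres, year %in% c(2020, 2025, 2030),
       c(cadre_id, year, need, supply, gap, sar_pct))
#>                    cadre_id year need supply   gap sar_pct
#>                     midwife 2020 7184  11930  4746   166.1
#>                     midwife 2025 8390  19955 11565   237.8
#>                     midwife 2030 9803  28818 19015   294.0
#>  obstetrician_gynaecologist 2020 1449    189 -1260    13.0
#>  obstetrician_gynaecologist 2025 1780    337 -1443    18.9
#>  obstetrician_gynaecologist 2030 2193    515 -1678    23.5
```

Reading the obstetrician/gynaecologist rows: the needs-based requirement
(1,449 FTE in 2020) far exceeds the projected supply (189), a shortage of
1,260 specialists; the SAR of 13.0% says the anticipated supply covers
13% of the need, improving only to 23.5% by 2030 under current training
rates. The midwife rows show the opposite pattern — a needs-based
oversupply growing over the horizon.

```r
summarize_growth(with(subset(res$cadres, cadre_id == "midwife"),
                      setNames(need, year)))$cagr_pct
#> 3.199...   # midwife need grows ~3.2% a year in this scenario

compute_saaf(c(0.125, 0.05))
#> 1.212121   # two support activities (12.5% + 5% of AWT) inflate need by 21.2%
```

`write_results(res, "out/")` exports `need.csv`, `supply.csv`, `gaps.csv`,
`costs.csv`, `services.csv` and a `summary.md`. A thin command-line
wrapper ships in `inst/cli/`:

```sh
Rscript inst/cli/hwfplan.R demo --out out/
Rscript inst/cli/hwfplan.R project --scenario my_scenario/ --variant no-rate-change --out out/
Rscript inst/cli/hwfplan.R sweep --scenario my_scenario/ --ranges ranges.yaml --seed 7 --out out/
```

The methods vignette
(`vignettes/needs-based-workforce-planning.Rmd`) documents the model,
its assumptions, the numerical conventions (geometric vs continuous rate
estimation, half-up rounding at reporting, clamping of proportions) and
the validation strategy.

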