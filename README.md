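# mycorisk

Dietary health-risk characterization of toxic elemental impurities (Cd,
Pb, As, Hg, or any element with a toxicity reference) in wild edible
mushrooms and similar single-commodity foods. The package is aimed at
food-safety and environmental-health analysts who have a species × element
concentration table (mg/kg dry weight, mean ± SD from replicate ICP-MS
measurements) and need the standard US EPA ingestion-risk indices, a
probabilistic (Monte Carlo) uncertainty layer over the exposure inputs,
and a way to validate the whole pipeline against synthetic data with known
ground truth.

## The model

For a concentration *MC* (mg/kg dw) and an exposure scenario with intake
rate *IR* (kg/day), exposure frequency *EF* (days/year), exposure duration
*ED* (years), body weight *BW* (kg), and averaging time *AT* (days):

```
EDI = (MC × IR × ED × EF) / (BW × AT)          [mg/kg bw/day]

THQ = EDI_noncarc / RfD        HI  = Σ_elements THQ
CR  = EDI_carc × CSF           TCR = Σ_elements CR
```

Non-carcinogenic risk averages dose over the exposure period itself
(AT = EF × ED); carcinogenic risk averages over a 70-year lifetime
(AT = 25,550 days) for children and adults alike, because cancer risk is
cumulative. HI ≤ 1 indicates no significant non-carcinogenic risk,
1 < HI < 10 a specific risk, HI ≥ 10 a significant risk; CR/TCR ≤ 1e-6 is
no hazard, 1e-6–1e-4 tolerable, ≥ 1e-4 unacceptable.

The Monte Carlo engine replaces each input with a declared distribution —
concentrations lognormal (fitted from mean ± SD, with an explicit choice
between median-anchored and moment-matched parameterization), IR and EF
uniform, BW truncated normal — and summarizes the HI and TCR draws at the
mean, median, and 95th percentile with exceedance probabilities.
Non-detects are carried as "not calculated", never as zeros.

## Worked example

```r
library(mycorisk)

tab <- mushroom_concentrations()     # packaged six-species ICP-MS table
res <- assess_risk(tab, groups = c("adult", "child"))
unique(res[res$group == "adult", c("species", "hi", "tcr", "hi_category")])
#>   species                        hi      tcr      hi_category
#>   Morchella importuna      1.176376 0.000500    specific_risk
#>   Tricholoma scalpturatum  0.420676 0.000251    no_risk
#>   Infundibulicybe geotropa 1.112872 0.000941    specific_risk
#>   Tricholoma populinum     1.159696 0.000656    specific_risk
#>   Pholiota carbonaria      0.980212 0.000745    no_risk
#>   Laccaria laccata         1.635772 0.002229    specific_risk
```

Only *T. scalpturatum* and *P. carbonaria* stay below the HI = 1 bound for
adults; every total carcinogenic risk exceeds the 1e-4 acceptability
threshold (driven by cadmium), with *L. laccata* worst. The probabilistic
layer:

```r
cfg <- simulation_config(tab, "adult", n_iter = 10000, seed = 1)
sim <- simulate_risk(cfg)
subset(sim$summary, species == "Laccaria laccata")
#>   species          group metric  mean    p50     p95    p_exceed
#>   Laccaria laccata adult HI     4.727   4.215   10.099  0.9656
#>   Laccaria laccata adult TCR    0.00618 0.00558 0.01296 1.0000
```

so even at the median the population HI for this species sits well above
1 once intake-rate and body-weight variability are propagated. Histograms
per species and metric: `export_histograms(sim, "out/")`.

A shell entry point with the same operations (plus synthetic-table
generation and an IC50 helper for dose–response series) is installed at
`exec/mycorisk`.

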