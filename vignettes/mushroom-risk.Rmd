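---
title: "Deterministic and probabilistic risk assessment of elemental impurities in mushrooms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic and probabilistic risk assessment of elemental impurities in mushrooms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycorisk)
```

## The problem

Wild edible mushrooms bioaccumulate toxic elements — cadmium, lead,
arsenic, mercury — from soil and atmosphere, so a food prized for its
phenolic and antioxidant content can simultaneously be a meaningful
dietary source of Class-I elemental impurities. mycorisk turns a measured
species × element concentration table (mg per kg dry weight, mean ± SD
over replicate digestions) into the standard ingestion-risk indices, both
as point estimates and as Monte Carlo distributions over the exposure
inputs.

## The exposure model

The estimated daily intake for one element in one food is

$$\mathrm{EDI} = \frac{MC \times IR \times ED \times EF}{BW \times AT},$$

with the concentration $MC$ in mg/kg dw, intake rate $IR$ in kg/day,
exposure frequency $EF$ in days/year, duration $ED$ in years, body weight
$BW$ in kg, and averaging time $AT$ in days. Two averaging conventions
coexist deliberately:

* **non-carcinogenic** risk averages the dose over the exposure period
  itself, $AT = EF \times ED$ (2,100 days for the default child scenario,
  9,100 for the adult), so for default scenarios the EDI collapses to
  $MC \times IR / BW$;
* **carcinogenic** risk averages over a 70-year lifetime,
  $AT = 25{,}550$ days, for children and adults alike, because cancer
  risk is treated as cumulative over a lifetime however early the
  exposure occurs.

The target hazard quotient divides the non-carcinogenic EDI by the
element's oral reference dose (RfD); the hazard index HI sums THQs over
the elements present in the food. Carcinogenic risk multiplies the
lifetime-averaged EDI by the oral cancer slope factor (CSF); TCR sums
over elements. Band edges follow the conventional inequality directions:
HI ≤ 1 no significant risk, 1 < HI < 10 specific risk, HI ≥ 10
significant risk; CR/TCR ≤ 1e-6 no hazard, up to 1e-4 tolerable, ≥ 1e-4
unacceptable. Ties land in the band the inequality names, so the bands
partition $[0, \infty)$.

Default constants: IR $6.6\times10^{-3}$ kg/person/day, EF 350 days/year,
ED 6 y (child) or 26 y (adult), BW 25.6 kg / 70 kg. Default toxicity
references (mg/kg/day and (mg/kg/day)$^{-1}$): RfD As $3\times10^{-4}$,
Cd $10^{-3}$, Hg $3\times10^{-4}$, Pb $3.5\times10^{-3}$; CSF As 1.5,
Cd 6.3, Hg 6.177, Pb 0.0085. All concentrations are on a dry-weight
basis; no wet/dry conversion, cooking-loss, or bioaccessibility
correction is attempted.

```{r deterministic}
tab <- mushroom_concentrations()
res <- assess_risk(tab, groups = c("adult", "child"))
head(subset(as.data.frame(res), group == "adult"), 8)
```

### Non-detects

Mercury in *Laccaria laccata* is below the detection limit. The record is
kept with `detected = FALSE` and no numbers — not as a zero — and every
downstream stage excludes it from sums while reporting the cell as NC
("not calculated"). Distinguishing "absent" from "measured zero" matters:
substituting 0 (or LOD/2) would silently change HI and TCR and hide the
censoring from the reader.

## The Monte Carlo layer

`simulation_config()` + `simulate_risk()` replace each input with a
declared distribution and propagate 10,000 draws (configurable) through
the same arithmetic as the deterministic chain:

| parameter | default distribution | rationale |
|---|---|---|
| MC | lognormal fitted from the row's mean ± SD | concentrations are positive and right-skewed |
| IR | uniform 0.0033–0.03 kg/day | consumption-survey range |
| EF | uniform 350–365 days/year | near-daily consumption |
| ED | point mass (6 y child, 26 y adult) | a single stated value admits no spread |
| BW | truncated normal, child 15–49 kg, adult 50–90 kg | see below |
| AT | EF × ED per draw (non-carc.), 25,550 d (carc.) | same conventions as above |

Design choices that were genuinely open:

* **Lognormal anchoring.** A reported arithmetic mean ± SD does not pin a
  lognormal down. `moment_matched` preserves the arithmetic moments
  ($\sigma^2 = \ln(1 + cv^2)$, $\mu = \ln m - \sigma^2/2$);
  `median_anchored` pins the median to the reported mean
  ($\mu = \ln m$, same $\sigma$). Both are exposed; `median_anchored` is
  the default because the resulting median HI tracks the deterministic
  HI rescaled by the median intake-rate ratio, which is how the
  probabilistic and deterministic summaries are usually compared. The
  choice is configurable rather than silent precisely because it is not
  identifiable from a mean ± SD table.
* **Body weight from a range.** Only a plausible range per group is
  specified, so BW is a normal with mean at the midpoint and sd a quarter
  of the range, truncated to the range (inverse-CDF sampling, so every
  draw respects the bounds). Midpoint/quarter-range is the standard
  range-to-normal heuristic; truncation prevents nonphysical weights.
* **Lifespan scenario.** A whole-life group (ED 70 y, BW truncated
  normal over 15–90 kg) is provided for exploration but is deliberately
  not part of the validated surface: its defining constants are not part
  of the core exposure model.
* **RNG substreams.** One master seed derives a deterministic substream
  per parameter (and per species × element concentration), so adding or
  removing a species never perturbs another species' draws, and a single
  logged draw can be replayed by hand.

Summaries report the mean, median, and 95th percentile (percentiles by
linear interpolation between order statistics, R's default type 7) and
the exceedance probabilities P(HI > 1) and P(TCR > 1e-4). With every
distribution degenerate (point masses at the deterministic constants) the
engine reproduces `assess_risk()` to machine precision — the central
cross-check between the two modules.

```{r simulate}
sim <- simulate_risk(simulation_config(tab, "adult", n_iter = 2000,
                                       seed = 1))
subset(sim$summary, metric == "HI")
```

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` / `generate_table()` simulate the *measurement* layer:
per (species, element) true mean and SD, replicate draws from a lognormal
moment-matched to those values (a normal option exists as a deliberate
mis-specification check), empirical mean/SD emitted exactly as a real
ICP-MS table would report them, non-detects passed through.
`recovery_experiment()` closes the loop: HI/TCR assessed from the
synthetic table versus from the true means. With no noise the recovery is
exact; with noise the error shrinks with the number of replicates (the
empirical cell means obey the law of large numbers).

The generator does **not** emulate soil-to-fruitbody transfer,
between-site contamination gradients, inter-element correlation (the
measured Pb–As correlation is ignored: elements are sampled
independently, matching the simulator), LOD censoring mechanics, or
recovery/matrix effects of the instrument. Passing recovery tests
therefore demonstrates the pipeline's internal consistency under its own
distributional assumptions, not the field accuracy of any particular
survey.

## Numerical choices

* Percentiles: linear interpolation between order statistics; the median
  of a constant vector is that constant; `p50 <= p95` always.
* Truncated normals: inverse-CDF restricted to the bounds' CDF mass;
  a zero-mass truncation region is an error, not a silent fallback.
* `sd = 0` lognormals collapse to a point mass at the mean in both
  anchoring modes.
* Sums over elements ignore non-detects (`NA`); an empty element set has
  HI = 0.
* Band classification is total on the non-negative axis; boundary values
  (HI = 1, CR = 1e-4) go to the band the defining inequality names.
* Validation comparisons against published 3–4-significant-figure tables
  use full double precision internally and allow, per cell, 0.5% plus
  the printed value's own half-ULP plus one ULP of the printed input
  concentration (0.001 mg/kg) propagated linearly — i.e., exactly the
  slack that printing, not computation, introduces.
* IC50: log-linear interpolation between the two concentrations
  bracketing 50% inhibition; a point exactly at 50% is returned as-is;
  sigmoid (4PL) fitting is out of scope by design — bracketing
  interpolation is deterministic and assumption-free.

Problem sizes used by the packaged checks: 10,000 Monte Carlo iterations
for summaries (with 1e3/1e4/1e5 used for the $1/\sqrt{n}$
standard-error scaling check) and 10,000 replicates per cell for the
recovery experiment — large enough that Monte Carlo error is well below
the tolerances being asserted, small enough to run in seconds.

## Limitations

* One commodity per run: no total-diet aggregation across foods.
* Exposure parameters are sampled independently; no correlation between
  intake rate and body weight (children both eat less and weigh less,
  which independent sampling ignores) and no 2-D
  variability-vs-uncertainty separation.
* The deterministic intake-rate constant (6.6e-3 kg/day) and the Monte
  Carlo intake-rate range (0.0033–0.03 kg/day) come from different
  conventions and are intentionally kept in their respective roles; the
  probabilistic medians therefore sit above the deterministic values by
  roughly the median intake ratio.
* Toxicity references (RfD, CSF) are treated as exact constants; their
  own uncertainty is not propagated.
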