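---
title: "Estimating how parental smoking exacerbates child poverty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating how parental smoking exacerbates child poverty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokepov)
```

## The problem and the method

UK child-poverty statistics count a child as in relative poverty when the
household's equivalised net income before housing costs (BHC) falls below
60% of the contemporary median. Tobacco is a substantial, regressive weekly
expense, so two questions follow naturally: how many children in poverty
live with a smoking parent, and how many children just above the line would
fall below it if the household's tobacco spend were deducted from its
income?

No microdata set answers this directly, so the method works entirely from
printed national survey aggregates (2011/12 HBAI income statistics, 2012
Opinions and Lifestyle Survey smoking figures, ONS family statistics, TMA
prices, HMRC illicit-market shares). `smokepov` implements that estimation
pipeline as a single estimator, `smoke_poverty()`, plus a household-level
Monte-Carlo microsimulation that rebuilds the same quantities bottom-up and
quantifies the approximations the aggregate arithmetic makes.

The pipeline has six stages:

1. **Equivalisation.** Modified OECD weights (first adult 0.67, each
   further person aged 14+ 0.33, each child under 14 0.20; childless couple
   = 1.00) convert the equivalised poverty line (0.60 x £427 = £256.20/week)
   into household-specific thresholds, e.g. £223 for a single parent with
   one young child and £392 for a couple with two children, one aged 14+.
2. **Prevalence weighting.** Routine-and-manual smoking prevalence by sex
   (33% men, 32% women) -- the conservative stand-in for prevalence among
   poor parents -- is multiplied by marital-status weights (ratio of the
   marital group's prevalence to the general 20%: single 1.35, married
   0.70, cohabiting 1.65), giving six sex-by-marital rates.
3. **Decomposition.** All-children counts per marital group are multiplied
   by the group's percentage below each band edge, singles are split 91/9
   between mothers and fathers, and each group total is spread over
   family-size classes (1 / 2 / 3+ children).
4. **Attribution.** Single-parent children multiply directly by the single
   rate. For couples, the expected number of smoking parents per household
   is the *sum* of the two sex marginals; smoking-parent instances then
   split 65/35 into sole smokers and smokers whose partner also smokes,
   with dual-smoker homes counted once (division by two).
5. **Expenditure.** Daily consumption (12/13 cigarettes for women/men)
   becomes weekly packs (20 sticks per pack; 50 g of hand-rolling tobacco
   makes about 100), priced licitly (£7.72 and £16.11) or illicitly (half
   price), mixed over the four product types.
6. **Drawn-in counts.** In the 60-70% band, all children in two-smoker
   households and half the children with exactly one smoking parent count
   as drawn into effective poverty.

With the packaged defaults the pipeline reproduces every published table
cell to nearest-thousand precision and yields the two headlines: about 1.09
million children in poverty living with at least one smoker (reported as
1.1 million) and about 432 thousand drawn into effective poverty.

```{r}
fit <- smoke_poverty()
fit
```

## The central approximation

The couple smoking rate is a sum of marginal probabilities -- *expected
smoking parents per couple* -- not a probability of "at least one smoker".
For cohabiting couples it exceeds one (0.5445 + 0.528 = 1.0725). The
double-counting of two-smoker homes is resolved afterwards by the 65/35
sole-smoker split: children with at least one smoking parent per stratum
equal `S x (0.65 + 0.35/2)`, which coincides exactly with
`P(at least one smoker)` when the within-couple joint probability satisfies
the same 65/35 identity. The microsimulation (below) confirms this
equivalence empirically: its with-smoker count matches the aggregate one to
within Monte-Carlo noise. The approximation *does* bite per stratum:
attributed children can exceed children present, and
`attribution_table()` warns when that happens.

## Tunable parameters

All inputs live in one `study_inputs()` object, overridable from a YAML
file (`load_inputs()`); every field carries a provenance label. The ones
that matter most:

| parameter | default | units | role |
|---|---|---|---|
| `median_income` | 427 | £/week equivalised BHC | all thresholds scale linearly in it |
| `poverty_fraction`, `upper_band_fraction` | 0.60, 0.70 | fraction of median | band edges |
| `base_prevalence` | 33 (m), 32 (f) | % | smoking among routine-and-manual adults |
| `marital_prevalence` | 27/14/33 | % | single/married/cohabiting weighting numerators |
| `sole_smoker_fraction` | 0.65 | proportion | sole smokers among partnered smoking parents |
| `cigs_per_day` | 13 (m), 12 (f) | sticks/day | consumption |
| `prices` | 7.72, 16.11, 0.5 | £, £, discount | licit pack, licit 50 g pouch, illicit multiplier |
| `illicit_share` | 0.07, 0.35 | proportion | illicit share of packeted / HRT smokers |
| `drawn_in_fractions` | 0.5, 1.0 | proportion | drawn-in rule for one-/two-smoker homes |

The family-size proportions differ by band: 25/39/36% in the poverty band
(stated directly in the source statistics) and 23/40/37% below the 70%
edge. The latter set is not printed anywhere; it is recovered by dividing
published family-size cells by their row totals, and is exposed in the
configuration so users can replace it. Using the poverty proportions for
both bands is available as a sensitivity scenario via
`sensitivity_sweep()`, but is not the default because it fails to reproduce
the published below-70% table.

Two presentation choices deserve a note. First, thresholds, counts and
rates are carried unrounded everywhere; rounding to the nearest thousand
(counts), one decimal (prevalence) or penny (spend) happens only in print
methods and `write_report()`. Second, the published overall average spends
(£25.90 and £25.01 per week) were computed from the product mix rounded to
integer percentages; `expenditure_profile(..., mix_rounding = "percent")`
replicates that exactly, while the default uses the unrounded mix (giving
£25.86 and £24.96). The rounded-mix option uses a largest-remainder
correction so the rounded proportions still sum to one.

## Numerical and interpretive choices

* **Equivalence-scale constants.** The source names the modified OECD scale
  but not its constants; 0.67/0.33/0.20 is the standard couple-equals-one
  rescaling used by HBAI, and it is validated by the published £223 and
  £392 household thresholds. Reproducing £392 for a "two-parent, two-child"
  household requires one child to be 14 or over, so composition is always
  explicit in the interface (`household_composition()`), never inferred
  from a child count.
* **Illicit prices** are computed as licit x 0.5 (illicit HRT = £8.055),
  not transcribed from the published table's £8.05; the illicit-HRT female
  spend therefore computes to £6.77 against a printed £6.72. The effect on
  the averages is below half a penny.
* **Between-band differencing** clips sub-tolerance negative cells (pure
  rounding noise) to zero and refuses larger violations.
* **Drawn-in totals** apply the half/all fractions to unrounded
  configuration row totals, not to sums of rounded cells (236.0 -> 118.0,
  not 49 + 97 + 90 halved cellwise).
* The published drawn-in table's column totals are internally inconsistent
  with its own cells; the package reports true column sums and asserts only
  the row-structure totals (about 758 and 432 thousand).

## What the microsimulation emulates -- and what it does not

`generate_households()` draws synthetic family households matching, in
expectation, every configured child-level marginal: marital-group shares,
band masses per group, band-specific family-size proportions, and (after
`assign_smoking()`) sex-by-marital smoking rates with a within-couple
dependence calibrated so the sole-smoker fraction is 65%
(`calibrate_concordance()` solves `2 P(both) / (P(m) + P(f)) = 0.35` in
closed form and refuses infeasible targets outside the Frechet bounds).
Because the configured band percentages count children while sampling is
per household, they are converted to household-level masses by dividing by
each band's mean children per household.

Some microdata features have no aggregate anchor and are declared synthetic
assumptions, configurable under `study_inputs()$microsim`: the realised
size of "3+ children" families ({3: 0.7, 4: 0.2, 5: 0.1}), the probability
a child is under 14 (0.7), and the income floor (0.30 x median) and
ceiling (1.60 x median) closing the unbounded bands. Equivalised income is
piecewise-uniform within bands -- uniform inside the 60-70% band, matching
the evenness the method assumes -- with a truncated log-normal alternative
(`income_model = "lognormal"`) for sensitivity. The generator does not
emulate survey weights, nonresponse, regional structure, cohabitation
dynamics, or any income-smoking dependence beyond the configured marginals,
so agreement between oracle and pipeline validates the *arithmetic and its
stated assumptions*, not the underlying survey estimates.

`microsim_estimates()` (or `simulate()` on a fit) replicates the whole
generation, pools Monte-Carlo standard errors, and
`compare_with_aggregate()` reports relative differences. At the default
problem size used throughout the package -- 200,000 households by 20
replicates, a few seconds of runtime -- the oracle reproduces the
with-smoker headline to within a fraction of a percent and the one-/two-
smoker split within Monte-Carlo noise. The drawn-in count, however, comes
out about 15% *below* the aggregate 432 thousand: under uniform within-band
incomes, one-smoker spend (about £25/week) against band widths of £38-77
implies crossing probabilities between roughly 0.33 and 0.67 depending on
household structure (not always 0.5), and two-smoker spend (about £51)
rarely covers the full band width for larger families. The half/all rule is
therefore mildly generous, and the microsimulation quantifies exactly how
much. Subtracting spend from equivalised rather than unequivalised income
(`equivalise_spend = TRUE`) weights spend up by the household factor and is
provided as a scenario flag.

## Interface notes

The package is a library, not a shell tool: `smoke_poverty()` is the entry
point, `summary()`/`coef()`/`plot()`/`simulate()` expose the results,
`sensitivity_sweep()` runs parameter grids, and `write_report()` emits the
six table CSVs, a deterministic JSON summary and a run manifest (versioned
subdirectories on collision). The packaged YAML defaults file round-trips
through `load_inputs()`/`write_inputs()`.

## Known limitations

The estimates inherit every conservatism of the source aggregates:
prevalence among poor parents proxied by the routine-and-manual group
(unemployed prevalence was 39%), self-reported smoking, recommended retail
prices, and general-population illicit shares. The uncertainty of the
survey inputs is not published, so the pipeline propagates none; the
Monte-Carlo standard errors describe simulation noise only, not survey
error. Single-parent gender and family-size splits are applied as
independent proportions; any correlation between family size and smoking,
or between income position within a band and smoking, is absent by
construction.
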