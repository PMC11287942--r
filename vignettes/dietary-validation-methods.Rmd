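---
title: "Validating dietary assessment methods: models, scoring and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating dietary assessment methods: models, scoring and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietvalidr)
```

## The problem this package addresses

Self-reported dietary intake is noisy and systematically biased, yet almost
every nutrition study depends on it. The accepted way to judge a dietary
assessment instrument is a validation study: the same participants report
their diet through the instrument under evaluation and through an
established comparison method, and -- for energy -- against total energy
expenditure (TEE) measured with doubly labelled water (DLW), the reference
method, since habitual energy intake approximately equals TEE under energy
balance. `dietvalidr` implements the complete computational chain of such a
study for a design with three repeated 24-h recalls per participant
reported through two methods (a web tool and telephone interviews), a
nine-component diet-quality index, and a DLW sub-sample, together with a
synthetic-cohort generator so the chain can be exercised and tested without
access to participant data.

## Recall aggregation

`aggregate_days()` turns item-level records (food code, grams) into daily
intakes by linking each item to a per-100 g food-composition table and
summing: energy (kJ), macronutrient masses, and grams per guideline food
group. Energy percentages use configurable conversion factors
(`energy_factors()`: protein and carbohydrate 17 kJ/g, fat 37 kJ/g);
fibre is also expressed per MJ and wholegrain per 10 MJ because
the diet-quality index scores them as densities. The aggregation is linear
in the item list and scale-equivariant, which the test suite checks as
properties.

Days with energy above 3500 kcal or below 800 kcal are flagged
(`plausibility_flag()`, strict inequalities, thresholds stored in kcal and
compared after a 4.184 kJ/kcal conversion). Flagged days are *retained* by
default -- in practice such days are checked manually and usually kept --
with an explicit switch in `participant_means()` to exclude them. A day at
exactly 3500 kcal is "ok" because the screen is defined by *exceeding* the
bound. An empty recall day is a valid all-zero day flagged low, not an
error: instruments do return empty days.

`participant_means()` averages over a participant's available days (2 or 3
in conformant data) and derives red-plus-processed meat in g/week as 7x the
daily mean, the unit in which meat guidelines are written.

## The SHEI score

The Swedish Healthy Eating Index summarises adherence to food-based
dietary guidelines as nine components, each scored 0-1 and summed to 0-9.
The published index defers the exact component functions to its own
reference material, so this package fixes a transparent, continuous,
piecewise-linear ramp (`shei_component_score()`) and ships every cut-off
as configuration (`shei_config()`), not code:

```{r}
shei_config()
```

Choices worth flagging:

* **Red and processed meat combined, g/week** (lower-better, full score at
  <= 500 g/week, zero at >= 700): validation reports tabulate this
  component as combined red + processed meat even where prose says "red
  meat"; the `column` field switches it.
* **Added sugar defaults to sucrose E%** (lower-better, 10-20 E%): added
  sugar is not a column of most composition tables; sucrose is the
  closest reported proxy and the config selects the column explicitly.
* **PUFA and MUFA are range-scored** (best at 5-10 E% and 10-20 E%): fat
  quality recommendations are two-sided. A consequence is that the total
  is *not* monotone in PUFA above its band -- the bounds and the monotone
  components are tested separately.
* These default cut-offs are package choices consistent with Swedish
  recommendations, **not** the published index's verbatim table; anyone
  reproducing a specific study should load that study's cut-offs via
  `read_shei_config()`.

Missing component inputs leave the total missing by default
(`missing_policy = "rescale"` averages the rest up to 0-9 instead). With
everything at its favourable reference the total is exactly 9; at every
worst bound it is exactly 0 -- both are exact identities of the ramp, and
the acceptance script recomputes the maximum.

## Doubly labelled water

After a weighed oral dose of 0.08 g/kg 2H2O and 0.15 g/kg H2-18O, both
isotopes wash out of body water exponentially; 18O leaves as water *and*
CO2, deuterium only as water, so the difference between the two
elimination rates measures CO2 production. The chain is:

1. `fit_elimination()`: baseline (mean of the two pre-dose urine samples)
   is subtracted, and OLS of ln(excess) on time over the day 1-15 schedule
   gives the rate k (minus the slope) and the zero-time excess
   (exp(intercept)). This is the slope-intercept (multi-point) protocol;
   the plateau method is out of scope.
2. `dilution_space()`: N = dose moles x dose enrichment / zero-time
   excess, with molar masses 18.02 (2H2O as water-equivalent) and 20.02
   (H2-18O). Dose and urine enrichments must share one unit (the unit
   cancels in k but not here -- validated at load).
3. `co2_production()`: the two-pool equation
   rCO2 = N(1.007 kO - 1.041 kD)(1/2.078 - 0.0246 x 1.05) with pool size
   N = (N_D/1.0427 + N_O)/2. The study whose design this package follows
   names this equation but prints no coefficients; the constants used here
   are the standard literature values and live in one configurable object,
   `dlw_constants()`, so a laboratory's own variant can be dropped in.
4. `energy_equivalent()`: (3.941/FQ + 1.106) kcal per L CO2 (a Weir-type
   expression), converted to kJ; the food quotient FQ defaults to 0.86, a
   typical mixed diet. `dlw_tee()` multiplies it by rCO2 in L/day
   (22.4 L/mol).

The ratio of dilution spaces N_D/N_O is a quality-control quantity near
1.035; results outside a configurable band (default 1.00-1.07) are flagged,
not dropped.

**Error amplification.** TEE rests on the *difference* of two similar
rates (1.007 kO - 1.041 kD is about 0.023/day while each k is about
0.1/day), so per-sample enrichment noise is amplified roughly four-fold:
1% multiplicative noise on the urine series produces a median TEE error
near 4%, and 1.5% noise near 8%. The tests assert exactly this envelope.
This is a property of the method, not of the implementation -- noise-free
series are recovered to numerical precision, which is how implementation
correctness is separated from measurement physics in the test suite.

## Method comparison

`bland_altman()` computes differences a - b against pair averages, the mean
difference, limits of agreement as mean +/- **2** SD (the convention of the
validation literature this package follows, not 1.96 SD), and the
difference-on-average OLS regression used to detect proportional bias. The
percentage mean difference is expressed relative to the comparison method's
mean by default (e.g. percent of mean TEE), switchable to the mean of both.

`paired_location_test()` and `paired_correlation()` wrap the standard
paired t / Wilcoxon signed-rank and Pearson / Spearman machinery. The
family is chosen per variable by an explicit rule -- Shapiro-Wilk on the
paired differences at alpha = 0.05 (`choose_family()`) -- because
validation reports rarely state their criterion; every reported p records
which family produced it, and the rule can be overridden per variable.
Wilcoxon follows the signed-rank conventions (zero differences excluded,
mid-ranks for ties, exact distribution for small untied samples and the
normal approximation above a configurable size). All tests are two-sided
at alpha = 0.05 and no multiple-testing correction is applied by default
(`p_adjust` exposes one).

A statistical caveat the package surfaces deliberately: when one series is
measured with much more error than the other (energy intake vs TEE), the
difference-on-average regression is tilted positive even with *no* true
proportional bias. The generator's `calibration_check()` demonstrates
this: with the bias-on-level slope set to zero the median regression slope
is still clearly positive at realistic noise. Observed proportional bias
in intake-vs-TEE plots should therefore not be read as purely behavioural.

## The synthetic cohort generator

`generate_cohort()` produces every table the pipeline consumes plus a
ground-truth sidecar that no pipeline stage reads. Per participant i and
day d:

* TEE_i ~ Normal(10252, 1197) kJ; weight ~ Normal(67.1, 7.6) kg;
* habitual intake H_i = TEE_i (1 + b + s (TEE_i - mu)/mu) with mean bias
  b = -0.023 (about -236 kJ) and bias-on-level slope s = 0.3;
* true daily energy E_id = H_i (1 + delta), delta ~ Normal(0, 0.23) --
  the day-to-day CV of energy intake is a generator parameter (no
  published within-person CV exists for this design), set to a value
  typical of repeated 24-h recalls and worth sensitivity-testing;
* each method's report scales the day's item amounts by (1 + e_mid), with
  (e_web, e_tel) jointly normal, SD 0.18 and correlation 0.25 -- one
  shared-error dial standing in for the correlated errors of two
  self-report instruments;
* food-group grams: participant means from truncated-normal (fruit & veg)
  or lognormal distributions pinned to published cohort means/SDs, with
  participant-level never-consumer probabilities and day-level
  zero-inflation for episodic groups (fish, nuts, beverages); groups are
  decomposed into three synthetic food codes each, and three "bulk diet"
  codes with the configured macronutrient E% profile fill each day's
  remaining energy, so aggregate E%, fibre and wholegrain densities land
  near their targets;
* the DLW subsample gets doses by the g/kg rules and urine series
  E0 exp(-kt) at days 1, 5, 8, 12, 15 plus two pre-dose baselines, with
  multiplicative noise (default CV 1.5%). k_D is drawn (0.090 +/- 0.006
  per day) and k_O is *solved* from the participant's TEE through the same
  two-pool constants the analysis uses, so the noise-free chain is exact
  by construction and recovery is a genuine numerical inverse problem.

The reporting-error SD and shared correlation were chosen once to put the
cohort SD of reported energy and the web-vs-telephone correlation in the
neighbourhood of published values; they are not fitted, and simulated
correlations tend to sit somewhat above the published 0.73 because the two
simulated methods share the full day-to-day variance of truly matched
days. What passing tests show is therefore that the *pipeline* recovers
what the generator encodes -- not that real pregnant women behave like the
generator. Real data add food-matching error, portion-size distortions
specific to foods (not days), and intake trends across gestation, none of
which are modelled.

## Problem sizes and numerical choices

The test suite simulates cohorts of 24-52 participants (200 replicates for
the calibration check, 500 for the limits-of-agreement coverage property,
10,000 random records for the score bounds), sizes chosen to keep the
whole suite comfortably under a coffee break while leaving Monte-Carlo
error well below the asserted tolerances. Ties in ranks use mid-ranks;
zero energy days propagate NA energy percentages rather than dividing by
zero; truncated normals are sampled by inverse-CDF so a fixed seed yields
identical cohorts across platforms (R's default Mersenne-Twister stream);
and all-zero difference vectors return p = 1 by convention with a logged
message.

## Known limitations

* The SHEI cut-offs are defensible defaults, not the published index's
  exact table; scores are comparable within a configuration only.
* Single-sample and plateau DLW protocols, three-pool models, and
  BMR/activity partitioning are out of scope.
* No measurement-error correction (regression calibration, attenuation
  factors) is provided; the package quantifies agreement, it does not
  de-attenuate.
* The generator produces matched days for both methods; designs with
  unmatched days need a different error structure.
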