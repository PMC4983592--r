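---
title: "Methods: quantifying seed predation, feeding preference and endozoochory by rodents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying seed predation, feeding preference and endozoochory by rodents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`seedfate` analyses the two complementary experiments that together pin
down the role of small rodents in the post-dispersal fate of arable plant
seeds: a paired-exclosure field experiment measuring rodent-attributable
seed removal, and a laboratory cafeteria experiment measuring intrinsic
feeding preference, followed by a feces screen for intact gut passage.
This vignette documents the estimators, their assumptions, the numerical
conventions, the simulation model behind the synthetic-data generator, and
the package's known limitations.

## Seed traits

Species are characterized by three binary descriptors: a weight class
(`light`/`heavy`, obtained by cutting per-seed weight in mg at a threshold,
default 3.62 mg), a nutrient flag (1 if the diaspore carries a substantial
nutrient store, making it attractive to consumers), and a Red-List status
(`common`/`endangered`). `classify_weight()` classes a weight exactly equal
to the threshold as **light**: the threshold is treated as the upper break
of the light interval, the same semantics as an interval cut. This is a
package convention — no species in the packaged set sits exactly on the
break, so the choice is inconsequential for the shipped fixture but is
documented because it is genuinely open.

The packaged 15-species trait table (`gen_traits()`, fixture mode) carries
the published light/heavy, nutrient and status classification of this
species set (12 light / 3 heavy, 5 nutrient-rich, 3 endangered, 8 species
also offered in the field). The *numeric* seed weights in the fixture are
representative values, not measurements: they are chosen so the 3.62 mg cut
reproduces the published classes, and they should not be used as trait data
in their own right.

## Field removal: the paired-depot estimator

Each plot holds an open depot and a rodent-exclosure depot, each with
`seeds_offered = 10` seeds per species. Assuming invertebrate removal is
equal in both treatments, rodent-attributable removal is

$$SR_R = \frac{R_{NRA} - R_{AA}}{R_{NRA}} \times 100\,[\%]$$

Sampling noise can invert a pair ($R_{NRA} \le R_{AA}$), which would give a
nonsensical rate $\le 0$. Following the standard zero/exclusion correction,
an inverted pair is **excluded** when the larger count exceeds the smaller
by more than `exclusion_ratio` (default 5:4) and **zeroed** otherwise.
Degenerate inputs: both depots empty is zeroed (no evidence either way); an
empty control depot with seeds left on the open depot is excluded (the
ratio is undefined and the control is saturated). Round averaging drops
excluded records only — a key excluded in one round keeps the other round's
value; a key excluded in both rounds is absent.

**The correction is not unbiased.** Every retained value is $\ge 0$: positive
differences are kept as positive rates while inversions are zeroed or
discarded. Under a *null* in which both depots face the same stochastic
background removal (per-seed probability 0.15, say), exact enumeration over
pairs of Binomial(10, 0.85) counts gives a grand-mean $SR_R$ of about
+7.4 %, not 0. The estimator converges to a positive constant wherever there
is shared background noise, and is exactly zero only in the noise-free case
where both depots always retain all seeds. The package's test suite pins
this behaviour down against the enumeration oracle rather than asserting
unbiasedness. Practical consequence: small positive mean removal rates
(single digits, comparable to the background-noise bias) should not be read
as evidence of rodent activity.

Summaries report the arithmetic mean and the standard error
$s/\sqrt{n}$ per group; a singleton group reports SE = 0 and is flagged by
its `n = 1` column rather than propagating `NaN` into tables. Report
formatting (the CLI) rounds to one decimal.

## Cafeteria preference: consumption areas and Rodgers' index

Consumption is recorded on the schedule 0, 15, …, 120, 150, …, 360 minutes,
with a final inspection at 1440 min (`cafeteria_schedule()`). Two different
curve conventions are used deliberately:

* **Areas** (`trapezoid_auc()`): the cumulative curve is taken as linear
  between observations and integrated by the trapezoidal rule (units
  seed·minutes). The integration window defaults to 0–360 min — the
  directly observed period; the 24 h check is a single far-away point that
  would dominate the area while carrying no preference information, since
  almost everything has been eaten by then.
* **Predation rates** (`predation_rate_at()`): $SP_R$ at a cut-off is the
  *recorded count* at the latest observation at or before the cut-off
  (a right-continuous step function), divided by the seeds offered. Rates
  reflect what was counted, not an interpolation; consequently
  $SP_R(24\,h) \ge SP_R(6\,h)$ always.

Preference is Rodgers' index $R_i = A_i / \max(A_i)$, the area standardized
by the maximum over a *standardization scope*, so $R_i \in [0, 1]$ with at
least one exact 1 per scope. The default scope is `per_vole_species`:
preferences are compared among the individuals of one vole species, since
the two species differ systematically in consumption speed and a global
maximum would compress one species' scores into a narrow band. A `global`
scope is available; whether the original analyses pooled vole species in
the maximum cannot be determined from their description, which is why both
are implemented. If every area in a scope is zero the index is undefined
and the package raises an error rather than returning 0/0.

## Activity summaries

Rodent density is the minimum number alive (captured individuals excluding
recaptures) divided by field area: 10 individuals on a 198 × 53 m field are
9.53 ha⁻¹. Feeding diversity per guild is Shannon
$H = -\sum p_i \ln p_i$ (natural log), and evenness is Pielou's
$J = H / \ln S$ with $S$ the number of seed species **offered**, not the
number consumed. The offered-species denominator is the only convention
under which a vole feeding diversity of $H = 1.83$ over 8 offered species
yields the companion value $J = 1.83/\ln 8 = 0.88$; it also makes $J$
comparable across guilds that happened to touch different numbers of
species. Because $H$ is scale-invariant, counts may be raw feeding events
or percentage feeding rates.

## Endozoochory

`recovery_rate()` summarizes intact seeds per individual (mean and SE over
individuals, zeros included — with rare passage the distribution is mostly
zeros, so the SE is reported from the sample SD without any distributional
pretence). Germination of digested vs undigested seeds is compared with the
exact conditional test on the 2×2 table (`fisher.test`); with single-digit
digested counts an asymptotic test would be meaningless. The difference is
reported in percentage points (digested − undigested).

## The synthetic-data generator

The generator exists so that every estimator above can be exercised, and
the inference layer calibrated, without access to raw field records. It
emulates the *designs* and the *reported magnitudes* of the two
experiments; it does not attempt behavioural realism.

Consumption is a discrete-time hazard process: within an inter-observation
interval of length $\Delta t$ each remaining seed is consumed independently
with probability $1 - e^{-\lambda \Delta t}$, where

$$\log \lambda = \beta_0 + \beta_{nut}\,\mathrm{nutrient}
  + \beta_{light}\,\mathrm{light} + \beta_{com}\,\mathrm{common} + u$$

and $u \sim N(0, \sigma_u^2)$ is a per-individual intercept
(default $\sigma_u = 0.3$) playing the role of the random individual effect
of a repeated-measures model. Exponential waiting times discretized to the
schedule guarantee monotone cumulative curves and map trait effects onto
$R_i$ monotonically. Defaults: $\beta_0 = -7.5$ (log per-minute hazard) and
positive trait effects ($\beta_{nut} = 0.5$, $\beta_{light} = 0.8$,
$\beta_{com} = 0.5$), chosen so that a study-sized simulation consumes
roughly half the seeds within the 6 h window and ~90 % by 24 h, with
preference ordered nutrient-rich > poor, light > heavy, common >
endangered — the directions reported for the laboratory experiment.

Field removal is binomial per depot × species: the caged depot sees the
invertebrate hazard (default 0.163 per 24 h, i.e. ~15 % background
removal), the open depot additionally the rodent hazard (default 0.31,
multiplied by $e^{0.62}$ on normally sown plots). These defaults reproduce
the reported magnitudes: overall removal ≈ 35 %, ≈ 43 % under normal and
≈ 26 % under reduced sowing. Gut passage is Bernoulli per consumed seed
with `p_intact_passage = 5/3900` (the observed 5 intact seeds of 26 × 150
fed) and germination probabilities 0.2 (digested; 1 of 5 observed) and 0.6
(undigested; a mid-range figure — the species-level control germination
table is not available, so this default is a package choice, not data).

All generators are deterministic given `rng_seed`: each draws from a
stream derived from the seed by a fixed per-table offset, so regenerating
any single table is reproducible regardless of call order.

What the generator does **not** emulate: density dependence and vole
population cycles, spatial structure among depots, seed caching
(synzoochory), handling-time trade-offs, within-species trait variation,
and any seasonal dynamics. Tests passing on synthetic data therefore
validate the *estimators and their wiring*, not ecological conclusions
about real fields.

## Permutation inference

The off-the-shelf layer of the original analyses (linear mixed models with
heteroscedastic variance structures, AIC backward selection, Tukey HSD) is
deliberately out of scope. Trait contrasts are instead tested by
permutation (`permutation_contrast()`): the observed statistic is the
difference in level means (documented orders: light − heavy, nutrient
1 − 0, common − endangered, normal − reduced), and the null distribution is
built by shuffling species trait labels **within each individual**
independently. Under the null of no trait effect the labels are
exchangeable within an individual whatever that individual's overall
appetite, so the test is exact while respecting the repeated-measures
structure — the same concern the random individual intercept addresses in
a mixed model. For a plot-level label (sowing rate) the labels are instead
permuted across plots. The add-one estimator
$p = (1 + \#\{|T^\ast| \ge |T|\})/(B + 1)$ avoids $p = 0$; tests are
two-sided with direction read from the effect sign. With $B = 99$ and
$\alpha = 0.05$, $\alpha(B+1)$ is an integer, so the nominal level is
attained exactly under exchangeability.

`recovery_report()` runs simulate → score → contrast end to end and
reports, per trait, the fraction of datasets with a significant contrast
of the correct sign (power/sign recovery) or, at zero true effect, the
rejection fraction (type-I error).

## Problem sizes used by the shipped checks

The test suite calibrates the null rejection rate over 500 reduced-size
datasets (6 individuals × 15 species, 99 permutations) and measures sign
recovery over 100 replicates of 200 individuals with
$\beta_{nut} = 1$ (999 permutations); Monte-Carlo checks of the field
estimator use 25 replications × 8 plots (1600 pairs). These sizes are
chosen to keep Monte-Carlo error well below the assertion tolerances while
remaining comfortable on a single CPU.

## Known limitations

* The paired-depot correction's positive bias under shared background
  removal (quantified above) is inherent to the published rule; the package
  reproduces it faithfully rather than "fixing" it, because comparability
  with the field literature is the point.
* Preference indices are relative within a scope; $R_i$ values are not
  comparable across datasets standardized separately.
* The permutation contrast tests one binary trait at a time; correlated
  traits (in the packaged set two of the three heavy species are also
  nutrient-poor) are confounded exactly as they are in single-factor
  models, and no multi-factor adjustment is attempted.
* Germination comparisons pool all recovered seeds per species; with
  single-digit counts, species-level conclusions are necessarily weak.
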