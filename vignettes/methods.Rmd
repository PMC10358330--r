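---
title: "Methods: from household food records to diet quality and environmental impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from household food records to diet quality and environmental impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietimpact)
```

# The analysis problem

National nutrition surveys in many low- and middle-income countries
record a single 24-hour food log *per household*: grams of each raw food
item acquired and consumed by everyone together. The questions this
package answers from such data are woman-centred: how adequate is the
diet available to an adult woman in the household, how diverse is it,
which broad dietary patterns exist in the population, and what
greenhouse-gas and blue-water footprint does each pattern carry?

The pipeline has six stages, each usable on its own:
household roster + consumption log → per-AFE intakes → PCA dietary
patterns → MPA and MDD-W → footprint linkage → quintile tables and
trend statistics.

# Adult female equivalents

Household intake is allocated to members proportionally to energy
requirement. Member $m$ counts as
$\mathrm{AFE}_m = E_m / E_{\mathrm{ref}}$, where $E_m$ is their daily
energy requirement by sex, age band and activity level and
$E_{\mathrm{ref}}$ is the requirement of the reference woman (20–30
years, moderate activity), whose AFE is 1 by definition. Dividing
household grams by $\sum_m \mathrm{AFE}_m$ yields the per-AFE diet.

**Assumption made explicit:** food is assumed to be shared in
proportion to energy requirement. Real intra-household allocation often
favours status over need, so per-AFE protein and iron can be
optimistic for women; the package makes no correction because the data
cannot identify one.

**Energy-requirement table.** The published analyses of this kind cite
national requirement tables without printing them, so the package ships
a documented FAO-style default (`default_energy_requirements()`):
moderate-activity requirements of 900–2,200 kcal (females) and
950–2,600 kcal (males) across eight age bands, with light/heavy
activity at −10 %/+15 %. The reference requirement is 2,200 kcal/day.
Only ratios to the reference matter, and the table is fully
user-replaceable. Lookup failures are lookup errors naming the missing
stratum, never silent defaults.

**Nutrients and retention.** Per-AFE nutrient intake of nutrient $n$ is
$\sum_{i} g_i \cdot d_{n}(i)/100 \cdot r_{n}(i)$ over items $i$, with
densities $d$ per 100 g of raw food and multiplicative retention
factors $r \in [0,1]$ for preparation losses. Retention is applied at
the intake step rather than baked into the composition table, keeping
the raw table auditable. Energy uses no retention factor.

# Dietary patterns

`fit_patterns()` runs PCA on the **correlation matrix** of the 18
food-group intakes. Correlation, not covariance: group intakes span two
orders of magnitude (rice hundreds of g/day, oils single grams), and a
covariance PCA would simply recover the staple's variance. Whether the
original analysis used correlation or covariance input, and whether any
rotation was applied, is not documented in this literature; both are
therefore package decisions — correlation input always, no rotation by
default with varimax behind a flag.

Definitions used throughout:

* eigenvalues $\lambda_1 \ge \dots \ge \lambda_{18}$ sum to 18 (trace
  of a correlation matrix; checked to 1e-8);
* **loadings** are variable–component correlations,
  $\ell_{jk} = v_{jk}\sqrt{\lambda_k}$ — the tests verify
  $\ell_{jk} = \mathrm{cor}(x_j, s_k)$ against a direct correlation
  oracle to 1e-8;
* **scores** are standardised to mean 0, variance 1;
* the **sign** of each component is fixed so its largest-|loading|
  entry is positive, making output deterministic across linear-algebra
  backends;
* `format_loading_table()` prints `round(100 * loading)` and blanks
  entries with |loading| < 0.20, the conventional display.

**Retention of K.** The scree report gives the eigenvalue spectrum,
cumulative variance, first differences, the eigenvalue-greater-than-1
count as the suggested K, and a noise margin $(1+\sqrt{p/n})^2$ (the
approximate upper edge of a pure-noise spectrum) for judging whether a
component is real. Retention is deliberately a user decision; K = 3 in
the motivating analysis was a dataset-specific judgment.

**Quintiles.** Households are ranked per pattern, ties broken by stable
input order, and cut at $n/5$ boundaries; Q5 is highest adherence.
Sizes differ by at most one household, so $n = 8{,}225$ gives exactly
1,645 per quintile — even when all scores are tied.

# Probability of adequacy and MPA

For most nutrients the requirement of an individual is modelled as
normal with mean EAR and SD = CV × EAR, and the probability that an
observed intake $\bar y$ covers it is
$\mathrm{PA} = \Phi\!\left((\bar y - \mathrm{EAR}) / \mathrm{SD}\right)$.
Two exceptions:

* **Iron** uses the full-probability approach: the absorbed-iron
  requirement of menstruating women is right-skewed, so a normal CDF is
  biased. The package models the absorbed requirement as log-normal
  (default median 1.46 mg/day, log-SD 0.42 — chosen so the 95th
  percentile sits near twice the median, matching the published shape
  of the distribution) and compares it to intake × bioavailability.
  Bioavailability defaults to 5 %, the regional convention for
  monotonous cereal-based diets.
* **Calcium** is a binary comparison with an adequate intake (AI),
  default 1,000 mg: PA ∈ {0, 1}.

**Standardisation to 2,000 kcal.** The phrase "standardised for 2,000
kcal" is implemented as scaling each nutrient intake by
$2000/\text{energy}$ *before* computing PA — the nutrient-density
interpretation, which makes MPA compare diet quality rather than
quantity and renders it invariant to proportional scaling of the whole
diet (a property the tests assert). This is an interpretive decision:
the source literature applies the phrase to MPA without elaboration.

**The nutrient list.** MPA averages the PAs of a configurable list
defaulting to 11 nutrients: protein, vitamins A, C, B6, B12, E, folate,
iron, zinc, calcium, magnesium. The motivating text is internally
inconsistent about whether protein is an eleventh or a twelfth term;
the list is configurable precisely because of that ambiguity, and MPA
is permutation-invariant over it. Where only RDAs are conventionally
tabled, EAR = RDA/1.2 (the standard relation at 10 % CV); CV defaults
to 0.10 for all normally treated nutrients. These are documented
defaults, not survey ground truth — users reproducing a specific
national analysis should supply their own requirement config.

MPA < 0.5 flags low micronutrient adequacy; the flag is strict
(exactly 0.5 does not flag).

# MDD-W dietary diversity

Per-AFE grams are summed within each of the 10 MDD-W food groups; a
group counts when it reaches **15 g or more** (the boundary is
inclusive and tested at exactly 15 g), and DDS ≥ 5 meets minimum
diversity. Items mapped to no MDD-W group — condiments, oils, fats,
sweets, alcohol — contribute to no group, so no quantity of fish sauce
changes a score. Note the MDD-W groups (10, item-level: pulses vs nuts,
dark-green leafy vs other vitamin-A-rich) cross-cut the 18 pattern
groups; the group map therefore carries both labels per item.

# Environmental footprints

Footprints are linear in consumption:
$\mathrm{GHGE} = \sum_i g_i/1000 \cdot f^{CO_2}_i$ and likewise for
blue water, with per-kg factors supplied at item level. Rules enforced
exactly:

* every consumed item must have a GHGE factor — a gap is a linkage
  error listing the offending items, never a silent zero (when a factor
  table is built from a published range, the *maximum* of the range is
  the documented convention for the user to apply);
* blue-water factors must be *absent* (empty field, never 0) for
  condiments, sweet foods and liquor/alcohol, which public water
  compilations do not cover; their consumed mass is reported as
  `excluded_mass`;
* per-2,000-kcal values are computed per household before any
  averaging (mean of ratios). The tests include a two-household
  counterexample showing mean-of-ratios ≠ ratio-of-means, so the order
  is load-bearing: when mean energy intake is below 2,000 kcal, the
  standardised population mean exceeds the raw one.

The repository ships only synthetic factor tables; real factor
compilations are external copyrighted datasets that users supply in the
documented CSV schema.

# The synthetic generator

`generate_population()` draws, per household $i$ with latent pattern
scores $z_i \sim N(\mu_i, \sigma)$:

$$\text{group intake}_{ij} = \max\!\big(0,\; b_j + (S z_i)_j + \varepsilon_{ij}\big),\quad \varepsilon_{ij} \sim N(0, \nu^2)$$

with $\mu_i$ the sum of region and wealth-quintile offsets. Group
intake is split uniformly across the group's items and multiplied by
household AFE to give household grams.

Defaults, chosen once on design grounds:

* **baseline** $b$: the published total-population group means of a
  rice-dominated Southeast-Asian diet (rice 365 g, vegetables ~220 g,
  oils 5 g, ...), which with the synthetic composition table yields a
  mean energy intake near 1,890 kcal/AFE — deliberately below the
  2,000-kcal standardisation base, as in the motivating population;
* **signatures** $S$: three loading-shaped patterns (omnivorous,
  traditional, pescatarian) mirroring the published loading table,
  Gram-Schmidt-orthogonalised with norms preserved. The raw shapes are
  mildly oblique (they share rice, fish and oils); PCA estimates
  orthogonal directions, so orthogonalising (which changes each shape
  by less than 0.02 in congruence) makes the planted structure the
  actual PCA estimand and pattern recovery a well-posed test.
  Amplitude 20 g/day per unit score;
* **noise** $\nu$ = 4.5 g/day, about 0.29 × the median baseline;
* region and wealth offsets of ±0.2–0.5 score units emulating the
  published gradients (delta wealth → omnivorous, mountains →
  traditional, coast → pescatarian).

**What a green test establishes — and what it does not.** The
generator produces the *structure* of a household survey (multi-member
households, six regions, five wealth strata, item-level logs, planted
latent patterns, truncation-induced zero inflation in rare groups). It
does **not** reproduce real marginal distributions, item-level
heterogeneity within groups, seasonal or day-of-week effects,
measurement error of portion estimation, or survey weights. Green
acceptance tests therefore certify the *machinery* (conversions,
estimators, conservation laws, calibration), not any published
population estimate: the published headline numbers were computed on a
restricted national dataset with external footprint compilations and
cannot be reproduced here.

Determinism: a fixed seed makes every generated file bit-identical;
truncation at zero (rather than resampling) keeps closed-form
expectations simple away from the boundary; uniform item splitting
keeps the generator auditable because item identity only matters
through the group map and footprint factors.

# Numerical and interface choices

* All interchange files are UTF-8 CSV, one header row, `.` decimal;
  doubles are serialised at 17 significant digits so write→read
  round-trips are lossless to at least 12 significant digits.
  Configuration is JSON (the R-native structured-config format with a
  guaranteed parser in the deployment image).
* Errors are classed conditions (`dietimpact_schema_error`,
  `dietimpact_referential_error`, `dietimpact_linkage_error`, ...) so
  callers can distinguish failure modes; referential errors list the
  offending identifiers.
* The homogeneity statistic is the unstratified general-association
  form of the Cochran–Mantel–Haenszel test,
  $(n-1)/n \times$ Pearson $\chi^2$ with $(r-1)(c-1)$ df — the
  motivating analysis names CMH but describes no stratifier, so the
  single-stratum form is the faithful reading. The trend test is OLS of
  the variable on quintile index 1–5 (closed form, verified against
  `lm()`); a zero-variance response is flagged undefined rather than
  given a fake p-value.
* Table flags mark p < 0.05 (`i`) and p < 0.01 (`ii`) — the two-tier
  superscript convention of survey tables, whose legend the motivating
  text omits; no multiple-testing correction by default, with
  Benjamini–Hochberg behind a flag.
* Degenerate inputs fail loudly: zero-energy diets, constant
  food-group columns (named), K > 18, quintile strata with zero
  households, consumption referencing unknown households.

# Known limitations

* No usual-intake correction: a single 24-hour recall observes one day,
  so PA is computed on observed intake and between/within-person
  variance is not separated.
* No intra-household allocation model beyond energy proportionality;
  no pregnancy/lactation adjustment of requirements.
* No survey weights, no covariate-adjusted regression, no land-use,
  eutrophication, acidification or food-waste accounting.
* Footprint matching granularity (multi-ingredient foods, processed
  items) is delegated to the user's factor table.
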