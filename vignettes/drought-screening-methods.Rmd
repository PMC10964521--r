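---
title: "Methods: yield-based drought screening, relative expression and factorial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yield-based drought screening, relative expression and factorial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtscreen)
```

## The screening problem

Drought screening of large germplasm collections typically proceeds in
two stages: a field stage, where many genotypes are grown under
well-watered and water-limited conditions and ranked on their yields,
and a greenhouse/laboratory stage, where a small number of contrasting
genotypes selected from the ranking are characterized in depth —
growth, pigments, antioxidant enzymes, stomata, and the expression of
drought-responsive genes — under controlled soil-moisture regimes.
`droughtscreen` implements the computational layer of both stages.

## Tolerance indices and the STS score

For a genotype with yield $Y_p$ under non-stress and $Y_s$ under
stress, with trial means $\bar{Y}_p$, $\bar{Y}_s$ and stress intensity
$SI = 1 - \bar{Y}_s/\bar{Y}_p$, the six classical indices are

$$TOL = Y_p - Y_s,\quad MP = \frac{Y_p+Y_s}{2},\quad GMP = \sqrt{Y_p Y_s},$$
$$HM = \frac{2 Y_p Y_s}{Y_p+Y_s},\quad STI = \frac{Y_p Y_s}{\bar{Y}_p^2},\quad
SSI = \frac{1 - Y_s/Y_p}{SI}.$$

Each captures a different compromise between potential yield and yield
stability; no single index identifies genotypes that are both
high-yielding and stable. The composite stress-tolerance score sums the
productivity-type indices and subtracts the loss/sensitivity measures:

$$STS = GMP + STI + HM + MP - TOL - SSI - b,$$

where $b$ is the genotype's sensitivity slope — the least-squares
regression coefficient of its yields on the environment mean yields
(the Finlay–Wilkinson regression). Genotypes are ranked by decreasing
STS; rank 1 is the most tolerant.

Three points here were genuinely open and are resolved as package
design choices:

* **$b$ is per-genotype.** The defining phrase ("the linear regression
  coefficient between the average performance in all environments")
  also admits a single population-level slope, but a scalar $b$ would
  shift every genotype's STS equally and could not change the ranking,
  which would make its presence in the score pointless. With only two
  environments the slope has the closed form
  $b_i = (Y_{p,i} - Y_{s,i})/(\bar{Y}_p - \bar{Y}_s)$.
* **Raw components.** The score sums raw index values; an optional
  z-score standardization (`sts_score(standardize = TRUE)`) exists but
  is off by default because the published ranking shows no
  standardization step. With raw components the yield-scaled indices
  (MP, GMP, HM, TOL) dominate the dimensionless ones (STI, SSI, b);
  standardizing weights all seven equally and will generally reorder
  mid-table genotypes.
* **Ties.** Equal STS values are broken by ascending genotype id, so
  the genotype-to-rank map is deterministic and invariant to the input
  row order.

Records with $Y_p \le 0$ are rejected (not dropped): a non-positive
potential yield is a data error, and silently removing it would change
the trial means that every index depends on. A trial with $SI = 0$
(stress mean equal to control mean) has no defined SSI and is an error
naming the trial.

The package ships the published ranking of the 114-genotype wild-barley
field screen as a fixture (`load_table1_fixture()`, with an MD5
integrity check). Re-ranking its STS column reproduces the printed rank
for all 114 genotypes, and the top-9/bottom-11 cut reproduces the
published tolerant and sensitive selections; this is the package's main
external anchor and is re-verified by the test suite and the acceptance
script.

## Relative gene expression (2^−ΔΔCT)

Quantification follows the Livak method with an assumed amplification
efficiency of exactly 2: technical replicates are collapsed by
arithmetic mean CT; each target is normalized against the reference
gene within the same (genotype, treatment, biological replicate) cell,
$\Delta CT = CT_{target} - CT_{ref}$; the calibrator is the same
genotype's control (90–95% FC) treatment, so
$\Delta\Delta CT = \Delta CT - \overline{\Delta CT}_{control}$, and the
fold change is $2^{-\Delta\Delta CT}$. Per-cell summaries average
$\Delta\Delta CT$ across biological replicates and report
$2^{-\overline{\Delta\Delta CT}}$ — the geometric-mean fold change,
the natural average on the cycle scale — which makes the calibrator
cell's summary exactly 1.

Primer efficiency from a dilution series (`primer_efficiency()`) is a
QC quantity only: $E = 10^{-1/slope} - 1$ from the least-squares slope
of CT on $\log_{10}$ input. It is deliberately not folded into the fold
change (no Pfaffl correction), matching the stated quantification
model; CT values outside [5, 45] are flagged with a warning rather than
rejected, since a single aberrant well should be visible, not silently
fatal.

Whether downstream ANOVA should run on fold changes or on
$\Delta\Delta CT$ is not fixed by the method; both columns are emitted
and the factorial layer accepts either as the response. Fold change is
the conventional positive-valued response for CV%-style reporting.

## Pigment quantification

For 96% ethanol extracts read at 663, 646 and 470 nm (Lichtenthaler
coefficient set):

$$Chl_a = 12.21 A_{663} - 2.81 A_{646}, \qquad
  Chl_b = 20.13 A_{646} - 5.10 A_{663},$$
$$Chl_T = Chl_a + Chl_b, \qquad
  Car = \frac{1000 A_{470} - 3.27\,Chl_a - 104\,Chl_b}{227}.$$

Two printing ambiguities in the source protocol are resolved here, and
flagged in the function documentation: the second formula appears
labeled "Chl a" but carries the chlorophyll-b coefficients, so it is
implemented as chlorophyll b; and the carotenoid formula's bracketing
is read as the whole numerator over 227, the standard form. Outputs
are µg/ml of extract (the protocol states no units; this is the
conventional scale for these coefficients), with an optional conversion
to mg/g fresh weight using the protocol's 2 ml extract per 25 mg
tissue. All four outputs are linear in the absorbances, which the test
suite asserts as homogeneity/additivity properties, and the inverse
mapping `invert_pigments()` (used by the synthetic generator) is exact
to floating precision.

## Factorial ANOVA and Duncan's multiple range test

The greenhouse stage is a two-factor completely randomized design:
genotype (2 levels) × soil-moisture regime (90–95%, 50–55%, 25–30% of
field capacity), with 3 replicates for traits and 4 (2 biological × 2
technical) for expression. `anova_crd2()` computes the closed-form
balanced decomposition

$$SS_{total} = SS_G + SS_S + SS_{G\times S} + SS_E,$$

with $F$ = effect MS / error MS, p-values from the F distribution, and
$CV\% = 100\sqrt{MSE}/\bar{y}$. The expected df columns are
(1, 2, 2, 12) at $r=3$ and error df 18 at $r=4$. Imbalance is an
explicit error: for unbalanced data the factorial sums of squares are
not unique (Type I/II/III), and silently picking one would change the
meaning of the table, so the function refuses rather than guesses.
$r = 1$ leaves no error term and is likewise an error.

Duncan's multiple range test compares the $k$ treatment-combination
cell means (matching the lettered group figures of greenhouse reports):
means are sorted decreasing, and a pair spanning $p$ positions differs
when its gap exceeds the least significant range
$R_p = q_{\alpha_p, p, df_E}\sqrt{MSE/r}$ with Duncan's protection
level $\alpha_p = 1-(1-\alpha)^{p-1}$, using studentized-range
quantiles computed from the distribution (`qtukey`), not lookup tables.
Under the protection rule ("a pair inside a non-significant spanning
range is never declared different") non-significance is an interval
property on the sorted means, so letters are maximal runs of mutually
non-significant means. $\alpha$ defaults to 0.05, the conventional
level where none is stated. The test suite checks the letter partition
against an exhaustive enclosing-pairs oracle on random fixtures.

## The synthetic-data generator

Raw field yields, CT values and trait measurements behind the published
tables are not available, so the package generates inputs with the
study's statistical structure (`sim_config()` and the `sim_*`
generators). Defaults are fixed to the study design and are not meant
to be fitted: 114 genotypes; three soil-moisture regimes; 3 greenhouse
replicates; 2 × 2 expression replicates.

* **Yields** are log-normal across genotypes (positive, right-skewed,
  as yield data are), mean 250 (g/plot scale) with 30% CV. Each
  genotype carries a truth archetype — tolerant (20% yield loss under
  stress), intermediate (45%), sensitive (70%), in proportions
  0.15/0.65/0.20 — and stress yield is
  $Y_s = Y_p(1 - reduction)(1 + \epsilon)$ with Gaussian multiplicative
  noise (sd 0.10). The archetype labels are returned with the data so
  recovery tests never re-derive truth from outputs.
* **CT tables** give the reference gene a flat baseline (CT 20) across
  treatments and shift each target's CT by $-\log_2(\text{fold})$ per
  treatment; the default shift matrix encodes the reported induction
  pattern (e.g. 12.51-fold dehydrin induction in the tolerant class
  under severe stress, 5.15-fold under mild stress), so a noise-free
  run round-trips those fold changes exactly through the expression
  module. Technical noise sd is 0.15 cycles and biological spread 0.25
  cycles, typical bench magnitudes.
* **Trait matrices** follow cell means
  $\mu + g_i + s_j + (gs)_{ij}$ with sum-to-zero patterns. The
  interaction amplitude (3 trait-sd units across the pattern) was set
  analytically so the $G\times S$ F-test at $r=3$ has ≈0.99 power
  (noncentrality $\lambda = r\sum(gs)^2/\sigma^2 = 27$), i.e. a
  clearly detectable interaction, in line with the very large
  interaction F ratios the published trait tables show.
* **Absorbance panels** are produced by drawing pigment targets and
  inverting the pigment formulas (a well-posed linear system), so the
  forward computation recovers the targets to numerical precision.

Every generator is deterministic given `sim_config(seed = )`; the same
config yields byte-identical tables.

What passing these simulation-based checks shows — and what it does
not: they demonstrate that the implementations are mutually consistent,
correctly calibrated (the null $G\times S$ rejection rate at
$\alpha = 0.05$ stays within [0.03, 0.07] over thousands of
simulations), and able to recover planted structure. They do not
validate the biology of real field data, which carries spatial
heterogeneity, genotype × year effects and non-Gaussian noise that the
generator deliberately omits.

## Problem sizes and numerical choices

The validation suite uses desk-scale problems chosen as the package's
own defaults: 50-fixture oracle sweeps for indices, ANOVA (1e−8
agreement) and Duncan partitions; 100 seeded field simulations for
archetype recovery; 200 simulations for interaction power; 3000 null
simulations for test size. Tolerances: exact identities are asserted
at 1e−12 (double precision), chained linear-algebra round-trips at
1e−9, ANOVA oracle agreement at 1e−8.

## A worked run

```{r}
report <- run_report(sim_config(seed = 1))
report
```

## Known limitations

* The ANOVA layer is balanced-fixed-effects only; no mixed models,
  repeated measures or unbalanced least squares.
* Expression quantification assumes perfect doubling; efficiencies
  from `primer_efficiency()` are reported for QC, not used to correct
  fold changes.
* Only the six named indices and the STS composite are provided; other
  published indices and multi-trait selection indices are out of scope.
* The field stage's augmented-design spatial adjustment is not
  implemented; the ranking layer consumes already-summarized
  two-environment yields.
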