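---
title: "Methods: random-effects meta-analysis of SNP association studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-effects meta-analysis of SNP association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The statistical model and its assumptions

Every quantity pooled by this package is a per-study log odds ratio
$y_i$ with standard error $s_i$. The random-effects model assumes

$$y_i \sim N(\mu + u_i,\; s_i^2), \qquad u_i \sim N(0, \tau^2),$$

i.e. each study estimates its own true effect, and the study-specific
effects scatter around an overall mean $\mu$ with between-study variance
$\tau^2$. The DerSimonian–Laird moment estimator is used throughout:
$\hat\tau^2 = \max\{0, (Q - (k-1))/C\}$ with
$C = \sum w_i - \sum w_i^2 / \sum w_i$, $w_i = 1/s_i^2$, and
$Q = \sum w_i (y_i - \hat y_{FE})^2$. The pooled estimate re-weights by
$w_i^* = 1/(s_i^2 + \hat\tau^2)$ and is reported with a normal (Wald)
interval $\exp(\hat\mu \pm 1.96\,\mathrm{SE})$.

This combination — DL with a Wald interval, not REML, Paule–Mandel or
Hartung–Knapp — is deliberate: it is the classical default of the STATA
`metan` era in genetic epidemiology, and it is the only combination that
reproduces the confidence intervals printed in the literature this
package's worked dataset is drawn from. The known costs are mild
anti-conservatism of the Wald interval at small $k$ and the negative bias
of DL's $\hat\tau^2$ under large heterogeneity; our parameter-recovery
simulation (below) quantifies both for the regime we care about.

Assumptions worth keeping in mind: within-study normality of $y_i$ on the
log scale (poor for very sparse tables, hence the continuity correction),
known $s_i$ (we plug in estimates), and independence across studies
(violated by shared control series — handled explicitly, below).

## Effect extraction

When genotype counts are available, they are collapsed to a 2×2 table
under the recessive (mtmt vs wt carriers) or dominant (mt carriers vs
wtwt) model, and $y = \ln(ad/bc)$, $s = \sqrt{1/a+1/b+1/c+1/d}$. If any
cell is zero, 0.5 is added to all four cells (Haldane–Anscombe) and the
event is logged; the correction is applied only then, so non-degenerate
tables are untouched.

When only a published OR and 95% CI are available,
$y = \ln(\mathrm{OR})$ and $s = (\ln U - \ln L)/(2\times 1.96)$. Two
consequences of working from printed, 2-decimal values:

* the CI ratio $U/L$ is recovered exactly, but $\exp(y \pm 1.96 s)$
  reproduces the printed bounds only to input precision, because a
  printed OR is generally not the exact geometric midpoint of its printed
  bounds;
* pooled statistics computed from back-transformed values carry an
  irreducible input-rounding error. For the packaged dataset this moves
  two subgroup CI bounds (bladder rs762551 lower: computed 0.69 vs
  printed 0.70; Mixed rs2470890 lower: 1.15 vs 1.16) and two
  leave-one-out $I^2$ integers (15% vs 14%; 7% vs 6%) by one printing
  unit, while every pooled OR itself matches at 2 decimals. The affected
  acceptance checks are asserted at the printed values and left failing
  rather than loosened: the failure documents the limit of what printed
  inputs can reproduce.

## Genetic-model selection

The crude contrasts $OR_1$ (wtmt vs wtwt) and $OR_2$ (mtmt vs wtwt) drive
the choice: recessive when $OR_2$ differs from 1 (95% CI excludes 1) but
$OR_1$ does not; dominant when both differ from 1. "Equal to 1" had to be
operationalised as CI-based non-significance because the motivating
dataset's own rs762551 contrasts (1.03, 0.98–1.07 and 1.06, 0.97–1.16)
satisfy neither strict pattern; for that case — both CIs containing 1 —
the tie-break picks recessive iff $|\ln OR_2| \ge |\ln OR_1|$, which
reproduces the recessive assignment actually used. The rule that fired is
always reported. For SNPs whose source studies never published the
contrasts, the model comes from the per-SNP default assignment
(`default_genetic_model()`), overridable per run.

## Hardy–Weinberg screening

Control series are tested against HWE proportions $p^2, 2pq, q^2$ at the
observed allele frequency with the asymptotic 1-df chi-square test —
matching the behaviour of the web calculators used in this literature —
and excluded at $p \le 0.01$ (boundary inclusive). An exact conditional
test on the heterozygote count is available (`exact = TRUE`) but off by
default, since the asymptotic test is what the published analyses used.
Monomorphic series return $\chi^2 = 0$, $p = 1$ by convention, logged.
All rows of the packaged table assert HWE compliance in their source, so
the filter acts only on user data and simulations.

## Shared control series

Three strata of one study in the packaged table (Gulyaeva 2008:
endometrium, ovaries, breast) reuse a single series of 180 controls. For
any pool that would include them together, they are merged into one
analysis unit by pooling the member log ORs; tumour-site stratification
bypasses the merge because the members then sit in different strata.

The member pool is DerSimonian–Laird by default, not fixed-effect. This
was a genuinely open design point (member genotype counts are not
published, so no exact aggregation exists) and the two choices differ
materially here because the three member ORs are wildly heterogeneous
(2.20, 9.21, 27.58): a fixed-effect merge hands the combined unit a
small SE and shifts the 62-unit rs762551 pool to 1.045 (prints as 1.04),
while the DL merge widens the unit's SE for its internal heterogeneity
and yields 1.034 — matching the published 1.03 (0.96–1.12, $I^2$ 50.4%)
— and is also the methodologically consistent choice, since the
downstream pool is itself DL. `aggregate_shared_controls(method =
"fixed")` keeps the alternative available.

## Sample-size stratification

"Large" means more than 200 cases; a study with exactly 200 cases is
small. The sentence this rule descends from is ambiguous, but the
membership it induces for the large stratum of rs2472304 (Hopper 204,
Sangrajrang 552, Ferlin 234) is the only one whose pooled OR reproduces
the published 0.79 for that stratum, which the test suite checks by
brute-force pooling.

## Bias diagnostics

*Egger*: unweighted OLS of $y_i/s_i$ on $1/s_i$ (the classic 1997 form);
the intercept is tested two-sided on $k-2$ df. A weighted variant
(`weighted = TRUE`) is provided because the literature rarely states
which was used. *Begg*: Kendall rank correlation between the
variance-stabilised deviates $(y_i - \hat y_{FE})/\sqrt{s_i^2 -
\mathrm{SE}_{FE}^2}$ and the variances $s_i^2$, with tie-corrected,
continuity-corrected normal approximation; an exact permutation p-value
is available for $k \le 8$. Equal-variance inputs make the variance ranks
degenerate: $p = 1$ by convention, logged. Published Begg/Egger p-values
are treated as soft checks only — they are sensitive to these variant
choices in exactly the way pooled ORs are not — and bias tests never gate
any pooling decision. *Galbraith*: residuals $(y_i - \hat y_{FE})/s_i$
with the conventional $\pm 2$ band; the band is a convention, not a
formal test, and is used to name heterogeneity contributors.

## The simulator: what it emulates and what it does not

`simulate_collection()` draws, per study: control genotypes multinomially
under HWE at the configured mutant-allele frequency (default 0.3, a
common-variant frequency typical of the studied SNPs); a study effect
$\theta_i = \ln(\mathrm{OR}) + N(0, \tau^2)$; case genotypes from the
control distribution with the exposed class's odds tilted by
$e^{\theta_i}$; and study sizes log-uniform in [100, 2000] cases with
controls = cases × Uniform(0.8, 1.5), echoing the spread of the packaged
table. Publication bias is emulated by dropping, with probability
`bias_severity`, any study whose collapsed-OR CI contains 1; the
collection is not refilled, so censoring thins it. Each row carries its
true $\theta_i$ in a hidden column for recovery tests.

Seeded simulations establish: DL recovers $\mu = \ln 1.5$ at
$\tau^2 = 0.05$, $K = 50$ with |bias| < 0.03 and 93% empirical CI
coverage (500 replicates); Egger's type-I error stays within [2.5%,
7.5%] under a symmetric null (2000 replicates, $K = 20$); HWE p-values
are KS-uniform on 2000 simulated control series; and significance
censoring at a true OR of 1.3 raises Egger's rejection rate several-fold
over the null rate. Note the power check needs a non-null effect: at a
true OR of exactly 1, two-sided significance censoring removes studies
symmetrically and induces no funnel asymmetry — a property of the
mechanism, not a bug, and the reason the check is parameterised at 1.3.

What the simulator does *not* emulate: linkage disequilibrium or
multi-SNP haplotypes, genotyping error, covariate-adjusted ORs (all
simulated effects are crude), non-normal random effects, and correlated
(shared-control) studies. A green simulation suite therefore validates
the estimators under the model's own assumptions; it cannot validate the
assumptions against any particular body of literature.

## Numerical and degenerate-case choices

* 1.96 is used as a fixed CI multiplier everywhere, never a re-derived
  quantile — required for round-tripping printed CIs.
* $\tau^2$ truncates at 0; $I^2$ truncates at 0 and is 0 when $Q = 0$.
* $k = 1$ pools degenerate to the single estimate ($Q = 0$, df 0,
  heterogeneity p undefined); $k = 2$ pools are allowed but Galbraith,
  leave-one-out and both bias tests require $k \ge 3$ (Egger additionally
  errors on a degenerate regressor: all precisions equal with unequal
  effects).
* Subgroup pools re-estimate $\tau^2$ independently per stratum (no
  shared-$\tau^2$ option), matching how stratified tables are reported in
  this literature.
* Report tables round ORs and CI bounds to 2 decimals and $I^2$ to 1
  decimal; JSON summaries keep full precision.
* 2×2 cells are held as doubles to avoid integer overflow at
  simulation-scale counts.

## Known limitations

No REML/Paule–Mandel or Hartung–Knapp options; no meta-regression,
cumulative meta-analysis or trim-and-fill; allele-contrast and codominant
models are out of scope (the workflow is dominant/recessive only);
aggregation of shared-control strata is an approximation forced by
unpublished member counts; and analyses driven from printed ORs/CIs
inherit 2-decimal input rounding, with the consequences quantified above.
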