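---
title: "Inferring the mode of inheritance with the degree-of-dominance index"
author: "degdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the mode of inheritance with the degree-of-dominance index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degdom)
```

## The problem

A case-control genetic association study (GAS) of a bi-allelic variant
yields a 3x2 table of genotype counts — wild-type homozygotes (wtwt),
heterozygotes (wtmt) and mutant homozygotes (mtmt), among controls and
cases. Beyond asking *whether* the variant is associated with disease, the
clinically relevant question is *how*: is the mutant allele dominant,
recessive, additive, or something stranger? Common practice fits four
non-orthogonal contrasts (additive, dominant, recessive, co-dominant) and
inspects which are significant, but a 3x2 table has only two degrees of
freedom, so those four tests are mutually dependent and frequently all
"significant" at once.

`degdom` instead works with the unique orthogonal pair:

* the **additive contrast**, odds ratio $\theta_a$ of mtmt versus wtwt
  (heterozygotes ignored), coefficients $(1, 0, -1)$;
* the **co-dominant contrast**, odds ratio $\theta_{co}$ of wtmt versus
  the pooled homozygotes, coefficients $(-0.5, 1, -0.5)$.

Their coefficient vectors have zero dot product, so the 2-df genotype
deviance of the logit model splits across them, and each can be read on
its own. The **degree of dominance** is

$$h = \frac{\ln \theta_{co}}{\lvert \ln \theta_a \rvert},$$

a continuous index of the mode of inheritance: $h = 0$ is perfect
additivity (non-dominance: the heterozygote log-odds of disease sit midway
between the homozygotes), $0 < h \le 1$ dominance of the mutant allele,
$-1 \le h < 0$ dominance of the wild-type allele, $h > 1$ over-dominance
(the heterozygote is at higher risk than either homozygote) and $h < -1$
under-dominance.

## The deviance decomposition

`fit_genotype_deviance()` fits the grouped binomial logit model
$\log \pi/(1-\pi) = \beta_0 + \beta_1 g$ with the 3-level genotype factor
$g$ via iteratively reweighted least squares (relative deviance tolerance
$10^{-10}$, at most 100 iterations; non-convergence is an error, never
silent). The genotype deviance $D_g$ (2 df) equals the likelihood-ratio
G statistic $2\sum O \ln(O/E)$ of the table, and that closed form is used
as an independent cross-check of the GLM route in the test suite.

The split is ordered the way the inference ladder reads it: $D_{Lco}$ is
the deviance drop from the null model when the co-dominant covariate alone
is added, and $D_{La} = D_g - D_{Lco}$ is the orthogonal remainder, so
$D_g = D_{La} + D_{Lco}$ holds exactly. A genuinely open design point is
that one could instead define both terms as marginal one-covariate drops;
orthogonality of the coefficient vectors does *not* make those add up
exactly, because the binomial weights of an unbalanced table differ by
row. On the ACE D/I worked example the marginal additive drop is 16.71
while the remainder is 16.62 against $D_g = 16.72$ — and only the
ordered split reproduces both published contrast deviances and the
non-significant additive p-value of the under-dominance example
(sequential $D_{La} = 0.42$, $p = 0.52$, versus a marginal 8.61,
$p = 0.003$). Both marginal drops are still returned
(`d_la_marginal`, `d_lco_marginal`, `orthogonality_gap`) as diagnostics
of how unbalanced the table is.

## The classification ladder

`classify_dominance()` applies an ordered sequence of hypotheses at a
single significance level `alpha` (default 0.05, no internal multiplicity
correction — genome-wide users should divide `alpha`; the CLI exposes a
Bonferroni divisor):

1. If the co-dominant contrast is non-significant, the call is
   **non-dominance**. The gate is the z-test of $\ln \theta_{co}$ with
   Woolf variance $\sum 1/\text{cell}$ on the collapsed 2x2 table; the
   deviance p-value of $D_{Lco}$ is reported alongside and agrees closely.
   The z-test is primary because the over/under-dominance stage is itself
   a z-test, keeping the ladder on one scale.
2. Otherwise, if $\lvert h \rvert \le 1$, the sign of $h$ names the
   dominant allele.
3. Otherwise the one-sided **k-test** asks whether
   $\lvert h \rvert > 1$ is beyond chance, with
   $k = \ln \theta_{co} - \lvert \ln \theta_a \rvert$ (written per the
   sign of $\ln\theta_a$ as $\ln(\theta_{co}/\theta_a)$ or
   $\ln(\theta_{co}\theta_a)$) and
   $\mathrm{Var}(k) = \mathrm{Var}[\ln \theta_{co}] +
   \mathrm{Var}[\ln \theta_a](1 - 2/\pi)$. The $(1 - 2/\pi)$ factor is
   the variance of a half-normal relative to its parent normal: taking
   $\lvert \ln \theta_a \rvert$ folds the sampling distribution.
   Significant gives **over-** or **under-dominance**; otherwise
   **dominance-unresolved** — dominance is established but its excess
   beyond the additive span is not.

$h$ is always computed and reported, including under non-dominance, so
batch summaries can plot the whole spectrum.

Two caveats are worth stating plainly. First, both sign branches of $k$
reduce algebraically to $\ln \theta_{co} - \lvert \ln \theta_a \rvert$,
which places the null boundary at $h = +1$ for *both* directions; the
under-dominance test is therefore conservative about its nominal boundary
$h = -1$. The package implements the stated branches verbatim and the test
suite documents the collapse. Second, on the BDNF G196A worked example the
one-sided k-test p-value under these formulas is 0.0050 (hand-checkable
from the printed counts: $k = -0.836$, $\mathrm{Var}(k) = 0.1052$,
$z = -2.58$); the value 0.02 sometimes quoted for this example is not
recoverable under any literal reading of the variance formula, so the
package validates the k-test against the hand-computed oracle instead.

### Zero cells

Collapsed 2x2 cells can be zero with rare genotypes. The `correction`
policy is `"haldane"` by default — add 0.5 to every collapsed cell before
the odds ratio and variance, with a classed warning
(`degdom_haldane_warning`) that simulation loops muffle via
`quiet_haldane()` — or `"strict"`, which raises a classed error. Haldane
is the default because rare-genotype tables are routine in the simulators
and an estimate with a flagged correction is more useful than an abort.

## Hardy–Weinberg disequilibrium and the bias of h

Control genotype frequencies are modelled as
$(p^2 + D,\; 2pq - 2D,\; q^2 + D)$ with $p$ the wild-type allele
frequency and $D$ the disequilibrium coefficient, bounded by
$\max(-p^2, -q^2) \le D \le pq$. `estimate_disequilibrium()` estimates
$p$ and $D$ from the control column and tests $H_0: D = 0$ with the 1-df
Pearson chi-squared test (no continuity correction) by default; a
conditional exact test is available but off by default, since the
standard screening filter in this literature is phrased as a plain
"HWE $p \ge 0.05$" rule.

`biased_contrasts()` substitutes the parametric model for the control
column: $\theta_a = (n_{32}/n_{12})(p^2+D)/(q^2+D)$ and
$\theta_{co} = (n_{22}/(n_{12}+n_{32}))(p^2+q^2+2D)/(2pq-2D)$. As $D$
grows toward $pq$ (homozygote excess, e.g. population stratification via
the Wahlund effect) the additive factor falls to its floor $p/q$ while
the co-dominant factor diverges, so $\lvert h \rvert$ is inflated —
stratified samples can manufacture spurious over-/under-dominance. A
heterozygote excess ($D < 0$) deflates $\lvert h \rvert$ and can flip its
sign. One analytic subtlety: the co-dominant floor
$n_{22}/(n_{12}+n_{32})$ quoted for the $D = -q^2$ endpoint only holds
when $p \ge 3q$ (mutant maf $\le 0.25$); the endpoint factor is
$(p-q)/2q$, which drops below 1 for more common mutant alleles. The
sandwich tests therefore run on $q \le 0.25$, where the inequality is
genuine, and the endpoint identities ($\theta_a$ floor at $D = pq$;
reduction to the plain odds ratios at $D = 0$) are asserted analytically.

`simulate_hwe_bias()` quantifies the bias by Monte Carlo: case counts
uniform on the integer 3-composition of 400 with case maf in
$[0.05, 0.40]$, parametric Weir controls with
$q_{\text{controls}} \le q_{\text{cases}}$ and $\lvert D \rvert \ge
0.005$, paired with a $D = 0$ reference at the same allele frequencies so
the bias is isolated from control sampling noise. Case draws with an
empty cell are redrawn so both parametric odds ratios stay finite. The
emitted records deliberately do not clip extreme $h$; that is a plotting
decision.

## The selection-cohort validation model

Whether $h$ tracks a *true* mode of inheritance is checked against a
one-locus selection model in which the truth is known. A cohort of
$N = 10{,}000$ starts in HWE at mutant frequency $q_1$; over one time
interval relative survival is $(1,\; 1-Hs,\; 1-s)$, with selection
coefficient $s$ and true dominance $H$ ($0$ recessive, $0.5$ co-dominant,
$1$ dominant). The "disease" is death in the interval: controls are the
initial cohort, cases the deaths. A genotype-independent background
mortality $m = 0.05$ keeps every genotype represented among cases.

The model itself does not say how background and selective mortality
compose; the package's choice is independent competing risks,
$\Pr(\text{death} \mid g) = 1 - (1-m) w_g$, because it reduces to pure
selection at $m = 0$, to uniform mortality at $s = 0$, and never yields
an empty case cell for $m > 0$ — precisely the reason the background
mortality exists. An additive-hazards alternative ($m + (1 - w_g)$) is
config-selectable for sensitivity checks. Expected (parametric) genotype
frequencies define the death pool; sampling noise enters only through
`sample_table()`, the inverse-CDF categorical sampler (each subject is a
uniform draw located within the cumulative frequency intervals).

`performance_sweep()` samples 400/400 studies across a $(q_1, H, s)$ grid
and scores Spearman's rank correlation between $H$ and the estimated $h$
per $(q_1, s)$ panel. Two cautions about reading it: at low $q_1$ the
mtmt cell is nearly empty, recessiveness ($H < 0.5$) is close to
invisible and $h$ floors near $-0.2$; and comparing selection strengths
must be done on matched $q_1$ panels — pooling panels before correlating
mixes panel-specific locations of $h$ and can invert the ordering
(a Simpson-type artefact we observed and test against).

## Power simulation

`estimate_power()` estimates the power of the co-dominant gate at
400/400. Case counts are uniform on the integer 3-composition of 400
(Dirichlet(1,1,1) scaled and rounded largest-remainder; the literature
names no distribution, and this choice is logged into every output),
filtered to a case-maf window; control counts are drawn the same way and
accepted when they pass HWE at $p \ge 0.05$ and
$q_{\text{controls}} \le q_{\text{cases}}$. Power in a bin of realized
$h$ (width 0.1 over $[-1,-0.1] \cup [0.1,1]$) is the fraction of
replicates with co-dominant $p < 0.05$; binning is on realized $h$
because the generator cannot target $h$ directly. Infeasible windows
exhaust a rejection budget ($10^5$ proposals per draw) and raise a
classed error.

Type-I calibration uses a generator that is additive *by construction*:
HWE controls at $q = 0.3$, case frequencies enriched by genotype odds
$(1, o_2, \theta_a)$ with $o_2$ the control-frequency-weighted mean of
the homozygote odds, which makes the population co-dominant odds ratio
exactly 1 while leaving a strong additive signal
($\theta_a = 2$). Note a log-odds-midpoint heterozygote (geometric-mean
odds) would *not* be null for this statistic: pooling the homozygotes
weights them by their control frequencies, so the null requires the
arithmetic weighted mean. At 10,000 replicates the empirical rejection
rate of the gate is within 3 binomial standard errors of 0.05.

## Problem sizes and defaults

Simulation defaults are the study conditions themselves: 400/400
case-control samples, cohort size 10,000, background mortality 5%,
$q_1 \in [0.05, 0.5]$, case maf windows $[0.09,0.11]$, $[0.09,0.21]$,
$[0.39,0.41]$, HWE screening at $p \ge 0.05$, $\lvert D \rvert \ge
0.005$, $\alpha = 0.05$. Replicate counts default to 10,000 where the
source procedure states none; the packaged checks run 2,000 per power
cell, 10,000 for type-I calibration, 50 per sweep grid point and 2,000
per disequilibrium arm, sizes at which every asserted contrast exceeds
its Monte-Carlo error severalfold. All simulators require an explicit
seed and embed it in their outputs.

## What the simulators do and do not emulate

The generators produce idealized studies: a single bi-allelic locus,
perfectly classified genotypes and phenotypes, no genotyping error, no
covariates, no linkage disequilibrium with a causal variant, controls
drawn from the same population as cases (except where disequilibrium is
injected on purpose). Passing tests therefore demonstrate the internal
consistency and calibration of the method under its own assumptions, not
robustness to the misclassification, confounding and selection phenomena
of real studies. Likewise, an underpowered real study will underestimate
the significance of both contrasts and hence the confidence of any
dominance call; $h$ itself remains estimable but noisy, which is why the
classifier reports it even when the gate does not reject.

## Worked example

```{r example}
tabs <- example_tables()
classify_dominance(tabs$bdnf)
```

## Known limitations

* The under-dominance k-test shares the over-dominance null boundary
  (see above) and is conservative for $h < -1$.
* The co-dominant endpoint bound under heterozygote excess holds only
  for mutant maf $\le 0.25$.
* No meta-analytic machinery: merging studies with heterogeneous modes
  of inheritance is exactly what the index is meant to expose, not
  average away.
* No VCF/genotype-calling ingestion; the package starts from 3x2 counts
  extracted upstream (`read_genotype_table()` documents the accepted
  layout).
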