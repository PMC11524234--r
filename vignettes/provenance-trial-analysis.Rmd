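---
title: "Quantitative genetics of a forest-tree provenance trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of a forest-tree provenance trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provtrial)
```

## The trial and its model

`provtrial` analyses common-garden provenance trials of forest trees laid
out as randomized complete blocks (RCB): each of $p$ provenances (seed
source populations) is planted once per block as an $n$-tree plot, in $b$
blocks. The motivating application is a 10-provenance x 10-block trial of
*Neolamarckia cadamba* in southern China with 5-tree plots, where sapling
mortality left plots with unequal survivor counts $n_{ij}$, making the data
unbalanced.

Every trait is analysed under the linear mixed model

$$ y = X\beta + Zu + \varepsilon, $$

with block as a fixed effect ($\beta$), provenance and provenance-by-block
interaction as random effects ($u$, variances $V_P$ and $V_{PB}$), and
residual variance $V_e$. Wood traits are measured on a few cored trees per
provenance with no block replication, so for them the interaction term is
omitted structurally and the model reduces to provenance + residual.

Derived traits are closed-form: stem volume
$V = 3.69\times10^{-5}\,DBH^2 H$ (DBH in cm, $H$ in m, $V$ in m$^3$; the
constant is species-specific and treated as exact), wood basic density
$WBD = w_2/w_1$ (oven-dry weight over displaced-water green volume), X-ray
crystallinity $Cr = 100\,(I_u - I_a)/I_u$, and the slenderness ratios
FL/FD and VL/VD. Ratio traits are computed per tree and then averaged;
the alternative (ratio of trait means) gives visibly different provenance
means, and per-tree ratios are what the reference summaries reproduce.

## REML estimation

Variance components are estimated by restricted maximum likelihood on the
individual-tree data. The engine iterates an average-information (AI)
update with a step-length cap so no component crosses zero; a step that
would decrease the restricted log-likelihood is halved and, as a last
resort, replaced by a monotone EM update. The log-likelihood is therefore
non-decreasing across iterations, which the test suite asserts on every
fit. Convergence is declared when the relative parameter change falls
below `tol` (default $10^{-8}$) or the log-likelihood change falls below
`loglik_tol` (default $10^{-10}$), with `max_iter = 500`.

Components are constrained to $[0, \infty)$. A component held near the
zero boundary for several consecutive iterations is dropped from the model
and reported as 0 with a boundary flag — the "not estimated and assumed to
be zero" (NE) convention of provenance-trial reports. Standard errors are
square roots of the diagonal of the inverse AI matrix at the optimum,
evaluated over all components so a boundary component still receives an SE
(the `0.00(SE)` style). On balanced one-way data the estimates coincide
with the closed-form ANOVA estimators to numerical precision, and on
unbalanced simulated trials they match `lme4::lmer` to about four decimal
places; both serve as independent oracles in the tests.

Between-trait provenance and error covariances come from the
variance-of-sum identity $\mathrm{Cov}(a,b) = [\mathrm{Var}(a+b) -
\mathrm{Var}(a) - \mathrm{Var}(b)]/2$ applied to three univariate fits on
the same trees, with the covariance projected so the implied correlation
lies in $[-1,1]$. Correlation standard errors use the delta method,
propagating the AI standard errors of the three provenance variances as if
independent; this ignores the (generally positive) covariance between the
three fits and is therefore approximate.

## Heritability, gain and the harmonic-mean correction

Provenance heritability is
$$ h^2 = \frac{V_P}{V_e/(n_h b) + V_{PB}/b + V_P}, $$
where $n_h = m / \sum_{ij} 1/n_{ij}$ is the harmonic mean of the $m$
non-empty plot counts — the replacement for the planted plot size when
mortality unbalances the design. Empty plots are excluded with $m$
reduced accordingly, since the formula is undefined for them. When
reproducing the published component table from its printed values we use
$n_h = 4.0$: the printed heritabilities back-solve to $n_h \approx
4.0$–$4.1$ for the growth traits, consistent with 5-tree plots at roughly
80% survival. The genetic variation coefficient is
$CV_G = 100\sqrt{V_P}/\bar X$ and realized gain is
$G = 100(\bar X_i - \bar X)/\bar X$, where $\bar X_i$ is the unweighted
mean of the selected provenances' means and $\bar X$ the unweighted mean
of all provenance means. Superior-provenance selection takes the overall
means of two indicator traits (volume + wood basic density for timber,
volume + fiber length for pulp) as thresholds and selects provenances
strictly above both.

The phenotypic correlation is computed exactly as
$r_P = (\mathrm{Cov}_P + \mathrm{Cov}_e)/\sqrt{(V_{P1}+V_{e1})(V_{P2}+V_{e2})}$;
note the interaction variance does not appear in this expression. We
follow the formula as printed for the trial rather than folding $V_{PB}$
into the phenotypic variance, and flag NE covariances as zero
contributions.

## Duncan's multiple range test

Provenance means are ranked and every span of $k$ adjacent means is
compared against the critical range
$q^*(\alpha_k, k, \nu)\sqrt{MS_e/n_e}$, where $q^*$ is the
studentized-range quantile at Duncan's protection level
$\alpha_k = 1-(1-\alpha)^{k-1}$, $MS_e$ and $\nu$ are the residual mean
square and df of the one-way provenance ANOVA, and $n_e$ is the harmonic
mean of group sizes (the standard convention for unequal survival, which
the source analyses do not specify). Letters are maximal homogeneous
spans, so they are contiguous over the ranked means, and ties are broken
by provenance code for determinism. At $k = 2$ the procedure is
algebraically a pooled two-sample t-test at level $\alpha$, which is how
the tests check its level: under a zero-provenance-variance null with two
groups the single-letter rate is $1-\alpha$ exactly. With more groups
Duncan's own protection level makes the all-homogeneous probability
$(1-\alpha)^{p-1}$ (about 0.81 at $p=5$), so the two-group case is the one
where "95% single letter" is the correct null expectation.

## Trend-surface analysis

Geographic variation is summarized by ordinary least squares on the binary
quadratic basis $Z = \beta_0 + \beta_1 x + \beta_2 y + \beta_3 x^2 +
\beta_4 y^2 + \beta_5 xy$ with $x$ = latitude and $y$ = longitude in raw
decimal degrees (no centering or projection — the reference coefficient
magnitudes indicate none was used). Observations are individual trees or
wood samples tagged with their provenance's coordinates: only this choice
reproduces the reference pattern of tiny fitting coefficients ($R^2
\approx 0.02$) that are nonetheless highly significant, which requires
hundreds of observations rather than ten provenance means. The raw
quadratic basis is ill-conditioned (condition number around $10^9$); the
fit uses QR via `lm`, warns above $10^{10}$, and the well-conditioned
summaries ($R^2$, $F$, $p$) are the quantities tested against a
normal-equations oracle at $10^{-10}$. Surfaces are evaluated on a
regular lattice over the data hull padded by 0.5 degrees (default
100 x 100; contouring is left to any plotting layer).

## The synthetic-trial generator

`simulation_config()` defaults encode the motivating study's conditions:
$p = b = 10$, $n = 5$, survival probability 0.8 (consistent with the
back-solved $n_h \approx 4$), two growth traits with grand means
12.52 cm and 11.98 m, components $(V_P, V_{PB}, V_e) = (0.47, 0.08,
8.97)$ and $(0.23, 0.26, 5.46)$, genetic correlation 0.97, and residual
covariance set so the phenotypic correlation is about 0.87. Blocks are
fixed effects in the analysis model, so the generator draws one set of
block effects per simulation (SD 1 on the cm scale — site heterogeneity of
the order of the provenance differences; the trial reports no block
variance) and reports them in the truth ledger. Mortality is i.i.d.
Bernoulli per tree because no mortality mechanism is recorded; the
generator therefore produces missingness completely at random, without the
spatial clustering, competition, or size-dependent mortality of real
plantations. Wood samples are generated without block structure, matching
their measurement design. The wood-trait lab process (one core per tree,
repeated measurements averaged) is summarized by a single residual term.
Passing parameter-recovery tests consequently show that the estimation
machinery inverts this idealized generating process, not that real trials
are free of spatial or non-random-missingness artifacts.

## Numerical choices and known limitations

* REML tolerances as above; initial values split the sample variance
  equally between components. Estimates are invariant to record order and
  to adding a constant to the response (tested).
* A genuinely boundary-valued component is reported as 0/NE rather than
  negative; this is the field's reporting convention, but it makes the
  *mean* of constrained estimates over replicates biased upward for
  components whose sampling error exceeds their true value. In the study
  conditions this is exactly the situation of $V_{PB} = 0.08$ (sampling SE
  about 0.25), and the recovery suite records mean $\hat V_{PB} \approx
  0.18$ and a mean $\hat h^2$ about 0.09 below the true-component value —
  a property of any non-negativity-constrained REML (an unconstrained fit
  would be mean-unbiased but can report negative variances). The same
  replicates recover $V_P$ and $V_e$ to well within the 15% band asserted
  by the suite and the simulated genetic correlation of 0.8 within its
  Monte-Carlo confidence interval.
* Duncan letters at $MS_e = 0$ degenerate to one letter per distinct mean.
* `trait_variation_summary()` reports the max/min fold for the provenance
  with the widest absolute range, skipping provenances with non-positive
  minima (their fold is undefined).
* Test problem sizes: recovery suites use 200 replicates of the full
  10 x 10 x 5 design; the Duncan level check uses 1,000 two-provenance
  trials; distributional checks on the generator use 25–300 replicates of
  reduced designs. These sizes put Monte-Carlo error comfortably inside
  the asserted tolerances.
* Out of scope by design: pedigree/kinship structure, spatial residual
  models, family-within-provenance effects, multi-trait selection indices,
  map projections and contour rendering, and moisture-content density
  variants.
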