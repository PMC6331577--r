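---
title: "Models and design choices in stocksel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in stocksel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stocksel` analyses a supplementation programme in a salmon river affected by
farmed-escapee introgression: broodstock caught in the river are crossed in a
hatchery, their offspring released as smolts, and returning adults are
genetically assigned back to their parents. The scientific question is whether
farmed ancestry in broodstock predicts the number of adult offspring
recaptured — i.e. whether the hatchery environment selects for domesticated
genotypes. This vignette explains each model, the choices behind the
defaults, and what the synthetic-data validation does and does not establish.

## Ancestry estimation

Each fish is genotyped at 81 nuclear SNPs of which 48 are diagnostic (large
wild/farmed frequency difference). With fixed reference frequencies $w_l$
(wild) and $f_l$ (farmed), the farmed-membership probability $P_{ind}$ is
estimated as the admixture proportion $q \in [0,1]$ maximising

$$\ell(q) = \sum_l g_l \log p_l(q) + (2-g_l)\log(1-p_l(q)),
\qquad p_l(q) = q f_l + (1-q) w_l,$$

over the non-missing diagnostic loci. This is a supervised maximum-likelihood
estimator with known reference frequencies rather than a Bayesian clustering
run: the downstream analyses use $P_{ind}$ only as a point estimate to be
rescaled, and the ML estimator is deterministic, fast, and directly testable
against a dense grid search (the test suite requires agreement within
$10^{-4}$). A curvature-based standard error is attached.

Proportion farmed ancestry is the affine rescaling
$D = (P_{ind} - P_W)/(P_D - P_W)$, where $P_W$ and $P_D$ are the mean
membership probabilities of pure wild and pure farmed reference samples
(published constants 0.0644 and 0.903). Because $P_W > 0$ and $P_D < 1$, raw
$D$ can fall slightly outside $[0,1]$; raw values are used in all models and a
clamp is available only for descriptive summaries. On simulated panels the
constants are re-derived by Monte Carlo from simulated pure-wild and
pure-farmed reference genomes, which is what makes $\hat D$ comparable with
the generating admixture proportion (the rescaling then corrects the
finite-panel shrinkage at the boundaries; without it the regression of
$\hat D$ on truth would have slope $1/(P_D - P_W)$ rather than 1).

Numerical details: reference frequencies are truncated to
$[10^{-4}, 1-10^{-4}]$ so fixed loci cannot produce infinite log-likelihoods;
optimisation is bracketed scalar maximisation on $[0,1]$ (tolerance $10^{-9}$)
with both endpoints checked; an individual with no scorable diagnostic locus
is returned as explicitly unestimable rather than silently zero.

## Parentage assignment

Offspring are assigned to dam $\times$ sire pairs by Mendelian exclusion: a
locus is a mismatch iff no combination of one transmitted allele per parent
can produce the offspring genotype; loci with any missing call among the trio
are skipped. The implementation reduces the per-locus check to interval
arithmetic on transmissible-allele counts and scores all candidate pairs with
cross-products, but the test suite verifies it against brute-force enumeration
of the four transmission combinations on random trios.

Decision thresholds follow the field protocol: offspring with more than 20%
missing nuclear genotypes are excluded before scoring; candidate parents are
all broodstock from the offspring's assigned brood year $\pm 1$ (aging
errors); the minimum-mismatch pair is accepted if unique and within 2
mismatches. Two mismatches is where re-genotyping, rather than acceptance,
became the protocol's remedy, and with 81 SNPs and a realistic per-call error
rate the true pair virtually never exceeds it. Ties are reported as
`ambiguous`, never broken silently — resolving them required re-genotyping in
the field, which has no analogue here. Maternity of accepted pairs is
verified against the dam's 15-SNP mitochondrial haplotype (tri-state:
consistent / inconsistent / untestable). Candidate pairs are enumerated
sex-aware (dams $\times$ sires from the roster); single-parent assignment is
not attempted.

## Phenotypes

Smolt length is back-calculated from scale readings with the classical
proportional body–scale relation $L_i = (S_i/S_{total}) \cdot L_{capture}$
(no intercept). Egg size is derived from the number of eggs spanning 25 cm via
a spherical egg model (diameter $250/n$ mm, volume $(\pi/6)d^3$ converted to
ml) and egg number as total volume over per-egg volume. Both conversions are
defined up to a multiplicative constant; since every downstream egg and
growth model is linear on the log scale, such constants move only intercepts,
never the reported effects. Egg size is treated as per-egg volume in ml.

## The model suite

All Gaussian mixed models (log offspring counts, log egg size, log egg
number, log smolt length) are fitted by **full maximum likelihood, not REML**,
through `lme4`, so that AIC comparisons across fixed-effect structures are
valid; the parameter count includes the variance components. The headline
count model is

$$\log N_{pair} = \beta_0 + \beta_H \mathrm{H(dam)} +
\beta_{W\!D} D_{pair}(1-\mathrm{H}) + \beta_{H\!D} D_{pair}\mathrm{H} +
\beta_E \log(\text{eggs}) + u_{year} + \varepsilon,$$

with $D_{pair}$ the dam–sire mean ancestry and $u_{year}$ a brood-year random
intercept. The suite reports this model with and without the egg covariate
and their AIC difference, and can fit a wider seven-candidate ladder. The
source tables describe these as least-squares regressions while the methods
text specifies a brood-year random factor; both variants are available
(`method = "mixed"` is the default, `method = "fixed"` the least-squares
fallback) since the discrepancy cannot be resolved from the text. Reported
multiplicative effects and percent effects use Wald intervals
($\pm 1.96\,$SE) transformed by `exp` or $100(e^x - 1)$.

The **sea-age model** is a multinomial logit with categories {1, 2, 3+}
(baseline 3+), per-contrast intercepts, within-year slopes on individual
ancestry $D$, slopes on the year-mean deviation $(\bar D_j - \bar{\bar D})$
separating within- from among-year effects, and independent normal year
random effects on both contrasts. Its marginal likelihood is maximised with a
Laplace approximation — an inner 2-D Newton solve per year (analytic gradient
and Hessian) inside an outer quasi-Newton optimisation. The test suite checks
the fixed-effects limit against an independent multinomial fit
(`nnet::multinom`, $10^{-3}$) and the integrated likelihood against
Gauss–Hermite quadrature ($10^{-3}$), and confirms that the 2-df
likelihood-ratio test for the ancestry slopes holds its nominal 5% size under
the null. Random-effect standard deviations are optimised on the log scale,
bounded to $[e^{-5}, e^{2}]$.

The **run-year contrast model** for ancestry of wild-born vs hatchery-reared
spawners is, as written,
$\mathrm{logit}(P_{ind,ij}) = a_i + b_i H_{ij} + e_{ij}$ with $e_{ij}$ iid
normal. Since $P_{ind}$ is continuous and $a_i, b_i$ are per-year parameters,
the observation-level random effect *is* the residual, and the maximum
likelihood fit is a Gaussian linear model on the logit scale with per-year
intercepts and contrasts; the package fits it exactly that way and reports
the residual SD as the overdispersion component. Proportions at the
boundaries are nudged inward by $10^{-6}$ before the logit. Per-year
contrasts get Wald z-tests at $\alpha = 0.05$; group grand means are the
across-year averages of the fitted year means back-transformed to the
proportion scale. Years sampled for only one origin are reported untestable.

## The synthetic-data generator

The generator's defaults are the study conditions, fixed once: 48 + 33
nuclear and 15 mitochondrial loci; 85 pairs over brood years 2005–2011; dam
and sire hatchery fractions 0.55 and 0.65; broodstock ancestry Beta with
means 0.113 (wild-born) and 0.303 (hatchery-reared), concentration 10 (the
study reports only means; concentration 10 gives the dispersion a diagnostic
panel can resolve); count-model coefficients at the reported best-model
estimates ($-4.5564$, $0.5560$, $1.5145$, $-0.5018$, $0.7069$); egg-size
factors 0.86 (hatchery dam) and 0.67 (full ancestry, wild-born dam); smolt
effects 6.2% (hatchery) and 5% (wild) around group means 232 mm and 152 mm;
run-year ancestry means 0.092 and 0.27 on the logit scale with year SD 0.3
and individual SD 0.8; genotyping error 0.002 per call (symmetric single
allele flip) and dropout 0.04 (matching a 96% offspring call rate;
broodstock are error-free, as they were re-genotyped to completeness).
Residual and year SDs of the count model (0.7, 0.2) are set to reproduce the
order of the reported standard errors at $n = 85$.

Unstated nuisance quantities were fixed analytically, once: dam weight is
lognormal (median 5.1 kg, sdlog 0.3) and egg production follows
$\log(\text{eggs}) = \log(1.45) + \log(\text{weight g})$ with a hatchery-dam
factor $e^{-0.12}$ — roughly 1450 eggs/kg — chosen so that the count model's
linear predictor yields an expected family size equal to the observed mean
10.3; egg size allometry (slope 0.10 on log weight, intercept $-3.27$) centres
eggs near 0.09 ml. Offspring counts are drawn as rounded lognormals with
zeros redrawn (the analysed families all have $\ge 1$ recapture, range 1–43).
Offspring genotypes follow Mendelian segregation from the simulated parental
genotypes before error injection, and mtDNA is inherited from the dam, so
zero-error data are exactly assignable. Smolt-length intercepts subtract the
ancestry slope times the group mean ancestry so group means stay centred on
232/152 mm. Sea-age categories are generated from the sea-age model's own
linear predictors (defaults: no ancestry effect, year SD 0.4), making the
type-I error of the LRT testable. All randomness flows from one seed through
named substreams, so repeated calls are byte-identical and modules can be
regenerated independently.

What the generator does **not** emulate: linkage between loci (the panel is
treated as independent SNPs), multi-generation dynamics of the river
population, aging error (offspring brood years are known; the $\pm 1$ window
is exercised only as a superset), farmed escapees mixed into the samples,
non-random broodstock capture, and any correlation between ancestry and
missingness or genotyping error. Passing recovery tests therefore shows the
estimators are correct and calibrated under the stated sampling model — not
that field data meet that model.

## Problem sizes in the test suite

Recovery tests use 200 replicates at study scale (85 pairs; 1500
hatchery-reared adults for the growth model; 20-year run-year studies with 70
fish per origin-year), 120 null replicates for the sea-age LRT size check,
and 300 random trios for the exclusion oracle. These sizes put Monte-Carlo
error well inside each test's acceptance band.

## Known limitations

* The ancestry standard error is a curvature approximation and degenerates at
  boundary optima; no uncertainty is propagated from $P_W$/$P_D$.
* The sea-age Laplace approximation is accurate for the year-level sample
  sizes used here (tens of fish per year) but is not adaptive quadrature;
  accuracy is verified on fixtures, not guaranteed globally.
* Likelihood-based parentage (LOD scores) and sibship reconstruction are out
  of scope; exclusion with a mismatch budget reproduces the original
  protocol.
* The least-squares/mixed-model ambiguity in the source tables is exposed as
  an option, not resolved.
* No multiple-testing correction is applied across run-year contrasts,
  matching the original analysis.
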