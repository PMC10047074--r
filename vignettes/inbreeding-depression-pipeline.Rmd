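---
title: "Two-step errors-in-variables analysis of inbreeding depression"
author: "dcinbreed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step errors-in-variables analysis of inbreeding depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Heterozygosity–fitness studies in non-pedigreed wild populations must
estimate each individual's inbreeding coefficient F from a modest panel of
markers, and F estimated from 20–30 microsatellites carries substantial
measurement error. Regressing fitness on a noisy covariate as if it were
known attenuates slopes and understates uncertainty. `dcinbreed`
implements a two-step errors-in-variables analysis designed for exactly
this situation, built around a long-term study of adult female Weddell
seals: 154 reproductive females genotyped at 29 microsatellite loci, with
life histories truncated to a 19-year observation horizon.

Both steps are fitted by **data cloning**: a Bayesian sampler is run on K
stacked copies of the data, for K on the schedule 1, 5, 10, 20, 40. As K
grows the posterior collapses onto the maximum-likelihood estimate and K
times the posterior covariance converges to the MLE covariance, so the
machinery delivers frequentist estimates, Wald intervals, and likelihoods
for information criteria while remaining free of prior influence.

## Step one: individual inbreeding coefficients

The genotype model treats each individual-by-locus call through a latent
identity-by-descent (IBD) indicator `x`. A heterozygote cannot be IBD; a
homozygote for an allele of frequency `p` is IBD with full-conditional
probability `q = F p / (F p + (1 - F) p^2)`. The Gibbs cycle is

1. `x | F, p` — Bernoulli(q), with q clamped to (0.00001, 0.99999);
2. `F_i | x` — conjugate Beta update from the Bayes–Laplace Beta(1, 1)
   prior: `Beta(1 + sum(x), 1 + K L_i - sum(x))` over the individual's
   `L_i` typed loci and K clones;
3. `p_l | x` — Dirichlet(1 + Z_l), where `Z_l` counts allele copies that
   are identical in state but **not** IBD (an IBD pair is counted once).

Cloning is carried exactly but implicitly: given (F, p) the K clone
indicators at one homozygous call are iid Bernoulli(q), so their sum is
drawn as a single Binomial(K, q) variate, with clone 1 materialised so
that the per-clone count of loci IBD, `sum_l x_il`, can be recorded. Each
individual's posterior histogram of that count is summarised by its mode
(the arithmetic mean of all modes when multimodal) and converted to the
measurement-error distribution step two consumes:
`F_i ~ Beta(A_i, B_i)` with `A = 1 + mode`, `B = 1 + L_i - mode` — the
natural conjugate reading of the modal-count summarisation. Loci are
assumed unlinked; missing calls simply drop out of `L_i`.

Convergence is monitored with the Gelman–Rubin statistic on every `F_i`
(threshold 1.1) and with the mean scaled posterior variance across the
clone schedule, which should fall roughly like 1/K (slope about -1 on
log–log axes).

The module also reports the field-standard genotype summaries: plug-in
expected heterozygosity `1 - sum(p^2)` (no small-sample correction, with
a normal-theory 95% CI across loci), Weir–Cockerham single-population
F_IS (undefined at monomorphic loci), the Brookfield estimator
`(He - Ho)/(1 + He)` for a potential null allele, multilocus
homozygosity, the David et al. (2007) identity-disequilibrium g2 with a
column-permutation p-value and an individual-bootstrap CI, and the
Pearson correlation between homozygosity and estimated F. The g2
permutation and bootstrap counts default to 1000 each and always require
an explicit seed.

## Step two: hierarchical fitness models

Four response families share the linear predictor
`eta = b0 + (b1 + theta_Y) F + b2 col + b3 F col + b4 first + gamma_Y`,
with `col` a birth-colony indicator, `first` marking the interval after a
female's first pup, and optional birth-year random intercepts `gamma_Y`
and slopes `theta_Y`:

* **Lifetime reproductive success** `r_i`: normal with mean `eta` and SD
  `sigma_r`, truncated below zero (only mothers are sampled, and one pup
  gives `r_i = 0` exactly) and censored above 0.3819509, the maximal
  value a female maturing at 4 and pupping yearly to 19 can attain.
* **Adult survival**: the death age is geometric in the annual survival
  `s`, with log-odds link `log((1-s)/s) = eta`; females alive at the
  horizon contribute the survivor mass `s^19`. By default the likelihood
  is censored only; `leftTruncateDeath = TRUE` additionally conditions on
  survival to age 4. We default to pure censoring because the model keeps
  (negligible) mass below the age of maturity and this matches the
  censoring description of the protocol; the switch makes the other
  reading available.
* **Age at first reproduction**: negative binomial with size 4 on
  `afr - 4` (four years of survival are needed to reach the minimum age
  at maturity), link `log(4 (1-p)/p) = eta`, so `exp(eta)` is the mean
  waiting time beyond age 4.
* **Pupping interval**: geometric on `wait - 1` with link
  `log((1-pi)/pi) = eta` and a parallel-lines `first` term.

`r_i` itself is the log dominant eigenvalue of an individual Leslie
matrix with unit survival and fecundity one at class `a - 1` for each pup
at maternal age `a`, making the characteristic equation
`sum(lambda^-(a-1)) = 1`. This convention is the unique simple one under
which a sole pup yields growth rate exactly zero and the maximal 19-year
schedule yields approximately the censoring constant (we compute
0.3818130, 1.4e-4 below the printed constant; the residual is a known
open point of the source protocol and far inside every tolerance used
here). The eigenvalue is found by bisection on the characteristic
equation, which is strictly decreasing in lambda, and cross-checked
against a dense eigendecomposition in the test-suite.

### Priors and starting values

Regression coefficients take Normal(0, var 10^4) priors; the `r_i`
intercept is truncated to (0, 0.3819509). The `r_i` family uses
half-Cauchy(0, 0.013) on `sigma_r` and half-Cauchy(0, 0.004) on the
year-intercept SD (fixed constants of the protocol, not recomputed from
data); the other families use Uniform(0, 100) on year-effect SDs.
Starting values follow the published per-family recipes, including the
ratio constructions `sigma_r = xi/chi`, redrawn until inside the prior
support. Chain lengths default to 20,000 iterations (burn-in 15,000) for
the growth-rate, survival and interval families and 10,000 (burn-in
5,000) for age at first reproduction, three chains, thinning 5 — the
protocol's own, mutually differing, settings.

### Sampler

The engine is an adaptive Metropolis-within-Gibbs written in C++: scalar
random-walk updates for each structural parameter with proposal scales
tuned toward roughly 30% acceptance and frozen after the adaptation
window (at most the burn-in) to preserve detailed balance; latent
`F_i`-per-clone values use independence proposals from their Beta(A, B)
measurement distributions, so the Beta prior cancels in the acceptance
ratio; year-effect blocks carry one column per clone, as cloning
replicates latent structure but not structural parameters. Latent F is
never clamped in step two; the clamp belongs to step one's Bernoulli
probability only. A non-finite starting likelihood triggers a fresh
start-value draw (up to ten attempts).

### Diagnostics, intervals, bands

A fit is declared converged when every R-hat is below 1.1 and the mean
scaled posterior variance at the final clone count is below 0.05
(single-level schedules skip the second rule). Reported diagnostics
mirror the data-cloning literature: the largest eigenvalue of the scaled
covariance, a mean-squared error and a correlation-like fit of the
pooled draws to their normal approximation, and the log scaled-variance
trajectory with its log–log slope. Non-convergence is a reported state:
such models stay in the output but are excluded from the evidence table.

Wald intervals are `mle ± z sqrt(diag(K_max × cov))` and refuse
non-converged fits unless forced. Confidence bands draw 10,000
coefficient vectors from MVN(mle, cov) and report pointwise 2.5/97.5%
quantiles of the fitted mean response on 1,000 equally spaced F values in
(0, 0.25); prediction bands additionally simulate new responses from the
fitted family (the growth-rate family respects its censoring bound). A
non-positive-definite covariance is repaired by eigenvalue clipping at
1e-12 with a warning.

### Marginal likelihood and model selection

Information criteria need the likelihood with latent quantities
integrated out. Each individual's F integrates by Gauss–Legendre
quadrature on the window `[qbeta(1e-12, A, B), qbeta(1 - 1e-12, A, B)]`
of the F scale: the window captures all but O(1e-12) of the Beta mass,
and on it the integrand (Beta density times likelihood) is smooth, so
convergence is spectral — a plain (0, 1) grid would starve concentrated
Betas of nodes, while the CDF substitution `F = qbeta(u)` has an
endpoint derivative singularity that degrades Gauss–Legendre to slow
algebraic convergence. The node count doubles from 64 to 512 until
every individual's log-marginal changes by less than 1e-6 (relative,
floored at magnitude one), and failure to converge is an error naming
the individual. Year random effects factorise by birth
year, so each year block is integrated by a one- or two-dimensional
Laplace approximation at its conditional mode; an importance-sampling
validator (`method = "is"`) is available to check the Laplace answer.
This deterministic route was chosen over the stochastic
likelihood-ratio-by-cloning method because it is testable against brute
force at desk scale.

`BIC = -2 loglik + k log n` and
`AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`, with `k` the number of
regression parameters (plus the residual SD for the growth-rate family);
random-effect parameters are not counted, matching the protocol's stated
convention, and the output footnote says so. `n` is the number of
individuals for the growth-rate, survival and maturity families and the
number of intervals for the pupping-interval family — the likelihood's
independent-unit count. Candidate sets are the nested sequence
intercept-only, +INB, +INB+COL, +INB+COL+INBxCOL (the interval family
always includes FIRST), optionally extended by year-effect variants.
Models within 2.77 of the minimum are flagged evidentially equivalent;
ties in the minimum go to the smaller k.

## The synthetic-data generator

The generator's defaults are the study conditions: 154 individuals, 29
loci with 4–15 alleles from flat Dirichlet frequency draws, birth years
1980–1992, horizon 19, colony probability 0.3, and a two-point F mixture
(90% outbred, 10% at F = 0.25) reflecting a wild-population regime;
a Beta option exists for conjugacy tests. Fitness coefficients default
to the study's natural-scale point estimates: non-inbred annual survival
0.945, mean age at first reproduction 7.39 y, experienced-breeder
reproduction probability 0.716 with a 2.08-fold longer first interval,
growth-rate intercept 0.1927 and slope -0.1056 per unit F (-0.0066 per
0.0625, one first-cousin increment). The growth-rate residual SD
defaults to 0.05, a realistic spread for a statistic confined to
(0, 0.382); the year-effect SD defaults to 0.001 on the link scale, in
keeping with the protocol's half-Cauchy scale being four times the
observed year SD.

Genotypes are generated by inverting the step-one model (with
probability `F_i` copy one allele, else draw two); life histories run
the survival, maturity and interval models generatively, and females
with no pup inside the horizon are redrawn, because the sample design
contains only mothers — the redraw count is logged so the selection
effect stays visible. A direct-response mode draws `r_i` from the
truncated-censored normal for clean recovery tests. What the generator
does **not** emulate: linkage between loci, genotyping error and null
alleles, age-varying survival, senescence, and the sampling design's
left truncation (a female must survive to her first pup to enter; the
fitted survival model does not condition on this unless
`leftTruncateDeath` is set). Passing recovery tests therefore show the
estimator is correct for its own assumptions, not that those
assumptions hold in any particular field system.

The conditioning does bias generative scenarios slightly: redrawing
zero-pup females enriches long-lived, early-maturing individuals, so
survival fitted to generated life histories sits above its generating
value. Recovery tests for the growth-rate slope use direct-response
mode, where no such selection operates.

## Numerical choices and test scale

Quadrature tolerances, the PSD repair threshold (1e-12), the bisection
bracket for the Leslie eigenvalue (the characteristic function is
monotone, so the root is unique), and the modal tie-break (average all
tied modes) are all fixed and documented above. The test-suite runs the
pipeline at reduced scale chosen once: step-one checks use 2 chains of
800–1,500 sweeps; step-two checks use 2 chains of 1,000–1,200 sweeps
with the two-point clone schedule {1, 40}; coverage of the
inbreeding-depression slope is assessed over 20 replicates of the full
two-step pipeline at n = 154 and L = 200 informative loci, and the
null-evidence property over 25 replicates at the study's own n. The
marker-recovery check fixes its seeds because, at L = 200, the realised
IBD fraction has binomial SD 0.031, so the ±0.05 window is only about
1.6 sigma wide even for an oracle estimator.

## Known limitations

* Survival is age-constant within the horizon; senescent declines are
  out of scope by design.
* The evidence table reproduces the published parameter-counting
  convention, which excludes random-effect parameters from k; treat k
  accordingly when comparing with other software.
* The marginal likelihood's Laplace step assumes a well-peaked year
  block; with two or three individuals per year and a large year SD the
  importance-sampling validator should be consulted.
* Identity disequilibrium with ~29 microsatellites has low power; g2
  near zero is expected even when a homozygosity–F correlation exists,
  and the package reports both so the contrast stays visible.
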