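# dcinbreed

Data-cloned errors-in-variables analysis of inbreeding depression in
non-pedigreed wild populations.

## The scientific problem

Detecting inbreeding depression without a pedigree means estimating each
individual's inbreeding coefficient F from a marker panel — and with
20–30 microsatellites those estimates are noisy. Treating them as known
covariates in a fitness regression attenuates slopes and understates
uncertainty. `dcinbreed` implements a two-step maximum-likelihood
analysis, developed for a long-term study of adult female Weddell seals
(*Leptonychotes weddellii*), that carries the measurement error through
to the fitness inference:

1. **Step one** estimates each F_i from multilocus genotypes with a Gibbs
   sampler over latent identity-by-descent indicators x_il: a homozygote
   for an allele of frequency p is IBD with probability
   `q = F p / (F p + (1 − F) p²)`; F_i gets a conjugate Beta update under
   the Bayes–Laplace Beta(1,1) prior; allele frequencies get a
   Dirichlet(1 + Z) update from the non-IBD allele counts. The posterior
   of the per-individual IBD count is summarised by its mode into a
   measurement-error distribution `F_i ~ Beta(A_i, B_i)`.
2. **Step two** fits hierarchical models of four fitness surrogates with
   F_i as a Beta-distributed latent covariate, sharing the predictor
   `eta = b0 + (b1 + theta_Y) F + b2 col + b3 F·col + b4 first + gamma_Y`:
   an individual Leslie-matrix growth rate r_i (normal, truncated below 0,
   censored above 0.3819509), adult survival (geometric, log-odds link),
   age at first reproduction (negative binomial, size 4), and pupping
   interval (geometric with a first-interval term). Candidate models are
   compared evidentially by ΔBIC/ΔAICc with models within 2.77 treated as
   equivalent.

Both steps are fitted by **data cloning** — running the sampler on K
stacked copies of the data for K = 1, 5, 10, 20, 40 — so the posterior
collapses onto the MLE and K × posterior covariance estimates the MLE
covariance, giving frequentist estimates and Wald intervals from Bayesian
machinery without prior sensitivity.

The package also provides GenePop input, the standard single-population
genotype summaries (expected heterozygosity, Weir–Cockerham F_IS,
Brookfield null-allele frequency, multilocus homozygosity, identity
disequilibrium g2), and synthetic-data generators that emulate the study
design so every stage is testable end to end.

## Worked example

```r
library(dcinbreed)

scenario <- simScenario(nIndividuals = 60, nLoci = 29, seed = 42)
study <- simulateStudy(scenario)

cfg <- ibdConfig(chains = 2, iterations = 2000, burnIn = 500, thin = 2,
                 cloneSchedule = c(1, 10, 40), seed = 42)
step1 <- estimateInbreeding(study$genotypes, cfg,
                            g2Perm = 200, g2Boot = 200)
step1$summary
#> InbreedingSummary: 60 individuals, clone schedule 1/10/40
#>   posterior mean F: median 0.0043, range 0.0011-0.3764
#>   max R-hat(F): 1.046 (converged)

step1$hetFCorrelation      # 0.87: homozygosity tracks estimated F
step1$g2$g2                # 0.0090: identity disequilibrium

responses <- deriveResponses(study$lifeHistories)
fit <- dcFit(modelSpec("ri", terms = "INB"), responses$ri,
             betaParams = betaParams(step1$summary),
             mcmc = mcmcConfig(chains = 2, iterations = 1200,
                               burnIn = 400, thin = 2, seed = 42),
             schedule = c(1, 40))
fit
#> DCFit [ ri ]: b0+b1INB
#>   clones: 1/40  converged: TRUE
#>           MLE     SE   lower  upper
#> b0     0.1487 0.0271  0.0955 0.2019
#> b1     0.2182 0.2093 -0.1921 0.6285
#> sigmaR 0.1149 0.0147  0.0860 0.1438

null <- dcFit(modelSpec("ri"), responses$ri,
              mcmc = mcmcConfig(chains = 2, iterations = 1200,
                                burnIn = 400, thin = 2, seed = 42),
              schedule = c(1, 40))
deltaTable(list(null, fit))
#> ModelComparison (n = 60 , equivalence < 2.77 )
#>     model k   loglik        BIC      AICc     dBIC     dAICc equivalent
#>        b0 2 55.42169 -102.65469 -106.6329 0.000000 0.0000000       TRUE
#>  b0+b1INB 3 56.09720  -99.91136 -105.7658 2.743335 0.8670355       TRUE
```

Reading the output: the MLE of the inbreeding slope `b1` has a Wald CI
straddling zero and the intercept-only model attains the minimum BIC,
with the inbreeding model inside the 2.77 equivalence band — the
evidence pattern of "at most slight inbreeding depression". (In this
generative scenario the life histories were simulated with no inbreeding
effect on survival or reproduction, so that is the right answer.)
`naturalScaleSummaries(fit)` translates coefficients into annual
survival, mean ages, and wait-time multipliers; `costOfInbreeding()`
turns the growth-rate coefficients into the fractional fitness cost
δ(F) = −b1·F/b0; `confidenceBand()` and `predictionBand()` produce the
1,000-point band tables on F ∈ (0, 0.25).

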