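#' Simulate a complete synthetic study
#'
#' Convenience wrapper around the generators: allele frequencies,
#' inbreeding coefficients, genotypes and life histories, optionally
#' written to disk as a fixture.
#'
#' @param scenario a [simScenario()].
#' @param outDir optional directory for [makeFixture()] output.
#' @return list with `genotypes` ([GenotypeTable-class]),
#'   `lifeHistories`, `truth`, and `paths` when written.
#' @export
simulateStudy <- function(scenario, outDir = NULL) {
  freqs <- simAlleleFrequencies(scenario)
  F <- simInbreedingCoefficients(scenario)
  gt <- simGenotypes(freqs, F, seed = scenario$seed + 5L)
  sim <- simLifeHistories(scenario, F)
  paths <- if (!is.null(outDir)) makeFixture(scenario, outDir) else NULL
  list(genotypes = gt, lifeHistories = sim$lifeHistories,
       truth = c(sim$truth, list(alleleFrequencies = freqs)),
       paths = paths)
}

#' Step one of the pipeline: inbreeding estimation and genotype summaries
#'
#' Runs the IBD Gibbs sampler across the clone schedule and reports the
#' per-individual Beta measurement distributions together with the locus
#' summaries, the homozygosity-F correlation, and identity disequilibrium
#' g2.
#'
#' @param genotypes a [GenotypeTable-class] or a GenePop file path.
#' @param config an [ibdConfig()].
#' @param g2Perm,g2Boot permutation/bootstrap counts for g2.
#' @return list: `summary` ([InbreedingSummary-class]), `locusSummaries`,
#'   `hetFCorrelation`, `g2`.
#' @export
estimateInbreeding <- function(genotypes, config = ibdConfig(seed = 1),
                               g2Perm = 1000, g2Boot = 1000) {
  gt <- if (is.character(genotypes)) readGenepop(genotypes) else genotypes
  summ <- runIbdSampler(gt, config)
  ls <- locusSummaries(gt)
  rho <- hetFCorrelation(gt, fEstimates(summ))
  g2 <- g2Microsats(gt, nPerm = g2Perm, nBoot = g2Boot,
                    seed = config$seed + 11L)
  list(summary = summ, locusSummaries = ls, hetFCorrelation = rho, g2 = g2)
}

#' Step two of the pipeline: data-cloned fitness-model selection
#'
#' Fits each family's nested candidate set by data cloning, integrates
#' the latent inbreeding coefficients out of the likelihood at the MLE,
#' and assembles the Delta-BIC/Delta-AICc evidence table plus
#' natural-scale summaries of the inbreeding model of each family.
#'
#' @param responses list of response data.frames from [deriveResponses()].
#' @param betaParams data.frame `id`, `A`, `B` from step one.
#' @param families subset of `c("ri", "death", "afr", "wait")`.
#' @param priors a [priorSet()].
#' @param schedule clone schedule.
#' @param seed integer seed.
#' @param quick use reduced chain lengths (2 chains of 1200 sweeps, 400
#'   burn-in) and the two-point schedule `c(1, K_max)`.
#' @param yearEffects fit year-effect variants as well.
#' @return list per family: `fits`, `comparison`
#'   ([ModelComparison-class]), `naturalScale` (for the model containing
#'   INB).
#' @export
fitFitnessModels <- function(responses, betaParams,
                             families = c("ri", "death", "afr", "wait"),
                             priors = priorSet(),
                             schedule = c(1, 5, 10, 20, 40), seed = 1,
                             quick = FALSE, yearEffects = FALSE) {
  out <- list()
  for (fam in families) {
    dat <- responses[[fam]]
    specs <- candidateSet(fam, yearEffects = yearEffects)
    sched <- if (quick) unique(c(1, schedule[length(schedule)])) else
      schedule
    fits <- lapply(specs, function(sp) {
      mc <- if (quick)
        mcmcConfig(chains = 2, iterations = 1200, burnIn = 400, thin = 2,
                   seed = seed)
      else .defaultMcmc(fam, seed)
      dcFit(sp, dat, betaParams = betaParams, priors = priors, mcmc = mc,
            schedule = sched)
    })
    lls <- vapply(fits, marginalLoglik, numeric(1))
    cmp <- deltaTable(fits, lls)
    # second entry of the nested set is the +INB model
    ns <- naturalScaleSummaries(fits[[2]])
    out[[fam]] <- list(fits = fits, logliks = lls, comparison = cmp,
                       naturalScale = ns)
  }
  out
}

#' Render a Markdown report of a full pipeline run
#'
#' @param stepOne output of [estimateInbreeding()].
#' @param stepTwo output of [fitFitnessModels()].
#' @param path output Markdown path.
#' @return `path`, invisibly.
#' @export
pipelineReport <- function(stepOne, stepTwo, path) {
  ls <- stepOne$locusSummaries
  U <- maxGrowthRateBound(19, 4)
  lines <- c(
    "# Inbreeding-depression pipeline report", "",
    "## Genotype summaries", "",
    sprintf("- mean expected heterozygosity: %.3f (95%% CI %.3f-%.3f)",
            ls$overall$mean_expected_het, ls$overall$ci_expected_het[1],
            ls$overall$ci_expected_het[2]),
    sprintf("- mean alleles per locus: %.1f", ls$overall$mean_n_alleles),
    sprintf("- homozygosity-F correlation: %.3f", stepOne$hetFCorrelation),
    sprintf("- identity disequilibrium g2: %.4f (p = %.3f, 95%% CI %.4f to %.4f)",
            stepOne$g2$g2, stepOne$g2$p_value, stepOne$g2$ci[1],
            stepOne$g2$ci[2]),
    "", "## Model selection", "",
    sprintf("Models within a Delta of %.2f are treated as evidentially equivalent.",
            2.77),
    sprintf("The growth-rate response is truncated below 0 and censored above %.7f.",
            U), "")
  for (fam in names(stepTwo)) {
    tb <- stepTwo[[fam]]$comparison@table
    lines <- c(lines, sprintf("### Family: %s", fam), "",
               "| Model | K | dBIC | dAICc | equivalent |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %.2f | %.2f | %s |", tb$model, tb$k,
                       tb$dBIC, tb$dAICc, tb$equivalent), "")
  }
  writeLines(lines, path)
  invisible(path)
}
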