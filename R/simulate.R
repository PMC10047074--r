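#' Simulation scenario for the two-step study design
#'
#' Defaults emulate the study conditions: 154 females genotyped at 29
#' microsatellite loci with 4-15 alleles per locus, inbreeding
#' coefficients from a two-point mixture (90 percent outbred, 10 percent
#' F = 0.25, the wild-population regime), birth years 1980-1992, a
#' 19-year observation horizon, and fitness-model coefficients at the
#' study's natural-scale point estimates: non-inbred annual survival
#' 0.945, mean age at first reproduction 7.39 y, experienced-breeder
#' annual reproduction probability 0.716 with a 2.08-fold longer first
#' interval, growth-rate intercept 0.1927 with slope -0.1056 per unit F
#' (-0.0066 per 0.0625).
#'
#' @param nIndividuals,nLoci study dimensions.
#' @param allelesPerLocus integer vector recycled across loci.
#' @param dirichletConcentration concentration of the allele-frequency
#'   Dirichlet.
#' @param fDistribution `list(type = "mixture", p = 0.1, f = 0.25)` or
#'   `list(type = "beta", a, b)`.
#' @param coefficients named list per family of coefficient vectors
#'   (`b0`, `b1` per unit F, `b2`, `b3`, and `b4` for the wait family);
#'   `sigmaR` the growth-rate residual SD.
#' @param yearLevels birth years; `sigmaGamma` SD of year random
#'   intercepts (per family, on the link scale); `sigmaTheta` SD of year
#'   random slopes on F.
#' @param colonyProbability probability of Dellbridge birth colony.
#' @param horizon observation horizon (years).
#' @param seed integer seed (required).
#' @return a `sim_scenario` list.
#' @export
simScenario <- function(nIndividuals = 154, nLoci = 29,
                        allelesPerLocus = 4:15,
                        dirichletConcentration = 1,
                        fDistribution = list(type = "mixture", p = 0.1,
                                             f = 0.25),
                        coefficients = list(
                          ri = c(b0 = 0.1927, b1 = -0.1056, b2 = 0, b3 = 0),
                          sigmaR = 0.05,
                          death = c(b0 = log(0.055 / 0.945), b1 = 0,
                                    b2 = 0, b3 = 0),
                          afr = c(b0 = log(3.39), b1 = 0, b2 = 0, b3 = 0),
                          wait = c(b0 = log(0.284 / 0.716), b1 = 0, b2 = 0,
                                   b3 = 0, b4 = log(2.08))),
                        yearLevels = 1980:1992, sigmaGamma = 0.001,
                        sigmaTheta = 0, colonyProbability = 0.3,
                        horizon = 19, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(nIndividuals >= 1, nLoci >= 1, all(allelesPerLocus >= 2),
            dirichletConcentration > 0, colonyProbability >= 0,
            colonyProbability <= 1, coefficients$sigmaR > 0)
  structure(list(nIndividuals = nIndividuals, nLoci = nLoci,
                 allelesPerLocus = allelesPerLocus,
                 dirichletConcentration = dirichletConcentration,
                 fDistribution = fDistribution,
                 coefficients = coefficients, yearLevels = yearLevels,
                 sigmaGamma = sigmaGamma, sigmaTheta = sigmaTheta,
                 colonyProbability = colonyProbability, horizon = horizon,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate per-locus allele-frequency simplexes
#'
#' One Dirichlet draw per locus, dimension cycling through
#' `allelesPerLocus`.
#'
#' @param scenario a [simScenario()].
#' @return list of frequency vectors (each sums to one).
#' @export
simAlleleFrequencies <- function(scenario) {
  set.seed(scenario$seed + 1L)
  dims <- rep_len(scenario$allelesPerLocus, scenario$nLoci)
  lapply(dims, function(d) {
    g <- rgamma(d, scenario$dirichletConcentration, 1)
    g / sum(g)
  })
}

#' Simulate individual inbreeding coefficients
#'
#' Draws from the configured Beta or two-point mixture; the mixture is the
#' default wild-population regime (mostly outbred with a minority at the
#' full-sib level).
#'
#' @param scenario a [simScenario()].
#' @return numeric vector of F, with the truth retained for recovery
#'   tests.
#' @export
simInbreedingCoefficients <- function(scenario) {
  set.seed(scenario$seed + 2L)
  fd <- scenario$fDistribution
  n <- scenario$nIndividuals
  if (fd$type == "mixture") {
    ifelse(runif(n) < fd$p, fd$f, 0)
  } else if (fd$type == "beta") {
    rbeta(n, fd$a, fd$b)
  } else stop("unknown F distribution type")
}

#' Simulate genotypes given allele frequencies and inbreeding
#'
#' Per individual and locus: with probability `F_i` a single allele is
#' drawn from the locus frequencies and copied (identical by descent);
#' otherwise two alleles are drawn independently.
#'
#' @param freqs list of per-locus frequency vectors.
#' @param F per-individual inbreeding coefficients in `[0, 1]`.
#' @param seed integer seed.
#' @param missingRate proportion of calls set missing at random.
#' @return a [GenotypeTable-class].
#' @export
simGenotypes <- function(freqs, F, seed, missingRate = 0) {
  stopifnot(all(F >= 0), all(F <= 1))
  set.seed(seed)
  n <- length(F); L <- length(freqs)
  lab <- function(i) formatC(i, width = 2, flag = "0")
  m1 <- matrix(NA_character_, n, L)
  m2 <- matrix(NA_character_, n, L)
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    ibd <- runif(n) < F
    a <- sample.int(length(p), n, replace = TRUE, prob = p)
    b <- sample.int(length(p), n, replace = TRUE, prob = p)
    b[ibd] <- a[ibd]
    m1[, l] <- lab(a)
    m2[, l] <- lab(b)
  }
  if (missingRate > 0) {
    drop <- matrix(runif(n * L) < missingRate, n, L)
    # never blank out a whole locus
    for (l in seq_len(L)) if (all(drop[, l])) drop[1, l] <- FALSE
    m1[drop] <- NA; m2[drop] <- NA
  }
  rownames(m1) <- rownames(m2) <- paste0("ind", seq_len(n))
  colnames(m1) <- colnames(m2) <- paste0("loc", seq_len(L))
  genotypeTable(m1, m2)
}

#' Emulate step-one Beta summaries from true inbreeding coefficients
#'
#' Draws a binomial IBD count at `nLoci` loci for each individual and
#' applies the conjugate summarisation `A = 1 + k`, `B = 1 + L - k`,
#' mimicking the shape of the Gibbs-sampler output without running it.
#'
#' @param F true inbreeding coefficients.
#' @param nLoci marker count L.
#' @param seed integer seed.
#' @param ids individual identifiers.
#' @return data.frame `id`, `A`, `B`.
#' @export
simBetaParams <- function(F, nLoci = 29, seed,
                          ids = paste0("ind", seq_along(F))) {
  set.seed(seed)
  k <- rbinom(length(F), nLoci, F)
  data.frame(id = ids, A = 1 + k, B = 1 + nLoci - k,
             stringsAsFactors = FALSE)
}

# year effects for one family: intercepts and slopes by year level
.simYearEffects <- function(scenario) {
  ny <- length(scenario$yearLevels)
  list(gamma = setNames(rnorm(ny, 0, scenario$sigmaGamma),
                        scenario$yearLevels),
       theta = setNames(rnorm(ny, 0, scenario$sigmaTheta),
                        scenario$yearLevels))
}

#' Simulate life histories from the generative fitness models
#'
#' Runs the survival, age-at-first-reproduction and pupping-interval
#' models generatively: afr from NB(4, p), death age from the geometric
#' survival model, waits from the geometric interval model with the
#' first-interval term, all on their log-odds links with colony, year and
#' inbreeding terms. Individuals whose schedule yields no pup inside the
#' horizon are redrawn (the sample design contains only mothers); the
#' redraw count is reported.
#'
#' @param scenario a [simScenario()].
#' @param F per-individual inbreeding coefficients (defaults drawn from
#'   the scenario).
#' @return list: `lifeHistories` (data.frame with `pup_ages` list-column),
#'   `truth` (F, coefficients, year effects, colony, redraws).
#' @export
simLifeHistories <- function(scenario, F = simInbreedingCoefficients(scenario)) {
  set.seed(scenario$seed + 3L)
  n <- scenario$nIndividuals
  cf <- scenario$coefficients
  hz <- scenario$horizon
  yeDeath <- .simYearEffects(scenario)
  yeAfr <- .simYearEffects(scenario)
  yeWait <- .simYearEffects(scenario)
  col <- rbinom(n, 1, scenario$colonyProbability)
  year <- sample(scenario$yearLevels, n, replace = TRUE)
  yc <- as.character(year)

  etaOf <- function(b, ye, i, first = 0) {
    v <- b[["b0"]] + (b[["b1"]] + ye$theta[yc[i]]) * F[i] +
      b[["b2"]] * col[i] + b[["b3"]] * F[i] * col[i] + ye$gamma[yc[i]]
    if ("b4" %in% names(b)) v <- v + b[["b4"]] * first
    unname(v)
  }

  redraws <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      sAnn <- 1 / (1 + exp(etaOf(cf$death, yeDeath, i)))
      d <- rgeom(1, 1 - sAnn)               # age at death (years survived)
      afr <- 4 + rnbinom(1, size = 4, prob = {
        e <- exp(etaOf(cf$afr, yeAfr, i)); 4 / (4 + e)
      })
      lastAge <- min(d, hz)
      if (afr > lastAge || afr > hz) { redraws <- redraws + 1L; next }
      pups <- afr
      age <- afr
      firstInt <- 1
      repeat {
        piProb <- 1 / (1 + exp(etaOf(cf$wait, yeWait, i, first = firstInt)))
        w <- 1 + rgeom(1, piProb)
        if (age + w > lastAge) break
        age <- age + w
        pups <- c(pups, age)
        firstInt <- 0
      }
      rows[[i]] <- data.frame(id = paste0("ind", i), birth_year = year[i],
                              dellbridge = col[i], last_observed_age = lastAge,
                              stringsAsFactors = FALSE)
      rows[[i]]$pup_ages <- list(pups)
      break
    }
  }
  lh <- do.call(rbind, rows)
  lh$horizon <- hz
  list(lifeHistories = lh,
       truth = list(F = F, coefficients = cf,
                    yearEffects = list(death = yeDeath, afr = yeAfr,
                                       wait = yeWait),
                    colony = col, birthYear = year, redraws = redraws))
}

#' Simulate growth-rate responses directly
#'
#' Direct-response mode for clean recovery tests of the growth-rate
#' family: draws `r_i` from the truncated-below-zero, censored-above-U
#' normal with mean `b0 + b1 F + b2 col + b3 F col` and SD `sigmaR`.
#'
#' @param scenario a [simScenario()].
#' @param F inbreeding coefficients.
#' @param col colony indicators (default drawn from the scenario).
#' @param seed integer seed (defaults to the scenario's).
#' @return data.frame `id`, `ri`, `censored_at_max`, `col`, `year`.
#' @export
simGrowthRates <- function(scenario, F,
                           col = rbinom(length(F), 1,
                                        scenario$colonyProbability),
                           seed = scenario$seed + 4L) {
  set.seed(seed)
  cf <- scenario$coefficients$ri
  U <- maxGrowthRateBound(scenario$horizon, 4)
  mu <- cf[["b0"]] + cf[["b1"]] * F + cf[["b2"]] * col +
    cf[["b3"]] * F * col
  s <- scenario$coefficients$sigmaR
  plo <- pnorm(-mu / s)
  y <- mu + s * qnorm(runif(length(F), plo, 1))
  cens <- y >= U
  data.frame(id = paste0("ind", seq_along(F)), ri = pmin(y, U),
             censored_at_max = cens, col = col,
             year = sample(scenario$yearLevels, length(F), replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture to disk
#'
#' GenePop genotypes, a life-history CSV, a truth JSON (inbreeding
#' coefficients, generator coefficients, year effects, seed) and a
#' scenario dump; deterministic given the scenario seed.
#'
#' @param scenario a [simScenario()].
#' @param outDir writable directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
makeFixture <- function(scenario, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  freqs <- simAlleleFrequencies(scenario)
  F <- simInbreedingCoefficients(scenario)
  gt <- simGenotypes(freqs, F, seed = scenario$seed + 5L)
  sim <- simLifeHistories(scenario, F)
  gp <- file.path(outDir, "genotypes.gen")
  writeGenepop(gt, gp)
  lh <- sim$lifeHistories
  lh$pup_ages <- vapply(lh$pup_ages, paste, character(1), collapse = ";")
  lhPath <- file.path(outDir, "life_histories.csv")
  write.csv(lh[, c("id", "birth_year", "dellbridge", "pup_ages",
                   "last_observed_age")], lhPath, row.names = FALSE)
  truthPath <- file.path(outDir, "truth.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(seed = scenario$seed, F = sim$truth$F,
           coefficients = sim$truth$coefficients,
           redraws = sim$truth$redraws),
      truthPath, auto_unbox = TRUE, digits = NA)
  } else {
    truthPath <- NA_character_
  }
  invisible(list(genotypes = gp, lifeHistories = lhPath,
                 truth = truthPath))
}
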