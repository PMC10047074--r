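# shared fixture builders; everything is generated in code

# genotype table from a character matrix of "a/b" strings, NA for missing
gtFromStrings <- function(calls) {
  calls <- as.matrix(calls)
  a1 <- matrix(NA_character_, nrow(calls), ncol(calls))
  a2 <- a1
  for (j in seq_len(ncol(calls))) {
    parts <- strsplit(calls[, j], "/")
    a1[, j] <- vapply(parts, function(p) if (length(p)) p[1] else NA_character_,
                      character(1))
    a2[, j] <- vapply(parts, function(p) if (length(p)) p[2] else NA_character_,
                      character(1))
  }
  rownames(a1) <- rownames(a2) <- rownames(calls)
  colnames(a1) <- colnames(a2) <- colnames(calls)
  genotypeTable(a1, a2)
}

# write a GenePop file from lines, return path
writeGenepopText <- function(lines) {
  path <- tempfile(fileext = ".gen")
  writeLines(lines, path)
  path
}

# independent direct-summation implementation of the multilocus g2
# estimator (quadruple loop; the oracle for the vectorised version)
g2BruteForce <- function(h) {
  L <- ncol(h); n <- nrow(h)
  typed <- !is.na(h)
  num <- 0; den <- 0
  for (l in seq_len(L)) for (k in seq_len(L)) {
    if (l == k) next
    ids <- which(typed[, l] & typed[, k])
    Nlk <- length(ids)
    if (Nlk < 2) next
    cross <- 0
    for (i in ids) cross <- cross + h[i, l] * h[i, k]
    num <- num + cross / Nlk
    pairSum <- 0
    for (i in ids) for (j in ids) if (i != j)
      pairSum <- pairSum + h[i, l] * h[j, k]
    den <- den + pairSum / (Nlk * (Nlk - 1))
  }
  num / den - 1
}

# minimal DCFit stand-in for table/selection tests
fakeFit <- function(label, k, converged = TRUE, n = 154, family = "ri") {
  sp <- list(family = family, terms = character(), yearIntercept = FALSE,
             yearSlope = FALSE, leftTruncateDeath = FALSE, kParams = k,
             label = label)
  new("DCFit", family = family, spec = sp, cloneSchedule = c(1, 40),
      mle = c(b0 = 0.1), covMle = matrix(1e-4, 1, 1,
                                         dimnames = list("b0", "b0")),
      waldCI = cbind(lower = 0, upper = 0.2), rhat = c(b0 = 1),
      diagnostics = list(), converged = converged,
      draws = matrix(0.1, 10, 1, dimnames = list(NULL, "b0")),
      perK = list(), data = list(), n = n)
}

# quick mcmc settings used throughout the stochastic tests
quickMcmc <- function(seed, chains = 2, iterations = 1200, burnIn = 400)
  mcmcConfig(chains = chains, iterations = iterations, burnIn = burnIn,
             thin = 2, seed = seed)
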