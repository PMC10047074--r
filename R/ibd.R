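#' Configuration for the identity-by-descent Gibbs sampler
#'
#' Defaults follow the study protocol: Bayes-Laplace Beta(1,1) prior on
#' each inbreeding coefficient, Bernoulli success probability clamped to
#' (0.00001, 0.99999), three chains of 10,000 sweeps with the first 5,000
#' discarded and every 5th sample kept, and a clone schedule of
#' 1/5/10/20/40 copies.
#'
#' @param betaPriorA,betaPriorB Beta prior shape parameters for F.
#' @param bernoulliFloor,bernoulliCeiling clamp for the IBD Bernoulli
#'   success probability.
#' @param chains,iterations,burnIn,thin MCMC settings per clone level.
#' @param cloneSchedule increasing clone counts; the last level provides the
#'   Beta(A, B) summaries.
#' @param seed integer seed (required); per-chain and per-level substreams
#'   are derived from it deterministically.
#' @return an `ibd_config` list.
#' @export
ibdConfig <- function(betaPriorA = 1, betaPriorB = 1,
                      bernoulliFloor = 0.00001, bernoulliCeiling = 0.99999,
                      chains = 3, iterations = 10000, burnIn = 5000,
                      thin = 5, cloneSchedule = c(1, 5, 10, 20, 40),
                      seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(bernoulliFloor > 0, bernoulliCeiling < 1,
            bernoulliFloor < bernoulliCeiling,
            thin >= 1, burnIn < iterations, chains >= 1,
            all(diff(cloneSchedule) > 0))
  structure(list(betaPriorA = betaPriorA, betaPriorB = betaPriorB,
                 bernoulliFloor = bernoulliFloor,
                 bernoulliCeiling = bernoulliCeiling,
                 chains = chains, iterations = iterations, burnIn = burnIn,
                 thin = thin, cloneSchedule = cloneSchedule,
                 seed = as.integer(seed)),
            class = "ibd_config")
}

#' Conditional IBD probability at a homozygous locus
#'
#' The Gibbs full conditional for the indicator that the two alleles of a
#' homozygote for an allele of frequency `p` are identical by descent:
#' `q = F p / (F p + (1 - F) p^2)`, with F clamped to the configured
#' Bernoulli bounds. Heterozygous calls have probability zero by
#' definition.
#'
#' @param f inbreeding coefficient(s) in `[0, 1]`.
#' @param p frequency of the homozygous allele.
#' @param floor,ceiling clamp applied to `f`.
#' @return probability (vectorised over `f` and `p`).
#' @export
ibdBernoulliProb <- function(f, p, floor = 0.00001, ceiling = 0.99999) {
  ft <- pmin(pmax(f, floor), ceiling)
  ft * p / (ft * p + (1 - ft) * p^2)
}

#' Non-IBD allele counts Z from genotypes and indicators
#'
#' For one clone of the data: each heterozygote contributes one copy to each
#' of its two allele states; a homozygote contributes two copies if its
#' alleles are not IBD and one copy (counted once) if they are.
#'
#' @param table a [GenotypeTable-class].
#' @param x integer matrix (individuals x loci) of IBD indicators; ignored
#'   (may be `NA`) at heterozygous or missing calls.
#' @return list per locus of named allele-count vectors.
#' @export
computeZ <- function(table, x) {
  L <- nLoci(table)
  out <- vector("list", L)
  names(out) <- locusNames(table)
  for (l in seq_len(L)) {
    reg <- table@alleleRegistry[[l]]
    z <- setNames(numeric(length(reg)), reg)
    for (i in seq_len(nIndividuals(table))) {
      a1 <- table@allele1[i, l]; a2 <- table@allele2[i, l]
      if (is.na(a1)) next
      if (a1 != a2) {
        z[a1] <- z[a1] + 1
        z[a2] <- z[a2] + 1
      } else {
        z[a1] <- z[a1] + if (isTRUE(x[i, l] == 1)) 1 else 2
      }
    }
    out[[l]] <- z
  }
  out
}

#' Beta measurement distribution from a modal IBD count
#'
#' Summarises the posterior histogram of the per-clone number of loci IBD
#' by its mode (ties: the arithmetic mean of all modes) and returns the
#' Bayes-Laplace conjugate Beta parameters `A = 1 + mode`,
#' `B = 1 + L_i - mode`.
#'
#' @param countPosterior named integer vector: histogram of the IBD count
#'   (names are counts, values are frequencies), or a raw vector of counts.
#' @param typedLoci number of typed loci `L_i`.
#' @param isHistogram whether `countPosterior` is already tabulated.
#' @return named numeric vector `c(A =, B =, modal =)`.
#' @export
summarizeToBeta <- function(countPosterior, typedLoci, isHistogram = !is.null(names(countPosterior))) {
  if (!isHistogram) {
    tb <- table(countPosterior)
  } else {
    tb <- countPosterior
  }
  if (!length(tb)) stop("empty count posterior")
  counts <- as.numeric(names(tb))
  if (any(is.na(counts))) stop("histogram names must be numeric counts")
  modes <- counts[tb == max(tb)]
  kbar <- mean(modes)
  if (kbar < 0 || kbar > typedLoci)
    stop("modal count outside [0, typed loci]")
  c(A = 1 + kbar, B = 1 + typedLoci - kbar, modal = kbar)
}

#' Gibbs estimation of individual inbreeding coefficients
#'
#' Step one of the two-step analysis: fits the latent-IBD model to the
#' genotypes at each clone count of the schedule, monitors the Gelman-Rubin
#' statistic of every F, and summarises the final clone level into
#' per-individual Beta(A, B) measurement-error distributions via the modal
#' number of loci identical by descent.
#'
#' @param table a [GenotypeTable-class].
#' @param config an [ibdConfig()].
#' @return an [InbreedingSummary-class].
#' @export
runIbdSampler <- function(table, config = ibdConfig(seed = 1)) {
  if (nIndividuals(table) == 0) stop("empty genotype table")
  n <- nIndividuals(table)
  typed <- .typedCounts(table)
  schedule <- config$cloneSchedule
  nAll <- vapply(table@alleleRegistry, length, integer(1))

  varByK <- numeric(length(schedule))
  finalF <- NULL; finalK <- NULL; rhat <- NULL
  for (si in seq_along(schedule)) {
    K <- schedule[si]
    Fch <- vector("list", config$chains)
    kch <- vector("list", config$chains)
    for (ch in seq_len(config$chains)) {
      set.seed(config$seed + 7919L * si + 104729L * ch)
      res <- ibd_gibbs_chain(table@allele1, table@allele2, nAll, K,
                             config$iterations, config$burnIn, config$thin,
                             config$betaPriorA, config$betaPriorB,
                             config$bernoulliFloor, config$bernoulliCeiling)
      Fch[[ch]] <- res$F
      kch[[ch]] <- res$k
    }
    allF <- do.call(rbind, Fch)
    varByK[si] <- mean(apply(allF, 2, var))
    if (si == length(schedule)) {
      finalF <- Fch
      finalK <- kch
      rhat <- vapply(seq_len(n), function(i)
        gelmanRubin(lapply(Fch, function(m) m[, i])), numeric(1))
    }
  }
  allF <- do.call(rbind, finalF)
  allK <- do.call(rbind, finalK)
  summ <- lapply(seq_len(n), function(i) {
    b <- summarizeToBeta(base::table(allK[, i]), typed[i],
                         isHistogram = TRUE)
    data.frame(id = individualIds(table)[i], typed_loci = typed[i],
               modal_ibd_count = b[["modal"]], A = b[["A"]], B = b[["B"]],
               posterior_mean_F = mean(allF[, i]), rhat_F = rhat[i],
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, summ)
  conv <- all(stats$rhat_F < 1.1, na.rm = TRUE)
  if (!conv)
    warning("R-hat above 1.1 for some inbreeding coefficients at the ",
            "final clone level")
  new("InbreedingSummary", stats = stats,
      cloneSchedule = as.numeric(schedule),
      finalClones = as.numeric(schedule[length(schedule)]),
      scaledVar = data.frame(K = schedule, scaled_var = varByK / varByK[1]),
      converged = conv)
}

#' Export an InbreedingSummary to CSV
#'
#' @param summary an [InbreedingSummary-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeInbreedingSummary <- function(summary, path) {
  write.csv(summary@stats, path, row.names = FALSE)
  invisible(path)
}
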