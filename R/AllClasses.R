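#' @import methods
#' @importFrom stats dbeta dnorm pnorm qnorm qbeta rnorm runif rbeta rbinom
#'   rgamma rcauchy rnbinom rgeom dbinom quantile var cor sd optimize optim
#'   uniroot setNames aggregate dcauchy
#' @importFrom utils head read.csv write.csv
#' @useDynLib dcinbreed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GenotypeTable: individuals x loci codominant genotype calls
#'
#' Stores unordered allele-pair calls for a set of individuals at a set of
#' codominant (e.g. microsatellite) loci, with support for missing calls.
#' Alleles are kept as integer indices into a per-locus allele registry so
#' that summaries are invariant to allele relabelling.
#'
#' @slot individualIds character vector of unique individual identifiers.
#' @slot locusNames character vector of unique locus names.
#' @slot allele1,allele2 integer matrices (individuals x loci) of allele
#'   indices into the locus registry; both `NA` where the call is missing.
#'   Pairs are stored with `allele1 <= allele2`.
#' @slot alleleRegistry list (one element per locus) of character vectors of
#'   allele labels.
#'
#' @export
setClass("GenotypeTable",
  representation(
    individualIds  = "character",
    locusNames     = "character",
    allele1        = "matrix",
    allele2        = "matrix",
    alleleRegistry = "list"
  )
)

setValidity("GenotypeTable", function(object) {
  msg <- character()
  n <- length(object@individualIds)
  L <- length(object@locusNames)
  if (anyDuplicated(object@individualIds))
    msg <- c(msg, "individual ids must be unique")
  if (anyDuplicated(object@locusNames))
    msg <- c(msg, "locus names must be unique")
  if (!all(dim(object@allele1) == c(n, L)) ||
      !all(dim(object@allele2) == c(n, L)))
    msg <- c(msg, "allele matrices must be individuals x loci")
  if (length(object@alleleRegistry) != L)
    msg <- c(msg, "alleleRegistry must have one entry per locus")
  if (!identical(is.na(object@allele1), is.na(object@allele2)))
    msg <- c(msg, "allele1 and allele2 must be missing together")
  if (L > 0 && n > 0) {
    for (l in seq_len(L)) {
      a <- c(object@allele1[, l], object@allele2[, l])
      a <- a[!is.na(a)]
      if (length(a) == 0) {
        msg <- c(msg, sprintf("locus '%s' has no typed individuals",
                              object@locusNames[l]))
      } else if (any(a < 1 | a > length(object@alleleRegistry[[l]]))) {
        msg <- c(msg, sprintf("allele index out of registry at locus '%s'",
                              object@locusNames[l]))
      }
    }
    bad <- which(!is.na(object@allele1) & object@allele1 > object@allele2)
    if (length(bad))
      msg <- c(msg, "allele pairs must be stored with allele1 <= allele2")
  }
  if (length(msg)) msg else TRUE
})

#' InbreedingSummary: per-individual inbreeding posteriors from step one
#'
#' Result of the identity-by-descent Gibbs sampler. For each individual the
#' posterior distribution of the number of loci identical by descent is
#' summarised by its mode (average of modes when multimodal) and converted
#' to a Beta(A, B) measurement-error distribution that step two consumes.
#'
#' @slot stats data.frame with one row per individual: `id`, `typed_loci`,
#'   `modal_ibd_count`, `A`, `B`, `posterior_mean_F`, `rhat_F`.
#' @slot cloneSchedule integer vector of clone counts fitted.
#' @slot finalClones clone count used for the summary (the last entry).
#' @slot scaledVar data.frame of per-clone-level mean scaled posterior
#'   variance of F (relative to the first level).
#' @slot converged logical: all R-hat below 1.1 at the final clone level.
#'
#' @export
setClass("InbreedingSummary",
  representation(
    stats         = "data.frame",
    cloneSchedule = "numeric",
    finalClones   = "numeric",
    scaledVar     = "data.frame",
    converged     = "logical"
  )
)

setValidity("InbreedingSummary", function(object) {
  need <- c("id", "typed_loci", "modal_ibd_count", "A", "B",
            "posterior_mean_F", "rhat_F")
  if (!all(need %in% names(object@stats)))
    return(paste("stats must contain:", paste(need, collapse = ", ")))
  s <- object@stats
  if (any(s$A <= 0) || any(s$B <= 0)) return("A and B must be positive")
  if (any(s$modal_ibd_count < 0 | s$modal_ibd_count > s$typed_loci))
    return("modal count must lie in [0, typed_loci]")
  if (any(abs(s$A + s$B - (s$typed_loci + 2)) > 1e-8))
    return("A + B must equal typed_loci + 2")
  TRUE
})

#' DCFit: a data-cloned maximum-likelihood model fit
#'
#' @slot family model family, one of `"ri"`, `"death"`, `"afr"`, `"wait"`,
#'   `"gaussian"`.
#' @slot spec the [modelSpec()] fitted.
#' @slot cloneSchedule clone counts used.
#' @slot mle named numeric vector: posterior mean at the largest clone count.
#' @slot covMle MLE covariance, K_max times the posterior covariance.
#' @slot waldCI matrix (parameters x 2) of 95 percent Wald intervals.
#' @slot rhat per-parameter potential scale reduction at K_max.
#' @slot diagnostics list of data-cloning diagnostics (largest eigenvalue of
#'   the scaled covariance, mean squared error and correlation-like fit of
#'   the normal approximation, scaled variance by clone level and its
#'   log-log slope).
#' @slot converged logical per the scaled-variance and R-hat rules.
#' @slot draws matrix of saved posterior draws at K_max (rows = draws).
#' @slot perK list of per-clone-level posterior means and covariances.
#' @slot data the internal model data list (kept for likelihood evaluation
#'   and band construction).
#' @slot n number of independent sampling units for information criteria.
#'
#' @export
setClass("DCFit",
  representation(
    family        = "character",
    spec          = "list",
    cloneSchedule = "numeric",
    mle           = "numeric",
    covMle        = "matrix",
    waldCI        = "matrix",
    rhat          = "numeric",
    diagnostics   = "list",
    converged     = "logical",
    draws         = "matrix",
    perK          = "list",
    data          = "list",
    n             = "numeric"
  )
)

setValidity("DCFit", function(object) {
  p <- length(object@mle)
  if (!all(dim(object@covMle) == c(p, p)))
    return("covMle dimension must match mle length")
  if (max(abs(object@covMle - t(object@covMle))) > 1e-8)
    return("covMle must be symmetric")
  TRUE
})

#' ModelComparison: a Delta-BIC / Delta-AICc evidence table
#'
#' @slot table data.frame of converged models ordered by Delta-BIC with
#'   columns `model`, `k`, `loglik`, `BIC`, `AICc`, `dBIC`, `dAICc`,
#'   `equivalent` (Delta-BIC below the threshold).
#' @slot excluded data.frame of models dropped for non-convergence.
#' @slot nEffective sample size used in the criteria.
#' @slot threshold evidential equivalence threshold (2.77).
#'
#' @export
setClass("ModelComparison",
  representation(
    table      = "data.frame",
    excluded   = "data.frame",
    nEffective = "numeric",
    threshold  = "numeric"
  )
)

setValidity("ModelComparison", function(object) {
  tb <- object@table
  if (nrow(tb)) {
    if (min(tb$dBIC) > 1e-8) return("minimum Delta-BIC must be 0")
    if (any(tb$dBIC < -1e-8) || any(tb$dAICc < -1e-8))
      return("Delta values must be non-negative")
  }
  TRUE
})
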