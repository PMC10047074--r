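#' Specify a hierarchical fitness model
#'
#' The four families are: `"ri"` — individual instantaneous growth rate,
#' normal with mean `eta`, truncated below zero and censored above the
#' horizon bound; `"death"` — geometric years-survived model with log-odds
#' link `log((1-s)/s) = eta`, censored at the horizon; `"afr"` — negative
#' binomial (size 4) for age at first reproduction minus the minimum age at
#' maturity, link `log(4 (1-p)/p) = eta`; `"wait"` — geometric pupping
#' interval minus one, link `log((1-pi)/pi) = eta`, with a parallel-lines
#' first-interval term. `"gaussian"` is a plain normal linear model used
#' for engine validation.
#'
#' @param family one of `"ri"`, `"death"`, `"afr"`, `"wait"`, `"gaussian"`.
#' @param terms character subset of `c("INB", "COL", "INBxCOL", "FIRST")`;
#'   `INBxCOL` requires both `INB` and `COL`; `FIRST` only for the wait
#'   family.
#' @param yearIntercept,yearSlope include birth-year random intercepts
#'   `gamma_Y` and/or random slopes `theta_Y` on F.
#' @param leftTruncateDeath condition the death likelihood on survival to
#'   age 4 (off by default; the default mirrors pure censoring).
#' @return a `model_spec` list with the parameter count `kParams`
#'   (regression parameters, plus the residual SD for the ri family;
#'   random-effect parameters are not counted).
#' @export
modelSpec <- function(family = c("ri", "death", "afr", "wait", "gaussian"),
                      terms = character(),
                      yearIntercept = FALSE, yearSlope = FALSE,
                      leftTruncateDeath = FALSE) {
  family <- match.arg(family)
  ok <- c("INB", "COL", "INBxCOL", "FIRST")
  if (!all(terms %in% ok)) stop("unknown terms: ",
                                paste(setdiff(terms, ok), collapse = ", "))
  if ("INBxCOL" %in% terms && !all(c("INB", "COL") %in% terms))
    stop("INBxCOL requires INB and COL")
  if ("FIRST" %in% terms && family != "wait")
    stop("FIRST applies only to the wait family")
  if (yearSlope && !("INB" %in% terms))
    stop("a year random slope applies to the inbreeding coefficient")
  k <- 1 + length(terms) + (family == "ri")
  lab <- paste(c("b0", if (length(terms))
    paste0("b", match(terms, ok), c("INB", "COL", "INBxCOL",
                                    "FIRST")[match(terms, ok)])),
    collapse = "+")
  structure(list(family = family, terms = terms,
                 yearIntercept = yearIntercept, yearSlope = yearSlope,
                 leftTruncateDeath = leftTruncateDeath,
                 kParams = k, label = lab),
            class = "model_spec")
}

#' Prior set for the fitness models
#'
#' Defaults follow the study protocol: Normal(0, var 10^4) on every
#' regression coefficient, with the ri intercept truncated to (0, U) where
#' U is the growth-rate censoring bound; half-Cauchy(0, 0.013) on the ri
#' residual SD and half-Cauchy(0, 0.004) on the ri-family year-intercept
#' SD; Uniform(0, 100) on the year-effect SDs in the other families.
#'
#' @param betaVar prior variance of regression coefficients.
#' @param riInterceptBounds truncation interval for the ri intercept.
#' @param sigmaRScale,sigmaGammaScale half-Cauchy scales for the ri family.
#' @param sigmaGammaUpper,sigmaThetaUpper uniform upper bounds for the
#'   year-effect SDs in the non-ri families.
#' @return a `prior_set` list.
#' @export
priorSet <- function(betaVar = 10000,
                     riInterceptBounds = c(0, maxGrowthRateBound(19, 4)),
                     sigmaRScale = 0.013, sigmaGammaScale = 0.004,
                     sigmaGammaUpper = 100, sigmaThetaUpper = 100) {
  stopifnot(betaVar > 0, sigmaRScale > 0, sigmaGammaScale > 0)
  structure(list(betaVar = betaVar, riInterceptBounds = riInterceptBounds,
                 sigmaRScale = sigmaRScale,
                 sigmaGammaScale = sigmaGammaScale,
                 sigmaGammaUpper = sigmaGammaUpper,
                 sigmaThetaUpper = sigmaThetaUpper),
            class = "prior_set")
}

.betaNames <- function(spec) {
  if (spec$family == "gaussian") return(NULL)
  nm <- "b0"
  if ("INB" %in% spec$terms) nm <- c(nm, "b1")
  if ("COL" %in% spec$terms) nm <- c(nm, "b2")
  if ("INBxCOL" %in% spec$terms) nm <- c(nm, "b3")
  if ("FIRST" %in% spec$terms) nm <- c(nm, "b4")
  nm
}

#' Linear predictor of a fitness model
#'
#' `eta = b0 + (b1 + theta_Y) F + b2 col + b3 F col + b4 first + gamma_Y`,
#' with absent terms contributing zero.
#'
#' @param spec a [modelSpec()].
#' @param params named list/vector with elements `b0`..`b4` as required,
#'   and optionally named vectors `gamma` and `theta` indexed by year label.
#' @param F,col,first covariate values (vectorised).
#' @param year year label(s) when year effects are active.
#' @return numeric linear predictor.
#' @export
linearPredictor <- function(spec, params, F = 0, col = 0, first = 0,
                            year = NULL) {
  p <- as.list(params)
  gv <- function(nm) if (!is.null(p[[nm]])) p[[nm]] else 0
  th <- 0; ga <- 0
  if (spec$yearSlope || spec$yearIntercept) {
    if (is.null(year)) stop("year labels required when year effects active")
    if (spec$yearSlope) {
      th <- p$theta[as.character(year)]
      if (anyNA(th)) stop("unknown year label in theta")
    }
    if (spec$yearIntercept) {
      ga <- p$gamma[as.character(year)]
      if (anyNA(ga)) stop("unknown year label in gamma")
    }
  }
  gv("b0") + (gv("b1") + th) * F + gv("b2") * col + gv("b3") * F * col +
    gv("b4") * first + ga
}

#' Log-likelihood of the growth-rate model
#'
#' Normal density truncated below zero; observations at the censoring
#' bound `U` contribute the censored mass `P(Y >= U) / P(Y > 0)`.
#'
#' @param y responses in `[0, U]`.
#' @param mu,sigma normal mean and SD.
#' @param upper censoring bound U.
#' @param censored logical; if missing, `y >= upper - 1e-12` is used.
#' @return log-likelihood vector.
#' @export
loglikRi <- function(y, mu, sigma, upper = maxGrowthRateBound(19, 4),
                     censored = NULL) {
  stopifnot(sigma > 0)
  if (any(y < 0 | y > upper + 1e-12)) stop("y outside [0, upper]")
  if (is.null(censored)) censored <- y >= upper - 1e-12
  lnorm <- pnorm(mu / sigma, log.p = TRUE)
  out <- dnorm(y, mu, sigma, log = TRUE) - lnorm
  if (any(censored))
    out[censored] <- pnorm((mu - upper) / sigma, log.p = TRUE)[censored] -
      if (length(lnorm) > 1) lnorm[censored] else lnorm
  out
}

#' Log-likelihood of the survival (death-age) model
#'
#' Geometric years-survived model: death at age `d` contributes
#' `d log(s) + log(1-s)`; an individual alive at the horizon contributes
#' the survivor mass `horizon * log(s)`. The annual survival probability
#' comes from the log-odds link `s = 1/(1 + exp(eta))`.
#'
#' @param d death ages (4..horizon).
#' @param s annual survival probabilities in (0,1).
#' @param censored logical: alive at the horizon.
#' @param horizon study horizon.
#' @param leftTruncate condition on survival to age 4.
#' @return log-likelihood vector.
#' @export
loglikDeath <- function(d, s, censored = FALSE, horizon = 19,
                        leftTruncate = FALSE) {
  n <- max(length(d), length(s), length(censored))
  d <- rep_len(d, n); s <- rep_len(s, n); censored <- rep_len(censored, n)
  if (any(!censored & d < 4)) stop("death before age 4 is not observable")
  ll <- ifelse(censored, horizon * log(s), d * log(s) + log(1 - s))
  if (leftTruncate) ll <- ll - 4 * log(s)
  ll
}

#' Log-likelihood of the age-at-first-reproduction model
#'
#' Negative binomial with size 4 on `afr - 4`; `p` from the link
#' `4 (1 - p) / p = exp(eta)`.
#'
#' @param afr ages at first reproduction (>= 4).
#' @param p NB success probabilities.
#' @return log-likelihood vector.
#' @export
loglikAfr <- function(afr, p) {
  if (any(afr < 4)) stop("age at first reproduction below the minimum 4")
  k <- afr - 4
  lchoose(k + 3, k) + 4 * log(p) + k * log(1 - p)
}

#' Log-likelihood of the pupping-interval model
#'
#' Geometric on `wait - 1`; `pi` from the link `(1 - pi)/pi = exp(eta)`.
#'
#' @param w waits in years (>= 1).
#' @param piProb geometric success probabilities.
#' @return log-likelihood vector.
#' @export
loglikWait <- function(w, piProb) {
  if (any(w < 1)) stop("waits must be at least one year")
  (w - 1) * log(1 - piProb) + log(piProb)
}

#' Inverse links of the four families
#'
#' @param family model family.
#' @param eta linear predictor.
#' @return the family's probability/mean parameter: `mu` (ri), `s` (death),
#'   `p` (afr), `pi` (wait).
#' @export
inverseLink <- function(family, eta) {
  switch(family,
         ri = eta,
         gaussian = eta,
         death = 1 / (1 + exp(eta)),
         afr = 4 / (4 + exp(eta)),
         wait = 1 / (1 + exp(eta)),
         stop("unknown family"))
}

.halfCauchyLog <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + dcauchy(x, 0, scale, log = TRUE))
}

#' Joint log prior of a fitness model
#'
#' Normal(0, var `betaVar`) on each regression coefficient (the ri
#' intercept truncated to its bounds), half-Cauchy scales for the ri
#' family's SDs, Uniform(0, upper) for the other families' year-effect SDs,
#' Normal(0, sigma^2) on each year effect, and Beta(A_i, B_i) on each
#' latent F. Out-of-support values return `-Inf`.
#'
#' @param spec a [modelSpec()].
#' @param params named list: `b0`..`b4`, `sigmaR`, `sigmaGamma`,
#'   `sigmaTheta`, `gamma`, `theta`, `F`.
#' @param priors a [priorSet()].
#' @param A,B Beta measurement parameters matching `params$F`.
#' @return scalar log prior density.
#' @export
logPrior <- function(spec, params, priors = priorSet(), A = NULL, B = NULL) {
  p <- as.list(params)
  lp <- 0
  for (nm in .betaNames(spec)) {
    if (is.null(p[[nm]])) next
    v <- p[[nm]]
    if (spec$family == "ri" && nm == "b0" &&
        (v <= priors$riInterceptBounds[1] || v >= priors$riInterceptBounds[2]))
      return(-Inf)
    lp <- lp + dnorm(v, 0, sqrt(priors$betaVar), log = TRUE)
  }
  if (spec$family == "ri" && !is.null(p$sigmaR)) {
    hc <- .halfCauchyLog(p$sigmaR, priors$sigmaRScale)
    if (!is.finite(hc)) return(-Inf)
    lp <- lp + hc
  }
  if (spec$yearIntercept && !is.null(p$sigmaGamma)) {
    if (spec$family == "ri") {
      hc <- .halfCauchyLog(p$sigmaGamma, priors$sigmaGammaScale)
      if (!is.finite(hc)) return(-Inf)
      lp <- lp + hc
    } else {
      if (p$sigmaGamma <= 0 || p$sigmaGamma >= priors$sigmaGammaUpper)
        return(-Inf)
      lp <- lp - log(priors$sigmaGammaUpper)
    }
    if (!is.null(p$gamma))
      lp <- lp + sum(dnorm(p$gamma, 0, p$sigmaGamma, log = TRUE))
  }
  if (spec$yearSlope && !is.null(p$sigmaTheta)) {
    if (p$sigmaTheta <= 0 || p$sigmaTheta >= priors$sigmaThetaUpper)
      return(-Inf)
    lp <- lp - log(priors$sigmaThetaUpper)
    if (!is.null(p$theta))
      lp <- lp + sum(dnorm(p$theta, 0, p$sigmaTheta, log = TRUE))
  }
  if (!is.null(p$F)) {
    if (any(p$F <= 0 | p$F >= 1)) return(-Inf)
    lp <- lp + sum(dbeta(p$F, A, B, log = TRUE))
  }
  lp
}

#' Draw starting values per the per-family recipes
#'
#' ri family: `b0 ~ N(0.15, 0.0001)` redrawn into its truncation support,
#' slope coefficients `~ N(0, 0.01)`, `sigmaR = xi/chi` with
#' `xi ~ N(0.1, 0.000225)` and `chi ~ N(0.3, 0.36)`, and
#' `sigmaGamma = zeta/tau` with `zeta ~ N(0.002, 0.000025)`,
#' `tau ~ N(0.4, 0.36)`. Other families: coefficients `~ N(0, 1)`, year
#' effects `~ N(0, 1)`, SDs `~ Unif(0, 10)`. Values are redrawn until they
#' lie in the prior support.
#'
#' @param spec a [modelSpec()].
#' @param priors a [priorSet()].
#' @param nYears number of year levels (for year-effect starts).
#' @return named list of starting values.
#' @export
drawStartValues <- function(spec, priors = priorSet(), nYears = 0) {
  redraw <- function(draw, ok) {
    for (i in 1:1000) { v <- draw(); if (ok(v)) return(v) }
    stop("could not draw a starting value in the prior support")
  }
  nm <- .betaNames(spec)
  out <- list()
  if (spec$family == "ri") {
    bounds <- priors$riInterceptBounds
    out$b0 <- redraw(function() rnorm(1, 0.15, sqrt(0.0001)),
                     function(v) v > bounds[1] && v < bounds[2])
    for (b in setdiff(nm, "b0")) out[[b]] <- rnorm(1, 0, sqrt(0.01))
    out$sigmaR <- redraw(function()
      rnorm(1, 0.1, sqrt(0.000225)) / rnorm(1, 0.3, sqrt(0.36)),
      function(v) is.finite(v) && v > 0)
    if (spec$yearIntercept)
      out$sigmaGamma <- redraw(function()
        rnorm(1, 0.002, sqrt(0.000025)) / rnorm(1, 0.4, sqrt(0.36)),
        function(v) is.finite(v) && v > 0)
  } else {
    for (b in nm) out[[b]] <- rnorm(1, 0, 1)
    if (spec$yearIntercept)
      out$sigmaGamma <- runif(1, 0, 10)
    if (spec$yearSlope)
      out$sigmaTheta <- runif(1, 0, 10)
  }
  if (spec$yearIntercept) out$gamma <- rnorm(max(nYears, 0), 0, 1)
  if (spec$yearSlope) out$theta <- rnorm(max(nYears, 0), 0, 1)
  out
}

#' Natural-scale effect summaries of a fitted model
#'
#' Translates the fitted coefficients into the quantities practitioners
#' report: annual survival at F = 0, mean age at first reproduction and
#' mean wait at F = 0, multiplicative change in each mean per an increase
#' `deltaF` in the inbreeding coefficient (`exp(-b1 deltaF)` under the
#' log-odds links, since the linked quantity is the mean of the shifted
#' response), the first-interval wait multiplier `exp(b4)`, and for the ri
#' family the additive slope `b1 deltaF` with its Wald CI.
#'
#' @param fit a [DCFit-class].
#' @param deltaF increment of F to report effects over (default 0.0625,
#'   one first-cousin mating).
#' @return named list of natural-scale quantities.
#' @export
naturalScaleSummaries <- function(fit, deltaF = 0.0625) {
  est <- mle(fit)
  se <- sqrt(diag(covMle(fit)))
  fam <- fit@family
  b0 <- est[["b0"]]
  b1 <- if ("b1" %in% names(est)) est[["b1"]] else 0
  seB1 <- if ("b1" %in% names(est)) se[["b1"]] else 0
  z <- qnorm(0.975)
  out <- list(family = fam, deltaF = deltaF)
  ratio <- exp(b1 * deltaF)             # multiplicative change in the mean
  ratioCI <- exp((b1 + c(-z, z) * seB1) * deltaF)
  if (fam == "ri") {
    out$slope_per_deltaF <- b1 * deltaF
    out$slope_ci <- (b1 + c(-z, z) * seB1) * deltaF
    out$mu_at_0 <- b0
  } else if (fam == "death") {
    # mean years survived is s/(1-s) = exp(-eta), so the sign flips
    out$annual_survival_at_0 <- inverseLink("death", b0)
    out$mean_death_age_ratio <- exp(-b1 * deltaF)
    out$mean_death_age_ratio_ci <- sort(exp(-(b1 + c(-z, z) * seB1) * deltaF))
  } else if (fam == "afr") {
    out$mean_afr_at_0 <- 4 + exp(b0)
    out$mean_afr_ratio <- ratio
    out$mean_afr_ratio_ci <- ratioCI
  } else if (fam == "wait") {
    out$mean_wait_at_0 <- 1 + exp(b0)
    out$mean_wait_ratio <- ratio
    out$mean_wait_ratio_ci <- ratioCI
    if ("b4" %in% names(est)) {
      out$first_pup_multiplier <- exp(est[["b4"]])
      out$first_pup_multiplier_ci <-
        exp(est[["b4"]] + c(-z, z) * se[["b4"]])
      out$prob_repro_after_first <-
        inverseLink("wait", b0 + est[["b4"]])
      out$prob_repro_experienced <- inverseLink("wait", b0)
    }
  }
  out
}

#' Cost of inbreeding in lifetime reproductive success
#'
#' `delta(F) = -b1 F / b0 = 1 - mu(F)/mu(0)` for the linear growth-rate
#' model; `raw` keeps the sign, `delta` clamps negative costs at zero.
#'
#' @param beta0 intercept (mean growth rate of a non-inbred individual,
#'   must be positive).
#' @param beta1PerUnit slope per unit of F.
#' @param F inbreeding coefficient(s) to evaluate at.
#' @return data.frame with `F`, `raw`, `delta` and `relative_fitness`.
#' @export
costOfInbreeding <- function(beta0, beta1PerUnit, F) {
  stopifnot(beta0 > 0)
  raw <- -beta1PerUnit * F / beta0
  data.frame(F = F, raw = raw, delta = pmax(0, raw),
             relative_fitness = 1 - raw)
}
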