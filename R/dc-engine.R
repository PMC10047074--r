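#' MCMC configuration for the data-cloning engine
#'
#' @param chains number of independent chains.
#' @param iterations,burnIn,thin sweeps per chain, burn-in discarded, and
#'   thinning interval.
#' @param seed integer seed (required).
#' @param adaptUntil proposal adaptation cutoff (frozen afterwards to
#'   preserve detailed balance); defaults to the burn-in.
#' @return an `mcmc_config` list.
#' @export
mcmcConfig <- function(chains = 3, iterations = 20000, burnIn = 15000,
                       thin = 5, seed, adaptUntil = burnIn) {
  if (missing(seed)) stop("seed is required")
  stopifnot(burnIn < iterations, thin >= 1, adaptUntil <= burnIn)
  structure(list(chains = chains, iterations = iterations, burnIn = burnIn,
                 thin = thin, seed = as.integer(seed),
                 adaptUntil = adaptUntil),
            class = "mcmc_config")
}

# per-family chain-length defaults mirroring the study protocol
.defaultMcmc <- function(family, seed) {
  if (family == "afr")
    mcmcConfig(chains = 3, iterations = 10000, burnIn = 5000, thin = 5,
               seed = seed)
  else
    mcmcConfig(chains = 3, iterations = 20000, burnIn = 15000, thin = 5,
               seed = seed)
}

#' Clone a dataset
#'
#' Replicates the observation rows K times (adding a `clone` column).
#' Within the fitting engine the cloning is carried implicitly:
#' observations and per-observation latent variables (F, year-effect
#' occupancy) are replicated while structural parameters remain single
#' copies.
#'
#' @param data a data.frame of observations.
#' @param K number of copies (>= 1).
#' @return data.frame with `nrow(data) * K` rows.
#' @export
cloneDataset <- function(data, K) {
  if (K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  out <- data[rep(seq_len(nrow(data)), K), , drop = FALSE]
  out$clone <- rep(seq_len(K), each = nrow(data))
  rownames(out) <- NULL
  out
}

.familyCode <- function(family)
  match(family, c("gaussian", "ri", "death", "afr", "wait")) - 1L

# assemble the internal model-data list shared by the sampler and the
# marginal likelihood
.buildModelData <- function(spec, data, betaParams = NULL,
                            horizon = 19, upper = NULL) {
  fam <- spec$family
  if (fam == "gaussian") {
    y <- data$y
    X <- as.matrix(data$X)
    return(list(family = .familyCode(fam), y = as.numeric(y),
                cens = integer(length(y)), col = numeric(length(y)),
                first = numeric(length(y)),
                year = rep(-1L, length(y)), ind = rep(0L, length(y)),
                A = 1, B = 1, X = X, U = Inf, horizon = horizon,
                sigmaFixed = if (is.null(data$sigma)) NA_real_ else
                  data$sigma,
                startSd = if (is.null(data$startSd)) 1 else data$startSd,
                nYears = 0L, yearLevels = character(), ids = NULL))
  }
  if (is.null(upper)) upper <- maxGrowthRateBound(horizon, 4)
  ids <- unique(data$id)
  ind <- match(data$id, ids) - 1L
  useYear <- spec$yearIntercept || spec$yearSlope
  yearLevels <- if (useYear) sort(unique(data$year)) else numeric()
  year <- if (useYear) match(data$year, yearLevels) - 1L else
    rep(-1L, nrow(data))
  hasINB <- "INB" %in% spec$terms
  if (hasINB) {
    if (is.null(betaParams))
      stop("betaParams (id, A, B) required for models with an INB term")
    m <- match(ids, betaParams$id)
    if (anyNA(m)) stop("betaParams missing individuals: ",
                       paste(ids[is.na(m)], collapse = ", "))
    A <- betaParams$A[m]; B <- betaParams$B[m]
  } else {
    A <- rep(1, length(ids)); B <- rep(1, length(ids))
  }
  y <- switch(fam, ri = data$ri, death = data$age, afr = data$afr,
              wait = data$wait)
  cens <- switch(fam,
                 ri = if (!is.null(data$censored_at_max))
                   as.integer(data$censored_at_max) else
                     as.integer(y >= upper - 1e-9),
                 death = as.integer(data$censored),
                 afr = integer(nrow(data)),
                 wait = integer(nrow(data)))
  list(family = .familyCode(fam), y = as.numeric(y), cens = cens,
       col = as.numeric(data$col),
       first = if (!is.null(data$first)) as.numeric(data$first) else
         numeric(nrow(data)),
       year = as.integer(year), ind = as.integer(ind),
       A = as.numeric(A), B = as.numeric(B),
       X = matrix(0, 0, 0), U = upper, horizon = horizon,
       sigmaFixed = NA_real_, nYears = length(yearLevels),
       yearLevels = yearLevels, ids = ids)
}

.specFlags <- function(spec) {
  list(hasINB = as.integer("INB" %in% spec$terms),
       hasCOL = as.integer("COL" %in% spec$terms),
       hasINT = as.integer("INBxCOL" %in% spec$terms),
       hasFIRST = as.integer("FIRST" %in% spec$terms),
       yearIcpt = as.integer(spec$yearIntercept),
       yearSlope = as.integer(spec$yearSlope),
       leftTrunc = as.integer(isTRUE(spec$leftTruncateDeath)))
}

.priorList <- function(spec, priors) {
  isRi <- spec$family == "ri"
  list(betaVar = priors$betaVar,
       b0Lower = if (isRi) priors$riInterceptBounds[1] else -Inf,
       b0Upper = if (isRi) priors$riInterceptBounds[2] else Inf,
       sigmaRScale = priors$sigmaRScale,
       sigmaGammaType = if (isRi) "hc" else "unif",
       sigmaGammaScale = priors$sigmaGammaScale,
       sigmaGammaUpper = priors$sigmaGammaUpper,
       sigmaThetaUpper = priors$sigmaThetaUpper)
}

.paramNames <- function(spec, md) {
  if (spec$family == "gaussian") {
    nm <- paste0("b", seq_len(ncol(md$X)) - 1)
    if (!is.finite(md$sigmaFixed)) nm <- c(nm, "sigmaR")
  } else {
    nm <- .betaNames(spec)
    if (spec$family == "ri") nm <- c(nm, "sigmaR")
    if (spec$yearIntercept) nm <- c(nm, "sigmaGamma")
    if (spec$yearSlope) nm <- c(nm, "sigmaTheta")
  }
  nm
}

# start-value list -> init list for the C++ sampler
.initList <- function(spec, md, start) {
  if (spec$family == "gaussian") {
    p <- ncol(md$X)
    beta <- if (!is.null(start$beta)) start$beta else
      rnorm(p, 0, md$startSd)
    return(list(beta = beta,
                sigmaR = if (!is.null(start$sigmaR)) start$sigmaR else
                  runif(1, 0.5, 2),
                sigmaGamma = 1, sigmaTheta = 1,
                gamma = numeric(0), theta = numeric(0),
                F = rep(0.5, length(md$A))))
  }
  beta <- vapply(.betaNames(spec), function(nm) start[[nm]], numeric(1))
  list(beta = as.numeric(beta),
       sigmaR = if (!is.null(start$sigmaR)) start$sigmaR else 1,
       sigmaGamma = if (!is.null(start$sigmaGamma)) start$sigmaGamma else 1,
       sigmaTheta = if (!is.null(start$sigmaTheta)) start$sigmaTheta else 1,
       gamma = if (!is.null(start$gamma)) start$gamma else
         numeric(md$nYears),
       theta = if (!is.null(start$theta)) start$theta else
         numeric(md$nYears),
       F = md$A / (md$A + md$B))
}

# total data log-likelihood at a parameter list (latents at their means);
# used to verify a finite starting point
.startLoglik <- function(spec, md, init) {
  eta <- .etaAt(spec, md, init$beta, F = init$F[md$ind + 1],
                gamma = if (md$nYears) init$gamma else NULL,
                theta = if (md$nYears) init$theta else NULL)
  sig <- if (!is.na(md$sigmaFixed)) md$sigmaFixed else init$sigmaR
  sum(obs_loglik_cpp(md$family, md$y, md$cens, eta,
                     if (is.null(sig) || !is.finite(sig)) 1 else sig,
                     md$U, md$horizon,
                     as.integer(isTRUE(spec$leftTruncateDeath))))
}

# linear predictor for the internal data list
.etaAt <- function(spec, md, beta, F = 0, gamma = NULL, theta = NULL) {
  if (spec$family == "gaussian") return(as.numeric(md$X %*% beta))
  nm <- .betaNames(spec)
  b <- setNames(beta, nm)
  th <- if (!is.null(theta) && md$nYears) theta[md$year + 1] else 0
  ga <- if (!is.null(gamma) && md$nYears) gamma[md$year + 1] else 0
  eta <- b[["b0"]] + ga
  if ("b1" %in% nm) eta <- eta + (b[["b1"]] + th) * F
  else if (any(th != 0)) eta <- eta + th * F
  if ("b2" %in% nm) eta <- eta + b[["b2"]] * md$col
  if ("b3" %in% nm) eta <- eta + b[["b3"]] * F * md$col
  if ("b4" %in% nm) eta <- eta + b[["b4"]] * md$first
  rep_len(as.numeric(eta), length(md$y))
}

#' Run MCMC chains for one clone count
#'
#' Adaptive Metropolis-within-Gibbs over the structural parameters and the
#' cloned latent blocks; proposal scales adapt toward 20-50 percent
#' acceptance during burn-in and are frozen afterwards. Starting values
#' follow [drawStartValues()]; a non-finite starting likelihood triggers a
#' redraw (up to 10 attempts).
#'
#' @param spec a [modelSpec()].
#' @param data observation data.frame (see [dcFit()]).
#' @param K clone count.
#' @param betaParams step-one Beta parameters (id, A, B) when the model
#'   has an INB term.
#' @param priors a [priorSet()].
#' @param mcmc an [mcmcConfig()].
#' @param horizon study horizon.
#' @return list of per-chain draw matrices (named columns).
#' @export
runChains <- function(spec, data, K = 1, betaParams = NULL,
                      priors = priorSet(), mcmc, horizon = 19) {
  md <- .buildModelData(spec, data, betaParams, horizon = horizon)
  pn <- .paramNames(spec, md)
  pl <- .priorList(spec, priors)
  fl <- .specFlags(spec)
  out <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 31L * K + 7907L * ch)
    init <- NULL
    for (attempt in 1:10) {
      start <- if (spec$family == "gaussian") list() else
        drawStartValues(spec, priors, nYears = md$nYears)
      cand <- .initList(spec, md, start)
      if (is.finite(.startLoglik(spec, md, cand))) { init <- cand; break }
    }
    if (is.null(init))
      stop("could not find a finite starting point in 10 attempts")
    res <- mwg_chain(md, fl, pl, init,
                     list(K = as.integer(K), nIter = mcmc$iterations,
                          burn = mcmc$burnIn, thin = mcmc$thin,
                          adaptUntil = mcmc$adaptUntil))
    dr <- res$draws
    colnames(dr) <- pn
    out[[ch]] <- dr
  }
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' @param chains list of numeric vectors (one parameter) or matrices with
#'   identical named columns (several parameters), at least two chains of
#'   at least 10 draws.
#' @return scalar or named per-parameter vector.
#' @export
gelmanRubin <- function(chains) {
  if (is.matrix(chains[[1]])) {
    return(vapply(seq_len(ncol(chains[[1]])), function(j)
      gelmanRubin(lapply(chains, function(m) m[, j])),
      numeric(1)) |> setNames(colnames(chains[[1]])))
  }
  m <- length(chains)
  if (m < 2) stop("at least two chains are required")
  n <- length(chains[[1]])
  if (n < 10) stop("chains must have at least 10 draws")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# dclone-style normal-approximation diagnostics on pooled draws
.dcDiagnostics <- function(draws) {
  p <- ncol(draws)
  ms <- numeric(p); r2 <- numeric(p)
  for (j in seq_len(p)) {
    x <- draws[, j]
    s <- sd(x)
    if (s < 1e-300) { ms[j] <- 0; r2[j] <- 1; next }
    z <- sort((x - mean(x)) / s)
    q <- qnorm(stats::ppoints(length(z)))
    ms[j] <- mean((z - q)^2)
    r2[j] <- cor(z, q)^2
  }
  list(ms_error = mean(ms), r_squared = mean(r2))
}

#' Data-cloned maximum-likelihood fit
#'
#' Runs [runChains()] at each clone count of the schedule; the MLE is the
#' posterior mean at the largest count and its covariance is K_max times
#' the posterior covariance there. Convergence of the cloning requires the
#' final mean scaled posterior variance (relative to the first level) to
#' fall below 0.05 and every R-hat below 1.1; non-convergence is a
#' reported state, not an error.
#'
#' @inheritParams runChains
#' @param schedule increasing clone counts starting at 1 (single-level
#'   schedules skip the scaled-variance rule).
#' @param level Wald confidence level.
#' @return a [DCFit-class].
#' @export
dcFit <- function(spec, data, betaParams = NULL, priors = priorSet(),
                  mcmc = NULL, schedule = c(1, 5, 10, 20, 40),
                  horizon = 19, level = 0.95) {
  stopifnot(all(diff(schedule) > 0))
  if (is.null(mcmc)) stop("an mcmcConfig (with a seed) is required")
  md <- .buildModelData(spec, data, betaParams, horizon = horizon)
  perK <- list()
  varByK <- NULL
  finalChains <- NULL
  for (K in schedule) {
    ch <- runChains(spec, data, K, betaParams, priors, mcmc, horizon)
    pooled <- do.call(rbind, ch)
    perK[[as.character(K)]] <- list(K = K, mean = colMeans(pooled),
                                    cov = stats::cov(pooled))
    varByK <- rbind(varByK, diag(stats::cov(pooled)))
    if (K == schedule[length(schedule)]) finalChains <- ch
  }
  Kmax <- schedule[length(schedule)]
  pooled <- do.call(rbind, finalChains)
  est <- colMeans(pooled)
  covP <- stats::cov(pooled)
  covM <- Kmax * covP
  covM <- (covM + t(covM)) / 2
  rhat <- gelmanRubin(finalChains)

  scaled <- sweep(varByK, 2, varByK[1, ], "/")
  scaledMean <- rowMeans(scaled)
  finalScaled <- if (length(schedule) > 1) scaledMean[length(schedule)] else
    NA_real_
  slope <- if (length(schedule) > 1)
    unname(stats::coef(stats::lm(log(scaledMean) ~ log(schedule)))[2]) else
      NA_real_
  diag2 <- .dcDiagnostics(pooled)
  diagnostics <- list(
    lambda_max = max(eigen(covM, symmetric = TRUE,
                           only.values = TRUE)$values),
    ms_error = diag2$ms_error, r_squared = diag2$r_squared,
    scaled_var_by_K = data.frame(K = schedule, scaled_var = scaledMean),
    final_scaled_var = finalScaled,
    slope_log_var_log_K = slope)
  converged <- all(rhat < 1.1) &&
    (is.na(finalScaled) || finalScaled < 0.05)
  z <- qnorm((1 + level) / 2)
  wci <- cbind(lower = est - z * sqrt(diag(covM)),
               upper = est + z * sqrt(diag(covM)))
  nEff <- if (spec$family == "gaussian") length(md$y) else
    if (spec$family == "wait") length(md$y) else length(unique(md$ind))
  new("DCFit", family = spec$family, spec = unclass(spec),
      cloneSchedule = as.numeric(schedule), mle = est, covMle = covM,
      waldCI = wci, rhat = rhat, diagnostics = diagnostics,
      converged = converged, draws = pooled, perK = perK, data = md,
      n = nEff)
}

#' Wald confidence intervals of a converged fit
#'
#' `mle +/- z * sqrt(diag(covMle))`.
#'
#' @param fit a [DCFit-class].
#' @param level confidence level.
#' @param force return intervals even when the cloning did not converge.
#' @return matrix (parameters x lower/upper).
#' @export
waldCI <- function(fit, level = 0.95, force = FALSE) {
  if (!isConverged(fit) && !force)
    stop("fit did not converge under data cloning; Wald intervals would ",
         "not be trustworthy (use force = TRUE to override)")
  z <- qnorm((1 + level) / 2)
  se <- sqrt(diag(covMle(fit)))
  cbind(lower = mle(fit) - z * se, upper = mle(fit) + z * se)
}

# nearest-PSD repair by eigenvalue clipping
.nearestPSD <- function(S, eps = 1e-12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (all(e$values >= 0)) return((S + t(S)) / 2)
  warning("covariance repaired to nearest positive semidefinite matrix")
  v <- pmax(e$values, eps)
  e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
}

# mean response on the natural scale for band construction
.meanResponse <- function(family, eta) {
  switch(family,
         ri = eta, gaussian = eta,
         death = exp(-eta),        # mean years survived s/(1-s)
         afr = 4 + exp(eta),       # mean age at first reproduction
         wait = 1 + exp(eta))      # mean pupping interval
}

#' Pointwise confidence band for the fitted mean response
#'
#' Draws coefficient vectors from MVN(mle, covMle) and returns the 2.5 and
#' 97.5 percent quantiles of the fitted mean response over a grid of
#' inbreeding coefficients (reference individual: col = 0, first = 0).
#'
#' @param fit a [DCFit-class].
#' @param grid inbreeding-coefficient grid (default 1000 equally spaced
#'   points on (0, 0.25)).
#' @param draws number of multivariate-normal draws.
#' @param seed integer seed.
#' @param level band level.
#' @return data.frame `F`, `fit`, `lower`, `upper`.
#' @export
confidenceBand <- function(fit, grid = defaultFGrid(), draws = 10000, seed,
                           level = 0.95) {
  if (!isConverged(fit))
    stop("confidence bands require a converged fit")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  S <- .nearestPSD(covMle(fit))
  th <- MASS::mvrnorm(draws, mle(fit), S)
  b1col <- function(mat, nm) if (nm %in% colnames(mat)) mat[, nm] else 0
  alpha <- (1 - level) / 2
  eta0 <- b1col(th, "b0")
  sl <- b1col(th, "b1")
  est <- mle(fit)
  out <- lapply(grid, function(f) {
    eta <- eta0 + sl * f
    m <- .meanResponse(fit@family, eta)
    q <- quantile(m, c(alpha, 1 - alpha), names = FALSE)
    fitted <- .meanResponse(fit@family,
                            est[["b0"]] +
                              (if ("b1" %in% names(est)) est[["b1"]] else 0) * f)
    data.frame(F = f, fit = fitted, lower = q[1], upper = q[2])
  })
  do.call(rbind, out)
}

#' Default inbreeding-coefficient grid
#'
#' 1000 equally spaced values in the open interval (0, 0.25), the span of
#' the data-cloned estimates in the study design.
#'
#' @param n number of points.
#' @param upper interval upper end.
#' @return numeric vector of length `n`.
#' @export
defaultFGrid <- function(n = 1000, upper = 0.25) {
  seq(0, upper, length.out = n + 2)[2:(n + 1)]
}

# simulate one response per coefficient draw at inbreeding coefficient f
.simResponse <- function(family, eta, sigmaR, U, horizon) {
  n <- length(eta)
  switch(family,
         ri = {
           plo <- pnorm((0 - eta) / sigmaR)
           u <- runif(n, plo, 1)
           y <- eta + sigmaR * qnorm(u)
           pmin(y, U)
         },
         gaussian = rnorm(n, eta, sigmaR),
         death = {
           s <- 1 / (1 + exp(eta))
           pmin(rgeom(n, 1 - s), horizon)
         },
         afr = 4 + rnbinom(n, size = 4, prob = 4 / (4 + exp(eta))),
         wait = 1 + rgeom(n, 1 / (1 + exp(eta))))
}

#' Pointwise prediction band for new responses
#'
#' Simulates new responses from the fitted family at each grid value of
#' the inbreeding coefficient, with coefficient uncertainty propagated by
#' MVN(mle, covMle) draws; returns pointwise 2.5/97.5 percent quantiles.
#' The growth-rate family respects its censoring bound.
#'
#' @inheritParams confidenceBand
#' @param mcmc an [mcmcConfig()]; the number of simulation draws per grid
#'   point is the config's saved-draw count (default single chain of
#'   10,000 iterations, burn-in 5,000, thin 5: 1,000 draws).
#' @return data.frame `F`, `lower`, `upper`.
#' @export
predictionBand <- function(fit, grid = defaultFGrid(), mcmc = NULL, seed,
                           level = 0.95) {
  if (!isConverged(fit))
    stop("prediction bands require a converged fit")
  if (missing(seed)) stop("seed is required")
  if (is.null(mcmc))
    mcmc <- mcmcConfig(chains = 1, iterations = 10000, burnIn = 5000,
                       thin = 5, seed = seed)
  nDraw <- ceiling((mcmc$iterations - mcmc$burnIn) / mcmc$thin) * mcmc$chains
  set.seed(seed)
  S <- .nearestPSD(covMle(fit))
  th <- MASS::mvrnorm(nDraw, mle(fit), S)
  alpha <- (1 - level) / 2
  b1col <- function(nm) if (nm %in% colnames(th)) th[, nm] else 0
  eta0 <- b1col("b0"); sl <- b1col("b1")
  sR <- if ("sigmaR" %in% colnames(th)) abs(th[, "sigmaR"]) else
    rep(1, nDraw)
  out <- lapply(grid, function(f) {
    eta <- eta0 + sl * f
    y <- .simResponse(fit@family, eta, sR, fit@data$U, fit@data$horizon)
    q <- quantile(y, c(alpha, 1 - alpha), names = FALSE)
    data.frame(F = f, lower = q[1], upper = q[2])
  })
  do.call(rbind, out)
}
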