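# log(sum(w * exp(ll))) by column, stable
.logSumExpW <- function(llMat, w) {
  m <- apply(llMat, 1, max)
  m + log(as.numeric(exp(llMat - m) %*% w))
}

# per-individual log integral over F ~ Beta(A, B) of the data likelihood,
# at fixed (gamma, theta) offsets. Gauss-Legendre on a per-individual
# window [qbeta(1e-12), qbeta(1 - 1e-12)]: the integrand is smooth there
# (Beta density times likelihood), so convergence is spectral, and the
# excluded tail mass is O(1e-12) even for near-degenerate Betas.
.margOverF <- function(spec, md, beta, sigma, nodes, gammaOff = 0,
                       thetaOff = 0, obsKeep = NULL) {
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  keep <- if (is.null(obsKeep)) seq_along(md$y) else obsKeep
  indKeep <- md$ind[keep] + 1
  uind <- sort(unique(indKeep))
  lo <- qbeta(1e-12, md$A, md$B)
  hi <- qbeta(1e-12, md$A, md$B, lower.tail = FALSE)
  llMat <- matrix(0, length(uind), nodes)
  logw <- matrix(0, length(uind), nodes)
  for (q in seq_len(nodes)) {
    Fq <- lo + (hi - lo) * gl$x[q]
    logw[, q] <- dbeta(Fq[uind], md$A[uind], md$B[uind], log = TRUE) +
      log(hi - lo)[uind]
    FqObs <- Fq[indKeep]
    nm <- .betaNames(spec)
    b <- setNames(beta, nm)
    eta <- b[["b0"]] + gammaOff
    if ("b1" %in% nm) eta <- eta + (b[["b1"]] + thetaOff) * FqObs
    if ("b2" %in% nm) eta <- eta + b[["b2"]] * md$col[keep]
    if ("b3" %in% nm) eta <- eta + b[["b3"]] * FqObs * md$col[keep]
    if ("b4" %in% nm) eta <- eta + b[["b4"]] * md$first[keep]
    eta <- rep_len(as.numeric(eta), length(keep))
    ll <- obs_loglik_cpp(md$family, md$y[keep], md$cens[keep], eta, sigma,
                         md$U, md$horizon,
                         as.integer(isTRUE(spec$leftTruncateDeath)))
    llMat[, q] <- rowsum(ll, indKeep)[as.character(uind), 1]
  }
  setNames(.logSumExpW(llMat + logw, gl$w), uind)
}

#' Marginal log-likelihood with latent quantities integrated out
#'
#' Integrates each individual's latent inbreeding coefficient over its
#' Beta(A, B) measurement distribution by adaptive Gauss-Legendre
#' quadrature (node count doubled from `nodes` until the per-individual
#' relative change falls below `tol`), and integrates birth-year random
#' effects by a per-year Laplace approximation (the likelihood factorises
#' across years), with an importance-sampling validator.
#'
#' @param fit a [DCFit-class] (or pass `spec`, `data`, `betaParams`
#'   explicitly through [dcFit()]'s internals).
#' @param params parameter vector (default the MLE).
#' @param nodes starting quadrature node count (>= 64 effective via
#'   doubling schedule 64/128/256/512).
#' @param tol relative-change tolerance on node doubling.
#' @param method `"laplace"` or `"is"` (importance sampling) for the
#'   year-effect integral.
#' @param isDraws importance-sampling draws per year when `method = "is"`.
#' @return scalar marginal log-likelihood.
#' @export
marginalLoglik <- function(fit, params = mle(fit), nodes = 64, tol = 1e-6,
                           method = c("laplace", "is"), isDraws = 2000) {
  method <- match.arg(method)
  spec <- structure(fit@spec, class = "model_spec")
  md <- fit@data
  nm <- .paramNames(spec, md)
  params <- setNames(as.numeric(params), nm)
  if (spec$family == "gaussian") {
    eta <- as.numeric(md$X %*% params[seq_len(ncol(md$X))])
    sig <- if (is.finite(md$sigmaFixed)) md$sigmaFixed else
      params[["sigmaR"]]
    return(sum(obs_loglik_cpp(md$family, md$y, md$cens, eta, sig, md$U,
                              md$horizon, 0L)))
  }
  bn <- .betaNames(spec)
  beta <- params[bn]
  sigma <- if (spec$family == "ri") params[["sigmaR"]] else 1
  hasINB <- "INB" %in% spec$terms
  useYear <- spec$yearIntercept || spec$yearSlope

  if (!hasINB && !useYear) {
    eta <- .etaAt(spec, md, beta)
    return(sum(obs_loglik_cpp(md$family, md$y, md$cens, eta, sigma, md$U,
                              md$horizon,
                              as.integer(isTRUE(spec$leftTruncateDeath)))))
  }

  margAtNodes <- function(nn, gammaOff = 0, thetaOff = 0, obsKeep = NULL) {
    if (!hasINB) {
      keep <- if (is.null(obsKeep)) seq_along(md$y) else obsKeep
      eta <- .etaAt(spec, md, beta)[keep] + gammaOff
      ll <- obs_loglik_cpp(md$family, md$y[keep], md$cens[keep], eta,
                           sigma, md$U, md$horizon,
                           as.integer(isTRUE(spec$leftTruncateDeath)))
      return(rowsum(ll, md$ind[keep] + 1)[, 1])
    }
    .margOverF(spec, md, beta, sigma, nn, gammaOff, thetaOff, obsKeep)
  }

  adaptiveMarg <- function(gammaOff = 0, thetaOff = 0, obsKeep = NULL) {
    if (!hasINB) return(margAtNodes(64, gammaOff, thetaOff, obsKeep))
    prev <- margAtNodes(nodes, gammaOff, thetaOff, obsKeep)
    for (nn in nodes * c(2, 4, 8)) {
      cur <- margAtNodes(nn, gammaOff, thetaOff, obsKeep)
      rel <- abs(cur - prev) / pmax(abs(prev), 1)
      if (max(rel) <= tol) return(cur)
      prev <- cur
    }
    worst <- names(prev)[which.max(abs(cur - prev))]
    stop("quadrature did not converge for individual index ", worst)
  }

  if (!useYear) return(sum(adaptiveMarg()))

  # factorise across birth years; Laplace (or IS) per year block
  sigmaG <- if (spec$yearIntercept) params[["sigmaGamma"]] else NA_real_
  sigmaT <- if (spec$yearSlope) params[["sigmaTheta"]] else NA_real_
  total <- 0
  lt <- as.integer(isTRUE(spec$leftTruncateDeath))
  for (yy in seq_len(md$nYears) - 1L) {
    obsY <- which(md$year == yy)
    if (!length(obsY)) next
    dim2 <- spec$yearIntercept + spec$yearSlope
    # precompute the F-node grid and base predictor for this year once;
    # each h(gamma, theta) evaluation is then a single vectorised
    # likelihood call. Adaptivity of the node count is verified at the
    # mode below.
    nn <- 2 * nodes
    indY <- md$ind[obsY] + 1
    uind <- sort(unique(indY))
    if (hasINB) {
      gl <- pracma::gaussLegendre(nn, 0, 1)
      lo <- qbeta(1e-12, md$A[uind], md$B[uind])
      hi <- qbeta(1e-12, md$A[uind], md$B[uind], lower.tail = FALSE)
      Fnode <- outer(lo, gl$x * 0, "+") +
        outer(hi - lo, gl$x)                     # |uind| x nn
      logw <- dbeta(Fnode, md$A[uind], md$B[uind], log = TRUE) +
        log(hi - lo)
      rowOf <- match(indY, uind)
      FqObs <- Fnode[rowOf, , drop = FALSE]      # |obsY| x nn
      bn <- .betaNames(spec)
      b <- setNames(beta, bn)
      etaBase <- b[["b0"]] + b[["b1"]] * FqObs
      if ("b2" %in% bn) etaBase <- etaBase + b[["b2"]] * md$col[obsY]
      if ("b3" %in% bn) etaBase <- etaBase + b[["b3"]] * FqObs * md$col[obsY]
      if ("b4" %in% bn) etaBase <- etaBase + b[["b4"]] * md$first[obsY]
      yRep <- rep(md$y[obsY], nn)
      cRep <- rep(md$cens[obsY], nn)
      blockMarg <- function(g, t) {
        eta <- etaBase + g + t * FqObs
        ll <- obs_loglik_cpp(md$family, yRep, cRep, as.numeric(eta),
                             sigma, md$U, md$horizon, lt)
        llMat <- rowsum(matrix(ll, nrow = length(obsY)), rowOf)
        sum(.logSumExpW(llMat + logw, gl$w))
      }
    } else {
      eta0 <- .etaAt(spec, md, beta)[obsY]
      blockMarg <- function(g, t)
        sum(obs_loglik_cpp(md$family, md$y[obsY], md$cens[obsY],
                           eta0 + g, sigma, md$U, md$horizon, lt))
    }
    h <- function(v) {
      g <- 0; t <- 0; j <- 1
      if (spec$yearIntercept) { g <- v[j]; j <- j + 1 }
      if (spec$yearSlope) t <- v[j]
      lp <- 0
      if (spec$yearIntercept) lp <- lp + dnorm(g, 0, sigmaG, log = TRUE)
      if (spec$yearSlope) lp <- lp + dnorm(t, 0, sigmaT, log = TRUE)
      blockMarg(g, t) + lp
    }
    opt <- optim(rep(0, dim2), function(v) -h(v), method = "BFGS",
                 hessian = TRUE)
    # quadrature-convergence contract, checked at the mode
    invisible(adaptiveMarg(
      gammaOff = if (spec$yearIntercept) opt$par[1] else 0,
      thetaOff = if (spec$yearSlope) opt$par[dim2] else 0,
      obsKeep = obsY))
    H <- opt$hessian  # of -h: positive definite at the mode
    if (method == "laplace") {
      ld <- determinant(H, logarithm = TRUE)$modulus
      total <- total - opt$value + dim2 / 2 * log(2 * pi) - 0.5 * ld
    } else {
      Sg <- .nearestPSD(solve(H)) * 1.5^2
      vs <- MASS::mvrnorm(isDraws, opt$par, Sg)
      if (dim2 == 1) vs <- matrix(vs, ncol = 1)
      lw <- apply(vs, 1, h) -
        apply(vs, 1, function(v)
          -0.5 * determinant(2 * pi * Sg, TRUE)$modulus -
            0.5 * as.numeric(t(v - opt$par) %*% solve(Sg) %*% (v - opt$par)))
      mlw <- max(lw)
      total <- total + mlw + log(mean(exp(lw - mlw)))
    }
  }
  total
}
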