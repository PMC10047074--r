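U <- maxGrowthRateBound(19, 4)

test_that("the linear predictor assembles active terms only", {
  sp0 <- modelSpec("ri")
  expect_equal(linearPredictor(sp0, list(b0 = 0.2)), 0.2)
  sp <- modelSpec("ri", terms = c("INB", "COL", "INBxCOL"))
  expect_equal(linearPredictor(sp, list(b0 = 0.2, b1 = -0.1, b2 = 0.05,
                                        b3 = 0), F = 0.25, col = 1),
               0.2 - 0.025 + 0.05)
  expect_equal(linearPredictor(sp, list(b0 = 0.2, b1 = 7, b2 = 0, b3 = 2),
                               F = 0, col = 1), 0.2)
})

test_that("growth-rate likelihood: density, censoring mass, and
           normalisation", {
  expect_equal(loglikRi(0.2, 0.2, 0.05), log(dnorm(0) / 0.05),
               tolerance = 1e-4)  # truncation factor ~ 1 when mu >> 0
  expect_lte(loglikRi(U, 0.3, 0.05), 0)  # a log-probability, not density
  mu <- 0.05; s <- 0.08
  dens <- integrate(function(y)
    exp(vapply(y, function(yy) loglikRi(yy, mu, s), numeric(1))),
    0, U - 1e-9, rel.tol = 1e-10)$value
  mass <- exp(loglikRi(U, mu, s))
  expect_equal(dens + mass, 1, tolerance = 1e-8)
  expect_error(loglikRi(-0.1, 0.1, 0.05), "outside")
})

test_that("survival likelihood and link round-trip", {
  expect_equal(loglikDeath(10, 0.945), 10 * log(0.945) + log(0.055))
  expect_equal(loglikDeath(19, 0.945, censored = TRUE), 19 * log(0.945))
  eta <- log(0.055 / 0.945)
  expect_equal(inverseLink("death", eta), 0.945)
  expect_error(loglikDeath(3, 0.9), "age 4")
  # normalisation over the full geometric support (the censored model
  # keeps mass below age 4; only the data are restricted to [4, 19])
  s <- 0.91
  tot <- sum(s^(0:3) * (1 - s)) +
    sum(exp(vapply(4:18, function(d) loglikDeath(d, s, horizon = 19),
                   numeric(1)))) +
    exp(loglikDeath(19, s, censored = TRUE, horizon = 19))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("age-at-first-reproduction likelihood and link round-trip", {
  expect_equal(loglikAfr(4, 0.5), log(0.5^4))
  eta <- log(3.39)
  p <- inverseLink("afr", eta)
  expect_equal(4 + 4 * (1 - p) / p, 7.39, tolerance = 1e-12)
  p2 <- 0.3
  tot <- sum(exp(loglikAfr(4:204, p2)))
  expect_equal(tot, 1, tolerance = 1e-10)
  expect_error(loglikAfr(3, 0.5), "minimum")
})

test_that("pupping-interval likelihood and link round-trip", {
  expect_equal(loglikWait(1, 0.7), log(0.7))
  piProb <- 0.548
  expect_equal(1 + (1 - piProb) / piProb, 1.8248, tolerance = 1e-4)
  expect_equal(inverseLink("wait", log((1 - piProb) / piProb)), piProb)
  tot <- sum(exp(loglikWait(1:500, 0.3)))
  expect_equal(tot, 1, tolerance = 1e-10)
  expect_error(loglikWait(0, 0.5), "at least one")
})

test_that("all four inverse links round-trip their forward links", {
  for (eta in c(-3, -0.5, 0, 0.7, 2)) {
    expect_equal(inverseLink("ri", eta), eta)
    s <- inverseLink("death", eta)
    expect_equal(log((1 - s) / s), eta, tolerance = 1e-12)
    p <- inverseLink("afr", eta)
    expect_equal(log(4 * (1 - p) / p), eta, tolerance = 1e-12)
    pi <- inverseLink("wait", eta)
    expect_equal(log((1 - pi) / pi), eta, tolerance = 1e-12)
  }
})

test_that("the R and compiled likelihoods agree", {
  set.seed(8)
  eta <- rnorm(20, 0, 1)
  d <- sample(4:18, 20, replace = TRUE)
  s <- inverseLink("death", eta)
  expect_equal(dcinbreed:::obs_loglik_cpp(2L, as.numeric(d),
                                          integer(20), eta, 1, U, 19, 0L),
               loglikDeath(d, s), tolerance = 1e-12)
  afr <- sample(4:15, 20, replace = TRUE)
  expect_equal(dcinbreed:::obs_loglik_cpp(3L, as.numeric(afr),
                                          integer(20), eta, 1, U, 19, 0L),
               loglikAfr(afr, inverseLink("afr", eta)), tolerance = 1e-12)
  w <- sample(1:6, 20, replace = TRUE)
  expect_equal(dcinbreed:::obs_loglik_cpp(4L, as.numeric(w),
                                          integer(20), eta, 1, U, 19, 0L),
               loglikWait(w, inverseLink("wait", eta)), tolerance = 1e-12)
  y <- runif(20, 0, U - 0.01)
  mu <- runif(20, 0, 0.3)
  expect_equal(dcinbreed:::obs_loglik_cpp(1L, y, integer(20), mu, 0.05,
                                          U, 19, 0L),
               loglikRi(y, mu, 0.05), tolerance = 1e-10)
})

test_that("log prior enforces supports and matches closed forms", {
  spR <- modelSpec("ri", terms = "INB")
  pr <- priorSet()
  expect_identical(logPrior(spR, list(b0 = 0.5, b1 = 0), pr), -Inf)
  lp <- logPrior(spR, list(b0 = 0.1, sigmaR = 0.013), pr)
  expect_equal(lp - dnorm(0.1, 0, 100, log = TRUE), log(1 / (pi * 0.013)))
  lpF <- logPrior(spR, list(F = 0.5), pr, A = 1, B = 30)
  expect_equal(lpF, 29 * log(0.5) + log(30))
})

test_that("starting values respect supports and are reproducible", {
  pr <- priorSet()
  spR <- modelSpec("ri", terms = c("INB", "COL"), yearIntercept = TRUE)
  for (i in 1:50) {
    st <- drawStartValues(spR, pr, nYears = 5)
    expect_gt(st$b0, 0); expect_lt(st$b0, U)
    expect_gt(st$sigmaR, 0)
    expect_gt(st$sigmaGamma, 0)
  }
  spD <- modelSpec("death", terms = "INB", yearIntercept = TRUE,
                   yearSlope = TRUE)
  for (i in 1:20) {
    st <- drawStartValues(spD, pr, nYears = 5)
    expect_gt(st$sigmaTheta, 0); expect_lt(st$sigmaTheta, 10)
  }
  set.seed(99); a <- drawStartValues(spR, pr, 3)
  set.seed(99); b <- drawStartValues(spR, pr, 3)
  expect_identical(a, b)
})

test_that("natural-scale summaries invert the links", {
  f <- fakeFit("b0+b1INB", 3)
  f@family <- "wait"
  f@mle <- c(b0 = log(0.284 / 0.716), b1 = 0, b4 = log(2.08))
  f@covMle <- diag(1e-6, 3)
  dimnames(f@covMle) <- list(names(f@mle), names(f@mle))
  ns <- naturalScaleSummaries(f)
  expect_equal(ns$mean_wait_ratio, 1)        # b1 = 0
  expect_equal(ns$first_pup_multiplier, 2.08)
  expect_equal(ns$prob_repro_experienced, 0.716, tolerance = 1e-12)

  g <- fakeFit("b0+b1INB", 3)
  g@mle <- c(b0 = 0.1927, b1 = -0.1056)
  g@covMle <- diag(1e-6, 2)
  dimnames(g@covMle) <- list(names(g@mle), names(g@mle))
  ns2 <- naturalScaleSummaries(g)
  expect_equal(ns2$slope_per_deltaF, -0.0066, tolerance = 1e-2)
})

test_that("the cost of inbreeding reproduces the headline arithmetic", {
  expect_equal(costOfInbreeding(0.2, 0, 0.25)$delta, 0)
  cd <- costOfInbreeding(0.1927, -0.1056, c(0.0625, 0.25))
  expect_equal(cd$delta[2], 0.137, tolerance = 1e-3)
  expect_equal(cd$relative_fitness[1], 0.966, tolerance = 1e-3)
})

test_that("the errors-in-variables likelihood collapses to the plug-in
           likelihood as the Beta variance vanishes", {
  set.seed(12)
  n <- 6
  Fbar <- 0.08
  sc <- simScenario(nIndividuals = n, seed = 1)
  ri <- simGrowthRates(sc, rep(Fbar, n))
  spec <- modelSpec("ri", terms = "INB")
  params <- c(b0 = 0.19, b1 = -0.1, sigmaR = 0.05)
  plugin <- sum(loglikRi(ri$ri, 0.19 - 0.1 * Fbar, 0.05))
  for (conc in c(1e2, 1e4, 1e6)) {
    bp <- data.frame(id = ri$id, A = Fbar * conc, B = (1 - Fbar) * conc)
    md <- dcinbreed:::.buildModelData(spec, ri, bp)
    fit <- new("DCFit", family = "ri", spec = unclass(spec),
               cloneSchedule = 1, mle = params,
               covMle = diag(1e-6, 3), waldCI = cbind(0, 0), rhat = 1,
               diagnostics = list(), converged = TRUE,
               draws = matrix(0, 2, 2), perK = list(), data = md, n = n)
    ml <- marginalLoglik(fit, params)
    if (conc == 1e6) expect_equal(ml, plugin, tolerance = 1e-4)
    else expect_lt(abs(ml - plugin), abs(plugin) * 0.5 + 2)
  }
})
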