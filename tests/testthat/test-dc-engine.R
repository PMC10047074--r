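test_that("cloning replicates observations and only observations", {
  df <- data.frame(id = letters[1:3], y = 1:3)
  expect_equal(cloneDataset(df, 1)[, names(df)], df, ignore_attr = TRUE)
  c5 <- cloneDataset(df, 5)
  expect_equal(nrow(c5), 15)
  expect_equal(sort(unique(c5$clone)), 1:5)
  expect_error(cloneDataset(df, 0), "K")
})

test_that("Gelman-Rubin statistic separates mixed from disjoint chains", {
  x <- rnorm(200)
  # identical chains give the finite-sample floor sqrt((n-1)/n)
  expect_equal(gelmanRubin(list(x, x)), 1, tolerance = 0.01)
  set.seed(14)
  same <- lapply(1:3, function(i) rnorm(2000))
  expect_lt(gelmanRubin(same), 1.1)
  apart <- list(rnorm(200, 0), rnorm(200, 50))
  expect_gt(gelmanRubin(apart), 10)
  expect_error(gelmanRubin(list(x)), "two chains")
})

test_that("chains are bitwise reproducible given the seed", {
  set.seed(2)
  dat <- list(y = rnorm(12, 1, 2), X = matrix(1, 12, 1), sigma = 2)
  sp <- modelSpec("gaussian")
  mc <- mcmcConfig(chains = 2, iterations = 300, burnIn = 100, thin = 2,
                   seed = 5)
  a <- runChains(sp, dat, K = 2, mcmc = mc)
  b <- runChains(sp, dat, K = 2, mcmc = mc)
  expect_identical(a, b)
})

test_that("the conjugate normal-mean toy matches its closed form", {
  # flat prior, known sigma: posterior is N(ybar, sigma^2 / (K n))
  set.seed(31)
  n <- 10; sig <- 2
  y <- rnorm(n, 1.5, sig)
  dat <- list(y = y, X = matrix(1, n, 1), sigma = sig)
  mc <- mcmcConfig(chains = 3, iterations = 2500, burnIn = 500, thin = 1,
                   seed = 7)
  ch <- runChains(modelSpec("gaussian"), dat, K = 4, mcmc = mc)
  pooled <- do.call(rbind, ch)[, 1]
  chainMeans <- vapply(ch, function(m) mean(m[, 1]), numeric(1))
  mcse <- sd(chainMeans) / sqrt(length(chainMeans))
  expect_lt(abs(mean(pooled) - mean(y)), 3 * mcse + 0.01)
  expect_equal(var(pooled), sig^2 / (4 * n), tolerance = 0.2)
})

test_that("dcFit recovers ordinary least squares on a linear model", {
  set.seed(44)
  n <- 60
  x <- runif(n, -1, 1)
  X <- cbind(1, x)
  y <- 2 + 1.5 * x + rnorm(n, 0, 0.5)
  dat <- list(y = y, X = X, sigma = NA_real_)   # sigma estimated
  mc <- mcmcConfig(chains = 2, iterations = 3000, burnIn = 1000, thin = 2,
                   seed = 9)
  fit <- dcFit(modelSpec("gaussian"), dat, mcmc = mc, schedule = c(1, 40))
  ols <- unname(coef(lm(y ~ x)))
  expect_equal(unname(mle(fit)[1:2]), ols, tolerance = 0.01)
  expect_true(isConverged(fit))
  # scaled variance drops roughly linearly in log K
  expect_lt(fit@diagnostics$final_scaled_var, 0.2)
})

test_that("a non-identifiable parameter is flagged by the scaled
           variance", {
  set.seed(55)
  n <- 40
  X <- matrix(1, n, 2)  # two confounded intercepts
  y <- rnorm(n, 1, 1)
  # overdispersed starts expose the ridge: chains cannot agree on the
  # individual intercepts however many clones are added
  dat <- list(y = y, X = X, sigma = 1, startSd = 30)
  mc <- mcmcConfig(chains = 3, iterations = 2000, burnIn = 500, thin = 2,
                   seed = 10)
  fit <- dcFit(modelSpec("gaussian"), dat, mcmc = mc,
               schedule = c(1, 10, 40))
  expect_gte(fit@diagnostics$final_scaled_var, 0.05)
  expect_false(isConverged(fit))
})

test_that("Wald intervals follow the covariance and refuse bad fits", {
  f <- fakeFit("b0", 1)
  f@covMle <- matrix(0.01, 1, 1, dimnames = list("b0", "b0"))
  f@mle <- c(b0 = 0)
  ci <- waldCI(f)
  expect_equal(unname(ci[1, ]), c(-0.196, 0.196), tolerance = 1e-3)
  ci99 <- waldCI(f, level = 0.99)
  expect_lt(ci99[1, "lower"], ci[1, "lower"])
  expect_gt(ci99[1, "upper"], ci[1, "upper"])
  f@covMle <- matrix(0, 1, 1, dimnames = list("b0", "b0"))
  expect_equal(unname(waldCI(f)[1, ]), c(0, 0))
  bad <- fakeFit("b0", 1, converged = FALSE)
  expect_error(waldCI(bad), "converge")
  expect_silent(waldCI(bad, force = TRUE))
})

test_that("marginal likelihood matches brute-force quadrature for a
           Beta latent covariate", {
  spec <- modelSpec("ri", terms = "INB")
  dat <- data.frame(id = "i1", ri = 0.12, censored_at_max = FALSE,
                    col = 0, year = 1985)
  bp <- data.frame(id = "i1", A = 1, B = 30)
  md <- dcinbreed:::.buildModelData(spec, dat, bp)
  params <- c(b0 = 0.19, b1 = -0.5, sigmaR = 0.04)
  fit <- new("DCFit", family = "ri", spec = unclass(spec),
             cloneSchedule = 1, mle = params, covMle = diag(1e-6, 3),
             waldCI = cbind(0, 0), rhat = 1, diagnostics = list(),
             converged = TRUE, draws = matrix(0, 2, 2), perK = list(),
             data = md, n = 1)
  ml <- marginalLoglik(fit, params)
  # brute force: 10^6-point trapezoid over F on (0, 1)
  Fg <- seq(1e-9, 1 - 1e-9, length.out = 1e6)
  integrand <- exp(loglikRi(rep(0.12, length(Fg)), 0.19 - 0.5 * Fg, 0.04) +
                     dbeta(Fg, 1, 30, log = TRUE))
  brute <- log(pracma::trapz(Fg, integrand))
  expect_equal(ml, brute, tolerance = 1e-6)
})

test_that("marginal likelihood of a degenerate integration equals the
           direct sum and nesting never hurts the richest model", {
  set.seed(66)
  sc <- simScenario(nIndividuals = 40, seed = 67)
  F <- simInbreedingCoefficients(sc)
  ri <- simGrowthRates(sc, F)
  bp <- simBetaParams(F, nLoci = 50, seed = 68, ids = ri$id)
  mc <- quickMcmc(3, iterations = 900, burnIn = 300)
  f0 <- dcFit(modelSpec("ri"), ri, mcmc = mc, schedule = c(1, 20))
  f1 <- dcFit(modelSpec("ri", terms = "INB"), ri, betaParams = bp,
              mcmc = mc, schedule = c(1, 20))
  ll0 <- marginalLoglik(f0)
  expect_equal(ll0, sum(loglikRi(ri$ri, mle(f0)[["b0"]],
                                 mle(f0)[["sigmaR"]])), tolerance = 1e-10)
  ll1 <- marginalLoglik(f1)
  expect_gte(ll1, ll0 - 1e-3)
})

test_that("confidence and prediction bands nest and respect censoring", {
  set.seed(77)
  sc <- simScenario(nIndividuals = 60, seed = 78)
  F <- simInbreedingCoefficients(sc)
  ri <- simGrowthRates(sc, F)
  bp <- simBetaParams(F, nLoci = 50, seed = 79, ids = ri$id)
  fit <- dcFit(modelSpec("ri", terms = "INB"), ri, betaParams = bp,
               mcmc = quickMcmc(4, iterations = 900, burnIn = 300),
               schedule = c(1, 20))
  grid <- defaultFGrid(50)
  cb <- confidenceBand(fit, grid, draws = 2000, seed = 80)
  pb <- predictionBand(fit, grid, seed = 81,
                       mcmc = mcmcConfig(chains = 1, iterations = 10000,
                                         burnIn = 5000, thin = 5,
                                         seed = 81))
  expect_true(all(pb$lower <= cb$lower + 1e-9))
  expect_true(all(pb$upper >= cb$upper - 1e-9))
  U <- maxGrowthRateBound(19, 4)
  expect_true(all(pb$upper <= U + 1e-12))
  expect_equal(nrow(confidenceBand(fit, defaultFGrid(), draws = 100,
                                   seed = 2)), 1000)
  expect_true(all(defaultFGrid() > 0 & defaultFGrid() < 0.25))
  # a collapsed covariance collapses the band onto the fitted line
  fit0 <- fit
  fit0@covMle <- matrix(0, nrow(covMle(fit)), ncol(covMle(fit)),
                        dimnames = dimnames(covMle(fit)))
  cb0 <- confidenceBand(fit0, grid, draws = 200, seed = 3)
  expect_equal(cb0$lower, cb0$fit, tolerance = 1e-12)
  expect_equal(cb0$upper, cb0$fit, tolerance = 1e-12)
})
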